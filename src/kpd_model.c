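/* Compiled RHS of the nine-state tumor-immune K-PD system for deSolve.
 * State order: trt_ag, trt_pic, trt_apd1, apc, tr_pic, tr_apd1_1, tr_apd1_2,
 * cd8_act, ts. Parameter order must match kpd_parm_order in R/model-core.R. */
#include <R.h>

static double parms[9];
#define lam        parms[0]
#define k_ag       parms[1]
#define k_cd8      parms[2]
#define k_pic      parms[3]
#define k_apd1     parms[4]
#define theta_cd8  parms[5]
#define theta_pic  parms[6]
#define theta_apd1 parms[7]
#define resistance parms[8]

void kpd_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void kpd_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double e_pic  = 1.0 / (1.0 + theta_pic * y[4]);
    double e_apd1 = 1.0 + theta_apd1 * y[6];
    double res    = resistance / e_apd1;

    ydot[0] = -k_ag * y[0];
    ydot[1] = -k_pic * y[1];
    ydot[2] = -k_apd1 * y[2];
    ydot[3] = k_ag * y[0] - k_ag * y[3] * e_pic;
    ydot[4] = k_pic * y[1] - k_pic * y[4];
    ydot[5] = k_apd1 * y[2] - k_apd1 * y[5];
    ydot[6] = k_apd1 * y[5] - k_apd1 * y[6];
    ydot[7] = k_cd8 * y[3] * e_pic - k_cd8 * y[7] * e_pic * res;
    ydot[8] = lam * y[8] - theta_cd8 * y[7] * y[8] / res;
}
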