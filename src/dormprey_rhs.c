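/* Right-hand sides of the dormancy predator-prey model for deSolve.
 *
 * Parameter vector order must match PARAM_NAMES in R/params.R:
 *   r_p r_y K d_z alpha k_p k_y1 k_y2 c_p c_y1 c_y2 h_p h_y1 h_y2
 *   eta sigma chi phi
 *
 * Densities are clamped at zero only inside the functional responses and
 * the crowding term, mirroring the R implementation in R/model.R, so the
 * stored trajectory keeps raw solver output while the RHS stays smooth.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 18
static double parms[N_PARMS];

#define r_p   parms[0]
#define r_y   parms[1]
#define Kcap  parms[2]
#define d_z   parms[3]
#define alpha parms[4]
#define k_p   parms[5]
#define k_y1  parms[6]
#define k_y2  parms[7]
#define c_p   parms[8]
#define c_y1  parms[9]
#define c_y2  parms[10]
#define h_p   parms[11]
#define h_y1  parms[12]
#define h_y2  parms[13]
#define eta   parms[14]
#define sigma parms[15]
#define chi   parms[16]
#define phi   parms[17]

static double holling(double q, double c, double h)
{
    if (q < 0.0) q = 0.0;
    return c * q / (1.0 + c * h * q);
}

static double mu_switch(double z)
{
    double ex = (z - eta) / sigma;
    if (ex > 700.0) ex = 700.0;
    if (ex < -700.0) ex = -700.0;
    return chi + phi / (1.0 + exp(ex));
}

void dormprey_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void dormprey_rhs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double p = y[0], y1 = y[1], y2 = y[2], z = y[3];
    double zc = z > 0.0 ? z : 0.0;
    double pc = p > 0.0 ? p : 0.0;
    double y1c = y1 > 0.0 ? y1 : 0.0;

    double mu = mu_switch(zc);
    double crowd = 1.0 - (pc + y1c) / Kcap;
    double f_p = holling(pc, c_p, h_p);
    double f_1 = holling(y1c, c_y1, h_y1);
    double f_2 = holling(y2 > 0.0 ? y2 : 0.0, c_y2, h_y2);

    ydot[0] = r_p * crowd * p - f_p * z;
    ydot[1] = r_y * crowd * mu * y1 + alpha * y2 - f_1 * z;
    ydot[2] = r_y * crowd * (1.0 - mu) * y1 - alpha * y2 - f_2 * z;
    ydot[3] = k_p * f_p * z + k_y1 * f_1 * z + k_y2 * f_2 * z - d_z * z;
}
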