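/* Right-hand side of the coevolutionary predator-prey system, in the
 * deSolve compiled-model convention (initfunc + derivs).
 *
 * State: y[0] = x (prey biomass), y[1] = y (predator biomass),
 *        y[2] = u (defense),      y[3] = v (offense).
 *
 * Parameter vector (order fixed, see R/simulate.R):
 *   r0, K, a0, h, theta, g0, d, cx, cy, Gx, Gy, eps
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double parms[12];
#define P_r0    parms[0]
#define P_K     parms[1]
#define P_a0    parms[2]
#define P_h     parms[3]
#define P_theta parms[4]
#define P_g0    parms[5]
#define P_d     parms[6]
#define P_cx    parms[7]
#define P_cy    parms[8]
#define P_Gx    parms[9]
#define P_Gy    parms[10]
#define P_eps   parms[11]

void coevo_init(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

void coevo_derivs(int *neq, double *t, double *state, double *ydot,
                  double *yout, int *ip)
{
    double x = state[0], y = state[1], u = state[2], v = state[3];

    /* attack rate with clamped exponent so exp never overflows */
    double z = P_theta * (u - v);
    if (z > 700.0) z = 700.0;
    if (z < -700.0) z = -700.0;
    double a = P_a0 / (1.0 + exp(z));

    double r = P_r0 * exp(-P_cx * u * u);
    double g = P_g0 * exp(-P_cy * v * v);

    double den = 1.0 + a * P_h * x;
    double den2 = den * den;

    double Wx = r * (1.0 - x / P_K) - a * y / den;
    double Wy = g * a * x / den - P_d;

    /* d a / d u = -theta * a * (1 - a/a0); d a / d v is its negative */
    double a_u = -P_theta * a * (1.0 - a / P_a0);

    double dWx_du = -2.0 * P_cx * u * r * (1.0 - x / P_K) - y * a_u / den2;
    double dWy_dv = -2.0 * P_cy * v * g * a * x / den
                    + g * x * (-a_u) / den2;

    /* boundary factor exp(-eps/u) smoothly halts trait evolution at 0+ */
    double bu = (u > 0.0) ? exp(-P_eps / u) : 0.0;
    double bv = (v > 0.0) ? exp(-P_eps / v) : 0.0;

    /* biomass below zero is solver round-off; freeze it there instead of
     * letting W * y amplify the unphysical sign */
    ydot[0] = Wx * (x > 0.0 ? x : 0.0);
    ydot[1] = Wy * (y > 0.0 ? y : 0.0);
    ydot[2] = P_Gx * dWx_du * bu;
    ydot[3] = P_Gy * dWy_dv * bv;
}

static const R_CMethodDef cMethods[] = {
    {"coevo_init",   (DL_FUNC) &coevo_init,   1},
    {"coevo_derivs", (DL_FUNC) &coevo_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_coevocycles(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    /* deSolve resolves "coevo_derivs"/"coevo_init" by symbol lookup */
    R_useDynamicSymbols(dll, TRUE);
}
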