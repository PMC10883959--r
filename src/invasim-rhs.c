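/* Right-hand side of the three-species invasion model for deSolve.
 *
 * State y = (X, Y, Z): native prey, native specialist predator, exotic
 * generalist predator.  Parameter vector (set through initmod):
 *   parms = (r, s, K, c, n, b, d, p, q, alpha, beta)
 *
 * dX/dt = r X (1 - X/K) - d X Y - alpha d X Z
 * dY/dt = p d X Y - q Y - beta b Y Z
 * dZ/dt = s Z (1 - Z / kappa(X)) - b Z Y,   kappa(X) = n alpha d X + c
 *
 * Components in (-1e-9, 0) are treated as 0 (adaptive solvers overshoot;
 * densities are nonnegative by construction).  Any coordinate axis or
 * face {X=0}, {Y=0}, {Z=0} is exactly invariant.
 */

#include <R.h>

static double parms[11];
#define P_r     parms[0]
#define P_s     parms[1]
#define P_K     parms[2]
#define P_c     parms[3]
#define P_n     parms[4]
#define P_b     parms[5]
#define P_d     parms[6]
#define P_p     parms[7]
#define P_q     parms[8]
#define P_alpha parms[9]
#define P_beta  parms[10]

void invasim_initmod(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

static double clampz(double v)
{
    return (v < 0.0 && v > -1e-9) ? 0.0 : v;
}

void invasim_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double X = clampz(y[0]);
    double Y = clampz(y[1]);
    double Z = clampz(y[2]);
    double kap = P_n * P_alpha * P_d * X + P_c;

    ydot[0] = P_r * X * (1.0 - X / P_K) - P_d * X * Y - P_alpha * P_d * X * Z;
    ydot[1] = P_p * P_d * X * Y - P_q * Y - P_beta * P_b * Y * Z;
    ydot[2] = P_s * Z * (1.0 - Z / kap) - P_b * Z * Y;
}
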