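/* Compiled right-hand sides for deSolve (lsodar).
 *
 * Izhikevich neuron:
 *   v' = 0.04 v^2 + 5 v + 140 - u + I + A sin(2 pi f0 t)
 *   u' = a (b v - u)
 * with the variational (tangent) system driven by the Jacobian
 *   J = [[0.08 v + 5, -1], [a b, -a]]
 * when the state is augmented to 6 entries (Phi stored column-major).
 *
 * Parameter vector (via initfunc): a, b, I, A, f0, phase_origin.
 */
#include <R.h>
#include <math.h>

static double parms[6];
#define P_a  parms[0]
#define P_b  parms[1]
#define P_I  parms[2]
#define P_A  parms[3]
#define P_f0 parms[4]
#define P_ph parms[5]

void izh_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void izh_deriv(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double v = y[0], u = y[1];
    double s = P_A != 0.0 ? P_A * sin(2.0 * M_PI * P_f0 * (*t - P_ph)) : 0.0;

    ydot[0] = 0.04 * v * v + 5.0 * v + 140.0 - u + P_I + s;
    ydot[1] = P_a * (P_b * v - u);

    if (*neq == 6) {
        double j11 = 0.08 * v + 5.0;
        double j21 = P_a * P_b, j22 = -P_a;
        /* columns of Phi: (y2,y3) and (y4,y5) */
        ydot[2] = j11 * y[2] - y[3];
        ydot[3] = j21 * y[2] + j22 * y[3];
        ydot[4] = j11 * y[4] - y[5];
        ydot[5] = j21 * y[4] + j22 * y[5];
    }
}

/* Firing surface v = 30 mV */
void izh_root(int *neq, double *t, double *y, int *ng, double *gout)
{
    gout[0] = y[0] - 30.0;
}
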