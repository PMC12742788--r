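/* Swing-phase dynamics of the powered simplest walker, for deSolve's lsodar.
 *
 * State y = (theta, theta_dot, phi, phi_dot):
 *   theta  stance angle from vertical, phi swing angle from the stance leg.
 * Dimensionless: lengths / l, time / sqrt(l/g), masses / M.
 *
 * Stance:  theta'' = sin(theta)            (inverted pendulum; swing leg is
 *                                           massless in the m/M -> 0 limit)
 * Swing:   phi'' = theta'' + theta_dot^2 sin(phi) - cos(theta) sin(phi) - k phi
 * with k = k1 while phi > 0 (first half of swing) and k = k2 while phi <= 0.
 */
#include <R.h>
#include <math.h>

static double parms[2];
#define K1 parms[0]
#define K2 parms[1]

void walker_init(void (*odeparms)(int *, double *))
{
    int n = 2;
    odeparms(&n, parms);
}

void walker_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double th = y[0], thd = y[1], ph = y[2], phd = y[3];
    double thdd = sin(th);
    double k = (ph > 0.0) ? K1 : K2;
    ydot[0] = thd;
    ydot[1] = thdd;
    ydot[2] = phd;
    ydot[3] = thdd + thd * thd * sin(ph) - cos(th) * sin(ph) - k * ph;
}

/* Event functions monitored during a step (lsodar stops at the first zero):
 *  g0 spring switch           phi = 0
 *  g1 swing-foot contact      phi - 2 theta = 0 (accepted only with phi < 0)
 *  g2 fall forward            theta = +pi/2
 *  g3 fall backward           theta = -pi/2
 *  g4 stance-rate sign change theta_dot = 0 (rocking back when theta > 0)
 */
void walker_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip)
{
    gout[0] = y[2];
    gout[1] = y[2] - 2.0 * y[0];
    gout[2] = y[0] - M_PI_2;
    gout[3] = y[0] + M_PI_2;
    gout[4] = y[1];
}
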