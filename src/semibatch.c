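/* Right-hand side of the semi-batch transesterification reactor model,
 * in the compiled-function form expected by deSolve.
 *
 * State (8): TG, DG, MG, GL, MeOH, E1, E2, E3 (mol/L).
 * Parameters (15): k1..k6, inv_tau (= 1/residence time, 0 for closed batch),
 * feed concentrations of the 8 species.
 */
#include <R.h>

static double parms[15];

#define K1      parms[0]
#define K2      parms[1]
#define K3      parms[2]
#define K4      parms[3]
#define K5      parms[4]
#define K6      parms[5]
#define INV_TAU parms[6]
#define FEED(i) parms[7 + (i)]

void init_semibatch(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms);
}

void derivs_semibatch(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double c[8];
    int i;

    /* floor tolerance-level negative excursions for rate evaluation */
    for (i = 0; i < 8; i++)
        c[i] = (y[i] < 0.0 && y[i] > -1e-12) ? 0.0 : y[i];

    double r1 = K1 * c[0] * c[4] - K2 * c[1] * c[5];
    double r2 = K3 * c[1] * c[4] - K4 * c[2] * c[6];
    double r3 = K5 * c[2] * c[4] - K6 * c[3] * c[7];

    ydot[0] = -r1;             /* TG   */
    ydot[1] = r1 - r2;         /* DG   */
    ydot[2] = r2 - r3;         /* MG   */
    ydot[3] = r3;              /* GL   */
    ydot[4] = -r1 - r2 - r3;   /* MeOH */
    ydot[5] = r1;              /* E1   */
    ydot[6] = r2;              /* E2   */
    ydot[7] = r3;              /* E3   */

    for (i = 0; i < 8; i++)
        ydot[i] += INV_TAU * (FEED(i) - y[i]);
}
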