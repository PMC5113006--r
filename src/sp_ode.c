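/* Five-state mass-action Hoechst staining kinetics for one cell.
 *
 * States (uM): x1 cytosolic free, x2 DNA-bound (nuclear), x3 cytosolic
 * transporter-bound, x4 nuclear free, x5 nuclear transporter-bound.
 * Conserved totals enter algebraically: DNA = DNAT - x2, TC = TCA - x3,
 * TN = TNA - x5.
 *
 * Units: volumes pl, areas um^2, k3 amol/(uM um^2 min); amol/pl == uM, so
 * membrane fluxes divided by the receiving volume are uM/min.
 */
#include <R.h>

static double parms[13];
#define k1   parms[0]
#define koff parms[1]
#define k3   parms[2]
#define k4   parms[3]
#define k5   parms[4]
#define AC   parms[5]
#define VC   parms[6]
#define AN   parms[7]
#define VN   parms[8]
#define He   parms[9]
#define DNAT parms[10]
#define TCA  parms[11]
#define TNA  parms[12]

void sp_initmod(void (*odeparms)(int *, double *))
{
    int n = 13;
    odeparms(&n, parms);
}

void sp_derivs(int *neq, double *t, double *x, double *dx,
               double *yout, int *ip)
{
    double DNA = DNAT - x[1];
    double TC  = TCA - x[2];
    double TN  = TNA - x[4];

    double r1 = k3 * (AC / VC) * (He - x[0]); /* uM/min */
    double r2 = k1 * x[3] * DNA;
    double r3 = koff * x[1];
    double r4 = k4 * x[0] * TC;
    double r5 = k5 * x[2];
    double r6 = k3 * AN * (x[3] - x[0]);      /* amol/min, nucleus -> cytosol */
    double r7 = k4 * x[3] * TN;
    double r8 = k5 * x[4];

    dx[0] = r1 - r4 + r6 / VC + (VN / VC) * r8;
    dx[1] = r2 - r3;
    dx[2] = r4 - r5;
    dx[3] = -r2 + r3 - r6 / VN - r7;
    dx[4] = r7 - r8;
}
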