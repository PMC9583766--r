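/* Rate laws for the two-step FXIIa -> PK -> nHK proteolytic cascade,
 * in the deSolve compiled-model convention.  The state vector holds one
 * or more assays stacked in blocks of five species
 * (F12a, PK, PKa, nHK, cHK); all blocks share one parameter set, so a
 * whole multi-assay SSD evaluation is a single lsoda call.
 *
 * Parameter vector (9 doubles):
 *   kcat1, KM1, kcat2, KM2, mech1, KI1, mech2, KI2, decay_rate
 * Mechanism codes: 0 none, 1 competitive, 2 noncompetitive,
 * 3 uncompetitive, 4 as_printed (KM divided by 1 + [cHK]/KI,
 * reaction 1 only; identical to uncompetitive on KM but kcat kept).
 */

#include <R.h>

static double parms[9];
#define KCAT1 parms[0]
#define KM1   parms[1]
#define KCAT2 parms[2]
#define KM2   parms[3]
#define MECH1 parms[4]
#define KI1   parms[5]
#define MECH2 parms[6]
#define KI2   parms[7]
#define DECAY parms[8]

void cascade_init(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

static void apparent(int mech, double kcat, double km, double alpha,
                     double *kc, double *k)
{
    switch (mech) {
    case 1:  *kc = kcat;         *k = km * alpha; break; /* competitive   */
    case 2:  *kc = kcat / alpha; *k = km;         break; /* noncompetitive */
    case 3:  *kc = kcat / alpha; *k = km / alpha; break; /* uncompetitive */
    case 4:  *kc = kcat;         *k = km / alpha; break; /* as printed    */
    default: *kc = kcat;         *k = km;         break; /* none          */
    }
}

void cascade_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int nblock = *neq / 5;
    for (int b = 0; b < nblock; b++) {
        double *s = y + 5 * b;
        double *d = ydot + 5 * b;
        double F12a = s[0] > 0 ? s[0] : 0;
        double PK   = s[1] > 0 ? s[1] : 0;
        double PKa  = s[2] > 0 ? s[2] : 0;
        double nHK  = s[3] > 0 ? s[3] : 0;
        double cHK  = s[4] > 0 ? s[4] : 0;

        double a1 = (MECH1 > 0.5) ? 1.0 + cHK / KI1 : 1.0;
        double a2 = (MECH2 > 0.5) ? 1.0 + cHK / KI2 : 1.0;
        double kc1, k1, kc2, k2;
        apparent((int) MECH1, KCAT1, KM1, a1, &kc1, &k1);
        apparent((int) MECH2, KCAT2, KM2, a2, &kc2, &k2);

        double v1 = kc1 * F12a * PK / (PK + k1);
        double v2 = kc2 * PKa * nHK / (nHK + k2);

        d[0] = (DECAY > 0 && s[0] > 0) ? -DECAY : 0.0;
        d[1] = -v1;
        d[2] =  v1;
        d[3] = -v2;
        d[4] =  v2;
    }
}
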