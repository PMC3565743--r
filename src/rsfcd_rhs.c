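/* Compiled right-hand side of the closed-loop chemotaxis pathway for
 * deSolve.  Parameter vector layout (see .packParms in R/model.R):
 *  0 variant (1|2|3)   1 logAct (0|1)
 *  2..6  membrane cluster: N, alpha, m0, K_I, K_A
 *  7..11 cytoplasmic cluster: N, alpha, m0, K_I, K_A
 * 12..18 totals: A2, A34, Y3, Y4, Y6, B1, B2
 * 19 kAutoA2  20 kAutoA34
 * 21..25 kTransA2: Y3, Y4, Y6, B1, B2
 * 26..27 kTransA34: Y6, B2
 * 28..32 kDephos: Y3, Y4, Y6, B1, B2
 * 33..37 kR, kRt, kB1, kB2, kB2t
 * 38..40 memB1, memB2, cytB2 (0|1)
 * 41 tauLt  42 mLeak  43 L (segment-constant external ligand)
 *
 * State: y = (m, mt, [Lt if variant 2], A2p, A34p, Y3p, Y4p, Y6p, B1p, B2p)
 */
#include <R.h>
#include <math.h>

#define NPAR 44
static double p[NPAR];

void rsfcd_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static double mwc_activity(double m, double L, double N, double alpha,
                           double m0, double KI, double KA, int logact)
{
    double g = logact ? log(L / KI) : (log1p(L / KI) - log1p(L / KA));
    return 1.0 / (1.0 + exp(N * (g - alpha * (m - m0))));
}

void rsfcd_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int variant = (int) p[0];
    int logact = (int) p[1];
    int off = (variant == 2) ? 3 : 2;
    double m = y[0], mt = y[1];
    double A2p = y[off], A34p = y[off + 1];
    double Y3p = y[off + 2], Y4p = y[off + 3], Y6p = y[off + 4];
    double B1p = y[off + 5], B2p = y[off + 6];
    double L = p[43];
    double Lt;

    if (variant == 1)
        Lt = 10.0 * L / (10.0 + Y3p + Y4p);
    else if (variant == 2)
        Lt = y[2];
    else
        Lt = L;

    double a = mwc_activity(m, L, p[2], p[3], p[4], p[5], p[6], logact);
    double at = mwc_activity(mt, Lt, p[7], p[8], p[9], p[10], p[11], logact);

    double pY3 = p[14] - Y3p, pY4 = p[15] - Y4p, pY6 = p[16] - Y6p;
    double pB1 = p[17] - B1p, pB2 = p[18] - B2p;

    double out2 = p[21] * pY3 + p[22] * pY4 + p[23] * pY6 +
                  p[24] * pB1 + p[25] * pB2;
    double out34 = p[26] * pY6 + p[27] * pB2;

    double dA2p = p[19] * a * (p[12] - A2p) - A2p * out2;
    double dA34p = p[20] * at * (p[13] - A34p) - A34p * out34;
    double dY3p = p[21] * A2p * pY3 - p[28] * Y3p;
    double dY4p = p[22] * A2p * pY4 - p[29] * Y4p;
    double dY6p = (p[23] * A2p + p[26] * A34p) * pY6 - p[30] * Y6p;
    double dB1p = p[24] * A2p * pB1 - p[31] * B1p;
    double dB2p = (p[25] * A2p + p[27] * A34p) * pB2 - p[32] * B2p;

    double demMem = (p[38] != 0.0 ? p[35] * B1p : 0.0) +
                    (p[39] != 0.0 ? p[36] * B2p : 0.0);
    double dm = p[33] * (1.0 - a) - demMem * a - p[42] * m;
    double dmt = p[34] * (1.0 - at) -
                 (p[40] != 0.0 ? p[37] * B2p : 0.0) * at;

    ydot[0] = dm;
    ydot[1] = dmt;
    if (variant == 2) {
        ydot[2] = (L - y[2]) / p[41];
    }
    ydot[off] = dA2p;
    ydot[off + 1] = dA34p;
    ydot[off + 2] = dY3p;
    ydot[off + 3] = dY4p;
    ydot[off + 4] = dY6p;
    ydot[off + 5] = dB1p;
    ydot[off + 6] = dB2p;
}
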