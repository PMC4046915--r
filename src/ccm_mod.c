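/* Compiled right-hand side of the extended E. coli central carbon
 * metabolism model, in the deSolve compiled-model convention.
 *
 * Parameter vector layout (must match oscimet:::ccm_parms_vector):
 *   [0]   mu            specific growth rate, 1/s
 *   [1]   feed_glcex    constant glucose inflow, mM/s (= mu * c_feed)
 *   [2]   pts_scale     reactor -> cytosol flux conversion for PTS
 *   [3..9]   co-metabolites: atp, adp, amp, nadp, nadph, nad, nadh (mM)
 *   [10..129] kinetic constants, reaction blocks in model order
 *   [130..385] forcing table, 32 rows x 8:
 *             kind (0 const, 1 cosine, 2 square), A, omega, phi, h,
 *             e_min, e_max, inverted (0/1)
 */

#include <R.h>
#include <math.h>
#include <R_ext/Rdynload.h>

#define NSTATE 18
#define NREACT 32
#define NPARMS 386
#define FORC0  130

static double parms[NPARMS];

void oscimet_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double enzyme_level(int j, double t)
{
    const double *f = parms + FORC0 + 8 * j;
    double kind = f[0], A = f[1], om = f[2], phi = f[3], h = f[4];
    double emin = f[5], emax = f[6];
    double osc, raw;
    if (kind == 0.0)
        return h;                      /* constants are not clamped */
    osc = cos(om * t + phi);
    if (kind == 2.0)
        osc = (osc > 0) - (osc < 0);   /* square wave, 50% duty */
    raw = f[7] != 0.0 ? h - A * osc : h + A * osc;
    if (raw < emin) raw = emin;
    if (raw > emax) raw = emax;
    return raw;
}

void oscimet_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double mu = parms[0], feed = parms[1], scale = parms[2];
    double atp = parms[3], adp = parms[4], amp = parms[5], nadp = parms[6],
           nadph = parms[7], nad = parms[8], nadh = parms[9];
    const double *k = parms;  /* absolute offsets below */
    double yc[NSTATE], r[NREACT], e[NREACT];
    double pr, a1, b1, x;
    int i;

    for (i = 0; i < NSTATE; i++)
        yc[i] = y[i] > 0 ? y[i] : 0;
    for (i = 0; i < NREACT; i++)
        e[i] = enzyme_level(i, *t);

    {
        double glcex = yc[0], g6p = yc[1], f6p = yc[2], fdp = yc[3],
               gap = yc[4], dhap = yc[5], pgp = yc[6], pg3 = yc[7],
               pg2 = yc[8], pep = yc[9], pyr = yc[10], pg6 = yc[11],
               ribu5p = yc[12], xyl5p = yc[13], sed7p = yc[14],
               rib5p = yc[15], e4p = yc[16], g1p = yc[17];

        pr = pyr > 0 ? pep / pyr : 0.0;
        /* PTS: k[10] rmax, Ka1, Ka2, Ka3, Kg6p, n */
        r[0] = scale * k[10] * glcex * pr /
            ((k[11] + k[12] * pr + k[13] * glcex + glcex * pr) *
             (1 + pow(g6p, k[15]) / k[14]));
        /* PGI: k[16] rmax, Keq, Kg6p, Kf6p, Kf6p_6pginh, Kg6p_6pginh */
        r[1] = k[16] * (g6p - f6p / k[17]) /
            (k[18] * (1 + f6p / (k[19] * (1 + pg6 / k[20])) + pg6 / k[21]) + g6p);
        /* PGM: k[22] rmax, Keq, Kg6p, Kg1p */
        r[2] = k[22] * (g6p - g1p / k[23]) /
            (k[24] * (1 + g1p / k[25]) + g6p);
        /* G6PDH: k[26] rmax, Kg6p, Knadp, Knadph_g6pinh, Knadph_nadpinh */
        r[3] = k[26] * g6p * nadp /
            ((g6p + k[27]) * (1 + nadph / k[29]) *
             (k[28] * (1 + nadph / k[30]) + nadp));
        /* PFK: k[31] rmax, Katp_s, Kadp_c, Kf6p_s, Kpep, Kadp_b, Kamp_b,
                 Kadp_a, Kamp_a, L, n */
        a1 = 1 + adp / k[38] + amp / k[39];
        b1 = 1 + pep / k[35] + adp / k[36] + amp / k[37];
        r[4] = k[31] * atp * f6p /
            ((atp + k[32] * (1 + adp / k[33])) *
             (f6p + k[34] * b1 / a1) *
             (1 + k[40] / pow(1 + f6p * a1 / (k[34] * b1), k[41])));
        /* TA: k[42] rmax, Keq */
        r[5] = k[42] * (gap * sed7p - e4p * f6p / k[43]);
        /* TKA: k[44] rmax, Keq */
        r[6] = k[44] * (rib5p * xyl5p - sed7p * gap / k[45]);
        /* TKB: k[46] rmax, Keq */
        r[7] = k[46] * (xyl5p * e4p - f6p * gap / k[47]);
        /* MURSYNTH: k[48] rmax */
        r[8] = k[48];
        /* ALDO: k[49] rmax, Keq, Kfdp, Kgap, Kdhap, Kgapinh, blf */
        r[9] = k[49] * (fdp - gap * dhap / k[50]) /
            (k[51] + fdp + k[52] * dhap / (k[50] * k[55]) +
             k[53] * gap / (k[50] * k[55]) + fdp * gap / k[54] +
             gap * dhap / (k[50] * k[55]));
        /* GAPDH: k[56] rmax, Keq, Kgap, Kpgp, Knad, Knadh */
        r[10] = k[56] * (gap * nad - pgp * nadh / k[57]) /
            ((k[58] * (1 + pgp / k[59]) + gap) *
             (k[60] * (1 + nadh / k[61]) + nad));
        /* TIS: k[62] rmax, Keq, Kdhap, Kgap */
        r[11] = k[62] * (dhap - gap / k[63]) /
            (k[64] * (1 + gap / k[65]) + dhap);
        /* TRPSYNTH: k[66] rmax */
        r[12] = k[66];
        /* G3PDH: k[67] rmax, Kdhap */
        r[13] = k[67] * dhap / (k[68] + dhap);
        /* PGK: k[69] rmax, Keq, Kadp, Katp, Kpgp, Kpg3 */
        r[14] = k[69] * (adp * pgp - atp * pg3 / k[70]) /
            ((k[71] * (1 + atp / k[72]) + adp) *
             (k[73] * (1 + pg3 / k[74]) + pgp));
        /* SER: k[75] rmax, Kpg3 */
        r[15] = k[75] * pg3 / (k[76] + pg3);
        /* PGLUMU: k[77] rmax, Keq, Kpg3, Kpg2 */
        r[16] = k[77] * (pg3 - pg2 / k[78]) /
            (k[79] * (1 + pg2 / k[80]) + pg3);
        /* ENO: k[81] rmax, Keq, Kpg2, Kpep */
        r[17] = k[81] * (pg2 - pep / k[82]) /
            (k[83] * (1 + pep / k[84]) + pg2);
        /* PK: k[85] rmax, Kpep, Kadp, Katp, Kfdp, Kamp, L, n */
        x = pep / k[86] + 1;
        r[18] = k[85] * pep * pow(x, k[92] - 1) * adp /
            (k[86] *
             (k[91] * pow((1 + atp / k[88]) /
                          (fdp / k[89] + amp / k[90] + 1), k[92]) +
              pow(x, k[92])) *
             (adp + k[87]));
        /* PEPC: k[93] rmax, Kpep, Kfdp, n */
        r[19] = k[93] * pep * (1 + pow(fdp / k[95], k[96])) / (k[94] + pep);
        /* SYN1: k[97] rmax, Kpep */
        r[20] = k[97] * pep / (k[98] + pep);
        /* SYN2: k[99] rmax, Kpyr */
        r[21] = k[99] * pyr / (k[100] + pyr);
        /* DAHPS: k[101] rmax, Ke4p, Kpep, ne4p, npep */
        r[22] = k[101] * pow(e4p, k[104]) * pow(pep, k[105]) /
            ((k[102] + pow(e4p, k[104])) * (k[103] + pow(pep, k[105])));
        /* PDH: k[106] rmax, Kpyr, n */
        r[23] = k[106] * pow(pyr, k[108]) / (k[107] + pow(pyr, k[108]));
        /* METSYNTH: k[109] rmax */
        r[24] = k[109];
        /* PGDH: k[110] rmax, Kpg6, Knadp, Knadphinh, Katpinh */
        r[25] = k[110] * pg6 * nadp /
            ((pg6 + k[111]) *
             (nadp + k[112] * (1 + nadph / k[113]) * (1 + atp / k[114])));
        /* R5PI: k[115] rmax, Keq */
        r[26] = k[115] * (ribu5p - rib5p / k[116]);
        /* RU5P: k[117] rmax, Keq */
        r[27] = k[117] * (ribu5p - xyl5p / k[118]);
        /* RPPK: k[119] rmax, Krib5p */
        r[28] = k[119] * rib5p / (k[120] + rib5p);
        /* G1PAT: k[121] rmax, Kg1p, Katp, Kfdp, n */
        r[29] = k[121] * g1p * atp * (1 + pow(fdp / k[124], k[125])) /
            ((k[123] + atp) * (k[122] + g1p));
        /* PPS: k[126] rmax, Kpyr */
        r[30] = k[126] * pyr / (k[127] + pyr);
        /* FBP: k[128] rmax, Kfdp */
        r[31] = k[128] * fdp / (k[129] + fdp);
    }

    for (i = 0; i < NREACT; i++)
        r[i] *= e[i];

    ydot[0]  = feed - r[0] / scale - mu * y[0];
    ydot[1]  = r[0] - r[1] - r[2] - r[3] - mu * y[1];
    ydot[2]  = r[1] + r[5] + r[7] + r[31] - r[4] - 2 * r[8] - mu * y[2];
    ydot[3]  = r[4] - r[9] - r[31] - mu * y[3];
    ydot[4]  = r[9] + r[11] + r[6] + r[7] + r[12] - r[5] - r[10] - mu * y[4];
    ydot[5]  = r[9] - r[11] - r[13] - mu * y[5];
    ydot[6]  = r[10] - r[14] - mu * y[6];
    ydot[7]  = r[14] - r[16] - r[15] - mu * y[7];
    ydot[8]  = r[16] - r[17] - mu * y[8];
    ydot[9]  = r[17] + r[30] - r[0] - r[18] - r[19] - r[20] - r[22] - mu * y[9];
    ydot[10] = r[0] + r[18] + r[24] + r[12] - r[23] - r[21] - r[30] - mu * y[10];
    ydot[11] = r[3] - r[25] - mu * y[11];
    ydot[12] = r[25] - r[26] - r[27] - mu * y[12];
    ydot[13] = r[27] - r[6] - r[7] - mu * y[13];
    ydot[14] = r[6] - r[5] - mu * y[14];
    ydot[15] = r[26] - r[6] - r[28] - mu * y[15];
    ydot[16] = r[5] - r[7] - r[22] - mu * y[16];
    ydot[17] = r[2] - r[29] - mu * y[17];
}

static const R_CMethodDef CEntries[] = {
    {"oscimet_initmod", (DL_FUNC) &oscimet_initmod, 1},
    {"oscimet_derivs",  (DL_FUNC) &oscimet_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_oscimet(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
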