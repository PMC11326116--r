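/* Compiled right-hand sides for the coculture ODEs, in the deSolve
 * compiled-model convention (initfunc fills a static parameter block,
 * derivs evaluates the rates). Must mirror the reference R implementations
 * in R/model.R exactly; a test asserts agreement on random states.
 *
 * Full-model parameter block layout (length 59):
 *   0-2   mu[B,Y,T]            3-5   death[B,Y,T]
 *   6-20  K[pop][L,W,U,H,G]    21-35 u[pop][L,W,U,H,G]
 *   36 sec_Y_L   37 sec_B_W   38 tau_loc   39 k_a   40 k_d
 *   41 gamma_f   42 gamma_c   43 P         44 per_total(0/1)
 *   45 volume    46 boost_L(0/1)
 *   47-58 required-nutrient masks req[pop][L,W,U,H] (0/1)
 * State: B_f,B_c,Y_f,Y_c,T_f,T_c,n_L,n_W,n_U,n_H,n_G,T_cum
 */
#include <R.h>

#define NP_FULL 59
static double p[NP_FULL];

void idc_initmod(void (*odeparms)(int *, double *))
{
    int n = NP_FULL;
    odeparms(&n, p);
}

static double pos(double x) { return x > 0 ? x : 0; }

void idc_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double B_f = pos(y[0]), B_c = pos(y[1]);
    double Y_f = pos(y[2]), Y_c = pos(y[3]);
    double T_f = pos(y[4]), T_c = pos(y[5]);
    double n[4], n_eff[4], n_G = pos(y[10]);
    int i;
    for (i = 0; i < 4; i++) n[i] = n_eff[i] = pos(y[6 + i]);

    double sec_Y_L = p[36], sec_B_W = p[37], tau = p[38];
    double ka = p[39], kd = p[40], g_f = p[41], g_c = p[42], P = p[43];
    int per_total = p[44] != 0;
    double vol = p[45];

    if (p[46] != 0)  /* proximity boost on clump-local leucine */
        n_eff[0] = n[0] + P * sec_Y_L * (Y_c + T_c) * tau;

    const double *KB = p + 6, *KY = p + 11, *KT = p + 16;
    const double *uB = p + 21, *uY = p + 26, *uT = p + 31;
    const double *reqB = p + 47, *reqY = p + 51, *reqT = p + 55;

    double fB_f = n_G / (KB[4] + n_G), fB_c = fB_f;
    double fY = n_G / (KY[4] + n_G), fT = n_G / (KT[4] + n_G);
    for (i = 0; i < 4; i++) {
        if (reqB[i] != 0) {
            fB_f *= n[i] / (KB[i] + n[i]);
            fB_c *= n_eff[i] / (KB[i] + n_eff[i]);
        }
        if (reqY[i] != 0) fY *= n[i] / (KY[i] + n[i]);
        if (reqT[i] != 0) fT *= n[i] / (KT[i] + n[i]);
    }
    double gB_f = p[0] * fB_f, gB_c = p[0] * fB_c;
    double gY = p[1] * fY, gT = p[2] * fT;

    double partner_Y = Y_f + Y_c + T_f + T_c;
    double partner_B = B_f + B_c;
    double assoc_B = ka * B_f * partner_Y;
    double assoc_Y = ka * partner_B * Y_f;
    double assoc_T = ka * partner_B * T_f;

    double rate_f = 0, rate_c = 0;
    if (g_f > 0 && B_f > 0 && Y_f > 0)
        rate_f = per_total ? g_f * B_f * Y_f / (B_f + Y_f + T_f)
                           : g_f * B_f * Y_f / vol;
    if (g_c > 0 && B_c > 0 && Y_c > 0)
        rate_c = per_total ? g_c * B_c * Y_c / (B_c + Y_c + T_c)
                           : g_c * B_c * Y_c / vol;

    double dn[4];
    dn[0] = sec_Y_L * (Y_f + Y_c + T_f + T_c);
    dn[1] = sec_B_W * (B_f + B_c);
    dn[2] = 0; dn[3] = 0;
    for (i = 0; i < 4; i++) {
        if (reqB[i] != 0) {
            double share = n_eff[i] > 0 ? n[i] / n_eff[i] : 0;
            dn[i] -= uB[i] * (gB_f * B_f + gB_c * B_c * share);
        }
        if (reqY[i] != 0) dn[i] -= uY[i] * gY * (Y_f + Y_c);
        if (reqT[i] != 0) dn[i] -= uT[i] * gT * (T_f + T_c);
    }
    double dn_G = -(uB[4] * (gB_f * B_f + gB_c * B_c) +
                    uY[4] * gY * (Y_f + Y_c) + uT[4] * gT * (T_f + T_c));

    double dB = p[3], dY = p[4], dT = p[5];
    ydot[0] = gB_f * B_f - dB * B_f - assoc_B + kd * B_c;
    ydot[1] = gB_c * B_c - dB * B_c + assoc_B - kd * B_c;
    ydot[2] = gY * Y_f - dY * Y_f - assoc_Y + kd * Y_c - rate_f;
    ydot[3] = gY * Y_c - dY * Y_c + assoc_Y - kd * Y_c - rate_c;
    ydot[4] = gT * T_f - dT * T_f - assoc_T + kd * T_c + rate_f;
    ydot[5] = gT * T_c - dT * T_c + assoc_T - kd * T_c + rate_c;
    for (i = 0; i < 4; i++) ydot[6 + i] = dn[i];
    ydot[10] = dn_G;
    ydot[11] = rate_f + rate_c;
}

/* Reduced two-population model.
 * Parameter block (length 34):
 *   0 mu_B  1 mu_Y  2 death_B  3 death_Y
 *   4-13  K[B][L,W,U,H,G], K[Y][...]
 *   14-23 u[B][...], u[Y][...]
 *   24 sec_Y_L  25 sec_B_W
 *   26-33 req masks B[L,W,U,H], Y[L,W,U,H]
 * State: B, Y, n_L, n_W, n_U, n_H, n_G
 */
#define NP_RED 34
static double q[NP_RED];

void idc_reduced_initmod(void (*odeparms)(int *, double *))
{
    int n = NP_RED;
    odeparms(&n, q);
}

void idc_reduced_derivs(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double B = pos(y[0]), Y = pos(y[1]);
    double n[4], n_G = pos(y[6]);
    int i;
    for (i = 0; i < 4; i++) n[i] = pos(y[2 + i]);

    const double *KB = q + 4, *KY = q + 9, *uB = q + 14, *uY = q + 19;
    const double *reqB = q + 26, *reqY = q + 30;

    double fB = n_G / (KB[4] + n_G), fY = n_G / (KY[4] + n_G);
    for (i = 0; i < 4; i++) {
        if (reqB[i] != 0) fB *= n[i] / (KB[i] + n[i]);
        if (reqY[i] != 0) fY *= n[i] / (KY[i] + n[i]);
    }
    double gB = q[0] * fB, gY = q[1] * fY;

    double dn[4];
    dn[0] = q[24] * Y; dn[1] = q[25] * B; dn[2] = 0; dn[3] = 0;
    for (i = 0; i < 4; i++) {
        if (reqB[i] != 0) dn[i] -= uB[i] * gB * B;
        if (reqY[i] != 0) dn[i] -= uY[i] * gY * Y;
    }
    ydot[0] = gB * B - q[2] * B;
    ydot[1] = gY * Y - q[3] * Y;
    for (i = 0; i < 4; i++) ydot[2 + i] = dn[i];
    ydot[6] = -(uB[4] * gB * B + uY[4] * gY * Y);
}

/* direct .C entry point used by the test suite to compare the compiled
 * derivatives against the reference R implementation */
void idc_derivs_check(double *parms, double *y, double *out)
{
    int i, neq = 12, ip = 0;
    double t = 0, yout = 0;
    for (i = 0; i < NP_FULL; i++) p[i] = parms[i];
    idc_derivs(&neq, &t, y, out, &yout, &ip);
}
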