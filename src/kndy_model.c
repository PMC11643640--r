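/* Compiled right-hand side of the KNDy neuron model for deSolve.
 *
 * State vector y (length 16):
 *   0: V (mV)
 *   1..12: gates mNaT hNaT pNaP mA hA bBK rh wM mT hT mCa hCa
 *   13: Ca (uM)   14: a_NKB   15: a_Dyn
 *
 * Parameter vector (length 139): 35 scalars, 12 gates x 8 fields, then 8
 * per-segment stimulus controls appended by the R driver. The ordering is
 * defined once in R/params.R (.kndy_scalars, .kndy_gates, .kndy_gate_fields)
 * and must match the #defines below.
 *
 * Output vector yout (length 13): the 12 ionic currents (pA, outward
 * positive) followed by their sum.
 */

#include <R.h>
#include <math.h>

#define N_PARMS 139
#define N_SCAL  35

static double parms[N_PARMS];
static double forcs[1]; /* additive noise current (pA), current clamp only */

/* scalar parameters */
#define G_NAT   parms[0]
#define G_NAP   parms[1]
#define G_A     parms[2]
#define G_BK    parms[3]
#define G_H     parms[4]
#define G_SK    parms[5]
#define G_M     parms[6]
#define G_T     parms[7]
#define G_CA    parms[8]
#define G_TRPC5 parms[9]
#define G_GIRK  parms[10]
#define G_LEAK  parms[11]
#define E_NA    parms[12]
#define E_K     parms[13]
#define E_CA    parms[14]
#define E_H     parms[15]
#define E_TRPC5 parms[16]
#define E_LEAK  parms[17]
#define CM      parms[18]
#define CA_REST parms[19]
#define TAU_CA  parms[20]
#define ALPHA_CA parms[21]
#define F_TRPC5 parms[22]
#define K_SK    parms[23]
#define N_SK    parms[24]
#define K_T5    parms[25]
#define N_T5    parms[26]
#define C_BASE  parms[27]
#define BK_SHIFT parms[28]
#define GIRK_VR parms[29]
#define GIRK_KR parms[30]
#define TAU_NKB_RISE  parms[31]
#define TAU_NKB_DECAY parms[32]
#define TAU_DYN_RISE  parms[33]
#define TAU_DYN_DECAY parms[34]

/* gate parameter accessors: gate index 0..11, field 0..7
 * fields: 0 vh, 1 k, 2 exp, 3 floor, 4 tau_min, 5 tau_amp, 6 tau_vh, 7 tau_k */
#define GP(i, f) parms[N_SCAL + 8 * (i) + (f)]

/* segment stimulus controls */
#define SEG_MODE   parms[131] /* 0 current clamp, 1 voltage clamp */
#define SEG_BASE   parms[132] /* pA */
#define SEG_RATE   parms[133] /* pA/s */
#define SEG_T0     parms[134] /* ms */
#define SEG_NKB    parms[135]
#define SEG_DYN    parms[136]
#define SEG_CACL   parms[137] /* 1 = clamp calcium at its current value */
#define SEG_NOISE  parms[138] /* 1 = add forcing noise current */

void kndy_initparms(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void kndy_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forcs);
}

static double hill(double x, double K, double n)
{
    double xn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    return xn / (xn + pow(K, n));
}

static double gate_pow(double x, double e)
{
    if (x < 0.0) x = 0.0;
    if (e == 1.0) return x;
    if (e == 2.0) return x * x;
    if (e == 3.0) return x * x * x;
    if (e == 4.0) return x * x * x * x;
    return pow(x, e);
}

void kndy_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double V = y[0];
    double ca = y[13] > 1e-6 ? y[13] : 1e-6;
    double I[12], Itot = 0.0;
    int i;

    if (ip[0] < 13)
        error("nout should be at least 13");

    /* gate kinetics */
    for (i = 0; i < 12; i++) {
        double vh = GP(i, 0), k = GP(i, 1), fl = GP(i, 3);
        double tau = GP(i, 4) + GP(i, 5) / cosh((V - GP(i, 6)) / GP(i, 7));
        double xinf;
        if (i == 5) /* bBK: calcium-shifted midpoint */
            vh += BK_SHIFT * log10(ca / CA_REST);
        xinf = fl + (1.0 - fl) / (1.0 + exp((vh - V) / k));
        ydot[1 + i] = (xinf - y[1 + i]) / tau;
    }

    {
        double mNaT = gate_pow(y[1], GP(0, 2)), hNaT = gate_pow(y[2], GP(1, 2));
        double pNaP = gate_pow(y[3], GP(2, 2));
        double mA = gate_pow(y[4], GP(3, 2)), hA = gate_pow(y[5], GP(4, 2));
        double bBK = gate_pow(y[6], GP(5, 2));
        double rh = gate_pow(y[7], GP(6, 2)), wM = gate_pow(y[8], GP(7, 2));
        double mT = gate_pow(y[9], GP(8, 2)), hT = gate_pow(y[10], GP(9, 2));
        double mCa = gate_pow(y[11], GP(10, 2)), hCa = gate_pow(y[12], GP(11, 2));
        double sk_o = hill(ca, K_SK, N_SK);
        double t5_o = (C_BASE + (1.0 - C_BASE) * y[14]) * hill(ca, K_T5, N_T5);
        double girk_r = 1.0 / (1.0 + exp((V - GIRK_VR) / GIRK_KR));

        I[0]  = G_NAT * mNaT * hNaT * (V - E_NA);
        I[1]  = G_NAP * pNaP * (V - E_NA);
        I[2]  = G_A * mA * hA * (V - E_K);
        I[3]  = G_BK * bBK * (V - E_K);
        I[4]  = G_H * rh * (V - E_H);
        I[5]  = G_SK * sk_o * (V - E_K);
        I[6]  = G_M * wM * (V - E_K);
        I[7]  = G_T * mT * hT * (V - E_CA);
        I[8]  = G_CA * mCa * hCa * (V - E_CA);
        I[9]  = G_TRPC5 * t5_o * (V - E_TRPC5);
        I[10] = G_GIRK * y[15] * girk_r * (V - E_K);
        I[11] = G_LEAK * (V - E_LEAK);
    }
    for (i = 0; i < 12; i++) {
        Itot += I[i];
        yout[i] = I[i];
    }
    yout[12] = Itot;

    /* calcium */
    if (SEG_CACL > 0.5) {
        ydot[13] = 0.0;
    } else {
        double influx = -ALPHA_CA * (I[7] + I[8] + F_TRPC5 * I[9]);
        ydot[13] = influx - (y[13] - CA_REST) / TAU_CA;
    }

    /* receptor drives */
    ydot[14] = (SEG_NKB - y[14]) /
        (SEG_NKB > y[14] ? TAU_NKB_RISE : TAU_NKB_DECAY);
    ydot[15] = (SEG_DYN - y[15]) /
        (SEG_DYN > y[15] ? TAU_DYN_RISE : TAU_DYN_DECAY);

    /* membrane potential */
    if (SEG_MODE > 0.5) {
        ydot[0] = 0.0; /* voltage clamp: V pinned by the driver */
    } else {
        double Iinj = SEG_BASE + SEG_RATE * (*t - SEG_T0) / 1000.0;
        if (SEG_NOISE > 0.5) Iinj += forcs[0];
        ydot[0] = (-Itot + Iinj) / CM;
    }
}
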