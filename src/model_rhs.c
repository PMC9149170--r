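/* Compiled right-hand side of the proteome-dependent kinetic model.
 *
 * Mirrors R/balances.R + R/rates.R exactly; the test suite asserts
 * agreement between the two implementations on random states. Used
 * through deSolve's compiled-model interface (initfunc "protalloc_init",
 * func "protalloc_derivs").
 *
 * Parameter vector layout: see param_vector() in R/params.R. The dilution
 * rate is constant per integration leg; feast/famine feeding is handled
 * by piecewise integration at the R level.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 69
static double p[NPAR];

/* parameter indices (0-based) */
#define PHI(i)      p[(i)]        /* 9 sector fractions            */
#define KCAT(i)     p[9 + (i)]    /* 9 specific activities         */
#define EC_MID      p[18]
#define EC_SLOPE    p[19]
#define KM_GLC_UPT  p[20]
#define KM_ATP_UPT  p[21]
#define KM_G6P_UGLC p[22]
#define KM_ATP_UGLC p[23]
#define KM_FBP_LGLC p[24]
#define KM_NAD_LGLC p[25]
#define KM_PI_LGLC  p[26]
#define KM_ADP_LGLC p[27]
#define KM_PYR_FERM p[28]
#define KM_NADH_FERM p[29]
#define KM_FBP_ESNK p[30]
#define KM_NADH_ESNK p[31]
#define KM_PYR_TCA  p[32]
#define KM_ADP_TCA  p[33]
#define KM_NADH_NDE p[34]
#define KM_ADP_NDE  p[35]
#define KM_PI_RESP  p[36]
#define KM_ATP_TRSN p[37]
#define KM_TRE_TRDG p[38]
#define KM_ATP_TRDG p[39]
#define KM_G6P_GRWT p[40]
#define KM_PYR_GRWT p[41]
#define KA_FBP_FERM p[42]
#define KA_G6P_TRSN p[43]
#define KA_AMP_UGLC p[44]
#define KI_G6P_UPT  p[45]
#define KI_PYR_LGLC p[46]
#define H_PYR_FERM  p[47]
#define H_FBP_FERM  p[48]
#define H_G6P_TRSN  p[49]
#define MNT_RATE    p[50]
#define KM_ATP_MNT  p[51]
#define PO_RATIO    p[52]
#define W_TCA       p[53]
#define A_TCA       p[54]
#define G6P_PER_X   p[55]
#define PYR_PER_X   p[56]
#define ATP_PER_X   p[57]
#define NADH_PER_X  p[58]
#define CO2_PER_X   p[59]
#define G_PER_CMOL  p[60]
#define K_AK        p[61]
#define K_AK_RELAX  p[62]
#define DRATE       p[63]
#define GLC_FEED    p[64]
#define CLAMP_GLC   p[65]
#define GLC_CLAMP   p[66]
#define CLAMP_TRE   p[67]
#define TRE_CLAMP   p[68]

/* sector indices */
enum { S_UPT, S_UGLC, S_LGLC, S_FERM, S_ESNK, S_RESP, S_TRSN, S_TRDG,
       S_GRWT };
/* state indices */
enum { I_GLC, I_G6P, I_FBP, I_PYR, I_ATP, I_ADP, I_AMP, I_NAD, I_NADH,
       I_PI, I_TRE, I_ETOH, I_GLYC, I_X };

void protalloc_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static double mm(double x, double k)
{
    return (x > 0.0) ? x / (x + k) : 0.0;
}

static double hillf(double x, double k, double n)
{
    double xn, kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n);
    kn = pow(k, n);
    return xn / (xn + kn);
}

void protalloc_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double s[14];
    double v[11]; /* Upt UGlc LGlc Ferm Esnk TCA NDE TrSn TrDg Grwt Mnt */
    double glc, ec, sigma, cap, v_tca, v_nde, load, mu, conv, vak, X;
    double d[14];
    int i;

    if (ip[0] < 15) error("nout too small");

    for (i = 0; i < 14; i++) s[i] = (y[i] > 0.0) ? y[i] : 0.0;
    glc = (CLAMP_GLC > 0.5) ? GLC_CLAMP : s[I_GLC];
    if (CLAMP_TRE > 0.5) s[I_TRE] = TRE_CLAMP;

    v[0] = PHI(S_UPT) * KCAT(S_UPT) * mm(glc, KM_GLC_UPT) *
           mm(s[I_ATP], KM_ATP_UPT) *
           KI_G6P_UPT / (KI_G6P_UPT + s[I_G6P]);
    v[1] = PHI(S_UGLC) * KCAT(S_UGLC) * mm(s[I_G6P], KM_G6P_UGLC) *
           mm(s[I_ATP], KM_ATP_UGLC) * mm(s[I_AMP], KA_AMP_UGLC);
    v[2] = PHI(S_LGLC) * KCAT(S_LGLC) * mm(s[I_FBP], KM_FBP_LGLC) *
           mm(s[I_NAD], KM_NAD_LGLC) * mm(s[I_PI], KM_PI_LGLC) *
           mm(s[I_ADP], KM_ADP_LGLC) *
           KI_PYR_LGLC / (KI_PYR_LGLC + s[I_PYR]);
    v[3] = PHI(S_FERM) * KCAT(S_FERM) *
           hillf(s[I_PYR], KM_PYR_FERM, H_PYR_FERM) *
           mm(s[I_NADH], KM_NADH_FERM) *
           hillf(s[I_FBP], KA_FBP_FERM, H_FBP_FERM);
    v[4] = PHI(S_ESNK) * KCAT(S_ESNK) * mm(s[I_FBP], KM_FBP_ESNK) *
           mm(s[I_NADH], KM_NADH_ESNK);

    cap = PHI(S_RESP) * KCAT(S_RESP);
    v_tca = cap / W_TCA * mm(s[I_PYR], KM_PYR_TCA) *
            mm(s[I_ADP], KM_ADP_TCA) * mm(s[I_PI], KM_PI_RESP);
    v_nde = cap * mm(s[I_NADH], KM_NADH_NDE) * mm(s[I_ADP], KM_ADP_NDE) *
            mm(s[I_PI], KM_PI_RESP);
    load = W_TCA * v_tca + v_nde;
    if (load > cap && load > 0.0) {
        double sc = cap / load;
        v_tca *= sc;
        v_nde *= sc;
        load = cap;
    }
    v[5] = v_tca;
    v[6] = v_nde;

    v[7] = PHI(S_TRSN) * KCAT(S_TRSN) *
           hillf(s[I_G6P], KA_G6P_TRSN, H_G6P_TRSN) *
           mm(s[I_ATP], KM_ATP_TRSN);
    v[8] = PHI(S_TRDG) * KCAT(S_TRDG) * mm(s[I_TRE], KM_TRE_TRDG) *
           mm(s[I_ATP], KM_ATP_TRDG);

    {
        double axp = s[I_ATP] + s[I_ADP] + s[I_AMP];
        ec = (axp > 0.0) ? (s[I_ATP] + 0.5 * s[I_ADP]) / axp : 0.0;
    }
    sigma = 1.0 / (1.0 + exp(-(ec - EC_MID) / EC_SLOPE));
    v[9] = PHI(S_GRWT) * KCAT(S_GRWT) * sigma *
           mm(s[I_G6P], KM_G6P_GRWT) * mm(s[I_PYR], KM_PYR_GRWT);

    v[10] = MNT_RATE * mm(s[I_ATP], KM_ATP_MNT);

    mu = v[9];
    conv = 1e6 / G_PER_CMOL;
    X = s[I_X];

    /* intracellular balances: conv * S'v. Growth dilution (-mu*c) is
     * omitted: it is < 0.05% of turnover for every pool, and it would
     * slowly drain the conserved moieties (which have no synthesis
     * reaction), forbidding any steady state. See methods vignette. */
    d[I_G6P] = conv * (v[0] - v[1] - 2.0 * v[7] + 2.0 * v[8]
                       - G6P_PER_X * v[9]);
    d[I_FBP] = conv * (v[1] - 0.5 * v[2] - 0.5 * v[4]);
    d[I_PYR] = conv * (v[2] - v[3] - v[5] - PYR_PER_X * v[9]);
    d[I_ATP] = conv * (-v[0] - v[1] + 2.0 * v[2] + A_TCA * v[5]
                       + PO_RATIO * v[6] - v[7] - 2.0 * v[8]
                       - ATP_PER_X * v[9] - v[10]);
    d[I_ADP] = conv * (v[0] + v[1] - 2.0 * v[2] - A_TCA * v[5]
                       - PO_RATIO * v[6] + v[7] + 2.0 * v[8]
                       + ATP_PER_X * v[9] + v[10]);
    d[I_AMP] = 0.0;
    d[I_NAD] = conv * (-v[2] + v[3] + v[4] + v[6] + NADH_PER_X * v[9]);
    d[I_NADH] = conv * (v[2] - v[3] - v[4] - v[6] - NADH_PER_X * v[9]);
    d[I_PI] = conv * (-v[2] + v[4] - A_TCA * v[5] - PO_RATIO * v[6]
                      + 3.0 * v[7] + (ATP_PER_X + G6P_PER_X) * v[9]
                      + v[10]);
    d[I_TRE] = conv * (v[7] - v[8]);

    /* fast adenylate kinase: 2 ADP <-> ATP + AMP */
    vak = K_AK_RELAX * (s[I_ADP] * s[I_ADP]
                        - s[I_ATP] * s[I_AMP] / K_AK);
    d[I_ADP] -= 2.0 * vak;
    d[I_ATP] += vak;
    d[I_AMP] += vak;

    /* extracellular balances */
    d[I_GLC] = DRATE * (GLC_FEED - s[I_GLC]) - v[0] * X * 1000.0;
    d[I_ETOH] = -DRATE * s[I_ETOH] + v[3] * X * 1000.0;
    d[I_GLYC] = -DRATE * s[I_GLYC] + v[4] * X * 1000.0;
    d[I_X] = (mu - DRATE) * X;

    if (CLAMP_GLC > 0.5) d[I_GLC] = 0.0;
    if (CLAMP_TRE > 0.5) d[I_TRE] = 0.0;

    for (i = 0; i < 14; i++) ydot[i] = d[i];

    for (i = 0; i < 11; i++) yout[i] = v[i];
    yout[11] = load;
    yout[12] = ec;
    yout[13] = W_TCA / 2.0 * v[5] + 0.5 * v[6];            /* q_O2  */
    yout[14] = v[3] + 3.0 * v[5] + CO2_PER_X * v[9];       /* q_CO2 */
}

/* root function: the glycolytic-collapse attractor (ATP exhausted into
 * AMP) is absorbing; once ATP falls through this floor the trajectory
 * can only wash out, so integration is terminated to save the extremely
 * stiff crawl through the collapse. */
void protalloc_root(int *neq, double *t, double *y, int *ng, double *gout)
{
    gout[0] = y[I_ATP] - 0.02;
}
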