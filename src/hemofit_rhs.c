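/* Compiled right-hand side of the closed-loop lumped-parameter model.
 * Mirrors the pure-R reference ode_rhs(); the two are checked against each
 * other in the test suite. Parameter order follows the package parameter
 * table (see R/parameters.R).
 */
#include <R.h>
#include <math.h>

#define N_PARMS 40
static double parms[N_PARMS];

/* indices into parms (table order) */
#define P_EOA        parms[0]
#define P_A_LVOT     parms[1]
#define P_LV_EMAX    parms[2]
#define P_LV_EMIN    parms[3]
#define P_LV_RC      parms[4]
#define P_LV_RR      parms[5]
#define P_LV_AS      parms[6]
#define P_LV_AD      parms[7]
#define P_LV_TMAX    parms[8]
#define P_LA_EMAX    parms[9]
#define P_LA_EMIN    parms[10]
#define P_LA_RC      parms[11]
#define P_LA_RR      parms[12]
#define P_LA_AS      parms[13]
#define P_LA_AD      parms[14]
#define P_LA_TMAX    parms[15]
#define P_LA_ONSET   parms[16]
#define P_C_AA       parms[17]
#define P_R_AO       parms[18]
#define P_C_PER      parms[19]
#define P_R_PER      parms[20]
#define P_R_MV       parms[21]
#define P_L_MV       parms[22]
#define P_T_CYCLE    parms[23]
#define P_LV_V0      parms[24]
#define P_LA_V0      parms[25]
#define P_RHO        parms[26]
#define P_B_AV       parms[27]
#define P_L_AO       parms[28]
#define P_R_AV_OPEN  parms[29]
#define P_R_PUL      parms[30]
#define P_R_VEN      parms[31]
#define P_C_PUL      parms[32]
#define P_V_PUL0     parms[33]
#define P_P_PUL0     parms[34]
#define P_AA_V0      parms[35]
#define P_PER_V0     parms[36]
#define P_R_CLOSED   parms[37]
#define P_DP_WIDTH   parms[38]
#define P_P_THORAX   parms[39]

#define PG_UNIT (0.06 / 133.322)

void hemo_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

static double hill_shape(double t, double alpha_s, double alpha_d,
                         double rc, double rr, double T)
{
    double xs, xd;
    double rise, fall;
    if (t <= 0.0) return 0.0;
    xs = pow(t / (alpha_s * T), rc);
    xd = pow(t / (alpha_d * T), rr);
    rise = R_FINITE(xs) ? xs / (1.0 + xs) : 1.0;
    fall = R_FINITE(xd) ? 1.0 / (1.0 + xd) : 0.0;
    return rise * fall;
}

static double elast(double t, double emax, double emin, double rc, double rr,
                    double as, double ad, double tmax, double T)
{
    double hp = hill_shape(tmax, as, ad, rc, rr, T);
    return emin + (emax - emin) * hill_shape(t, as, ad, rc, rr, T) / hp;
}

static double sigm(double x)
{
    if (x > 40.0) return 1.0;
    if (x < -40.0) return 0.0;
    return 1.0 / (1.0 + exp(-x));
}

/* open when driving pressure positive or forward flow persists */
static double gate(double dp, double q, double w)
{
    double sp = sigm(dp / w), sq = sigm(q / 0.5);
    return 1.0 - (1.0 - sp) * (1.0 - sq);
}

void hemo_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double T = P_T_CYCLE;
    double tc = fmod(*t, T);
    double tla = fmod(*t - P_LA_ONSET, T);
    double v_lv, v_la, v_aa, v_per, v_pul, q_mv, q_av, q_ao;
    double e_lv, e_la, p_lv, p_la, p_aa, p_per, p_pul;
    double q_pul, q_sys, dp_mv, dp_av, g_mv, g_av, elco, kap, dq_av;

    if (tla < 0.0) tla += T;

    v_lv = y[0]; v_la = y[1]; v_aa = y[2]; v_per = y[3]; v_pul = y[4];
    q_mv = y[5]; q_av = y[6]; q_ao = y[7];

    e_lv = elast(tc, P_LV_EMAX, P_LV_EMIN, P_LV_RC, P_LV_RR,
                 P_LV_AS, P_LV_AD, P_LV_TMAX, T);
    e_la = elast(tla, P_LA_EMAX, P_LA_EMIN, P_LA_RC, P_LA_RR,
                 P_LA_AS, P_LA_AD, P_LA_TMAX, T);

    p_lv  = P_P_THORAX + e_lv * (v_lv - P_LV_V0);
    p_la  = P_P_THORAX + e_la * (v_la - P_LA_V0);
    p_aa  = (v_aa - P_AA_V0) / P_C_AA;
    p_per = (v_per - P_PER_V0) / P_C_PER;
    p_pul = P_P_PUL0 + (v_pul - P_V_PUL0) / P_C_PUL;

    q_pul = (p_pul - p_la) / P_R_PUL;

    dp_mv = p_la - p_lv;
    g_mv = gate(dp_mv, q_mv, P_DP_WIDTH);

    dp_av = p_lv - p_aa;
    elco = P_EOA * P_A_LVOT / (P_A_LVOT - P_EOA);
    kap = P_RHO / (2.0 * elco * elco) * PG_UNIT;
    g_av = gate(dp_av, q_av, P_DP_WIDTH);
    if (P_B_AV > 0.0) {
        dq_av = (dp_av - kap * q_av * fabs(q_av) - P_R_AV_OPEN * q_av -
                 P_R_CLOSED * (1.0 - g_av) * q_av) / P_B_AV;
    } else {
        double r0 = P_R_AV_OPEN, q_alg = 0.0;
        if (dp_av > 0.0)
            q_alg = (-r0 + sqrt(r0 * r0 + 4.0 * kap * dp_av)) / (2.0 * kap);
        dq_av = (g_av * q_alg - q_av) / 1e-4;
    }

    q_sys = (p_per - p_pul) / (P_R_PER + P_R_VEN);

    ydot[0] = q_mv - q_av;                       /* v_lv  */
    ydot[1] = q_pul - q_mv;                      /* v_la  */
    ydot[2] = q_av - q_ao;                       /* v_aa  */
    ydot[3] = q_ao - q_sys;                      /* v_per */
    ydot[4] = q_sys - q_pul;                     /* v_pul */
    ydot[5] = (dp_mv - P_R_MV * q_mv -
               P_R_CLOSED * (1.0 - g_mv) * q_mv) / P_L_MV;
    ydot[6] = dq_av;
    ydot[7] = (p_aa - p_per - P_R_AO * q_ao) / P_L_AO;
}
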