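/* Compiled right-hand side of the whole-cell VSM calcium model, in the
 * deSolve compiled-model interface (initfunc + derivs).  The parameter
 * vector layout must match .param_order in R/params.R; the state layout
 * matches .state_names.  Sign convention: fluxes are cytosol-referenced
 * uM/s, positive raises cytosolic calcium. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 79

static double parms[NPAR];

/* parameter indices (0-based), mirroring .param_order */
#define K_CaM        parms[0]
#define CaM_tot      parms[1]
#define K_B          parms[2]
#define B_tot        parms[3]
#define Myo_tot      parms[4]
#define gamma_cross  parms[5]
#define K2m          parms[6]
#define K3m          parms[7]
#define K4m          parms[8]
#define K5m          parms[9]
#define K7m          parms[10]
#define ca_per_myo   parms[11]
#define eta_IP3      parms[12]
#define kdeg_IP3     parms[13]
#define k_c          parms[14]
#define PIP2_rr      parms[15]
#define PIP2_tot     parms[16]
#define G_conc       parms[17]
#define nu_mcu       parms[18]
#define nu_nclx      parms[19]
#define K_mcu1       parms[20]
#define K_mcu2       parms[21]
#define L_mcu        parms[22]
#define p1v          parms[23]
#define p2v          parms[24]
#define dPsi_m       parms[25]
#define nu_mit_leak  parms[26]
#define K_CalC       parms[27]
#define CalC_tot     parms[28]
#define K_CalP       parms[29]
#define CalP_tot     parms[30]
#define K1_serca     parms[31]
#define K3_serca     parms[32]
#define k2_serca     parms[33]
#define km2_serca    parms[34]
#define k4_serca     parms[35]
#define km4_serca    parms[36]
#define SERCA_tot    parms[37]
#define serca_scale  parms[38]
#define nu_ipr       parms[39]
#define a1v          parms[40]
#define a2v          parms[41]
#define a3v          parms[42]
#define a4v          parms[43]
#define a5v          parms[44]
#define b1v          parms[45]
#define b2v          parms[46]
#define b3v          parms[47]
#define b4v          parms[48]
#define b5v          parms[49]
#define nu_ryr       parms[50]
#define Kr1          parms[51]
#define Kr2          parms[52]
#define Kmr1         parms[53]
#define Kmr2         parms[54]
#define phi_ecs      parms[55]
#define Na_cyt       parms[56]
#define Na_ecs       parms[57]
#define eta_ncx      parms[58]
#define d_ncx        parms[59]
#define k_ncx1       parms[60]
#define Q_ncx        parms[61]
#define Q_pmca       parms[62]
#define k_pmca       parms[63]
#define Q_vocc       parms[64]
#define g_leak_ecs   parms[65]
#define Faraday      parms[66]
#define r_ercyt      parms[67]
#define r_mitcyt     parms[68]
#define V_cyt        parms[69]
#define Ca_ecs       parms[70]
#define Ca_mit       parms[71]
#define RT_over_2F   parms[72]
#define alpha_er     parms[73]
#define alpha_mit    parms[74]
#define alpha_pm     parms[75]
#define ca_floor     parms[76]
/* protons_per_Ca, protons_per_ATP occupy the tail; unused here */

void vsm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

void vsm_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, parms);
}

void vsm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double c = y[0] > ca_floor ? y[0] : ca_floor;
    double cer = y[1], ip3 = y[2], pip2 = y[3];
    double Mp = y[4], AMp = y[5], AM = y[6];
    double X00 = y[7], X01 = y[8], X10 = y[9];
    double R10 = y[10], R11 = y[11], R01 = y[12];

    /* ER: SERCA (two-state reduced cycle, normalized concentrations) */
    double chat2 = (c / K1_serca) * (c / K1_serca);
    double shat2 = (cer * K3_serca) * (cer * K3_serca);
    double num = 2.0 * (km2_serca * km4_serca * shat2 -
                        k2_serca * k4_serca * chat2) * SERCA_tot;
    double den = chat2 * shat2 * (k2_serca + km2_serca) +
        chat2 * (k2_serca + k4_serca) +
        shat2 * (km2_serca + km4_serca) + (k4_serca + km4_serca);
    double J_serca = serca_scale * num / den;

    double po = X10 * X10 * X10 * (X10 + 4.0 * (1.0 - X10));
    double J_ipr = nu_ipr * po * (cer - c);
    double J_ryr = nu_ryr * R10 * R10 * (cer - c);
    double J_er = alpha_er * (J_serca + J_ipr + J_ryr);

    /* mitochondria: MCU + NCLX + Ohmic leak, matrix calcium fixed */
    double x = c / K_mcu1;
    double op = 1.0 + x;
    double J_mcu = -nu_mcu * x * op * op * op /
        (op * op * op * op + L_mcu * pow(1.0 + c / K_mcu2, 2.3)) *
        exp(p1v * dPsi_m);
    double J_nclx = nu_nclx * (Ca_mit / c) * exp(p2v * dPsi_m);
    double E_mit = RT_over_2F * log(Ca_mit / c);
    double J_mleak = nu_mit_leak * (E_mit - dPsi_m);
    double J_mit = alpha_mit * (J_mcu + J_nclx + J_mleak);

    /* plasma membrane */
    double E_ecs = RT_over_2F * log(Ca_ecs / c);
    double v = phi_ecs / (2.0 * RT_over_2F);
    double phiF = exp(eta_ncx * v), phiR = exp((eta_ncx - 1.0) * v);
    double na_c3 = Na_cyt * Na_cyt * Na_cyt;
    double na_e3 = Na_ecs * Na_ecs * Na_ecs;
    double drive = (na_c3 * Ca_ecs * phiF - na_e3 * c * phiR) /
        (1.0 + d_ncx * (c * na_e3 + Ca_ecs * na_c3));
    double act = 1.0 / (1.0 + (k_ncx1 / c) * (k_ncx1 / c));
    double J_ncx = Q_ncx * drive * act;
    double dbar = 1.0 / (1.0 + exp(-phi_ecs / 8.3));
    double fbar = 1.0 / (1.0 + exp((phi_ecs + 42.0) / 9.1));
    double J_vocc = Q_vocc * dbar * fbar * (E_ecs - phi_ecs);
    double J_leak = -g_leak_ecs * (phi_ecs - E_ecs);
    double J_pmca = -Q_pmca * c / (c + k_pmca);
    double J_ecs = alpha_pm * (J_leak + J_pmca + J_ncx + J_vocc);

    /* cross bridges; K1 = K6 = gamma * c^3 */
    double K1 = gamma_cross * c * c * c;
    double M = 1.0 - Mp - AMp - AM;
    double dMp = K4m * AMp + K1 * M - (K2m + K3m) * Mp;
    double dAMp = K3m * Mp + K1 * AM - (K4m + K5m) * AMp;
    double dAM = K5m * AMp - (K7m + K1) * AM;
    double J_cyt = -ca_per_myo * Myo_tot * (dMp + dAMp);

    /* IP3 / PIP2 */
    double rh = eta_IP3 * c / (k_c + c) * G_conc;
    double dip3 = rh * pip2 - kdeg_IP3 * ip3;
    double dpip2 = -(rh + PIP2_rr) * pip2 + PIP2_rr * (PIP2_tot - ip3);

    /* IP3R gating (four-state De Young-Keizer reduction) */
    double k1g = b1v / (a1v * ip3);
    double k3g = b3v / (a3v * ip3);
    double act0 = a5v * c / (1.0 + k1g);
    double act1 = a5v * c / (1.0 + k3g);
    double inact0 = (a2v + a4v * k1g) * c / (1.0 + k1g);
    double rec0 = (b2v + b4v * k3g) / (1.0 + k3g);
    double inact1 = a2v * c;
    double X11 = 1.0 - X00 - X01 - X10;
    double dX00 = -(act0 + inact0) * X00 + rec0 * X01 + b5v * X10;
    double dX01 = inact0 * X00 - (rec0 + act1) * X01 + b5v * X11;
    double dX10 = act0 * X00 - (b5v + inact1) * X10 + b2v * X11;

    /* RyR gating */
    double ka = Kr1 * c * c, ki = Kr2 * c;
    double R00 = 1.0 - R10 - R11 - R01;
    double dR10 = ka * R00 - (Kmr1 + ki) * R10 + Kmr2 * R11;
    double dR11 = ki * R10 + ka * R01 - (Kmr2 + Kmr1) * R11;
    double dR01 = ki * R00 - (Kmr2 + ka) * R01 + Kmr1 * R11;

    /* buffering divisors */
    double bc = 1.0 + K_CaM * CaM_tot / ((K_CaM + c) * (K_CaM + c)) +
        K_B * B_tot / ((K_B + c) * (K_B + c));
    double be = 1.0 + K_CalC * CalC_tot / ((K_CalC + cer) * (K_CalC + cer)) +
        K_CalP * CalP_tot / ((K_CalP + cer) * (K_CalP + cer));

    ydot[0] = (J_er + J_mit + J_ecs + J_cyt) / bc;
    ydot[1] = -r_ercyt * J_er / be;
    ydot[2] = dip3;
    ydot[3] = dpip2;
    ydot[4] = dMp;
    ydot[5] = dAMp;
    ydot[6] = dAM;
    ydot[7] = dX00;
    ydot[8] = dX01;
    ydot[9] = dX10;
    ydot[10] = dR10;
    ydot[11] = dR11;
    ydot[12] = dR01;
    ydot[13] = -J_ecs;   /* ca_sink */
    ydot[14] = J_mit;    /* ca_source */
}

static const R_CMethodDef cMethods[] = {
    {"vsm_derivs", (DL_FUNC) &vsm_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_mitovasc(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
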