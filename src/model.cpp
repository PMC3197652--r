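// Charge-difference guinea-pig ventricular myocyte model with coupled
// intra/extracellular pH, dynamic volumes and phosphometabolite schedules,
// plus the fixed-step forward-Euler ischemia-reperfusion protocol driver.
//
// Membrane potential is an affine function of the valence-weighted ion
// content of the cell (free + buffered species + the generic ischemic
// anion), not an integrated current balance.  Units: mM, ms, mV, uA/uF, uL.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double LN10 = 2.302585092994046;

static inline double exp10_(double x) { return std::exp(LN10 * x); }
static inline double cube(double x) { return x * x * x; }
static inline double sq(double x) { return x * x; }
// x / (exp(x) - 1), stable near 0
static inline double xoexpm1(double x) {
  if (std::fabs(x) < 1e-9) return 1.0 - 0.5 * x;
  return x / std::expm1(x);
}

// ------------------------------------------------------------------ state --
enum StateIdx {
  iV = 0, iPHI, iPHO, iNAI, iNAO, iKI, iKO, iCLI, iCLO, iCAI, iCAO,
  iCAJSR, iCANSR, iCO2I, iCO2O, iHCO3I, iHCO3O, iANION,
  iM, iH, iJ, iD, iF, iXR, iXS1, iXS2, iB, iG, iML, iHL, iHLS, iRYRO, iRYRI,
  iVMYO, iVEXT, iOSMI, iXIMP, iATP, iADP, iAMP, iPI, iCR, iPCR,
  iHB1I, iHB2I, iHB1O, iHB2O, iT, NSTATE
};

static const char* STATE_NAMES[NSTATE] = {
  "V", "pH_i", "pH_o", "Na_i", "Na_o", "K_i", "K_o", "Cl_i", "Cl_o",
  "Ca_i", "Ca_o", "Ca_jsr", "Ca_nsr", "CO2_i", "CO2_o", "HCO3_i", "HCO3_o",
  "Anion_i",
  "m", "h", "j", "d", "f", "x_r", "x_s1", "x_s2", "b", "g",
  "m_L", "h_L", "h_Ls", "ryr_o", "ryr_i",
  "V_myo", "V_ext", "Osm_i", "X_i", "ATP", "ADP", "AMP", "Pi", "Cr", "PCr",
  "HBuf1_i", "HBuf2_i", "HBuf1_o", "HBuf2_o", "t"
};

// ---------------------------------------------------------------- aux out --
enum AuxIdx {
  aINA = 0, aINAL, aICAL, aICALCA, aICALNA, aICALK, aICAT, aIKR, aIKS, aIK1,
  aIKP, aIKATP, aINAK, aINCX, aIPCA, aINAB, aICAB, aICLB, aISTIM,
  aJUP, aJREL, aJLEAK, aJTR, aJNHE, aJNBC, aJCHE, aJAE,
  aJCO2M, aRCO2I, aRCO2O, aBETAI, aBETAO, aJW,
  aFATPLCC, aALLONHE, aFHNCX, aFPHNAK, aVCYC, aITOT, NAUX
};

static const char* AUX_NAMES[NAUX] = {
  "I_Na", "I_NaL", "I_CaL", "I_CaL_Ca", "I_CaL_Na", "I_CaL_K", "I_CaT",
  "I_Kr", "I_Ks", "I_K1", "I_Kp", "I_KATP", "I_NaK", "I_NCX", "I_pCa",
  "I_Nab", "I_Cab", "I_Clb", "I_stim",
  "J_up", "J_rel", "J_leak", "J_tr", "J_NHE", "J_NBC", "J_CHE", "J_AE",
  "J_CO2m", "R_CO2_i", "R_CO2_o", "beta_i", "beta_o", "J_water",
  "f_ATP_LCC", "allo_NHE", "f_H_NCX", "f_pH_NaK", "v_SERCA", "I_total"
};

// ------------------------------------------------------------- parameters --
struct Par {
  double faraday, rgas, temp, cap_total, kq, rtf, kw_mM2;
  double v_nsr, v_jsr, x_o;
  double g_na, g_nal;
  double p_ca, p_ca_na, p_ca_k, gamma_cai, gamma_cao, gamma_nai, gamma_nao,
         gamma_ki, gamma_ko, km_fca, km_atp_lcc, hill_atp_lcc, g_cat;
  double g_kr, g_ks_base, g_k1, g_kp, p_nak_perm;
  double g_katp, katp_km_base, katp_km_adp, katp_km_exp, katp_hill,
         katp_ko_exp;
  double ibar_nak, km_nai_nak, km_ko_nak, km_atp_nak, ki_adp_nak, ki_pi_nak,
         pk_nak, hill_nak, ph_ref_nak;
  double c_ncx, c2_ncx, gamma_ncx, pk_ncx, hill_ncx;
  double ipca_max, km_pca, g_nab, g_cab, g_clb;
  double vmax_serca, serca_factor, kmf_serca, kmr_serca, keq_serca, pk_serca;
  double grel, kt_ryr, tau_ro, km_ri, tau_ri, pk_ryr, hill_ryr, tau_tr, kleak;
  double cmdn, km_cmdn, trpn, km_trpn, csqn, km_csqn;
  double buf1_conc, buf1_pk, buf2_conc, buf2_pk;
  double k_a_co2, k_hyd, p_co2, j_co2_prod, tau_co2_prod;
  double v_nhe, k_h_nhe, hill_nhe_i, hill_nhe_o, km_nao_nhe;
  double v_nbc, km_nbc, k_che, k_ae;
  double k_water, tau_anion_wash;
  double buf_vmyo_ref, buf_vext_ref;
  double k_ck, k_ak, total_cr, total_p;
  double n_offset, v_at_offset;
  bool   calibrated;
};

static double getp(const List& l, const char* nm) {
  if (!l.containsElementNamed(nm))
    stop(std::string("missing model parameter: ") + nm);
  return as<double>(l[nm]);
}

static Par make_par(const List& l) {
  Par p;
  p.faraday = getp(l, "faraday"); p.rgas = getp(l, "rgas");
  p.temp = getp(l, "temp"); p.cap_total = getp(l, "cap_total");
  p.rtf = 1000.0 * p.rgas * p.temp / p.faraday;
  p.kq = 1000.0 * p.faraday / (p.cap_total * 1e-6);
  p.kw_mM2 = getp(l, "kw_mM2");
  p.v_nsr = getp(l, "v_nsr"); p.v_jsr = getp(l, "v_jsr");
  p.x_o = getp(l, "x_o");
  p.g_na = getp(l, "g_na"); p.g_nal = getp(l, "g_nal");
  p.p_ca = getp(l, "p_ca"); p.p_ca_na = getp(l, "p_ca_na");
  p.p_ca_k = getp(l, "p_ca_k");
  p.gamma_cai = getp(l, "gamma_cai"); p.gamma_cao = getp(l, "gamma_cao");
  p.gamma_nai = getp(l, "gamma_nai"); p.gamma_nao = getp(l, "gamma_nao");
  p.gamma_ki = getp(l, "gamma_ki"); p.gamma_ko = getp(l, "gamma_ko");
  p.km_fca = getp(l, "km_fca"); p.km_atp_lcc = getp(l, "km_atp_lcc");
  p.hill_atp_lcc = getp(l, "hill_atp_lcc"); p.g_cat = getp(l, "g_cat");
  p.g_kr = getp(l, "g_kr"); p.g_ks_base = getp(l, "g_ks_base");
  p.g_k1 = getp(l, "g_k1"); p.g_kp = getp(l, "g_kp");
  p.p_nak_perm = getp(l, "p_nak_perm");
  p.g_katp = getp(l, "g_katp"); p.katp_km_base = getp(l, "katp_km_base");
  p.katp_km_adp = getp(l, "katp_km_adp");
  p.katp_km_exp = getp(l, "katp_km_exp");
  p.katp_hill = getp(l, "katp_hill"); p.katp_ko_exp = getp(l, "katp_ko_exp");
  p.ibar_nak = getp(l, "ibar_nak"); p.km_nai_nak = getp(l, "km_nai_nak");
  p.km_ko_nak = getp(l, "km_ko_nak"); p.km_atp_nak = getp(l, "km_atp_nak");
  p.ki_adp_nak = getp(l, "ki_adp_nak"); p.ki_pi_nak = getp(l, "ki_pi_nak");
  p.pk_nak = getp(l, "pk_nak"); p.hill_nak = getp(l, "hill_nak");
  p.ph_ref_nak = getp(l, "ph_ref_nak");
  p.c_ncx = getp(l, "c_ncx"); p.c2_ncx = getp(l, "c2_ncx");
  p.gamma_ncx = getp(l, "gamma_ncx"); p.pk_ncx = getp(l, "pk_ncx");
  p.hill_ncx = getp(l, "hill_ncx");
  p.ipca_max = getp(l, "ipca_max"); p.km_pca = getp(l, "km_pca");
  p.g_nab = getp(l, "g_nab"); p.g_cab = getp(l, "g_cab");
  p.g_clb = getp(l, "g_clb");
  p.vmax_serca = getp(l, "vmax_serca");
  p.serca_factor = getp(l, "serca_factor");
  p.kmf_serca = getp(l, "kmf_serca"); p.kmr_serca = getp(l, "kmr_serca");
  p.keq_serca = getp(l, "keq_serca"); p.pk_serca = getp(l, "pk_serca");
  p.grel = getp(l, "grel"); p.kt_ryr = getp(l, "kt_ryr");
  p.tau_ro = getp(l, "tau_ro"); p.km_ri = getp(l, "km_ri");
  p.tau_ri = getp(l, "tau_ri"); p.pk_ryr = getp(l, "pk_ryr");
  p.hill_ryr = getp(l, "hill_ryr"); p.tau_tr = getp(l, "tau_tr");
  p.kleak = getp(l, "kleak");
  p.cmdn = getp(l, "cmdn"); p.km_cmdn = getp(l, "km_cmdn");
  p.trpn = getp(l, "trpn"); p.km_trpn = getp(l, "km_trpn");
  p.csqn = getp(l, "csqn"); p.km_csqn = getp(l, "km_csqn");
  p.buf1_conc = getp(l, "buf1_conc"); p.buf1_pk = getp(l, "buf1_pk");
  p.buf2_conc = getp(l, "buf2_conc"); p.buf2_pk = getp(l, "buf2_pk");
  p.k_a_co2 = getp(l, "k_a_co2"); p.k_hyd = getp(l, "k_hyd");
  p.p_co2 = getp(l, "p_co2"); p.j_co2_prod = getp(l, "j_co2_prod");
  p.tau_co2_prod = getp(l, "tau_co2_prod");
  p.v_nhe = getp(l, "v_nhe"); p.k_h_nhe = getp(l, "k_h_nhe");
  p.hill_nhe_i = getp(l, "hill_nhe_i"); p.hill_nhe_o = getp(l, "hill_nhe_o");
  p.km_nao_nhe = getp(l, "km_nao_nhe");
  p.v_nbc = getp(l, "v_nbc"); p.km_nbc = getp(l, "km_nbc");
  p.k_che = getp(l, "k_che"); p.k_ae = getp(l, "k_ae");
  p.k_water = getp(l, "k_water");
  p.tau_anion_wash = getp(l, "tau_anion_wash");
  p.buf_vmyo_ref = getp(l, "buf_vmyo_ref");
  p.buf_vext_ref = getp(l, "buf_vext_ref");
  p.k_ck = getp(l, "k_ck"); p.k_ak = getp(l, "k_ak");
  p.total_cr = getp(l, "total_cr"); p.total_p = getp(l, "total_p");
  p.n_offset = getp(l, "n_offset");
  p.v_at_offset = getp(l, "v_at_offset");
  p.calibrated = R_finite(p.n_offset);
  return p;
}

// --------------------------------------------- voltage-dependent kinetics --
// The 24 purely voltage-dependent quantities used by the RHS.  The driver
// tabulates them on a 0.02 mV grid with linear interpolation; the exact
// evaluation path computes them directly.
enum TvIdx {
  tAM = 0, tBM, tAH, tBH, tAJ, tBJ, tDINF, tITAUD, tFINF, tITAUF,
  tXRINF, tKXR, tXSINF, tKXS, tBINF, tITAUB, tGINF, tITAUG, tHLINF,
  tRKR, tKPF, tEXPV, tXO1, tXO2, tE01, tEG1, NTV
};

static void tv_direct(double V, double rtf, double gamma_ncx, double* tv) {
  double vfrt = V / rtf;
  tv[tAM] = (std::fabs(V + 47.13) < 1e-6) ? 3.2
          : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  tv[tBM] = 0.08 * std::exp(-V / 11.0);
  if (V < -40.0) {
    tv[tAH] = 0.135 * std::exp((80.0 + V) / -6.8);
    tv[tBH] = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    tv[tAJ] = (-1.2714e5 * std::exp(0.2444 * V)
               - 3.474e-5 * std::exp(-0.04391 * V))
              * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    tv[tBJ] = 0.1212 * std::exp(-0.01052 * V) /
              (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    tv[tAH] = 0.0;
    tv[tBH] = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
    tv[tAJ] = 0.0;
    tv[tBJ] = 0.3 * std::exp(-2.535e-7 * V) /
              (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  double dinf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 6.24));
  double taud;
  if (std::fabs(V + 10.0) < 1e-4) {
    taud = dinf / (0.035 * 6.24);
  } else {
    taud = dinf * (1.0 - std::exp(-(V + 10.0) / 6.24)) / (0.035 * (V + 10.0));
  }
  tv[tDINF] = dinf; tv[tITAUD] = 1.0 / taud;
  tv[tFINF] = 1.0 / (1.0 + std::exp((V + 32.0) / 8.0))
            + 0.6 / (1.0 + std::exp((50.0 - V) / 20.0));
  tv[tITAUF] = 0.0197 * std::exp(-sq(0.0337 * (V + 10.0))) + 0.02;
  tv[tXRINF] = 1.0 / (1.0 + std::exp(-(V + 21.5) / 7.5));
  double axr = (std::fabs(V + 14.2) < 1e-6) ? 0.00138 / 0.123
             : 0.00138 * (V + 14.2) / (1.0 - std::exp(-0.123 * (V + 14.2)));
  double bxr = (std::fabs(V + 38.9) < 1e-6) ? 0.00061 / 0.145
             : 0.00061 * (V + 38.9) / (std::exp(0.145 * (V + 38.9)) - 1.0);
  tv[tKXR] = axr + bxr;
  tv[tXSINF] = 1.0 / (1.0 + std::exp(-(V - 1.5) / 16.7));
  double axs = (std::fabs(V + 30.0) < 1e-6) ? 7.19e-5 / 0.148
             : 7.19e-5 * (V + 30.0) / (1.0 - std::exp(-0.148 * (V + 30.0)));
  double bxs = (std::fabs(V + 30.0) < 1e-6) ? 1.31e-4 / 0.0687
             : 1.31e-4 * (V + 30.0) / (std::exp(0.0687 * (V + 30.0)) - 1.0);
  tv[tKXS] = axs + bxs;
  tv[tBINF] = 1.0 / (1.0 + std::exp(-(V + 14.0) / 10.8));
  tv[tITAUB] = 1.0 / (3.7 + 6.1 / (1.0 + std::exp((V + 25.0) / 4.5)));
  tv[tGINF] = 1.0 / (1.0 + std::exp((V + 60.0) / 5.6));
  tv[tITAUG] = 1.0 / ((V <= 0.0) ? (-0.875 * V + 12.0) : 12.0);
  tv[tHLINF] = 1.0 / (1.0 + std::exp((V + 91.0) / 6.1));
  tv[tRKR] = 1.0 / (1.0 + std::exp((V + 9.0) / 22.4));
  tv[tKPF] = 1.0 / (1.0 + std::exp((7.488 - V) / 5.98));
  tv[tEXPV] = std::exp(vfrt);
  tv[tXO1] = xoexpm1(vfrt);
  tv[tXO2] = xoexpm1(2.0 * vfrt);
  tv[tE01] = std::exp(-0.1 * vfrt);
  tv[tEG1] = std::exp((gamma_ncx - 1.0) * vfrt);
}

struct VTab {
  std::vector<double> tab;   // NTV values per grid point
  double vmin, dv, inv_dv;
  int n;
  void build(double rtf, double gamma_ncx) {
    vmin = -160.0; dv = 0.02; n = (int)((90.0 - vmin) / dv) + 2;
    inv_dv = 1.0 / dv;
    tab.resize((size_t)n * NTV);
    for (int i = 0; i < n; ++i)
      tv_direct(vmin + i * dv, rtf, gamma_ncx, &tab[(size_t)i * NTV]);
  }
  inline void lookup(double V, double* tv) const {
    double x = (V - vmin) * inv_dv;
    int i = (int)x;
    if (i < 0) { i = 0; x = 0.0; }
    if (i >= n - 1) { i = n - 2; x = (double)(n - 1); }
    double w = x - i;
    const double* a = &tab[(size_t)i * NTV];
    const double* b = a + NTV;
    for (int q = 0; q < NTV; ++q) tv[q] = a[q] + w * (b[q] - a[q]);
  }
};

// Hill power with fast paths for the integer orders used by the model
static inline double powh(double x, double h) {
  if (h == 1.0) return x;
  if (h == 2.0) return x * x;
  if (h == 3.0) return x * x * x;
  return std::pow(x, h);
}

// ------------------------------------------------------- per-step control --
struct Ctl {
  int phase;              // 0 pre-ischemia, 1 ischemia, 2 reperfusion
  double g_na_scale;
  double g_nal_scale;     // absolute scale (conductance) for late Na
  double nhe_scale;
  double nak_scale;
  bool   nak_clamp;
  double nak_ph;
  double istim;
  bool   pHi_prescribed;
  double dphi_dt_presc;   // 1/ms in real time
  double co2_prod_scale;  // metabolic CO2 production multiplier
};

// ----------------------------------------------------- derived quantities --
static inline double buf_scale_i(const double* s, const Par& p) {
  return (p.buf_vmyo_ref > 0.0) ? p.buf_vmyo_ref / s[iVMYO] : 1.0;
}
static inline double buf_scale_o(const double* s, const Par& p) {
  return (p.buf_vext_ref > 0.0) ? p.buf_vext_ref / s[iVEXT] : 1.0;
}

static void update_derived(double* s, const Par& p) {
  double Hi = exp10_(3.0 - s[iPHI]);
  // intrinsic buffer amounts are conserved across volume changes: the
  // effective concentrations scale with the reference/current volume ratio
  double fi = buf_scale_i(s, p), fo = buf_scale_o(s, p);
  s[iHB1I] = fi * p.buf1_conc / (1.0 + exp10_(s[iPHI] - p.buf1_pk));
  s[iHB2I] = fi * p.buf2_conc / (1.0 + exp10_(s[iPHI] - p.buf2_pk));
  s[iHB1O] = fo * p.buf1_conc / (1.0 + exp10_(s[iPHO] - p.buf1_pk));
  s[iHB2O] = fo * p.buf2_conc / (1.0 + exp10_(s[iPHO] - p.buf2_pk));
  s[iCR]  = p.total_cr - s[iPCR];
  double adp = s[iATP] * s[iCR] / (s[iPCR] * p.k_ck * Hi);
  s[iADP] = adp;
  s[iAMP] = p.k_ak * adp * adp / s[iATP];
  s[iPI]  = p.total_p - 3.0 * s[iATP] - 2.0 * adp - s[iAMP] - s[iPCR];
  s[iXIMP] = s[iOSMI] - (s[iNAI] + s[iKI] + s[iCAI] + s[iCLI]);
}

// Valence-weighted intracellular content (free + buffered + SR) in mol.
static double charge_mol(const double* s, const Par& p) {
  double Hi = exp10_(3.0 - s[iPHI]);
  double OHi = p.kw_mM2 / Hi;
  double ca_f = s[iCAI];
  double catot = ca_f + p.cmdn * ca_f / (ca_f + p.km_cmdn)
                      + p.trpn * ca_f / (ca_f + p.km_trpn);
  double cajsr_tot = s[iCAJSR] + p.csqn * s[iCAJSR] / (s[iCAJSR] + p.km_csqn);
  double zi = s[iNAI] + s[iKI] + 2.0 * catot + Hi + s[iHB1I] + s[iHB2I]
            - s[iCLI] - s[iHCO3I] - OHi - s[iANION];
  double n = s[iVMYO] * zi + p.v_nsr * 2.0 * s[iCANSR]
           + p.v_jsr * 2.0 * cajsr_tot;
  return n * 1e-9;  // mM*uL -> mol
}

static double voltage_from_charge(const double* s, const Par& p) {
  if (!p.calibrated)
    stop("charge-difference offset is not calibrated; "
         "use calibrated_parameters()");
  return p.kq * (charge_mol(s, p) - p.n_offset) + p.v_at_offset;
}

// ---------------------------------------------------------------- the RHS --
static void model_eval(const double* s, const Par& p, const Ctl& c,
                       double* ds, double* aux, const VTab* vt = 0) {
  for (int k = 0; k < NSTATE; ++k) ds[k] = 0.0;
  for (int k = 0; k < NAUX; ++k) aux[k] = 0.0;

  const double V = voltage_from_charge(s, p);
  ds[iV] = V;  // value, not derivative: assigned by the stepper
  const double vfrt = V / p.rtf;
  double tv[NTV];
  if (vt) vt->lookup(V, tv); else tv_direct(V, p.rtf, p.gamma_ncx, tv);
  const double Nai = s[iNAI], Nao = s[iNAO], Ki = s[iKI], Ko = s[iKO];
  const double Cli = s[iCLI], Clo = s[iCLO], Cai = s[iCAI], Cao = s[iCAO];
  const double Hi = exp10_(3.0 - s[iPHI]);
  const double Ho = exp10_(3.0 - s[iPHO]);
  const double OHi = p.kw_mM2 / Hi, OHo = p.kw_mM2 / Ho;
  const double Vmyo = s[iVMYO], Vext = s[iVEXT];

  const double ENa = p.rtf * std::log(Nao / Nai);
  const double EK  = p.rtf * std::log(Ko / Ki);
  const double EKs = p.rtf * std::log((Ko + p.p_nak_perm * Nao) /
                                      (Ki + p.p_nak_perm * Nai));
  const double ECl = -p.rtf * std::log(Clo / Cli);
  const double ECa = 0.5 * p.rtf * std::log(Cao / Cai);

  // fast sodium current
  ds[iM] = tv[tAM] * (1.0 - s[iM]) - tv[tBM] * s[iM];
  ds[iH] = tv[tAH] * (1.0 - s[iH]) - tv[tBH] * s[iH];
  ds[iJ] = tv[tAJ] * (1.0 - s[iJ]) - tv[tBJ] * s[iJ];
  double INa = p.g_na * c.g_na_scale * cube(s[iM]) * s[iH] * s[iJ] * (V - ENa);

  // late sodium current: fast-Na-like activation, slow biphasic inactivation
  ds[iML] = tv[tAM] * (1.0 - s[iML]) - tv[tBM] * s[iML];
  ds[iHL]  = (tv[tHLINF] - s[iHL]) / 200.0;
  ds[iHLS] = (tv[tHLINF] - s[iHLS]) / 600.0;
  double INaL = c.g_nal_scale * cube(s[iML]) *
                (0.5 * s[iHL] + 0.5 * s[iHLS]) * (V - ENa);

  // L-type calcium current (GHK) with ATP-dependent availability
  ds[iD] = (tv[tDINF] - s[iD]) * tv[tITAUD];
  ds[iF] = (tv[tFINF] - s[iF]) * tv[tITAUF];
  double fca = 1.0 / (1.0 + Cai / p.km_fca);
  double fatp = 1.0 / (1.0 + powh(p.km_atp_lcc / s[iATP], p.hill_atp_lcc));
  aux[aFATPLCC] = fatp;
  double expv = tv[tEXPV];
  double ibarca = p.p_ca * 2.0 * p.faraday * tv[tXO2] *
    (p.gamma_cai * Cai * expv * expv - p.gamma_cao * Cao);
  double ibarna = p.p_ca_na * p.faraday * tv[tXO1] *
    (p.gamma_nai * Nai * expv - p.gamma_nao * Nao);
  double ibark = p.p_ca_k * p.faraday * tv[tXO1] *
    (p.gamma_ki * Ki * expv - p.gamma_ko * Ko);
  double gate_ca = s[iD] * s[iF] * fca * fatp;
  double ICaL_Ca = gate_ca * ibarca;
  double ICaL_Na = gate_ca * ibarna;
  double ICaL_K  = gate_ca * ibark;
  double ICaL = ICaL_Ca + ICaL_Na + ICaL_K;

  // T-type calcium
  ds[iB] = (tv[tBINF] - s[iB]) * tv[tITAUB];
  ds[iG] = (tv[tGINF] - s[iG]) * tv[tITAUG];
  double ICaT = p.g_cat * sq(s[iB]) * s[iG] * (V - ECa);

  // potassium currents
  ds[iXR] = (tv[tXRINF] - s[iXR]) * tv[tKXR];
  double IKr = p.g_kr * std::sqrt(Ko / 5.4) * s[iXR] * tv[tRKR] * (V - EK);

  ds[iXS1] = (tv[tXSINF] - s[iXS1]) * tv[tKXS];
  ds[iXS2] = (tv[tXSINF] - s[iXS2]) * tv[tKXS] * 0.25;
  double gks = p.g_ks_base * (1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / Cai, 1.4)));
  double IKs = gks * s[iXS1] * s[iXS2] * (V - EKs);

  double vk = V - EK;
  double ak1 = 1.02 / (1.0 + std::exp(0.2385 * (vk - 59.215)));
  double bk1 = (0.49124 * std::exp(0.08032 * (vk + 5.476))
              + std::exp(0.06175 * (vk - 594.31))) /
               (1.0 + std::exp(-0.5143 * (vk + 4.753)));
  double IK1 = p.g_k1 * std::sqrt(Ko / 5.4) * ak1 / (ak1 + bk1) * vk;

  double IKp = p.g_kp * vk * tv[tKPF];

  // ATP-inactivated K current, Ferrero-type nucleotide gating
  double adp_uM = s[iADP] * 1000.0;
  double km_katp = p.katp_km_base +
                   p.katp_km_adp * std::pow(adp_uM, p.katp_km_exp);
  double fkatp = 1.0 / (1.0 + powh(s[iATP] / km_katp, p.katp_hill));
  double IKATP = p.g_katp * fkatp * std::pow(Ko / 5.4, p.katp_ko_exp) * vk;

  // sodium-potassium pump: voltage, Na_i, K_o, phosphometabolites, pH
  double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  double fv_nak = 1.0 / (1.0 + 0.1245 * tv[tE01]
                       + 0.0365 * sigma / expv);
  double nai15 = Nai * std::sqrt(Nai);
  double km15 = p.km_nai_nak * std::sqrt(p.km_nai_nak);
  double f_nai = nai15 / (nai15 + km15);
  double f_ko = Ko / (Ko + p.km_ko_nak);
  double f_atp_nak = 1.0 / (1.0 + (p.km_atp_nak / s[iATP]) *
                      (1.0 + s[iADP] / p.ki_adp_nak) *
                      (1.0 + s[iPI] / p.ki_pi_nak));
  double ph_seen = c.nak_clamp ? c.nak_ph : s[iPHI];
  double h_seen = exp10_(3.0 - ph_seen);
  double h_knak = exp10_(3.0 - p.pk_nak);
  double f_ph_nak = (1.0 / (1.0 + powh(h_seen / h_knak, p.hill_nak))) /
    (1.0 / (1.0 + powh(exp10_(3.0 - p.ph_ref_nak) / h_knak, p.hill_nak)));
  aux[aFPHNAK] = f_ph_nak;
  double INaK = c.nak_scale * p.ibar_nak * fv_nak * f_nai * f_ko *
                f_atp_nak * f_ph_nak;

  // sodium-calcium exchanger (scale 0.60 x published; proton block pK 7.0,
  // Hill 0.75)
  double f_h_ncx = 1.0 /
    (1.0 + powh(Hi / exp10_(3.0 - p.pk_ncx), p.hill_ncx));
  aux[aFHNCX] = f_h_ncx;
  double eg1 = tv[tEG1];
  double na3 = cube(Nai), no3 = cube(Nao);
  double INCX = f_h_ncx * p.c_ncx * eg1 *
                (expv * na3 * Cao - no3 * Cai) /
                (1.0 + p.c2_ncx * eg1 * (expv * na3 * Cao + no3 * Cai));

  // sarcolemmal Ca pump and background currents
  double IpCa = p.ipca_max * Cai / (Cai + p.km_pca);
  double INab = p.g_nab * (V - ENa);
  double ICab = p.g_cab * (V - ECa);
  double IClb = p.g_clb * (V - ECl);

  // SR calcium handling; SERCA flux = 0.00820 x reduced-cycle rate
  double f_ph_up = 1.0 / (1.0 + Hi / exp10_(3.0 - p.pk_serca));
  double si = sq(Cai / p.kmf_serca);
  double ssr = sq(s[iCANSR] / p.kmr_serca);
  double eps_rev = (s[iADP] * s[iPI]) / (s[iATP] * p.keq_serca);
  double vcyc = p.vmax_serca * f_ph_up * (si - eps_rev * ssr) /
                (1.0 + si + ssr);
  double Jup = p.serca_factor * vcyc;           // myoplasm-referenced mM/ms
  aux[aVCYC] = vcyc;
  double Jleak = p.kleak * s[iCANSR];
  double Jtr = (s[iCANSR] - s[iCAJSR]) / p.tau_tr;
  double trig = -ICaL_Ca;
  double roinf = (trig > 0.0) ? sq(trig) / (sq(trig) + sq(p.kt_ryr)) : 0.0;
  ds[iRYRO] = (roinf - s[iRYRO]) / p.tau_ro;
  double riinf = p.km_ri / (p.km_ri + Cai);
  ds[iRYRI] = (riinf - s[iRYRI]) / p.tau_ri;
  double f_ph_ryr = 1.0 /
    (1.0 + powh(Hi / exp10_(3.0 - p.pk_ryr), p.hill_ryr));
  double Jrel_jsr = p.grel * s[iRYRO] * s[iRYRI] * f_ph_ryr *
                    (s[iCAJSR] - Cai);

  // acid transporters
  double f_act = 1.0 / (1.0 + powh(p.k_h_nhe / Hi, p.hill_nhe_i));
  double f_inh = 1.0 / (1.0 + powh(Ho / p.k_h_nhe, p.hill_nhe_o));
  double allo = f_act * f_inh;
  aux[aALLONHE] = allo;
  double JNHE = c.nhe_scale * p.v_nhe * allo * Nao / (Nao + p.km_nao_nhe);
  double JNBC = p.v_nbc * (s[iHCO3O] / (s[iHCO3O] + p.km_nbc)
                         - s[iHCO3I] / (s[iHCO3I] + p.km_nbc));
  double JCHE = p.k_che * (Clo * OHi - Cli * OHo);
  double JAE  = p.k_ae  * (Clo * s[iHCO3I] - Cli * s[iHCO3O]);

  // CO2 <-> bicarbonate equilibration (H+ production rate, mM/ms)
  double RCO2i = p.k_hyd * (s[iCO2I] - Hi * s[iHCO3I] / p.k_a_co2);
  double RCO2o = p.k_hyd * (s[iCO2O] - Ho * s[iHCO3O] / p.k_a_co2);
  double JCO2m = p.p_co2 * (s[iCO2I] - s[iCO2O]);

  // intrinsic buffering power, mM per pH unit (buffers + free protons)
  double fbi = buf_scale_i(s, p), fbo = buf_scale_o(s, p);
  double r1i = exp10_(s[iPHI] - p.buf1_pk), r2i = exp10_(s[iPHI] - p.buf2_pk);
  double beta_i = LN10 * (fbi * p.buf1_conc * r1i / sq(1.0 + r1i)
                        + fbi * p.buf2_conc * r2i / sq(1.0 + r2i) + Hi);
  double r1o = exp10_(s[iPHO] - p.buf1_pk), r2o = exp10_(s[iPHO] - p.buf2_pk);
  double beta_o = LN10 * (fbo * p.buf1_conc * r1o / sq(1.0 + r1o)
                        + fbo * p.buf2_conc * r2o / sq(1.0 + r2o) + Ho);

  // osmotic water flux (Na, K, Ca, Cl + impermeant osmolytes on both sides)
  double osm_ext = Nao + Ko + Cao + Clo + p.x_o;
  double Jw = p.k_water * (s[iOSMI] - osm_ext);  // uL/ms, >0 swells the cell
  ds[iVMYO] = Jw;
  ds[iVEXT] = -Jw;

  double Istim = c.istim;
  double conv_i = p.cap_total / (p.faraday * Vmyo);
  double conv_o = p.cap_total / (p.faraday * Vext);
  double rv = Vmyo / Vext;

  double INa_chan = INa + INaL + INab + ICaL_Na;
  double INa_tot = INa_chan + 3.0 * INCX + 3.0 * INaK;
  double dNai = -INa_tot * conv_i + JNHE + JNBC;
  double IK_tot = IKr + IKs + IK1 + IKp + IKATP + ICaL_K + Istim - 2.0 * INaK;
  double dKi = -IK_tot * conv_i;
  double dCli = IClb * conv_i + JCHE + JAE;
  double ICa_tot = ICaL_Ca + ICaT + IpCa + ICab - 2.0 * INCX;
  double jrel_myo = Jrel_jsr * p.v_jsr / Vmyo;
  double bca = 1.0 / (1.0 + p.cmdn * p.km_cmdn / sq(p.km_cmdn + Cai)
                          + p.trpn * p.km_trpn / sq(p.km_trpn + Cai));
  double dCai = bca * (-ICa_tot * conv_i * 0.5 + jrel_myo + Jleak - Jup);
  double bjsr = 1.0 / (1.0 + p.csqn * p.km_csqn / sq(p.km_csqn + s[iCAJSR]));
  ds[iCAJSR] = bjsr * (Jtr - Jrel_jsr);
  ds[iCANSR] = (Jup - Jleak) * Vmyo / p.v_nsr - Jtr * p.v_jsr / p.v_nsr;

  // dilution of dissolved myoplasmic species by water flux
  double dil = Jw / Vmyo;
  ds[iNAI] = dNai - Nai * dil;
  ds[iKI]  = dKi - Ki * dil;
  ds[iCLI] = dCli - Cli * dil;
  ds[iCAI] = dCai - bca * Cai * dil;

  // intracellular pH / bicarbonate / CO2
  ds[iPHI] = (JNHE - JCHE - RCO2i) / beta_i;
  ds[iHCO3I] = RCO2i + JNBC - JAE - s[iHCO3I] * dil;
  double prod_co2 = p.j_co2_prod * c.co2_prod_scale;
  ds[iCO2I] = -RCO2i - JCO2m + prod_co2 - s[iCO2I] * dil;
  ds[iANION] = -s[iANION] * dil;

  // reperfusion clearance of the accumulated metabolic acid: the anion
  // and a proton leave together (neutral pair), driving pH recovery that
  // does not depend on the NHE
  if (c.phase == 2 && s[iANION] > 0.0) {
    double ja = s[iANION] / p.tau_anion_wash;
    ds[iANION] += -ja;
    ds[iPHI] += ja / beta_i;
  }

  // extracellular compartment: isolated during ischemia
  if (c.phase == 1) {
    double dil_o = -Jw / Vext;
    ds[iNAO] = INa_tot * conv_o - (JNHE + JNBC) * rv - Nao * dil_o;
    ds[iKO]  = IK_tot * conv_o - Ko * dil_o;
    ds[iCAO] = ICa_tot * conv_o * 0.5 - Cao * dil_o;
    ds[iCLO] = -IClb * conv_o - (JCHE + JAE) * rv - Clo * dil_o;
    ds[iPHO] = (-JNHE * rv + JCHE * rv - RCO2o) / beta_o;
    ds[iHCO3O] = RCO2o - (JNBC - JAE) * rv - s[iHCO3O] * dil_o;
    ds[iCO2O] = JCO2m * rv - RCO2o - s[iCO2O] * dil_o;
    // generic anion: counter-ion to the imposed metabolic acid production
    if (c.pHi_prescribed) {
      double dhtot = -beta_i * c.dphi_dt_presc;
      ds[iANION] += dhtot + JNHE - JCHE - RCO2i;
    }
  }

  double Itot = INa + INaL + ICaL + ICaT + IKr + IKs + IK1 + IKp + IKATP
              + INaK + INCX + IpCa + INab + ICab + IClb + Istim;

  aux[aINA] = INa; aux[aINAL] = INaL; aux[aICAL] = ICaL;
  aux[aICALCA] = ICaL_Ca; aux[aICALNA] = ICaL_Na; aux[aICALK] = ICaL_K;
  aux[aICAT] = ICaT; aux[aIKR] = IKr; aux[aIKS] = IKs; aux[aIK1] = IK1;
  aux[aIKP] = IKp; aux[aIKATP] = IKATP; aux[aINAK] = INaK; aux[aINCX] = INCX;
  aux[aIPCA] = IpCa; aux[aINAB] = INab; aux[aICAB] = ICab; aux[aICLB] = IClb;
  aux[aISTIM] = Istim;
  aux[aJUP] = Jup; aux[aJREL] = jrel_myo; aux[aJLEAK] = Jleak;
  aux[aJTR] = Jtr; aux[aJNHE] = JNHE; aux[aJNBC] = JNBC; aux[aJCHE] = JCHE;
  aux[aJAE] = JAE; aux[aJCO2M] = JCO2m; aux[aRCO2I] = RCO2i;
  aux[aRCO2O] = RCO2o; aux[aBETAI] = beta_i; aux[aBETAO] = beta_o;
  aux[aJW] = Jw; aux[aITOT] = Itot;
}

// ------------------------------------------------------------- R helpers --
static NumericVector named_state(const double* s) {
  NumericVector out(NSTATE);
  for (int k = 0; k < NSTATE; ++k) out[k] = s[k];
  CharacterVector nm(NSTATE);
  for (int k = 0; k < NSTATE; ++k) nm[k] = STATE_NAMES[k];
  out.attr("names") = nm;
  return out;
}

static void fill_state(const NumericVector& v, double* s) {
  if (v.size() != NSTATE) stop("state vector must have %d entries", NSTATE);
  for (int k = 0; k < NSTATE; ++k) s[k] = v[k];
}

static Ctl make_ctl(const List& l) {
  Ctl c;
  c.phase = as<int>(l["phase"]);
  c.g_na_scale = as<double>(l["g_na_scale"]);
  c.g_nal_scale = as<double>(l["g_nal_scale"]);
  c.nhe_scale = as<double>(l["nhe_scale"]);
  c.nak_scale = as<double>(l["nak_scale"]);
  c.nak_clamp = as<bool>(l["nak_clamp"]);
  c.nak_ph = as<double>(l["nak_ph"]);
  c.istim = as<double>(l["istim"]);
  c.pHi_prescribed = as<bool>(l["pHi_prescribed"]);
  c.dphi_dt_presc = as<double>(l["dphi_dt_presc"]);
  c.co2_prod_scale = as<double>(l["co2_prod_scale"]);
  return c;
}

// [[Rcpp::export]]
CharacterVector cpp_state_names() {
  CharacterVector nm(NSTATE);
  for (int k = 0; k < NSTATE; ++k) nm[k] = STATE_NAMES[k];
  return nm;
}

// [[Rcpp::export]]
CharacterVector cpp_aux_names() {
  CharacterVector nm(NAUX);
  for (int k = 0; k < NAUX; ++k) nm[k] = AUX_NAMES[k];
  return nm;
}

// [[Rcpp::export]]
double cpp_charge_mol(NumericVector state, List params) {
  double s[NSTATE]; fill_state(state, s);
  Par p = make_par(params);
  update_derived(s, p);
  return charge_mol(s, p);
}

// [[Rcpp::export]]
double cpp_voltage(NumericVector state, List params) {
  double s[NSTATE]; fill_state(state, s);
  Par p = make_par(params);
  update_derived(s, p);
  return voltage_from_charge(s, p);
}

// [[Rcpp::export]]
NumericVector cpp_update_derived(NumericVector state, List params) {
  double s[NSTATE]; fill_state(state, s);
  Par p = make_par(params);
  update_derived(s, p);
  if (p.calibrated) s[iV] = voltage_from_charge(s, p);
  return named_state(s);
}

// [[Rcpp::export]]
List cpp_rates(NumericVector state, List params, List ctl) {
  double s[NSTATE]; fill_state(state, s);
  Par p = make_par(params);
  Ctl c = make_ctl(ctl);
  update_derived(s, p);
  double ds[NSTATE], aux[NAUX];
  model_eval(s, p, c, ds, aux);
  NumericVector dv(NSTATE), av(NAUX);
  CharacterVector dn(NSTATE), an(NAUX);
  for (int k = 0; k < NSTATE; ++k) { dv[k] = ds[k]; dn[k] = STATE_NAMES[k]; }
  for (int k = 0; k < NAUX; ++k) { av[k] = aux[k]; an[k] = AUX_NAMES[k]; }
  dv.attr("names") = dn; av.attr("names") = an;
  return List::create(_["V"] = ds[iV], _["deriv"] = dv, _["aux"] = av);
}

// Closed-form calibration constants from the initial state: the charge
// offset, stationarity of Cl, pH, CO2 and the SR at t = 0, and the pump
// scale sized to the initial sodium influx times a pacing reserve.
// [[Rcpp::export]]
List cpp_calibrate(NumericVector state, List params, double v_init,
                   double nak_reserve) {
  double s[NSTATE]; fill_state(state, s);
  List par2 = clone(params);
  Par p0 = make_par(params);
  update_derived(s, p0);
  double n0 = charge_mol(s, p0);
  par2["n_offset"] = n0;
  par2["v_at_offset"] = v_init;
  // neutral placeholder values so that the probe evaluation is well defined
  par2["k_che"] = 0.0; par2["k_ae"] = 0.0; par2["g_clb"] = 0.0;
  par2["kleak"] = 0.0; par2["ibar_nak"] = 1.0; par2["j_co2_prod"] = 0.0;
  Par p = make_par(par2);
  Ctl c; c.phase = 0; c.g_na_scale = 1.0; c.g_nal_scale = p.g_nal;
  c.nhe_scale = 1.0; c.nak_scale = 1.0; c.nak_clamp = false; c.nak_ph = 7.15;
  c.istim = 0.0; c.pHi_prescribed = false; c.dphi_dt_presc = 0.0;
  c.co2_prod_scale = 0.0;
  double ds[NSTATE], aux[NAUX];
  model_eval(s, p, c, ds, aux);

  double Hi = exp10_(3.0 - s[iPHI]), Ho = exp10_(3.0 - s[iPHO]);
  double OHi = p.kw_mM2 / Hi, OHo = p.kw_mM2 / Ho;
  double che_drive = s[iCLO] * OHi - s[iCLI] * OHo;
  double ae_drive = s[iCLO] * s[iHCO3I] - s[iCLI] * s[iHCO3O];
  double jnhe0 = aux[aJNHE], jnbc0 = aux[aJNBC];
  double rco2i0 = aux[aRCO2I];
  // pH stationarity: J_NHE - J_CHE - R_CO2_i = 0
  double k_che = (jnhe0 - rco2i0) / che_drive;
  if (k_che < 0) k_che = 0.0;
  double jche0 = k_che * che_drive;
  // bicarbonate stationarity: R_CO2_i + J_NBC - J_AE = 0
  double k_ae = (rco2i0 + jnbc0) / ae_drive;
  if (k_ae < 0) k_ae = 0.0;
  double jae0 = k_ae * ae_drive;
  // chloride stationarity: I_Clb*conv + J_CHE + J_AE = 0
  double conv_i = p.cap_total / (p.faraday * s[iVMYO]);
  double ecl = -p.rtf * std::log(s[iCLO] / s[iCLI]);
  double g_clb = -(jche0 + jae0) / (conv_i * (v_init - ecl));
  // CO2 stationarity: production balances membrane transport at t = 0
  double j_co2_prod = aux[aJCO2M];
  // SR stationarity: leak balances uptake at the initial SR load
  double kleak = aux[aJUP] / s[iCANSR];
  if (kleak < 0) kleak = 0.0;
  // pump scale: the initial (diastolic) Na influx times a pacing reserve
  double na_in0 = -(aux[aINA] + aux[aINAL] + aux[aINAB] + aux[aICALNA]
                    + 3.0 * aux[aINCX]) * conv_i + jnhe0 + jnbc0;
  double nak_factors = aux[aINAK];  // probe run used ibar_nak = 1
  double ibar_nak = nak_reserve * na_in0 / (3.0 * conv_i * nak_factors);
  return List::create(
    _["n_offset"] = n0, _["v_at_offset"] = v_init,
    _["k_che"] = k_che, _["k_ae"] = k_ae, _["g_clb"] = g_clb,
    _["j_co2_prod"] = j_co2_prod, _["kleak"] = kleak,
    _["ibar_nak"] = ibar_nak);
}

// ------------------------------------------------------- protocol driver --
struct Sched {
  double pre_ms, isch_ms, rep_ms, dt, period, stim_amp, stim_width;
  double tau_pho, tau_wash, tau_osm, tau_metab_rec;
  double ph_end_isch, tau_ph_isch;
  double osm_slope, isch_ref_ms;
  double atp_drop_frac, atp_drop_exp, pcr_floor, tau_pcr;
  double pcr_rec_frac;
  double compress;
  double g_na_isch_scale, g_nal_normal, g_nal_isch;
  double tau_co2_prod;
};

static double getod(const List& l, const char* nm, double def) {
  if (!l.containsElementNamed(nm)) return def;
  double v = as<double>(l[nm]);
  return R_finite(v) ? v : def;
}

// [[Rcpp::export]]
List cpp_run(NumericVector state0, List params, List schedule, List interv,
             int out_every, bool record_series, bool record_beats,
             List anchors) {
  Par p = make_par(params);
  if (!p.calibrated) stop("parameters are not calibrated");
  Sched sc;
  sc.pre_ms = getp(schedule, "pre_ms");
  sc.isch_ms = getp(schedule, "isch_ms");
  sc.rep_ms = getp(schedule, "rep_ms");
  sc.dt = getp(schedule, "dt");
  sc.period = getp(schedule, "period");
  sc.stim_amp = getp(schedule, "stim_amp");
  sc.stim_width = getp(schedule, "stim_width");
  sc.tau_pho = getp(schedule, "tau_pho");
  sc.tau_wash = getp(schedule, "tau_wash");
  sc.tau_osm = getp(schedule, "tau_osm");
  sc.tau_metab_rec = getp(schedule, "tau_metab_rec");
  sc.ph_end_isch = getp(schedule, "ph_end_isch");
  sc.tau_ph_isch = getp(schedule, "tau_ph_isch");
  sc.osm_slope = getp(schedule, "osm_slope");
  sc.isch_ref_ms = getp(schedule, "isch_ref_ms");
  sc.atp_drop_frac = getp(schedule, "atp_drop_frac");
  sc.atp_drop_exp = getp(schedule, "atp_drop_exp");
  sc.pcr_floor = getp(schedule, "pcr_floor");
  sc.tau_pcr = getp(schedule, "tau_pcr");
  sc.pcr_rec_frac = getp(schedule, "pcr_rec_frac");
  sc.compress = getp(schedule, "compress");
  sc.g_na_isch_scale = getp(schedule, "g_na_isch_scale");
  sc.g_nal_normal = getp(schedule, "g_nal_normal");
  sc.g_nal_isch = getp(schedule, "g_nal_isch");
  sc.tau_co2_prod = getp(schedule, "tau_co2_prod");

  double nhe_scale = getp(interv, "nhe_scale");
  int nhe_onset = as<int>(interv["nhe_onset"]);  // 0 none,1 rep,2 mid,3 isch
  bool nak_clamp = as<bool>(interv["nak_clamp"]);
  double nak_clamp_ph = getp(interv, "nak_clamp_ph");  // NA -> pre-end pH
  double nak_scale = getp(interv, "nak_scale");
  double atp_rec_frac = getp(interv, "atp_rec_frac");

  const double dt = sc.dt;
  const long n_pre = (long)std::llround(sc.pre_ms / dt);
  const long n_isch = (long)std::llround(sc.isch_ms / dt);
  const long n_rep = (long)std::llround(sc.rep_ms / dt);
  const long n_tot = n_pre + n_isch + n_rep;

  double t_isch0 = n_pre * dt;
  double t_rep0 = (n_pre + n_isch) * dt;
  double nhe_onset_t = R_PosInf;
  if (nhe_onset == 1) nhe_onset_t = t_rep0;
  else if (nhe_onset == 2) nhe_onset_t = t_isch0 + 0.5 * sc.isch_ms;
  else if (nhe_onset == 3) nhe_onset_t = t_isch0;

  double s[NSTATE], ds[NSTATE], aux[NAUX];
  fill_state(state0, s);
  update_derived(s, p);
  s[iV] = voltage_from_charge(s, p);
  s[iT] = 0.0;

  // washout / clamp targets: the pre-ischemic extracellular state
  // (overridable so that a run can resume from a mid-protocol snapshot)
  const double wNao = getod(anchors, "na_o", s[iNAO]);
  const double wKo = getod(anchors, "k_o", s[iKO]);
  const double wCao = getod(anchors, "ca_o", s[iCAO]);
  const double wClo = getod(anchors, "cl_o", s[iCLO]);
  const double wHCO3o = getod(anchors, "hco3_o", s[iHCO3O]);
  const double wCO2o = getod(anchors, "co2_o", s[iCO2O]);
  const double wpHo = getod(anchors, "ph_o", s[iPHO]);
  const double osm_normal = getod(anchors, "osm_normal", s[iOSMI]);
  const double isch_off = getod(anchors, "isch_t_offset_ms", 0.0);

  // phase-entry anchors (filled at the boundaries unless supplied)
  double ph_anchor = getod(anchors, "ph_anchor", s[iPHI]);
  double atp_pre = getod(anchors, "atp_pre", s[iATP]);
  double pcr_pre = getod(anchors, "pcr_pre", s[iPCR]);
  double atp_end_isch = s[iATP], pcr_end_isch = s[iPCR];
  double nak_ph_normal = getod(anchors, "nak_ph_normal", s[iPHI]);
  const bool anchored = anchors.containsElementNamed("ph_anchor");

  long n_series = 0;
  if (record_series) n_series = n_tot / out_every + 2;
  NumericMatrix series(record_series ? n_series : 1,
                       record_series ? (NSTATE + NAUX) : 1);
  long srow = 0;

  long max_beats = (long)(n_tot * dt / sc.period) + 3;
  NumericMatrix beats(record_beats ? max_beats : 1, record_beats ? 9 : 1);
  long brow = 0;
  long cur_beat = -1;
  double bvmax = 0, bvmin = 0, bcamax = 0, bcamin = 0, bnakmax = 0,
         bnakmin = 0, btstart = 0;

  // reperfusion sodium ledger (sampled every 10th step, as written data)
  double led[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  long led_samples = 0;

  NumericVector snap_pre, snap_isch;
  bool have_pre = false, have_isch = false;

  const int conc_idx[] = {iNAI, iNAO, iKI, iKO, iCLI, iCLO, iCAI, iCAO,
                          iCAJSR, iCANSR, iCO2I, iCO2O, iHCO3I, iHCO3O};
  const int nconc = 14;

  VTab vtab;
  vtab.build(p.rtf, p.gamma_ncx);

  Ctl c;
  c.nak_ph = nak_ph_normal;

  for (long k = 0; k <= n_tot; ++k) {
    double t = k * dt;
    int phase = (k < n_pre) ? 0 : (k < n_pre + n_isch ? 1 : 2);
    if (n_isch == 0 && n_rep == 0) phase = 0;

    // ---- phase boundary bookkeeping ----
    if (!have_pre && k == n_pre && (n_isch > 0 || n_rep > 0)) {
      if (!anchored) {
        ph_anchor = s[iPHI]; atp_pre = s[iATP]; pcr_pre = s[iPCR];
        nak_ph_normal = s[iPHI];
      }
      snap_pre = named_state(s); have_pre = true;
    }
    if (!have_isch && k == n_pre + n_isch && n_rep > 0 && k >= n_pre) {
      atp_end_isch = s[iATP]; pcr_end_isch = s[iPCR];
      snap_isch = named_state(s); have_isch = true;
    }

    // ---- prescriptions / relaxations (before the step from t); the
    // terminal iteration only records, so the final state is the pure
    // Euler result and segment restarts compose exactly ----
    double dphi_presc = 0.0;
    if (k == n_tot) {
      update_derived(s, p);
    } else if (phase == 1 && n_isch > 0) {
      double tt = (t - t_isch0 + isch_off) * sc.compress;  // trajectory ms
      double e = std::exp(-tt / sc.tau_ph_isch);
      s[iPHI] = sc.ph_end_isch + (ph_anchor - sc.ph_end_isch) * e;
      dphi_presc = -(ph_anchor - sc.ph_end_isch) / sc.tau_ph_isch * e *
                   sc.compress;
      double ttc = std::min(tt, sc.isch_ref_ms);
      double atp = atp_pre * (1.0 - sc.atp_drop_frac *
                   std::pow(ttc / sc.isch_ref_ms, sc.atp_drop_exp));
      s[iATP] = std::max(atp, 0.05 * atp_pre);
      s[iPCR] = pcr_pre * (sc.pcr_floor + (1.0 - sc.pcr_floor) *
                           std::exp(-tt / sc.tau_pcr));
      s[iOSMI] = osm_normal + sc.osm_slope * tt;
    } else if (phase == 2) {
      double tt = (t - t_rep0) * sc.compress;
      double fac = dt * sc.compress;
      s[iPHO] += fac / sc.tau_pho * (wpHo - s[iPHO]);
      s[iNAO]  += fac / sc.tau_wash * (wNao - s[iNAO]);
      s[iKO]   += fac / sc.tau_wash * (wKo - s[iKO]);
      s[iCAO]  += fac / sc.tau_wash * (wCao - s[iCAO]);
      s[iCLO]  += fac / sc.tau_wash * (wClo - s[iCLO]);
      s[iHCO3O] += fac / sc.tau_wash * (wHCO3o - s[iHCO3O]);
      s[iCO2O] += fac / sc.tau_wash * (wCO2o - s[iCO2O]);
      s[iOSMI] += fac / sc.tau_osm * (osm_normal - s[iOSMI]);
      double er = std::exp(-tt / sc.tau_metab_rec);
      double atp_target = atp_rec_frac * atp_pre;
      double pcr_target = sc.pcr_rec_frac * pcr_pre;
      s[iATP] = atp_target + (atp_end_isch - atp_target) * er;
      s[iPCR] = pcr_target + (pcr_end_isch - pcr_target) * er;
    }
    if (k < n_tot) update_derived(s, p);

    // ---- control flags ----
    c.phase = phase;
    c.g_na_scale = (phase == 1) ? sc.g_na_isch_scale : 1.0;
    c.g_nal_scale = (phase == 1) ? sc.g_nal_isch : sc.g_nal_normal;
    c.nhe_scale = (t >= nhe_onset_t) ? nhe_scale : 1.0;
    c.nak_scale = (phase == 2) ? nak_scale : 1.0;
    c.nak_clamp = (phase == 2) && nak_clamp;
    c.nak_ph = R_finite(nak_clamp_ph) ? nak_clamp_ph : nak_ph_normal;
    c.pHi_prescribed = (phase == 1);
    c.dphi_dt_presc = dphi_presc;
    c.co2_prod_scale = (phase == 1)
      ? std::exp(-(t - t_isch0 + isch_off) * sc.compress / sc.tau_co2_prod)
      : 1.0;
    double beat_f = std::floor(t / sc.period + 1e-9);
    double tin = t - beat_f * sc.period;
    c.istim = (tin < sc.stim_width - 1e-9) ? sc.stim_amp : 0.0;

    model_eval(s, p, c, ds, aux, &vtab);
    s[iV] = ds[iV];

    // ---- recording ----
    if (record_series && (k % out_every == 0 || k == n_tot)) {
      if (srow < series.nrow()) {
        for (int q = 0; q < NSTATE; ++q) series(srow, q) = s[q];
        for (int q = 0; q < NAUX; ++q) series(srow, NSTATE + q) = aux[q];
        ++srow;
      }
    }
    if (record_beats) {
      long beat = (long)beat_f;
      if (beat != cur_beat) {
        if (cur_beat >= 0 && brow < beats.nrow()) {
          beats(brow, 0) = cur_beat; beats(brow, 1) = btstart;
          beats(brow, 2) = bvmax; beats(brow, 3) = bvmin;
          beats(brow, 4) = bcamax; beats(brow, 5) = bcamin;
          beats(brow, 6) = bnakmax; beats(brow, 7) = bnakmin;
          beats(brow, 8) = (bvmax > -30.0) ? 1.0 : 0.0;
          ++brow;
        }
        cur_beat = beat; btstart = beat * sc.period;
        bvmax = bvmin = s[iV]; bcamax = bcamin = s[iCAI];
        bnakmax = bnakmin = aux[aINAK];
      } else {
        if (s[iV] > bvmax) bvmax = s[iV];
        if (s[iV] < bvmin) bvmin = s[iV];
        if (s[iCAI] > bcamax) bcamax = s[iCAI];
        if (s[iCAI] < bcamin) bcamin = s[iCAI];
        if (aux[aINAK] > bnakmax) bnakmax = aux[aINAK];
        if (aux[aINAK] < bnakmin) bnakmin = aux[aINAK];
      }
    }
    if (phase == 2) {
      long krep = k - (n_pre + n_isch);
      if (krep % 10 == 0) {
        double w = 10.0 * dt;
        double molA = p.cap_total * 1e-9 / p.faraday * w;  // per uA/uF
        led[0] += aux[aJNHE] * w * s[iVMYO] * 1e-9;        // NHE
        led[1] += aux[aJNBC] * w * s[iVMYO] * 1e-9;        // NBC
        led[2] += -3.0 * aux[aINCX] * molA;                // NCX
        led[3] += -3.0 * aux[aINAK] * molA;                // NaK
        led[4] += -aux[aINA] * molA;                       // I_Na
        led[5] += -aux[aINAB] * molA;                      // I_Nab
        led[6] += -aux[aINAL] * molA;                      // I_NaL
        led[7] += -aux[aICALNA] * molA;                    // I_CaL(Na)
        ++led_samples;
      }
    }

    if (k == n_tot) break;

    // ---- forward Euler update ----
    for (int q = iPHI; q < iT; ++q) {
      if (q == iPHI && c.pHi_prescribed) continue;
      s[q] += dt * ds[q];
    }
    // prescribed / clamped variables are re-assigned at the next step top;
    // keep extracellular state frozen where the phase dictates it
    if (phase == 0) {
      s[iNAO] = wNao; s[iKO] = wKo; s[iCAO] = wCao; s[iCLO] = wClo;
      s[iHCO3O] = wHCO3o; s[iCO2O] = wCO2o; s[iPHO] = wpHo;
    }
    s[iT] = (k + 1) * dt;

    // ---- guards ----
    if (!R_finite(s[iV]) || s[iV] < -300.0 || s[iV] > 300.0)
      stop("membrane potential diverged (V = %g mV) at t = %g ms (phase %d)",
           s[iV], t, phase);
    for (int q = 0; q < nconc; ++q) {
      double v = s[conc_idx[q]];
      if (!R_finite(v) || v <= 0.0)
        stop("concentration '%s' left (0, Inf) (value %g) at t = %g ms "
             "(phase %d)", STATE_NAMES[conc_idx[q]], v, t, phase);
    }
    if (s[iVMYO] <= 0.0 || s[iVEXT] <= 0.0)
      stop("compartment volume became non-positive at t = %g ms", t);
    if (s[iANION] < -1e-6)
      stop("generic anion concentration became negative (%g mM) at t = %g ms",
           s[iANION], t);
    if (s[iANION] < 0.0) s[iANION] = 0.0;
  }

  // flush the last beat
  if (record_beats && cur_beat >= 0 && brow < beats.nrow()) {
    beats(brow, 0) = cur_beat; beats(brow, 1) = btstart;
    beats(brow, 2) = bvmax; beats(brow, 3) = bvmin;
    beats(brow, 4) = bcamax; beats(brow, 5) = bcamin;
    beats(brow, 6) = bnakmax; beats(brow, 7) = bnakmin;
    beats(brow, 8) = (bvmax > -30.0) ? 1.0 : 0.0;
    ++brow;
  }

  List out;
  if (record_series) {
    NumericMatrix ser = series(Range(0, srow - 1), _);
    CharacterVector cn(NSTATE + NAUX);
    for (int q = 0; q < NSTATE; ++q) cn[q] = STATE_NAMES[q];
    for (int q = 0; q < NAUX; ++q) cn[NSTATE + q] = AUX_NAMES[q];
    colnames(ser) = cn;
    out["series"] = ser;
  }
  if (record_beats && brow > 0) {
    NumericMatrix bt = beats(Range(0, brow - 1), _);
    colnames(bt) = CharacterVector::create(
      "beat", "t_start", "V_max", "V_min", "Ca_max", "Ca_min",
      "I_NaK_max", "I_NaK_min", "ap_elicited");
    out["beats"] = bt;
  }
  NumericVector ledger(8);
  ledger[0] = led[0]; ledger[1] = led[1]; ledger[2] = led[2];
  ledger[3] = led[3]; ledger[4] = led[4]; ledger[5] = led[5];
  ledger[6] = led[6]; ledger[7] = led[7];
  ledger.attr("names") = CharacterVector::create(
    "NHE", "NBC", "NCX", "NaK", "I_Na", "I_Nab", "I_NaL", "I_CaL_Na");
  out["ledger"] = ledger;
  out["ledger_samples"] = (double)led_samples;
  out["final_state"] = named_state(s);
  if (have_pre) out["snapshot_pre_end"] = snap_pre;
  if (have_isch) out["snapshot_ischemia_end"] = snap_isch;
  out["n_steps"] = (double)n_tot;
  return out;
}
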