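/* Compiled right-hand side of the mouse atrial myocyte model, called by
 * deSolve (lsoda) through the standard compiled-model interface.
 *
 * This file mirrors, equation for equation, the reference implementation in
 * R/deriv.R, R/currents.R, R/markov.R and R/calcium.R; a testthat
 * consistency check holds the two together. Parameter and state index
 * macros follow the order of .PARAM_DEFAULTS (R/parameters.R) and
 * .STATE_NAMES (R/state.R).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 207
#define P_temp p[0]
#define P_cm p[1]
#define P_vcell p[2]
#define P_f_myo p[3]
#define P_f_sr p[4]
#define P_f_sl p[5]
#define P_f_junc p[6]
#define P_nao p[7]
#define P_ko p[8]
#define P_clo p[9]
#define P_cao p[10]
#define P_d_j_sl p[11]
#define P_d_sl_myo p[12]
#define P_g_na p[13]
#define P_g_nal_parent p[14]
#define P_f_nal p[15]
#define P_tau_hl p[16]
#define P_na_mshift p[17]
#define P_g_nab p[18]
#define P_g_cal_parent p[19]
#define P_f_cal p[20]
#define P_cal_shift p[21]
#define P_cal_vh p[22]
#define P_cal_k p[23]
#define P_cal_r0 p[24]
#define P_cal_k1 p[25]
#define P_cal_k2 p[26]
#define P_cal_kcdi p[27]
#define P_cal_kd_cdi p[28]
#define P_cal_rcdi p[29]
#define P_cal_kif p[30]
#define P_cal_kir p[31]
#define P_cal_rec2 p[32]
#define P_cal_kvdi p[33]
#define P_cal_vdi_vh p[34]
#define P_cal_vdi_k p[35]
#define P_cal_rvdi p[36]
#define P_cal_kvf p[37]
#define P_cal_kvr p[38]
#define P_cal_rec2v p[39]
#define P_g_to p[40]
#define P_ito_a p[41]
#define P_ito_sa p[42]
#define P_ito_b p[43]
#define P_ito_sb p[44]
#define P_ito_ki p[45]
#define P_ito_r0 p[46]
#define P_ito_sr p[47]
#define P_ito_kis1f p[48]
#define P_ito_kis1r p[49]
#define P_ito_kis2f p[50]
#define P_ito_kis2r p[51]
#define P_q10_ito_kin p[52]
#define P_q10_ito_cond p[53]
#define P_texp_ito p[54]
#define P_g_kur p[55]
#define P_kur_a p[56]
#define P_kur_sa p[57]
#define P_kur_b p[58]
#define P_kur_sb p[59]
#define P_kur_scale p[60]
#define P_kur_ki p[61]
#define P_kur_ri p[62]
#define P_q10_kur_kin p[63]
#define P_q10_kur_cond p[64]
#define P_texp_kur p[65]
#define P_g_kr p[66]
#define P_kr_a3 p[67]
#define P_kr_s3 p[68]
#define P_kr_b3 p[69]
#define P_kr_sb3 p[70]
#define P_kr_a2 p[71]
#define P_kr_s2 p[72]
#define P_kr_b2 p[73]
#define P_kr_sb2 p[74]
#define P_kr_ao p[75]
#define P_kr_so p[76]
#define P_kr_bo p[77]
#define P_kr_sbo p[78]
#define P_kr_ki p[79]
#define P_kr_ski p[80]
#define P_kr_ri p[81]
#define P_kr_sri p[82]
#define P_g_ss p[83]
#define P_ss_vh p[84]
#define P_ss_k p[85]
#define P_ss_tau0 p[86]
#define P_ss_tau1 p[87]
#define P_ss_tvh p[88]
#define P_ss_tk p[89]
#define P_q10_ss p[90]
#define P_texp_ss p[91]
#define P_tref_cond_ss p[92]
#define P_g_k1 p[93]
#define P_g_kb p[94]
#define P_kb_vh p[95]
#define P_kb_k p[96]
#define P_g_kach p[97]
#define P_ach p[98]
#define P_kach_k05 p[99]
#define P_g_kca p[100]
#define P_kca_kd p[101]
#define P_kca_h p[102]
#define P_g_clca p[103]
#define P_clca_kd p[104]
#define P_g_clb p[105]
#define P_g_cab p[106]
#define P_ibar_nak_parent p[107]
#define P_f_nak p[108]
#define P_km_naip p[109]
#define P_km_ko p[110]
#define P_ibar_ncx p[111]
#define P_ncx_eta p[112]
#define P_ncx_ksat p[113]
#define P_km_cai p[114]
#define P_km_cao p[115]
#define P_km_nai p[116]
#define P_km_nao p[117]
#define P_ncx_kdact p[118]
#define P_ibar_pmca p[119]
#define P_km_pca p[120]
#define P_vmax_serca_parent p[121]
#define P_f_vmax p[122]
#define P_kmf_parent p[123]
#define P_f_kmf p[124]
#define P_kmr p[125]
#define P_hill_serca p[126]
#define P_ko_ca p[127]
#define P_kom p[128]
#define P_ki_ca p[129]
#define P_kim p[130]
#define P_ec50sr_parent p[131]
#define P_f_ec50 p[132]
#define P_maxsr p[133]
#define P_minsr p[134]
#define P_ks_rel p[135]
#define P_kleak p[136]
#define P_tnc_bmax p[137]
#define P_tnc_kon p[138]
#define P_tnc_koff p[139]
#define P_cam_bmax p[140]
#define P_cam_kon p[141]
#define P_cam_koff p[142]
#define P_srb_bmax p[143]
#define P_srb_kon p[144]
#define P_srb_koff p[145]
#define P_sllsl_bmax p[146]
#define P_sllsl_kon p[147]
#define P_sllsl_koff p[148]
#define P_slhsl_bmax p[149]
#define P_slhsl_kon p[150]
#define P_slhsl_koff p[151]
#define P_sllj_bmax p[152]
#define P_sllj_kon p[153]
#define P_sllj_koff p[154]
#define P_slhj_bmax p[155]
#define P_slhj_kon p[156]
#define P_slhj_koff p[157]
#define P_csqn_bmax p[158]
#define P_csqn_kon p[159]
#define P_csqn_koff p[160]
#define P_ck_kact p[161]
#define P_ck_kdeact p[162]
#define P_ck_kdj p[163]
#define P_ck_kdsl p[164]
#define P_ck_kdcyt p[165]
#define P_ck_hill p[166]
#define P_plb_kp p[167]
#define P_plb_kdp p[168]
#define P_ck_fltcc p[169]
#define P_ck_fryr p[170]
#define P_ck_fleak p[171]
#define P_kserca_mid p[172]
#define P_kserca_hill p[173]
#define P_pka_ltcc p[174]
#define P_pka_plb p[175]
#define P_pka_nak p[176]
#define P_pka_ryr p[177]
#define P_vm_kur p[178]
#define P_vm_k1 p[179]
#define P_b_na p[180]
#define P_b_nal p[181]
#define P_b_cal p[182]
#define P_b_to p[183]
#define P_b_kur p[184]
#define P_b_kr p[185]
#define P_b_ss p[186]
#define P_b_k1 p[187]
#define P_b_kb p[188]
#define P_b_kca p[189]
#define P_b_kach p[190]
#define P_b_clca p[191]
#define P_b_ncx p[192]
#define P_b_nak p[193]
#define P_b_pmca p[194]
#define P_b_serca p[195]
#define P_b_cab p[196]
#define P_stim_amp p[197]
#define P_vclamp_on p[198]
#define P_clamp_nai p[199]
#define P_clamp_ki p[200]
#define P_clamp_cli p[201]
#define P_clamp_cai p[202]
#define P_caff_ryr p[203]
#define P_ryr_hill p[204]
#define P_ryr_kd p[205]
#define P_k1_rect p[206]

#define NSTATE 55
#define S_V 0
#define S_cal_C2 1
#define S_cal_C1 2
#define S_cal_O 3
#define S_cal_I1Ca 4
#define S_cal_I2Ca 5
#define S_cal_I1V 6
#define S_cal_I2V 7
#define S_ito_C3 8
#define S_ito_C2 9
#define S_ito_C1 10
#define S_ito_O 11
#define S_ito_I 12
#define S_ito_IS1 13
#define S_ito_IS2 14
#define S_kur_C4 15
#define S_kur_C3 16
#define S_kur_C2 17
#define S_kur_C1 18
#define S_kur_O 19
#define S_kur_I 20
#define S_kr_C3 21
#define S_kr_C2 22
#define S_kr_C1 23
#define S_kr_O 24
#define S_kr_I 25
#define S_ryr_R 26
#define S_ryr_O 27
#define S_ryr_I 28
#define S_ryr_RI 29
#define S_m 30
#define S_h 31
#define S_j 32
#define S_mL 33
#define S_hL 34
#define S_x_ss 35
#define S_Na_i 36
#define S_K_i 37
#define S_Cl_i 38
#define S_Ca_i 39
#define S_Ca_sl 40
#define S_Ca_j 41
#define S_Ca_sr 42
#define S_TnCL 43
#define S_CaM 44
#define S_SRB 45
#define S_SLLsl 46
#define S_SLHsl 47
#define S_SLLj 48
#define S_SLHj 49
#define S_Csqn 50
#define S_ck_j 51
#define S_ck_sl 52
#define S_ck_cyt 53
#define S_Ph_PLB 54

#define FARADAY 96485.0

static double p[NPAR];

void mamyo_initmod(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static double q10f(double q10, double texp, double tsim)
{
    return pow(q10, (tsim - texp) / 10.0);
}

void mamyo_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double tc = P_temp;
    const double rtf = 1000.0 * 8.314 * (tc + 273.15) / FARADAY;
    const double V = y[S_V];
    int k;

    /* reversal potentials */
    const double e_na = rtf * log(P_nao / y[S_Na_i]);
    const double e_k  = rtf * log(P_ko / y[S_K_i]);
    const double e_cl = -rtf * log(P_clo / y[S_Cl_i]);
    const double e_ca = rtf / 2.0 * log(P_cao / y[S_Ca_sl]);

    /* ---- Na+ currents -------------------------------------------------- */
    const double i_na = P_g_na * (1.0 - P_b_na) *
        y[S_m] * y[S_m] * y[S_m] * y[S_h] * y[S_j] * (V - e_na);
    const double i_nal = P_g_nal_parent * P_f_nal * (1.0 - P_b_nal) *
        y[S_mL] * y[S_mL] * y[S_mL] * y[S_hL] * (V - e_na);
    const double i_nab = P_g_nab * (V - e_na);

    /* ---- L-type Ca2+ current (GHK through the open state) --------------- */
    double i_cal;
    {
        double gam = 0.341, u = 2.0 * V / rtf, drive;
        if (fabs(u) < 1e-6)
            drive = rtf / 2.0 * gam * (y[S_Ca_j] - P_cao);
        else
            drive = V * gam * (y[S_Ca_j] * exp(u) - P_cao) / (exp(u) - 1.0);
        double g = P_g_cal_parent * P_f_cal * (1.0 + 0.5 * P_pka_ltcc) *
            (1.0 - P_b_cal);
        i_cal = g * y[S_cal_O] * drive;
    }

    /* ---- K+ currents ---------------------------------------------------- */
    const double g_to = P_g_to * q10f(P_q10_ito_cond, P_texp_ito, tc) *
        (1.0 - P_b_to);
    const double i_to = g_to * y[S_ito_O] * (V - e_k);
    const double g_kur = P_g_kur * P_vm_kur *
        q10f(P_q10_kur_cond, P_texp_kur, tc) * (1.0 - P_b_kur);
    const double i_kur = g_kur * y[S_kur_O] * (V - e_k);
    const double i_kr = P_g_kr * (1.0 - P_b_kr) * y[S_kr_O] * (V - e_k);
    const double g_ss_eff = P_g_ss * q10f(P_q10_ss, P_tref_cond_ss, tc) *
        (1.0 - P_b_ss);
    const double i_ss = g_ss_eff * y[S_x_ss] * (V - e_k);

    double i_k1;
    {
        double dv = V - e_k;
        double a = 1.02 / (1.0 + exp(0.2385 * (dv - 59.215)));
        double b = P_k1_rect * (0.49124 * exp(0.08032 * (dv + 5.476)) +
                    exp(0.06175 * (dv - 594.31))) /
                   (1.0 + exp(-0.5143 * (dv + 4.753)));
        i_k1 = P_g_k1 * P_vm_k1 * sqrt(P_ko / 5.4) * (1.0 - P_b_k1) *
            a / (a + b) * dv;
    }
    const double i_kb = P_g_kb / (1.0 + exp(-(V - P_kb_vh) / P_kb_k)) *
        (1.0 - P_b_kb) * (V - e_k);
    double i_kach;
    {
        double act = P_ach / (P_ach + P_kach_k05);
        double rect = 0.1 / (1.0 + exp((V - e_k - 140.0) / 25.0)) +
                      0.9 / (1.0 + exp((V - e_k + 10.0) / 12.0));
        i_kach = P_g_kach * (1.0 - P_b_kach) * act * rect * (V - e_k);
    }
    double i_kca;
    {
        double h = P_kca_h;
        double act = pow(y[S_Ca_sl], h) /
            (pow(y[S_Ca_sl], h) + pow(P_kca_kd, h));
        i_kca = P_g_kca * (1.0 - P_b_kca) * act * (V - e_k);
    }

    /* ---- Cl- currents --------------------------------------------------- */
    const double i_clca = P_g_clca * (1.0 - P_b_clca) *
        y[S_Ca_sl] / (y[S_Ca_sl] + P_clca_kd) * (V - e_cl);
    const double i_clb = P_g_clb * (V - e_cl);

    /* ---- pumps and exchangers ------------------------------------------- */
    double i_nak;
    {
        double sigma = (exp(P_nao / 67.3) - 1.0) / 7.0;
        double fnak = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V / rtf) +
                             0.0365 * sigma * exp(-V / rtf));
        double km_na = P_km_naip * (1.0 - 0.3 * P_pka_nak);
        double r4 = km_na / y[S_Na_i];
        i_nak = P_ibar_nak_parent * P_f_nak * (1.0 - P_b_nak) * fnak *
            P_ko / (P_ko + P_km_ko) / (1.0 + r4 * r4 * r4 * r4);
    }
    double i_ncx;
    {
        double eta = P_ncx_eta;
        double ef = exp(eta * V / rtf), er = exp((eta - 1.0) * V / rtf);
        double na3 = y[S_Na_i] * y[S_Na_i] * y[S_Na_i];
        double nao3 = P_nao * P_nao * P_nao;
        double kn3 = P_km_nai * P_km_nai * P_km_nai;
        double kd3 = P_ncx_kdact / y[S_Ca_sl];
        double ka = 1.0 / (1.0 + kd3 * kd3 * kd3);
        double num = ef * na3 * P_cao - er * nao3 * y[S_Ca_sl];
        double den = (P_km_cao * na3 + pow(P_km_nao, 3.0) * y[S_Ca_sl] +
                      kn3 * P_cao * (1.0 + y[S_Ca_sl] / P_km_cai) +
                      P_km_cai * nao3 * (1.0 + na3 / kn3) +
                      na3 * P_cao + nao3 * y[S_Ca_sl]) *
                     (1.0 + P_ncx_ksat * er);
        i_ncx = P_ibar_ncx * (1.0 - P_b_ncx) * ka * num / den;
    }
    const double i_pmca = P_ibar_pmca * (1.0 - P_b_pmca) *
        pow(y[S_Ca_sl], 1.6) /
        (pow(y[S_Ca_sl], 1.6) + pow(P_km_pca, 1.6));
    const double i_cab = P_g_cab * (1.0 - P_b_cab) * (V - e_ca);

    const double i_ion = i_na + i_nal + i_nab + i_cal + i_to + i_kur +
        i_kr + i_ss + i_k1 + i_kb + i_kach + i_kca + i_clca + i_clb +
        i_nak + i_ncx + i_pmca + i_cab;
    const double stim = P_stim_amp;

    /* ---- Markov chains: dp/dt = Q p ------------------------------------- */
    /* ICaL */
    {
        double Vs = V + P_cal_shift;
        double a = P_cal_r0 * exp((Vs - P_cal_vh) / (2.0 * P_cal_k));
        double b = P_cal_r0 * exp(-(Vs - P_cal_vh) / (2.0 * P_cal_k));
        double ca = y[S_Ca_j];
        double phi = ca * ca / (ca * ca + P_cal_kd_cdi * P_cal_kd_cdi);
        double kcdi = P_cal_kcdi * phi / (1.0 + P_ck_fltcc * y[S_ck_j]);
        double kvdi = P_cal_kvdi /
            (1.0 + exp(-(V - P_cal_vdi_vh) / P_cal_vdi_k));
        double C2 = y[S_cal_C2], C1 = y[S_cal_C1], O = y[S_cal_O];
        double I1Ca = y[S_cal_I1Ca], I2Ca = y[S_cal_I2Ca];
        double I1V = y[S_cal_I1V], I2V = y[S_cal_I2V];
        ydot[S_cal_C2] = b * C1 + P_cal_rec2 * I2Ca + P_cal_rec2v * I2V -
            a * C2;
        ydot[S_cal_C1] = a * C2 + P_cal_k2 * O - (b + P_cal_k1) * C1;
        ydot[S_cal_O] = P_cal_k1 * C1 + P_cal_rcdi * I1Ca + P_cal_rvdi * I1V -
            (P_cal_k2 + kcdi + kvdi) * O;
        ydot[S_cal_I1Ca] = kcdi * O + P_cal_kir * I2Ca -
            (P_cal_rcdi + P_cal_kif) * I1Ca;
        ydot[S_cal_I2Ca] = P_cal_kif * I1Ca - (P_cal_kir + P_cal_rec2) * I2Ca;
        ydot[S_cal_I1V] = kvdi * O + P_cal_kvr * I2V -
            (P_cal_rvdi + P_cal_kvf) * I1V;
        ydot[S_cal_I2V] = P_cal_kvf * I1V - (P_cal_kvr + P_cal_rec2v) * I2V;
    }
    /* Ito */
    {
        double f = q10f(P_q10_ito_kin, P_texp_ito, tc);
        double a = P_ito_a * exp(V / P_ito_sa);
        double b = P_ito_b * exp(-V / P_ito_sb);
        double ro = P_ito_r0 * exp(-V / P_ito_sr);
        double C3 = y[S_ito_C3], C2 = y[S_ito_C2], C1 = y[S_ito_C1];
        double O = y[S_ito_O], I = y[S_ito_I];
        double IS1 = y[S_ito_IS1], IS2 = y[S_ito_IS2];
        ydot[S_ito_C3] = f * (b * C2 - 3.0 * a * C3);
        ydot[S_ito_C2] = f * (3.0 * a * C3 + 2.0 * b * C1 -
                              (b + 2.0 * a) * C2);
        ydot[S_ito_C1] = f * (2.0 * a * C2 + 3.0 * b * O -
                              (2.0 * b + a) * C1);
        ydot[S_ito_O] = f * (a * C1 + ro * I - (3.0 * b + P_ito_ki) * O);
        ydot[S_ito_I] = f * (P_ito_ki * O + P_ito_kis1r * IS1 -
                             (ro + P_ito_kis1f) * I);
        ydot[S_ito_IS1] = f * (P_ito_kis1f * I + P_ito_kis2r * IS2 -
                               (P_ito_kis1r + P_ito_kis2f) * IS1);
        ydot[S_ito_IS2] = f * (P_ito_kis2f * IS1 - P_ito_kis2r * IS2);
    }
    /* IKur */
    {
        double f = q10f(P_q10_kur_kin, P_texp_kur, tc);
        double a = P_kur_scale * P_kur_a * exp(V / P_kur_sa);
        double b = P_kur_scale * P_kur_b * exp(-V / P_kur_sb);
        double C4 = y[S_kur_C4], C3 = y[S_kur_C3], C2 = y[S_kur_C2];
        double C1 = y[S_kur_C1], O = y[S_kur_O], I = y[S_kur_I];
        ydot[S_kur_C4] = f * (b * C3 - 4.0 * a * C4);
        ydot[S_kur_C3] = f * (4.0 * a * C4 + 2.0 * b * C2 -
                              (b + 3.0 * a) * C3);
        ydot[S_kur_C2] = f * (3.0 * a * C3 + 3.0 * b * C1 -
                              (2.0 * b + 2.0 * a) * C2);
        ydot[S_kur_C1] = f * (2.0 * a * C2 + 4.0 * b * O -
                              (3.0 * b + a) * C1);
        ydot[S_kur_O] = f * (a * C1 + P_kur_ri * I -
                             (4.0 * b + P_kur_ki) * O);
        ydot[S_kur_I] = f * (P_kur_ki * O - P_kur_ri * I);
    }
    /* IKr */
    {
        double a3 = P_kr_a3 * exp(V / P_kr_s3);
        double b3 = P_kr_b3 * exp(-V / P_kr_sb3);
        double a2 = P_kr_a2 * exp(V / P_kr_s2);
        double b2 = P_kr_b2 * exp(-V / P_kr_sb2);
        double ao = P_kr_ao * exp(V / P_kr_so);
        double bo = P_kr_bo * exp(-V / P_kr_sbo);
        double ki = P_kr_ki * exp(V / P_kr_ski);
        double ri = P_kr_ri * exp(-V / P_kr_sri);
        double C3 = y[S_kr_C3], C2 = y[S_kr_C2], C1 = y[S_kr_C1];
        double O = y[S_kr_O], I = y[S_kr_I];
        ydot[S_kr_C3] = b3 * C2 - a3 * C3;
        ydot[S_kr_C2] = a3 * C3 + b2 * C1 - (b3 + a2) * C2;
        ydot[S_kr_C1] = a2 * C2 + bo * O - (b2 + ao) * C1;
        ydot[S_kr_O] = ao * C1 + ri * I - (bo + ki) * O;
        ydot[S_kr_I] = ki * O - ri * I;
    }
    /* RyR */
    {
        double ec50 = P_ec50sr_parent * P_f_ec50;
        double kcasr = P_maxsr - (P_maxsr - P_minsr) /
            (1.0 + pow(ec50 / y[S_Ca_sr], 2.5));
        double ko_sr = (1.0 + P_ck_fryr * y[S_ck_j]) *
            (1.0 + 0.5 * P_pka_ryr) * P_ko_ca / kcasr;
        double ki_sr = P_ki_ca * kcasr;
        double ca_act = y[S_Ca_j] * P_caff_ryr;
        double caj2 = pow(ca_act, P_ryr_hill) /
            (pow(ca_act, P_ryr_hill) + pow(P_ryr_kd, P_ryr_hill));
        double R_ = y[S_ryr_R], O = y[S_ryr_O], I = y[S_ryr_I],
               RI = y[S_ryr_RI];
        ydot[S_ryr_R] = P_kom * O + P_kim * RI -
            (ko_sr * caj2 + ki_sr * y[S_Ca_j]) * R_;
        ydot[S_ryr_O] = ko_sr * caj2 * R_ + P_kim * I -
            (P_kom + ki_sr * y[S_Ca_j]) * O;
        ydot[S_ryr_I] = ki_sr * y[S_Ca_j] * O + ko_sr * caj2 * RI -
            (P_kim + P_kom) * I;
        ydot[S_ryr_RI] = P_kom * I + ki_sr * y[S_Ca_j] * R_ -
            (P_kim + ko_sr * caj2) * RI;
    }

    /* ---- HH gates -------------------------------------------------------- */
    {
        double Vm_ = V + P_na_mshift;
        double dvm = Vm_ + 47.13;
        double am = (fabs(dvm) < 1e-6) ? 3.2 :
            0.32 * dvm / (1.0 - exp(-0.1 * dvm));
        double bm = 0.08 * exp(-Vm_ / 11.0);
        double ah, bh, aj, bj;
        if (V >= -40.0) {
            ah = 0.0;
            bh = 1.0 / (0.13 * (1.0 + exp((V + 10.66) / -11.1)));
            aj = 0.0;
            bj = 0.3 * exp(-2.535e-7 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
        } else {
            ah = 0.135 * exp((80.0 + V) / -6.8);
            bh = 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V);
            aj = (-1.2714e5 * exp(0.2444 * V) -
                  3.474e-5 * exp(-0.04391 * V)) * (V + 37.78) /
                 (1.0 + exp(0.311 * (V + 79.23)));
            bj = 0.1212 * exp(-0.01052 * V) /
                 (1.0 + exp(-0.1378 * (V + 40.14)));
        }
        ydot[S_m] = am * (1.0 - y[S_m]) - bm * y[S_m];
        ydot[S_h] = ah * (1.0 - y[S_h]) - bh * y[S_h];
        ydot[S_j] = aj * (1.0 - y[S_j]) - bj * y[S_j];
        ydot[S_mL] = am * (1.0 - y[S_mL]) - bm * y[S_mL];
        double hlinf = 1.0 / (1.0 + exp((V + 91.0) / 6.1));
        ydot[S_hL] = (hlinf - y[S_hL]) / P_tau_hl;
        double xinf = 1.0 / (1.0 + exp(-(V - P_ss_vh) / P_ss_k));
        double tau22 = P_ss_tau0 / (1.0 + exp((V - P_ss_tvh) / P_ss_tk)) +
            P_ss_tau1;
        double tau = tau22 / q10f(P_q10_ss, P_texp_ss, tc);
        ydot[S_x_ss] = (xinf - y[S_x_ss]) / tau;
    }

    /* ---- membrane potential ---------------------------------------------- */
    ydot[S_V] = (P_vclamp_on > 0.0) ? 0.0 : -(i_ion + stim);

    /* ---- ion bookkeeping -------------------------------------------------- */
    const double vmyo = P_vcell * P_f_myo;
    const double vsr  = P_vcell * P_f_sr;
    const double vsl  = P_vcell * P_f_sl;
    const double vjun = P_vcell * P_f_junc;
    const double cmyo = P_cm * 1e-12 / (FARADAY * vmyo);
    const double csl  = P_cm * 1e-12 / (FARADAY * vsl);
    const double cjun = P_cm * 1e-12 / (FARADAY * vjun);

    ydot[S_Na_i] = -(i_na + i_nal + i_nab + 3.0 * i_ncx + 3.0 * i_nak) * cmyo;
    ydot[S_K_i] = -(i_to + i_kur + i_kr + i_ss + i_k1 + i_kb + i_kach +
                    i_kca - 2.0 * i_nak + stim) * cmyo;
    ydot[S_Cl_i] = (i_clca + i_clb) * cmyo;

    /* Ca2+ buffers */
    const double dTnCL = P_tnc_kon * y[S_Ca_i] * (P_tnc_bmax - y[S_TnCL]) -
        P_tnc_koff * y[S_TnCL];
    const double dCaM = P_cam_kon * y[S_Ca_i] * (P_cam_bmax - y[S_CaM]) -
        P_cam_koff * y[S_CaM];
    const double dSRB = P_srb_kon * y[S_Ca_i] * (P_srb_bmax - y[S_SRB]) -
        P_srb_koff * y[S_SRB];
    const double dSLLsl = P_sllsl_kon * y[S_Ca_sl] *
        (P_sllsl_bmax - y[S_SLLsl]) - P_sllsl_koff * y[S_SLLsl];
    const double dSLHsl = P_slhsl_kon * y[S_Ca_sl] *
        (P_slhsl_bmax - y[S_SLHsl]) - P_slhsl_koff * y[S_SLHsl];
    const double dSLLj = P_sllj_kon * y[S_Ca_j] *
        (P_sllj_bmax - y[S_SLLj]) - P_sllj_koff * y[S_SLLj];
    const double dSLHj = P_slhj_kon * y[S_Ca_j] *
        (P_slhj_bmax - y[S_SLHj]) - P_slhj_koff * y[S_SLHj];
    const double dCsqn = P_csqn_kon * y[S_Ca_sr] *
        (P_csqn_bmax - y[S_Csqn]) - P_csqn_koff * y[S_Csqn];
    ydot[S_TnCL] = dTnCL;  ydot[S_CaM] = dCaM;   ydot[S_SRB] = dSRB;
    ydot[S_SLLsl] = dSLLsl; ydot[S_SLHsl] = dSLHsl;
    ydot[S_SLLj] = dSLLj;  ydot[S_SLHj] = dSLHj; ydot[S_Csqn] = dCsqn;

    /* SERCA and RyR fluxes */
    double ph = (y[S_Ph_PLB] > 1e-6) ? y[S_Ph_PLB] : 1e-6;
    const double kserca = 1.0 /
        (pow(P_kserca_mid / ph, P_kserca_hill) + 1.0);
    double j_up;
    {
        double kmf = P_kmf_parent * P_f_kmf * (1.0 - 0.45 * P_pka_plb);
        double fwd = pow(y[S_Ca_i] / kmf, P_hill_serca);
        double rev = pow(y[S_Ca_sr] / P_kmr, P_hill_serca);
        double vmax = P_vmax_serca_parent * P_f_vmax * (1.0 + kserca) *
            (1.0 - P_b_serca);
        j_up = vmax * (fwd - rev) / (1.0 + fwd + rev);
    }
    const double grad = y[S_Ca_sr] - y[S_Ca_j];
    const double j_rel = P_ks_rel * y[S_ryr_O] * grad;          /* SR-ref */
    const double j_leak = P_kleak * (1.0 + P_ck_fleak * y[S_ck_j]) * grad;

    const double jd_jsl = P_d_j_sl * (y[S_Ca_j] - y[S_Ca_sl]);
    const double jd_slmy = P_d_sl_myo * (y[S_Ca_sl] - y[S_Ca_i]);

    ydot[S_Ca_sr] = j_up * vmyo / vsr - j_rel - j_leak * vmyo / vsr - dCsqn;
    ydot[S_Ca_j] = -i_cal * cjun / 2.0 + j_rel * vsr / vjun +
        j_leak * vmyo / vjun - jd_jsl / vjun - dSLLj - dSLHj;
    ydot[S_Ca_sl] = (i_ncx - (i_cab + i_pmca) / 2.0) * csl +
        jd_jsl / vsl - jd_slmy / vsl - dSLLsl - dSLHsl;
    ydot[S_Ca_i] = jd_slmy / vmyo - j_up - dTnCL - dCaM - dSRB;

    /* CaMKII / phospholamban */
    {
        double hh = P_ck_hill;
        double aj_ = pow(y[S_Ca_j], hh) /
            (pow(y[S_Ca_j], hh) + pow(P_ck_kdj, hh));
        double asl = pow(y[S_Ca_sl], hh) /
            (pow(y[S_Ca_sl], hh) + pow(P_ck_kdsl, hh));
        double acy = pow(y[S_Ca_i], hh) /
            (pow(y[S_Ca_i], hh) + pow(P_ck_kdcyt, hh));
        ydot[S_ck_j] = P_ck_kact * aj_ * (1.0 - y[S_ck_j]) -
            P_ck_kdeact * y[S_ck_j];
        ydot[S_ck_sl] = P_ck_kact * asl * (1.0 - y[S_ck_sl]) -
            P_ck_kdeact * y[S_ck_sl];
        ydot[S_ck_cyt] = P_ck_kact * acy * (1.0 - y[S_ck_cyt]) -
            P_ck_kdeact * y[S_ck_cyt];
        ydot[S_Ph_PLB] = P_plb_kp * y[S_ck_cyt] * (1.0 - y[S_Ph_PLB]) -
            P_plb_kdp * y[S_Ph_PLB];
    }

    /* ion clamps */
    if (P_clamp_nai > 0.0) ydot[S_Na_i] = 0.0;
    if (P_clamp_ki > 0.0)  ydot[S_K_i] = 0.0;
    if (P_clamp_cli > 0.0) ydot[S_Cl_i] = 0.0;
    if (P_clamp_cai > 0.0) ydot[S_Ca_i] = 0.0;

    /* auxiliary outputs */
    if (ip[0] >= 4) {
        yout[0] = i_cal;
        yout[1] = i_ion;
        yout[2] = j_up;
        yout[3] = j_rel;
    }
    for (k = 0; k < NSTATE; k++) {
        if (!R_FINITE(ydot[k]))
            error("non-finite derivative in state index %d (t = %g)", k, *t);
    }
}

static const R_CMethodDef cMethods[] = {
    {"mamyo_initmod", (DL_FUNC) &mamyo_initmod, 1},
    {"mamyo_derivs", (DL_FUNC) &mamyo_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_mamyo(DllInfo *info)
{
    R_registerRoutines(info, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
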