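/* Compiled right-hand side of the coupled electromechanical tissue model.
 * Mirrors the pure-R reference implementation (assembleTissueRHS) exactly;
 * a parity test asserts agreement at randomised states.
 *
 * Parameter vector layout: see .tissueParVec() in R/compiled.R.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define RTF (8314.0 * 310.0 / 96485.0)
#define FARADAY 96485.0

/* per-CRU state block: field offsets */
enum { F_VM, F_M, F_H, F_J, F_D, F_F, F_XTO, F_YTO, F_XKS, F_XKR,
       F_RYRO, F_RYRR, F_CASS, F_CASR, F_CACY, F_NAI, F_KI,
       F_SL, F_TNC, F_XB, NCRU_STATES };
#define NFIB_STATES 5

static double vtrap(double x, double k)
{
    if (fabs(x) < 1e-7) return 1.0 / k;
    return x / (1.0 - exp(-k * x));
}

static double buf_beta(double ca, double btot, double kd)
{
    double s = kd + ca;
    return 1.0 / (1.0 + btot * kd / (s * s));
}

SEXP C_tissue_rhs(SEXP st, SEXP sy, SEXP sp)
{
    const double t = REAL(st)[0];
    const double *y = REAL(sy);
    const double *p = REAL(sp);

    const int n_states = (int) p[0];
    const int n_cru = (int) p[1];
    const int n_cells = (int) p[2];
    const int n_fib = (int) p[3];
    const int eq6_verbatim = (int) p[4];
    const int sl_mode = (int) p[5];      /* 0 verbatim, 1 relaxed */
    const double sl_kappa = p[6];
    const int pattern = (int) p[7];      /* -1 none, 0 I, 1 H, 2 S, 3 P */
    const double cl = p[8], compression = p[9], stretch_amp = p[10],
        plateau = p[11], tau_rise = p[12], tau_decay = p[13],
        decay_frac = p[14], stretch_stop = p[15];
    const double stim_amp = p[16], stim_dur = p[17], stim_period = p[18],
        stim_n_beats = p[19];
    const int stim_target = (int) p[20]; /* 1-based local CRU in cell 1 */
    const double tau_ss = p[21], tau_sr = p[22], tau_cyto = p[23],
        tau_vm = p[24];
    const int ca_coupling = (int) p[25], vm_coupling = (int) p[26];

    const double *ip = p + 27;   /* ionic params, 51 values */
    const double ca_o = ip[0], na_o = ip[1], k_o = ip[2], cm_cru = ip[3],
        v_cyto = ip[4], v_sr = ip[5], v_ss = ip[6], g_na = ip[7],
        p_cal = ip[8], k_fca = ip[9], g_to = ip[10], g_ks = ip[11],
        g_kr = ip[12], g_k1 = ip[13], i_nak_max = ip[14], km_nai = ip[15],
        km_ko = ip[16], v_ncx = ip[17], km_na_ncx = ip[18],
        km_ca_ncx = ip[19], k_sat = ip[20], eta = ip[21], g_cab = ip[22],
        g_nab = ip[23], v_pca = ip[24], km_pca = ip[25], v_rel = ip[26],
        f_relss = ip[27], k_act0 = ip[28], h_act = ip[29], k_sr_thr = ip[30],
        h_sr = ip[31], k_sr_dep = ip[32], tau_ryr_o = ip[33],
        k_ryr_rec = ip[34], k_ryr_inact = ip[35], k_inh = ip[36],
        v_up = ip[37], k_up = ip[38], h_up = ip[39], k_srmax = ip[40],
        v_leak = ip[41], v_leak_ss = ip[42], h_leak = ip[43],
        tau_xfer = ip[44], b_ss = ip[45], k_b_ss = ip[46], b_cyto = ip[47],
        k_b_cyto = ip[48], b_csqn = ip[49], k_csqn = ip[50];

    const double *mp = ip + 51;  /* mechanics params, 18 values */
    const double b_tnc = mp[0], n_coop = mp[1], f_xb = mp[2], g_xb = mp[3],
        gamma_xb = mp[4], beta_lda = mp[5], sl_ref = mp[6], sl_min = mp[7],
        sl_max = mp[8], tau_sl = mp[9];
    /* mp[10] = f_max (not needed for derivatives) */
    const double kon0 = mp[11], koff0 = mp[12], alpha_on = mp[13],
        alpha_off = mp[14], alpha_xb = mp[15], gamma_sl = mp[16],
        max_log_mod = mp[17];

    const double *fp = mp + 18;  /* fibroblast params, 9 values */
    const double c_f = fp[0], g_kv = fp[1], g_k1f = fp[2],
        i_nakf_max = fp[3], km_naif = fp[4], km_kof = fp[5], g_bna = fp[6],
        na_o_f = fp[7], k_o_f = fp[8];

    const double *arr = fp + 9;
    const double *cell_first = arr;               /* 1-based global CRU */
    const double *cell_n = arr + n_cells;
    const double *g_gap = arr + 2 * n_cells;
    const int n_junc = n_cells > 1 ? n_cells - 1 : 0;
    const double *cru_off_d = arr + 2 * n_cells + n_junc;
    const double *rest = cru_off_d + n_cru;
    const double *fib_off_d = rest + n_cru;
    const double *fib_host_d = fib_off_d + n_fib;
    const double *fib_g = fib_host_d + n_fib;

    SEXP sdy = PROTECT(allocVector(REALSXP, n_states));
    double *dy = REAL(sdy);
    for (int i = 0; i < n_states; i++) dy[i] = 0.0;

    /* stretch scaling at t */
    double scale = 1.0;
    if (pattern > 0 && t < stretch_stop) {
        double tc = t - floor(t / cl) * cl;
        double w = 2.0 * M_PI / cl;
        if (pattern == 1) {          /* H */
            scale = 1.0 - compression * (1.0 - cos(w * tc)) / 2.0;
        } else if (pattern == 2) {   /* S */
            scale = 1.0 + stretch_amp * sin(w * tc);
        } else if (pattern == 3) {   /* P */
            double td = decay_frac * cl;
            double s_at_td = 1.0 + plateau * (1.0 - exp(-td / tau_rise));
            if (tc < td)
                scale = 1.0 + plateau * (1.0 - exp(-tc / tau_rise));
            else
                scale = 1.0 + (s_at_td - 1.0) * exp(-(tc - td) / tau_decay);
        }
    }

    /* mechanical coupling: isotonic rates then stencil */
    double *iso = (double *) R_alloc(n_cru, sizeof(double));
    double *dsl = (double *) R_alloc(n_cru, sizeof(double));
    for (int i = 0; i < n_cru; i++) {
        int off = (int) cru_off_d[i];
        iso[i] = (rest[i] * scale - y[off + F_SL]) / tau_sl;
    }
    for (int c = 0; c < n_cells; c++) {
        int i0 = (int) cell_first[c] - 1;
        int nc = (int) cell_n[c];
        for (int k = 0; k < nc; k++) {
            int i = i0 + k;
            if (sl_mode == 0) {      /* verbatim */
                if (k == 0) dsl[i] = iso[i] - iso[i + 1];
                else if (k == nc - 1) dsl[i] = iso[i] - iso[i - 1];
                else dsl[i] = 2.0 * iso[i] - (iso[i + 1] + iso[i - 1]);
            } else {                 /* relaxed */
                double nb;
                if (k == 0) nb = iso[i + 1];
                else if (k == nc - 1) nb = iso[i - 1];
                else nb = (iso[i - 1] + iso[i + 1]) / 2.0;
                dsl[i] = iso[i] + sl_kappa * (nb - iso[i]);
            }
        }
    }
    for (int c = 0; c + 1 < n_cells; c++) {
        int u = (int) cell_first[c] - 1 + (int) cell_n[c] - 1;
        int d0 = (int) cell_first[c + 1] - 1;
        dsl[u] -= iso[d0];
        dsl[d0] -= iso[u];
    }

    const double conv_ss = cm_cru / (2.0 * FARADAY * v_ss);
    const double conv_cyto = cm_cru / (2.0 * FARADAY * v_cyto);
    const double conv1 = cm_cru / (FARADAY * v_cyto);
    const double sigma = (exp(na_o / 67.3) - 1.0) / 7.0;

    for (int i = 0; i < n_cru; i++) {
        const int off = (int) cru_off_d[i];
        const double v = y[off + F_VM];
        const double m = y[off + F_M], h = y[off + F_H], jg = y[off + F_J];
        const double d = y[off + F_D], f = y[off + F_F];
        const double xto = y[off + F_XTO], yto = y[off + F_YTO];
        const double xks = y[off + F_XKS], xkr = y[off + F_XKR];
        const double ryr_o = y[off + F_RYRO], ryr_r = y[off + F_RYRR];
        const double ca_ss = y[off + F_CASS], ca_sr = y[off + F_CASR];
        const double ca_cy = y[off + F_CACY];
        const double na_i = y[off + F_NAI], k_i = y[off + F_KI];
        const double sl_raw = y[off + F_SL], tnc = y[off + F_TNC],
            xb = y[off + F_XB];

        /* mechanics */
        double sl = sl_raw;
        if (sl < sl_min) sl = sl_min;
        if (sl > sl_max) sl = sl_max;
        double sr_rate = dsl[i] / rest[i];
        double lfac = 1.0 + gamma_sl * (sl - sl_ref) / sl_ref;
        double eon = alpha_on * sr_rate;
        if (eon > max_log_mod) eon = max_log_mod;
        if (eon < -max_log_mod) eon = -max_log_mod;
        double eoff = alpha_off * sr_rate * lfac;
        if (eoff > max_log_mod) eoff = max_log_mod;
        if (eoff < -max_log_mod) eoff = -max_log_mod;
        double kon = kon0 * exp(eon) *
            (1.0 + beta_lda * (sl - sl_ref) / sl_ref);
        double koff = koff0 * exp(eoff) * (1.0 - gamma_xb * xb);
        double dtnc = kon * ca_cy * (1.0 - tnc) - koff * tnc;
        double exb = alpha_xb * fabs(sr_rate);
        if (exb > max_log_mod) exb = max_log_mod;
        double g_eff = g_xb * exp(exb);
        double dxb = f_xb * pow(tnc, n_coop) * (1.0 - xb) - g_eff * xb;
        double tnc_flux = b_tnc * dtnc;

        /* reversal potentials */
        double e_na = RTF * log(na_o / na_i);
        double e_k = RTF * log(k_o / k_i);
        double e_ca = RTF / 2.0 * log(ca_o / ca_cy);

        /* INa */
        double a_m = 0.32 * vtrap(v + 47.13, 0.1);
        double b_m = 0.08 * exp(-v / 11.0);
        double a_h, b_h, a_j, b_j;
        if (v < -40.0) {
            a_h = 0.135 * exp(-(80.0 + v) / 6.8);
            b_h = 3.56 * exp(0.079 * v) + 3.1e5 * exp(0.35 * v);
            a_j = (-1.2714e5 * exp(0.2444 * v) -
                   3.474e-5 * exp(-0.04391 * v)) * (v + 37.78) /
                (1.0 + exp(0.311 * (v + 79.23)));
            b_j = 0.1212 * exp(-0.01052 * v) /
                (1.0 + exp(-0.1378 * (v + 40.14)));
        } else {
            a_h = 0.0;
            b_h = 1.0 / (0.13 * (1.0 + exp(-(v + 10.66) / 11.1)));
            a_j = 0.0;
            b_j = 0.3 * exp(-2.535e-7 * v) /
                (1.0 + exp(-0.1 * (v + 32.0)));
        }
        double i_na = g_na * m * m * m * h * jg * (v - e_na);

        /* ICaL */
        double d_inf = 1.0 / (1.0 + exp(-(v + 10.0) / 6.24));
        double tau_d = fabs(v + 10.0) < 1e-6 ? 2.289 :
            d_inf * (1.0 - exp(-(v + 10.0) / 6.24)) / (0.035 * (v + 10.0));
        double f_inf = 1.0 / (1.0 + exp((v + 32.0) / 8.6));
        double tau_f = 1.0 /
            (0.0065 * exp(-pow(0.0337 * (v + 10.0), 2)) + 0.006);
        double f_ca = k_fca / (k_fca + ca_ss);
        double zv = 2.0 * v / RTF;
        double ghk = fabs(zv) < 1e-6 ?
            2.0 * (ca_ss - 0.341 * ca_o) :
            2.0 * zv * (ca_ss * exp(zv) - 0.341 * ca_o) / (exp(zv) - 1.0);
        double i_cal = p_cal * d * f * f_ca * ghk;

        /* K currents */
        double xto_inf = 1.0 / (1.0 + exp(-(v - 19.0) / 13.0));
        double tau_xto = 3.5 * exp(-pow(v / 30.0, 2)) + 1.5;
        double yto_inf = 1.0 / (1.0 + exp((v + 33.5) / 10.0));
        double tau_yto = 20.0 + 20.0 * exp(-pow((v + 33.5) / 10.0, 2));
        double i_to = g_to * xto * yto * (v - e_k);

        double xks_inf = 1.0 / (1.0 + exp(-(v - 1.5) / 16.7));
        double tau_xks = 1.0 / (7.19e-5 * vtrap(v + 30.0, 0.148) +
                                1.31e-4 * vtrap(-(v + 30.0), 0.0687));
        double i_ks = g_ks * xks * xks * (v - e_k);

        double xkr_inf = 1.0 / (1.0 + exp(-(v + 21.5) / 7.5));
        double tau_xkr = 1.0 / (0.00138 * vtrap(v + 14.2, 0.123) +
                                0.00061 * vtrap(-(v + 38.9), 0.145));
        double r_kr = 1.0 / (1.0 + exp((v + 9.0) / 22.4));
        double i_kr = g_kr * xkr * r_kr * (v - e_k);

        double dvk = v - e_k;
        double a_k1 = 1.02 / (1.0 + exp(0.2385 * (dvk - 59.215)));
        double b_k1 = (0.49124 * exp(0.08032 * (dvk + 5.476)) +
                       exp(0.06175 * (dvk - 594.31))) /
            (1.0 + exp(-0.5143 * (dvk + 4.753)));
        double i_k1 = g_k1 * sqrt(k_o / 5.4) * a_k1 / (a_k1 + b_k1) * dvk;

        /* pumps and exchangers */
        double f_nak = 1.0 / (1.0 + 0.1245 * exp(-0.1 * v / RTF) +
                              0.0365 * sigma * exp(-v / RTF));
        double i_nak = i_nak_max * f_nak * (k_o / (k_o + km_ko)) /
            (1.0 + pow(km_nai / na_i, 1.5));

        double ex1 = exp(eta * v / RTF);
        double ex2 = exp((eta - 1.0) * v / RTF);
        double na_i3 = na_i * na_i * na_i;
        double na_o3 = na_o * na_o * na_o;
        double i_ncx = v_ncx * (ex1 * na_i3 * ca_o - ex2 * na_o3 * ca_ss) /
            ((pow(km_na_ncx, 3) + na_o3) * (km_ca_ncx + ca_o) *
             (1.0 + k_sat * ex2));

        double ghk_b = fabs(zv) < 1e-6 ?
            2.0 * (ca_cy - 0.341 * ca_o) :
            2.0 * zv * (ca_cy * exp(zv) - 0.341 * ca_o) / (exp(zv) - 1.0);
        double i_cab = g_cab * ghk_b;
        double i_nab = g_nab * (v - e_na);
        double i_pca = v_pca * ca_cy / (ca_cy + km_pca);

        double i_m = i_na + i_cal + i_to + i_ks + i_kr + i_k1 + i_nak +
            i_ncx + i_cab + i_nab + i_pca;

        /* SR calcium cycling */
        double k_act = k_act0 *
            (1.0 + pow(k_sr_dep / ca_sr, 2)) /
            (1.0 + pow(ca_sr / k_sr_thr, h_sr));
        double o_inf = pow(ca_ss, h_act) /
            (pow(ca_ss, h_act) + pow(k_act, h_act));
        double j_rel = v_rel * ryr_o * ryr_r * (ca_sr - ca_cy);
        double j_spark = v_leak_ss * (ca_sr - ca_ss) *
            pow(ca_sr / k_sr_thr, h_leak);
        double fw = pow(ca_cy / k_up, h_up);
        double rv = pow(ca_sr / k_srmax, h_up);
        double j_up = v_up * (fw - rv) / (1.0 + fw + rv);
        double j_leak = v_leak * (ca_sr - ca_cy);
        double j_xfer = (ca_ss - ca_cy) / tau_xfer;

        double beta_ss = buf_beta(ca_ss, b_ss, k_b_ss);
        double beta_cy = buf_beta(ca_cy, b_cyto, k_b_cyto);
        double beta_sr = buf_beta(ca_sr, b_csqn, k_csqn);

        dy[off + F_VM] = -i_m;
        dy[off + F_M] = a_m * (1.0 - m) - b_m * m;
        dy[off + F_H] = a_h * (1.0 - h) - b_h * h;
        dy[off + F_J] = a_j * (1.0 - jg) - b_j * jg;
        dy[off + F_D] = (d_inf - d) / tau_d;
        dy[off + F_F] = (f_inf - f) / tau_f;
        dy[off + F_XTO] = (xto_inf - xto) / tau_xto;
        dy[off + F_YTO] = (yto_inf - yto) / tau_yto;
        dy[off + F_XKS] = (xks_inf - xks) / tau_xks;
        dy[off + F_XKR] = (xkr_inf - xkr) / tau_xkr;
        dy[off + F_RYRO] = (o_inf - ryr_o) / tau_ryr_o;
        {
            double ki2 = k_inh * k_inh, ki4 = ki2 * ki2;
            double cs2 = ca_ss * ca_ss, cs4 = cs2 * cs2;
            dy[off + F_RYRR] = k_ryr_rec * (1.0 - ryr_r) * ki4 / (ki4 + cs4) -
                k_ryr_inact * cs2 / (cs2 + ki2) * ryr_r;
        }
        dy[off + F_CASS] = beta_ss *
            ((f_relss * j_rel + j_spark) * (v_sr / v_ss) - j_xfer +
             conv_ss * (-i_cal + 2.0 * i_ncx));
        dy[off + F_CASR] = beta_sr *
            (j_up * (v_cyto / v_sr) - j_leak - j_rel - j_spark);
        dy[off + F_CACY] = beta_cy *
            ((1.0 - f_relss) * j_rel * (v_sr / v_cyto) +
             j_xfer * (v_ss / v_cyto) + j_leak * (v_sr / v_cyto) - j_up -
             tnc_flux - conv_cyto * (i_cab + i_pca));
        dy[off + F_NAI] = -(i_na + i_nab + 3.0 * i_nak + 3.0 * i_ncx) * conv1;
        dy[off + F_KI] = -(i_to + i_ks + i_kr + i_k1 - 2.0 * i_nak) * conv1;
        dy[off + F_SL] = dsl[i];
        dy[off + F_TNC] = dtnc;
        dy[off + F_XB] = dxb;
    }

    /* inter-CRU coupling within each cell (zero-sum stencils) */
    if (ca_coupling || vm_coupling) {
        for (int c = 0; c < n_cells; c++) {
            int i0 = (int) cell_first[c] - 1;
            int nc = (int) cell_n[c];
            for (int k = 0; k < nc; k++) {
                int i = i0 + k;
                int off = (int) cru_off_d[i];
                int offl = (int) cru_off_d[k == 0 ? i : i - 1];
                int offr = (int) cru_off_d[k == nc - 1 ? i : i + 1];
                if (ca_coupling) {
                    dy[off + F_CASS] +=
                        (y[offl + F_CASS] + y[offr + F_CASS] -
                         2.0 * y[off + F_CASS]) / tau_ss;
                    dy[off + F_CASR] +=
                        (y[offl + F_CASR] + y[offr + F_CASR] -
                         2.0 * y[off + F_CASR]) / tau_sr;
                    dy[off + F_CACY] +=
                        (y[offl + F_CACY] + y[offr + F_CACY] -
                         2.0 * y[off + F_CACY]) / tau_cyto;
                }
                if (vm_coupling) {
                    dy[off + F_VM] +=
                        (y[offl + F_VM] + y[offr + F_VM] -
                         2.0 * y[off + F_VM]) / tau_vm;
                }
            }
        }
    }

    /* stimulus on the target CRU of cell 1 */
    if (vm_coupling) {
        double beat = floor(t / stim_period);
        double phase = t - beat * stim_period;
        if (beat < stim_n_beats && phase < stim_dur) {
            int tgt = (int) cell_first[0] - 1 + stim_target - 1;
            dy[(int) cru_off_d[tgt] + F_VM] += stim_amp / stim_dur;
        }
    }

    /* gap junctions between adjacent myocytes */
    for (int c = 0; c + 1 < n_cells; c++) {
        int u = (int) cell_first[c] - 1 + (int) cell_n[c] - 1;
        int d0 = (int) cell_first[c + 1] - 1;
        int offu = (int) cru_off_d[u], offd = (int) cru_off_d[d0];
        double i_gap = g_gap[c] * (y[offu + F_VM] - y[offd + F_VM]);
        double dv = i_gap / cm_cru;
        if (eq6_verbatim) {
            dy[offu + F_VM] += dv;
            dy[offd + F_VM] -= dv;
        } else {
            dy[offu + F_VM] -= dv;
            dy[offd + F_VM] += dv;
        }
    }

    /* fibroblasts */
    for (int q = 0; q < n_fib; q++) {
        int off = (int) fib_off_d[q];
        int host = (int) fib_host_d[q] - 1;
        int hoff = (int) cru_off_d[host];
        double v = y[off], r = y[off + 1], s = y[off + 2];
        double na_f = y[off + 3], k_f = y[off + 4];
        double e_k = RTF * log(k_o_f / k_f);
        double e_na = RTF * log(na_o_f / na_f);

        double r_inf = 1.0 / (1.0 + exp(-(v + 20.0) / 11.0));
        double tau_r = 20.3 + 138.0 * exp(-pow((v + 20.0) / 25.9, 2));
        double s_inf = 1.0 / (1.0 + exp((v + 23.0) / 7.0));
        double tau_s = 1574.0 + 5268.0 * exp(-pow((v + 23.0) / 22.7, 2));
        double i_kv = g_kv * r * s * (v - e_k);

        double dvk = v - e_k;
        double a_k1 = 0.1 / (1.0 + exp(0.06 * (dvk - 200.0)));
        double b_k1 = (3.0 * exp(2e-4 * (dvk + 100.0)) +
                       exp(0.1 * (dvk - 10.0))) /
            (1.0 + exp(-0.5 * dvk));
        double i_k1 = g_k1f * a_k1 / (a_k1 + b_k1) * dvk;

        double i_nak = i_nakf_max * (k_o_f / (k_o_f + km_kof)) *
            pow(na_f, 1.5) / (pow(na_f, 1.5) + pow(km_naif, 1.5)) *
            (v + 150.0) / (v + 200.0);
        double i_bna = g_bna * (v - e_na);

        double i_junc = fib_g[q] * (v - y[hoff + F_VM]);

        double conv = c_f / (FARADAY * 1.0);
        dy[off] = -(i_kv + i_k1 + i_nak + i_bna) - i_junc / c_f;
        dy[off + 1] = (r_inf - r) / tau_r;
        dy[off + 2] = (s_inf - s) / tau_s;
        dy[off + 3] = -(i_bna + 3.0 * i_nak) * conv;
        dy[off + 4] = -(i_kv + i_k1 - 2.0 * i_nak) * conv;

        dy[hoff + F_VM] += i_junc / cm_cru;
    }

    UNPROTECT(1);
    return sdy;
}
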