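# Parameter constructors for the three cell models and their couplings.

# Physical constants
.FARADAY <- 96485       # C/mol
.RTF <- 8314 * 310 / 96485  # ~26.71 mV at 310 K

#' Ionic membrane parameters for one calcium-release unit
#'
#' Constructs the parameter set of the reduced rabbit ventricular ionic model
#' used for each calcium-release unit (CRU). Currents: fast sodium (INa),
#' L-type calcium (ICaL, GHK driving force so that extracellular calcium
#' `ca_o` acts on calcium loading), transient outward (Ito), rapid and slow
#' delayed rectifiers (IKr, IKs), inward rectifier (IK1), sodium-potassium
#' pump (INaK), sodium-calcium exchanger (INCX), background sodium/calcium
#' and a sarcolemmal calcium pump. Calcium is handled in three compartments
#' per CRU (subsarcolemmal space, junctional SR, bulk cytosol) with a
#' luminally sensitised ryanodine-receptor release flux: when free SR calcium
#' exceeds a threshold the release activation threshold collapses, producing
#' deterministic spontaneous release under calcium overload.
#'
#' All conductances are in mS/uF (currents in pA/pF), concentrations in mM,
#' time in ms, volumes in pL per CRU.
#'
#' @param ca_o extracellular calcium concentration (mM)
#' @param cm_cru per-CRU membrane capacitance (pF); a 150 pF myocyte split
#'   over 50 CRUs
#' @param ... named overrides of any default parameter value
#' @return an object of class `ionicParams` (named list)
#' @export
ionicParams <- function(ca_o = 2.0, cm_cru = 3.0, ...) {
  p <- list(
    ca_o = ca_o, na_o = 140, k_o = 5.4,
    cm_cru = cm_cru,
    # compartment volumes per CRU (pL)
    v_cyto = 0.42, v_sr = 0.023, v_ss = 0.002,
    # maximal conductances / fluxes
    g_na   = 12,       # mS/uF
    p_cal  = 5,        # L-type permeability scale (GHK, pA/pF per mM)
    k_fca  = 0.03,     # mM, Ca-dependent ICaL inactivation
    g_to   = 0.10,
    g_ks   = 0.04,
    g_kr   = 0.02,
    g_k1   = 0.50,
    i_nak_max = 1.1,   # pA/pF
    km_nai = 10, km_ko = 1.5,
    v_ncx  = 40,       # pA/pF (scale of the NCX formulation)
    km_na_ncx = 87.5, km_ca_ncx = 1.38, k_sat = 0.1, eta = 0.35,
    g_cab  = 6e-3,     # GHK permeability scale of the background Ca current
    g_nab  = 2.0e-4,
    v_pca  = 0.05, km_pca = 5e-4,
    # SR calcium cycling (fluxes per target-compartment volume, 1/ms or mM/ms)
    v_rel  = 0.42,     # 1/ms, RyR release rate constant (per SR volume)
    f_relss = 0.1,     # fraction of the release flux routed via the subspace
    k_act0 = 0.02,     # mM, baseline RyR half-activation (subspace Ca)
    h_act  = 4,        # Hill steepness of Ca-dependent RyR activation
    k_sr_thr = 1.31,   # mM, free SR Ca scale of luminal sensitisation
                       # (mild RyR sensitisation; gates the ignition leak)
    h_sr   = 50,       # Hill steepness of luminal sensitisation
    k_sr_dep = 0.45,   # mM, luminal depletion level that desensitises release
    tau_ryr_o = 3,     # ms, RyR activation time constant
    k_ryr_rec = 5e-3,  # 1/ms, RyR refractoriness recovery (gated on low subspace Ca)
    k_ryr_inact = 0.06,   # 1/ms, Ca-dependent RyR inactivation rate scale
    k_inh  = 0.02,     # mM, subspace Ca half-inactivation
    v_up   = 6e-3,     # mM/ms per cytosolic volume, SERCA maximum
    k_up   = 4e-4,     # mM, forward half-activation (cytosolic Ca)
    h_up   = 3,        # SERCA Hill exponent (forward and reverse terms)
    k_srmax = 3.0,     # mM, reverse half-saturation: sets the load ceiling
                       # ca_sr ~ k_srmax * ca_cyto / k_up (thermodynamic
                       # balance of the reversible pump)
    v_leak = 3e-3,     # 1/ms (per SR volume), background SR->cytosol leak
    v_leak_ss = 0,     # 1/ms, optional luminal-gated SR->subspace leak
    h_leak = 10,       # steepness of the luminal gating of that leak
    tau_xfer = 1.0,    # ms, subspace <-> cytosol transfer
    # rapid buffering (non-TnC; TnC is owned by the mechanics model)
    b_ss = 0.005, k_b_ss = 3e-4,
    b_cyto = 0.030, k_b_cyto = 5e-4,
    b_csqn = 10, k_csqn = 0.8,
    remodeled = FALSE
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown ionicParams fields: ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$ca_o > 0, p$cm_cru > 0)
  structure(p, class = "ionicParams")
}

#' Conductance remodeling specification
#'
#' Multiplicative remodeling of four currents, representing electrical
#' remodeling of the transient outward current (+30%), slow delayed rectifier
#' (-15%), inward rectifier (-30%) and sodium-potassium pump (+15%).
#'
#' @param scale_Ito,scale_IKs,scale_IK1,scale_INaK multiplicative factors
#' @return an object of class `remodelingSpec`
#' @export
remodelingSpec <- function(scale_Ito = 1.30, scale_IKs = 0.85,
                           scale_IK1 = 0.70, scale_INaK = 1.15) {
  stopifnot(scale_Ito >= 0, scale_IKs >= 0, scale_IK1 >= 0, scale_INaK >= 0)
  structure(list(scale_Ito = scale_Ito, scale_IKs = scale_IKs,
                 scale_IK1 = scale_IK1, scale_INaK = scale_INaK),
            class = "remodelingSpec")
}

#' Apply conductance remodeling to an ionic parameter set
#'
#' Returns a modified copy; the input is untouched. A provenance flag
#' prevents accidental double application (which would silently compound the
#' percentages).
#'
#' @param params an [ionicParams()] object
#' @param spec a [remodelingSpec()] object
#' @return remodeled `ionicParams`
#' @export
applyRemodeling <- function(params, spec = remodelingSpec()) {
  stopifnot(inherits(params, "ionicParams"), inherits(spec, "remodelingSpec"))
  if (isTRUE(params$remodeled))
    stop("ionicParams already remodeled; refusing to apply remodeling twice")
  params$g_to <- params$g_to * spec$scale_Ito
  params$g_ks <- params$g_ks * spec$scale_IKs
  params$g_k1 <- params$g_k1 * spec$scale_IK1
  params$i_nak_max <- params$i_nak_max * spec$scale_INaK
  params$remodeled <- TRUE
  params
}

#' Strain-rate coupling parameters of the myofilament model
#'
#' The mechano-electric feedback: troponin-C calcium on/off rates and the
#' crossbridge detachment constant are modulated exponentially by sarcomere
#' strain rate, `k = k0 * exp(alpha * strain_rate)`. At zero strain rate the
#' modulated rates equal the baselines exactly. The alpha defaults are a
#' package calibration chosen so that a 10% stretch applied over 100 ms
#' raises diastolic cytosolic calcium measurably (>5%); they are not
#' literature constants.
#'
#' @param kon0 baseline TnC on-rate (1/mM/ms)
#' @param koff0 baseline TnC off-rate (1/ms)
#' @param alpha_on,alpha_off strain-rate sensitivities (ms, i.e. per unit
#'   strain rate in 1/ms); positive `alpha_off` means stretch promotes
#'   calcium dissociation from TnC
#' @param alpha_xb strain-rate sensitivity of crossbridge detachment
#' @param max_log_mod clamp on the modulation exponent `alpha *
#'   strain_rate` (dimensionless); rates are modulated by at most
#'   `exp(max_log_mod)` in either direction
#' @param gamma_sl length-dependence of the off-rate strain sensitivity:
#'   the effective `alpha_off` is scaled by
#'   `1 + gamma_sl * (SL - SL_ref)/SL_ref`, so the same strain rate releases
#'   more TnC calcium in a stretched sarcomere than in a shortened one
#' @return an object of class `strainCouplingParams`
#' @export
strainCouplingParams <- function(kon0 = 40, koff0 = 0.03,
                                 alpha_on = 0, alpha_off = 1500,
                                 alpha_xb = 150, gamma_sl = 3,
                                 max_log_mod = 3) {
  stopifnot(kon0 > 0, koff0 > 0, max_log_mod > 0)
  structure(list(kon0 = kon0, koff0 = koff0, alpha_on = alpha_on,
                 alpha_off = alpha_off, alpha_xb = alpha_xb,
                 gamma_sl = gamma_sl, max_log_mod = max_log_mod),
            class = "strainCouplingParams")
}

#' Sarcomere mechanics parameters
#'
#' Reduced myofilament model: one TnC calcium-occupancy state, one
#' crossbridge-occupancy state with cooperative activation by TnC, and
#' sarcomere length relaxing toward the length command of the stretch
#' protocol (length-controlled loading). Total TnC site concentration
#' `b_tnc` links the mechanics to the ionic model: the net calcium flux onto
#' TnC is withdrawn from the cytosol of the same CRU (strong coupling).
#'
#' @param coupling a [strainCouplingParams()] object
#' @param ... named overrides
#' @return an object of class `sarcomereParams`
#' @export
sarcomereParams <- function(coupling = strainCouplingParams(), ...) {
  p <- list(
    b_tnc = 0.07,        # mM total TnC regulatory sites (cytosolic volume)
    n_coop = 3,          # crossbridge activation cooperativity
    f_xb = 0.05,         # 1/ms attachment
    g_xb = 0.10,         # 1/ms detachment
    gamma_xb = 0.4,      # force feedback on TnC off-rate (0..1)
    beta_lda = 1.0,      # length-dependent activation of kon per unit rel. SL
    sl_ref = 1.89,       # um reference sarcomere length
    sl_min = 1.4, sl_max = 2.4,   # validity range (um)
    tau_sl = 8,          # ms, relaxation toward length command
    f_max = 1.0,         # normalised force scale
    coupling = coupling
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown sarcomereParams fields: ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  structure(p, class = "sarcomereParams")
}

#' Fibroblast membrane parameters
#'
#' Active fibroblast model with four ionic currents: a time- and
#' voltage-dependent K+ current (IKv, one activation and one inactivation
#' gate), an inward-rectifying K+ current, a Na+/K+ pump and a background
#' Na+ current, plus a linear gap junction of conductance `g_f_gap` to the
#' host myocyte CRU.
#'
#' @param g_f_gap myocyte-fibroblast gap junction conductance (nS)
#' @param ... named overrides
#' @return an object of class `fibroblastParams`
#' @export
fibroblastParams <- function(g_f_gap = 3.0, ...) {
  p <- list(
    c_f = 6.3,         # pF
    g_kv = 0.25,       # mS/uF
    g_k1f = 0.48,
    i_nakf_max = 2.0,  # pA/pF
    km_naif = 11, km_kof = 1.0,
    g_bna = 9.5e-3,
    na_o = 140, k_o = 5.4,
    g_f_gap = g_f_gap
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown fibroblastParams fields: ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$g_f_gap >= 0, p$c_f > 0)
  structure(p, class = "fibroblastParams")
}
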