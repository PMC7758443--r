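# Bridge to the compiled tissue RHS. The parameter vector serialises the
# full model configuration; layout must stay in lockstep with
# src/tissue_rhs.c (a parity test asserts R/C agreement).

.IONIC_PAR_ORDER <- c("ca_o", "na_o", "k_o", "cm_cru", "v_cyto", "v_sr",
                      "v_ss", "g_na", "p_cal", "k_fca", "g_to", "g_ks",
                      "g_kr", "g_k1", "i_nak_max", "km_nai", "km_ko",
                      "v_ncx", "km_na_ncx", "km_ca_ncx", "k_sat", "eta",
                      "g_cab", "g_nab", "v_pca", "km_pca", "v_rel", "f_relss",
                      "k_act0", "h_act", "k_sr_thr", "h_sr", "k_sr_dep", "tau_ryr_o",
                      "k_ryr_rec", "k_ryr_inact", "k_inh", "v_up", "k_up", "h_up", "k_srmax",
                      "v_leak", "v_leak_ss", "h_leak", "tau_xfer", "b_ss", "k_b_ss", "b_cyto",
                      "k_b_cyto", "b_csqn", "k_csqn")
.MECH_PAR_ORDER <- c("b_tnc", "n_coop", "f_xb", "g_xb", "gamma_xb",
                     "beta_lda", "sl_ref", "sl_min", "sl_max", "tau_sl",
                     "f_max")
.STRAIN_PAR_ORDER <- c("kon0", "koff0", "alpha_on", "alpha_off", "alpha_xb", "gamma_sl", "max_log_mod")
.FIB_PAR_ORDER <- c("c_f", "g_kv", "g_k1f", "i_nakf_max", "km_naif",
                    "km_kof", "g_bna", "na_o", "k_o")

# serialise a tissue configuration for the C kernel
.tissueParVec <- function(spec, diffusion, conduction, ionic, mech,
                          stretch = NULL, stretch_stop = Inf,
                          sl_mode = "verbatim", sl_kappa = 0.5,
                          ca_coupling = TRUE, vm_coupling = TRUE) {
  lay <- tissueLayout(spec)
  pat <- if (is.null(stretch)) -1L
         else match(stretch$pattern, c("I", "H", "S", "P")) - 1L
  sp <- if (is.null(stretch))
    list(cycle_length = 1000, compression = 0, stretch = 0, plateau = 0,
         tau_rise = 1, tau_decay = 1, decay_start_frac = 0.5)
  else stretch
  cell_first <- vapply(lay$cell_cru_idx, min, 1L)
  cell_n <- vapply(lay$cell_cru_idx, length, 1L)
  header <- c(
    lay$n_states, lay$n_cru_total, spec$n_cells, nrow(lay$fib),
    as.numeric(spec$eq6_verbatim_signs),
    match(sl_mode, c("verbatim", "relaxed")) - 1L, sl_kappa,
    pat, sp$cycle_length, sp$compression, sp$stretch, sp$plateau,
    sp$tau_rise, sp$tau_decay, sp$decay_start_frac, stretch_stop,
    conduction$stim_amplitude, conduction$stim_duration,
    conduction$stim_period, conduction$stim_n_beats, conduction$stim_target,
    diffusion$tau_ss, diffusion$tau_sr, diffusion$tau_cyto,
    conduction$tau_vm,
    as.numeric(ca_coupling), as.numeric(vm_coupling)
  )
  c(header,
    unlist(ionic[.IONIC_PAR_ORDER], use.names = FALSE),
    unlist(mech[.MECH_PAR_ORDER], use.names = FALSE),
    unlist(mech$coupling[.STRAIN_PAR_ORDER], use.names = FALSE),
    unlist(spec$fibroblast_params[.FIB_PAR_ORDER], use.names = FALSE),
    cell_first, cell_n,
    if (spec$n_cells > 1) spec$g_gap else numeric(0),
    lay$cru_off, lay$resting_sl,
    lay$fib$off, lay$fib$cru, lay$fib$g_f_gap)
}

#' Compiled tissue right-hand side (fast path)
#'
#' Same contract as [assembleTissueRHS()], evaluated by the compiled kernel.
#'
#' @inheritParams assembleTissueRHS
#' @return function `f(t, y)` returning `dy/dt`
#' @export
compiledTissueRHS <- function(spec, diffusion = diffusionParams(),
                              conduction = conductionParams(),
                              ionic = ionicParams(), mech = sarcomereParams(),
                              stretch = NULL, stretch_stop = Inf,
                              sl_mode = "verbatim", sl_kappa = 0.5,
                              ca_coupling = TRUE, vm_coupling = TRUE) {
  pv <- .tissueParVec(spec, diffusion, conduction, ionic, mech,
                      stretch, stretch_stop, sl_mode, sl_kappa,
                      ca_coupling, vm_coupling)
  n <- pv[1]
  function(t, y) {
    if (length(y) != n)
      stop(sprintf("tissue RHS: state length %d != expected %d",
                   length(y), n))
    .Call(C_tissue_rhs, as.numeric(t), as.numeric(y), pv)
  }
}
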