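# Reduced sarcomere mechanics: TnC calcium binding (the mechano-electric
# feedback pathway), cooperative crossbridge cycling, and length-controlled
# sarcomere dynamics. Vectorised over sarcomeres.

#' Construct a sarcomere mechanical state
#'
#' @param n number of sarcomeres
#' @param sl sarcomere length (um); scalar or length-`n`
#' @param ... named overrides (`tnc`, `xb`)
#' @return object of class `sarcomereState`
#' @export
sarcomereState <- function(n = 1, sl = 1.89, ...) {
  s <- list(sl = sl, tnc = 0.1, xb = 0.002)
  ov <- list(...)
  bad <- setdiff(names(ov), names(s))
  if (length(bad)) stop("unknown sarcomereState fields: ", paste(bad, collapse = ", "))
  s[names(ov)] <- ov
  s <- lapply(s, function(x) rep_len(as.numeric(x), n))
  structure(s, class = "sarcomereState")
}

#' Strain-rate-modulated TnC calcium binding rates
#'
#' The core mechano-electric coupling primitive: both troponin-C rates are
#' scaled exponentially by the sarcomere strain rate,
#' `kon = kon0 * exp(alpha_on * strain_rate)` and
#' `koff = koff0 * exp(alpha_off * strain_rate)`.
#' At zero strain rate the baselines are returned exactly; both outputs are
#' strictly positive and strictly monotone in `strain_rate` for nonzero
#' alphas.
#'
#' @param coupling a [strainCouplingParams()] object
#' @param strain_rate sarcomere strain rate (1/ms); any numeric vector
#' @return list with numeric elements `kon`, `koff`
#' @export
strainModulatedRates <- function(coupling, strain_rate) {
  cap <- coupling$max_log_mod
  cl <- function(x) pmin(pmax(x, -cap), cap)
  list(kon = coupling$kon0 * exp(cl(coupling$alpha_on * strain_rate)),
       koff = coupling$koff0 * exp(cl(coupling$alpha_off * strain_rate)))
}

# thick/thin filament overlap factor, clamped to [0, 1]
.overlap <- function(sl) pmax(0, 1 - ((sl - 2.1) / 0.7)^2)

#' Time derivative of the sarcomere state plus the TnC calcium flux
#'
#' Computes TnC occupancy and crossbridge dynamics at the given cytosolic
#' calcium and strain rate, the active force, and the signed net calcium
#' flux onto TnC (mM/ms, cytosolic volume) that the ionic model withdraws
#' from the cytosol. The returned `sl` derivative is the *isotonic*
#' length-change rate (relaxation toward the length command `sl_cmd` with
#' time constant `tau_sl`); inter-sarcomere coupling replaces it in fiber
#' simulations.
#'
#' Sarcomere lengths outside the model's validity range are clamped for the
#' force/affinity computations and a warning is issued.
#'
#' @param state a [sarcomereState()]
#' @param ca_cyto cytosolic calcium (mM), per sarcomere
#' @param strain_rate effective strain rate dSL/dt / resting SL (1/ms)
#' @param params a [sarcomereParams()]
#' @param sl_cmd commanded sarcomere length (um); defaults to the current
#'   length (isometric)
#' @return list with `deriv` (list `sl`, `tnc`, `xb`), `force` (normalised)
#'   and `tnc_flux` (mM/ms)
#' @export
myofilamentRHS <- function(state, ca_cyto, strain_rate, params,
                           sl_cmd = state$sl) {
  .checkFinite(state, "myofilamentRHS")
  if (any(ca_cyto <= 0)) stop("myofilamentRHS: ca_cyto must be > 0")
  p <- params
  sl <- state$sl
  if (any(sl < p$sl_min | sl > p$sl_max)) {
    warning("sarcomere length outside validity range [",
            p$sl_min, ", ", p$sl_max, "] um; clamped", call. = FALSE)
    sl <- pmin(pmax(sl, p$sl_min), p$sl_max)
  }
  lfac <- 1 + p$coupling$gamma_sl * (sl - p$sl_ref) / p$sl_ref
  rates <- strainModulatedRates(p$coupling, strain_rate * lfac)
  kon <- p$coupling$kon0 * exp(p$coupling$alpha_on * strain_rate) *
    (1 + p$beta_lda * (sl - p$sl_ref) / p$sl_ref)
  koff <- rates$koff * (1 - p$gamma_xb * state$xb)
  dtnc <- kon * ca_cyto * (1 - state$tnc) - koff * state$tnc
  cap <- p$coupling$max_log_mod
  g_eff <- p$g_xb * exp(pmin(p$coupling$alpha_xb * abs(strain_rate), cap))
  dxb <- p$f_xb * state$tnc^p$n_coop * (1 - state$xb) - g_eff * state$xb
  force <- p$f_max * state$xb * .overlap(sl)
  list(deriv = list(sl = (sl_cmd - state$sl) / p$tau_sl, tnc = dtnc, xb = dxb),
       force = force,
       tnc_flux = p$b_tnc * dtnc)
}
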