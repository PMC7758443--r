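# Reduced rabbit ventricular ionic model, one calcium-release unit (CRU).
# All functions are vectorised over CRUs: every state field may be a numeric
# vector of length n_cru and the returned derivatives have the same shape.

#' Construct an ionic state
#'
#' @param n number of CRUs
#' @param ... named overrides of any state field (recycled to length `n`)
#' @return object of class `ionicState`: named list of numeric vectors
#' @export
ionicState <- function(n = 1, ...) {
  s <- list(
    vm = -85.5, m = 0.0017, h = 0.983, j = 0.989,
    d = 3e-6, f = 1.0, xto = 3.3e-4, yto = 0.994,
    xks = 5.6e-3, xkr = 2.1e-4,
    ryr_o = 0, ryr_r = 1,
    ca_ss = 1.0e-4, ca_sr = 0.55, ca_cyto = 1.0e-4,
    na_i = 10, k_i = 140
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(s))
  if (length(bad)) stop("unknown ionicState fields: ", paste(bad, collapse = ", "))
  s[names(ov)] <- ov
  s <- lapply(s, function(x) rep_len(as.numeric(x), n))
  structure(s, class = "ionicState")
}

#' @export
print.ionicState <- function(x, ...) {
  n <- length(x$vm)
  cat(sprintf("<ionicState: %d CRU%s>\n", n, if (n == 1) "" else "s"))
  cat(sprintf("  Vm %.2f..%.2f mV | Ca_SR %.3f..%.3f mM | Ca_cyto %.2e..%.2e mM\n",
              min(x$vm), max(x$vm), min(x$ca_sr), max(x$ca_sr),
              min(x$ca_cyto), max(x$ca_cyto)))
  invisible(x)
}

.GATE_FIELDS <- c("m", "h", "j", "d", "f", "xto", "yto", "xks", "xkr",
                  "ryr_o", "ryr_r")
.CONC_FIELDS <- c("ca_ss", "ca_sr", "ca_cyto", "na_i", "k_i")

.checkFinite <- function(state, where) {
  for (nm in names(state)) {
    if (!all(is.finite(state[[nm]]))) {
      i <- which(!is.finite(state[[nm]]))[1]
      stop(sprintf("%s: non-finite state variable '%s' (index %d)", where, nm, i))
    }
  }
  invisible(TRUE)
}

# x/(1 - exp(-k*x)) with the removable singularity at x = 0 filled in
.vtrap <- function(x, k) {
  out <- x / (1 - exp(-k * x))
  small <- abs(x) < 1e-7
  if (any(small)) out[small] <- 1 / k
  out
}

# rapid-buffering factor: free-Ca fraction of a single saturable buffer
.bufBeta <- function(ca, btot, kd) 1 / (1 + btot * kd / (kd + ca)^2)

#' Time derivative of the ionic state of one or more CRUs
#'
#' Computes all membrane currents and calcium-cycling fluxes of the reduced
#' CRU model and returns the local (uncoupled) state derivative together with
#' the total membrane current. Cytosolic calcium buffering by troponin C is
#' *not* part of this model: the net TnC flux computed by the myofilament
#' model is passed in through `tnc_flux` and withdrawn from the cytosol here
#' (strong electromechanical coupling), replacing the internal troponin
#' buffer an electrophysiology-only model would carry.
#'
#' @param state an [ionicState()]
#' @param params an [ionicParams()]
#' @param tnc_flux net calcium flux onto troponin C (mM/ms, cytosolic
#'   volume); scalar or per-CRU vector
#' @return list with elements `deriv` (an `ionicState`-shaped list of
#'   derivatives), `i_m` (total membrane current, pA/pF) and `currents`
#'   (named list of the individual currents)
#' @export
ionicRHS <- function(state, params, tnc_flux = 0) {
  .checkFinite(state, "ionicRHS")
  if (!all(is.finite(tnc_flux))) stop("ionicRHS: non-finite tnc_flux")
  p <- params
  v <- state$vm
  rtf <- .RTF

  e_na <- rtf * log(p$na_o / state$na_i)
  e_k  <- rtf * log(p$k_o / state$k_i)
  e_ca <- rtf / 2 * log(p$ca_o / state$ca_cyto)

  ## fast sodium current
  a_m <- 0.32 * .vtrap(v + 47.13, 0.1)
  b_m <- 0.08 * exp(-v / 11)
  low <- v < -40
  a_h <- ifelse(low, 0.135 * exp(-(80 + v) / 6.8), 0)
  b_h <- ifelse(low, 3.56 * exp(0.079 * v) + 3.1e5 * exp(0.35 * v),
                1 / (0.13 * (1 + exp(-(v + 10.66) / 11.1))))
  a_j <- ifelse(low,
                (-1.2714e5 * exp(0.2444 * v) - 3.474e-5 * exp(-0.04391 * v)) *
                  (v + 37.78) / (1 + exp(0.311 * (v + 79.23))),
                0)
  b_j <- ifelse(low,
                0.1212 * exp(-0.01052 * v) / (1 + exp(-0.1378 * (v + 40.14))),
                0.3 * exp(-2.535e-7 * v) / (1 + exp(-0.1 * (v + 32))))
  i_na <- p$g_na * state$m^3 * state$h * state$j * (v - e_na)

  ## L-type calcium current (GHK driving force; Ca_o enters here)
  d_inf <- 1 / (1 + exp(-(v + 10) / 6.24))
  tau_d <- ifelse(abs(v + 10) < 1e-6, 2.289,
                  d_inf * (1 - exp(-(v + 10) / 6.24)) / (0.035 * (v + 10)))
  f_inf <- 1 / (1 + exp((v + 32) / 8.6))
  tau_f <- 1 / (0.0065 * exp(-(0.0337 * (v + 10))^2) + 0.006)
  f_ca <- p$k_fca / (p$k_fca + state$ca_ss)
  zv <- 2 * v / rtf
  ghk <- ifelse(abs(zv) < 1e-6,
                2 * (state$ca_ss - 0.341 * p$ca_o),
                2 * zv * (state$ca_ss * exp(zv) - 0.341 * p$ca_o) / (exp(zv) - 1))
  i_cal <- p$p_cal * state$d * state$f * f_ca * ghk

  ## potassium currents
  xto_inf <- 1 / (1 + exp(-(v - 19) / 13))
  tau_xto <- 3.5 * exp(-(v / 30)^2) + 1.5
  yto_inf <- 1 / (1 + exp((v + 33.5) / 10))
  tau_yto <- 20 + 20 * exp(-((v + 33.5) / 10)^2)
  i_to <- p$g_to * state$xto * state$yto * (v - e_k)

  xks_inf <- 1 / (1 + exp(-(v - 1.5) / 16.7))
  tau_xks <- 1 / (7.19e-5 * .vtrap(v + 30, 0.148) +
                  1.31e-4 * .vtrap(-(v + 30), 0.0687))
  i_ks <- p$g_ks * state$xks^2 * (v - e_k)

  xkr_inf <- 1 / (1 + exp(-(v + 21.5) / 7.5))
  tau_xkr <- 1 / (0.00138 * .vtrap(v + 14.2, 0.123) +
                  0.00061 * .vtrap(-(v + 38.9), 0.145))
  r_kr <- 1 / (1 + exp((v + 9) / 22.4))
  i_kr <- p$g_kr * state$xkr * r_kr * (v - e_k)

  dvk <- v - e_k
  a_k1 <- 1.02 / (1 + exp(0.2385 * (dvk - 59.215)))
  b_k1 <- (0.49124 * exp(0.08032 * (dvk + 5.476)) +
             exp(0.06175 * (dvk - 594.31))) /
    (1 + exp(-0.5143 * (dvk + 4.753)))
  i_k1 <- p$g_k1 * sqrt(p$k_o / 5.4) * a_k1 / (a_k1 + b_k1) * dvk

  ## pumps and exchangers
  sigma <- (exp(p$na_o / 67.3) - 1) / 7
  f_nak <- 1 / (1 + 0.1245 * exp(-0.1 * v / rtf) + 0.0365 * sigma * exp(-v / rtf))
  i_nak <- p$i_nak_max * f_nak * (p$k_o / (p$k_o + p$km_ko)) /
    (1 + (p$km_nai / state$na_i)^1.5)

  ex1 <- exp(p$eta * v / rtf)
  ex2 <- exp((p$eta - 1) * v / rtf)
  i_ncx <- p$v_ncx *
    (ex1 * state$na_i^3 * p$ca_o - ex2 * p$na_o^3 * state$ca_ss) /
    ((p$km_na_ncx^3 + p$na_o^3) * (p$km_ca_ncx + p$ca_o) * (1 + p$k_sat * ex2))

  ghk_b <- ifelse(abs(zv) < 1e-6,
                  2 * (state$ca_cyto - 0.341 * p$ca_o),
                  2 * zv * (state$ca_cyto * exp(zv) - 0.341 * p$ca_o) /
                    (exp(zv) - 1))
  i_cab <- p$g_cab * ghk_b
  i_nab <- p$g_nab * (v - e_na)
  i_pca <- p$v_pca * state$ca_cyto / (state$ca_cyto + p$km_pca)

  i_m <- i_na + i_cal + i_to + i_ks + i_kr + i_k1 + i_nak + i_ncx +
    i_cab + i_nab + i_pca

  ## SR calcium cycling
  k_act <- p$k_act0 * (1 + (p$k_sr_dep / state$ca_sr)^2) /
    (1 + (state$ca_sr / p$k_sr_thr)^p$h_sr)
  o_inf <- state$ca_ss^p$h_act / (state$ca_ss^p$h_act + k_act^p$h_act)
  # release flux (per SR volume): bulk into the cytosol, a fraction routed
  # via the subspace where it is sensed (CICR, NCX, inter-CRU diffusion)
  j_rel <- p$v_rel * state$ryr_o * state$ryr_r * (state$ca_sr - state$ca_cyto)
  # luminal-load-gated SR leak into the subspace: the deterministic trigger
  # of spontaneous release under SR calcium overload
  j_spark <- p$v_leak_ss * (state$ca_sr - state$ca_ss) *
    (state$ca_sr / p$k_sr_thr)^p$h_leak
  fw <- (state$ca_cyto / p$k_up)^p$h_up
  rv <- (state$ca_sr / p$k_srmax)^p$h_up
  j_up <- p$v_up * (fw - rv) / (1 + fw + rv)
  j_leak <- p$v_leak * (state$ca_sr - state$ca_cyto)
  j_xfer <- (state$ca_ss - state$ca_cyto) / p$tau_xfer

  conv_ss <- p$cm_cru / (2 * .FARADAY * p$v_ss)
  conv_cyto <- p$cm_cru / (2 * .FARADAY * p$v_cyto)
  conv1 <- p$cm_cru / (.FARADAY * p$v_cyto)

  beta_ss <- .bufBeta(state$ca_ss, p$b_ss, p$k_b_ss)
  beta_cyto <- .bufBeta(state$ca_cyto, p$b_cyto, p$k_b_cyto)
  beta_sr <- .bufBeta(state$ca_sr, p$b_csqn, p$k_csqn)

  deriv <- list(
    vm = -i_m,
    m = a_m * (1 - state$m) - b_m * state$m,
    h = a_h * (1 - state$h) - b_h * state$h,
    j = a_j * (1 - state$j) - b_j * state$j,
    d = (d_inf - state$d) / tau_d,
    f = (f_inf - state$f) / tau_f,
    xto = (xto_inf - state$xto) / tau_xto,
    yto = (yto_inf - state$yto) / tau_yto,
    xks = (xks_inf - state$xks) / tau_xks,
    xkr = (xkr_inf - state$xkr) / tau_xkr,
    ryr_o = (o_inf - state$ryr_o) / p$tau_ryr_o,
    ryr_r = p$k_ryr_rec * (1 - state$ryr_r) *
      p$k_inh^4 / (p$k_inh^4 + state$ca_ss^4) -
      p$k_ryr_inact * state$ca_ss^2 / (state$ca_ss^2 + p$k_inh^2) * state$ryr_r,
    ca_ss = beta_ss * ((p$f_relss * j_rel + j_spark) * (p$v_sr / p$v_ss) -
                         j_xfer + conv_ss * (-i_cal + 2 * i_ncx)),
    ca_sr = beta_sr * (j_up * (p$v_cyto / p$v_sr) - j_leak - j_rel - j_spark),
    ca_cyto = beta_cyto * ((1 - p$f_relss) * j_rel * (p$v_sr / p$v_cyto) +
                             j_xfer * (p$v_ss / p$v_cyto) +
                             j_leak * (p$v_sr / p$v_cyto) - j_up -
                             tnc_flux - conv_cyto * (i_cab + i_pca)),
    na_i = -(i_na + i_nab + 3 * i_nak + 3 * i_ncx) * conv1,
    k_i = -(i_to + i_ks + i_kr + i_k1 - 2 * i_nak) * conv1
  )
  list(deriv = deriv, i_m = i_m,
       currents = list(i_na = i_na, i_cal = i_cal, i_to = i_to, i_ks = i_ks,
                       i_kr = i_kr, i_k1 = i_k1, i_nak = i_nak, i_ncx = i_ncx,
                       i_cab = i_cab, i_nab = i_nab, i_pca = i_pca,
                       j_rel = j_rel, j_spark = j_spark, j_up = j_up))
}
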