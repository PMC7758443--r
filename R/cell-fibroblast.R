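# Active fibroblast membrane model: five time- and voltage-dependent state
# variables (V_f, IKv activation/inactivation gates, Na_f, K_f) and four
# ionic currents (IKv, inward-rectifier IK1, NaK pump, background Na), plus
# a linear gap junction to the host myocyte CRU.

#' Construct a fibroblast state
#'
#' @param n number of fibroblasts
#' @param ... named overrides (`v_f`, `r_f`, `s_f`, `na_f`, `k_f`)
#' @return object of class `fibroblastState`
#' @export
fibroblastState <- function(n = 1, ...) {
  s <- list(v_f = -49.6, r_f = 0.06, s_f = 0.99, na_f = 8.5, k_f = 130)
  ov <- list(...)
  bad <- setdiff(names(ov), names(s))
  if (length(bad)) stop("unknown fibroblastState fields: ", paste(bad, collapse = ", "))
  s[names(ov)] <- ov
  s <- lapply(s, function(x) rep_len(as.numeric(x), n))
  structure(s, class = "fibroblastState")
}

#' Time derivative of the fibroblast state plus junctional current
#'
#' The junctional current is `i_junc = g_f_gap * (v_f - v_myocyte)` (pA):
#' positive current flows from fibroblast into myocyte, so a fibroblast
#' below the myocyte potential drains depolarising charge from the myocyte.
#' The identical term, with opposite sign and scaled by the fibroblast
#' capacitance, enters `dV_f/dt`; the myocyte side applies `+i_junc/C_cru`.
#'
#' @param state a [fibroblastState()]
#' @param params a [fibroblastParams()]
#' @param v_myocyte membrane potential of the host CRU (mV)
#' @return list with `deriv`, `i_junc` (pA) and `currents` (pA/pF)
#' @export
fibroblastRHS <- function(state, params, v_myocyte) {
  .checkFinite(state, "fibroblastRHS")
  p <- params
  v <- state$v_f
  e_k <- .RTF * log(p$k_o / state$k_f)
  e_na <- .RTF * log(p$na_o / state$na_f)

  r_inf <- 1 / (1 + exp(-(v + 20) / 11))
  tau_r <- 20.3 + 138 * exp(-((v + 20) / 25.9)^2)
  s_inf <- 1 / (1 + exp((v + 23) / 7))
  tau_s <- 1574 + 5268 * exp(-((v + 23) / 22.7)^2)
  i_kv <- p$g_kv * state$r_f * state$s_f * (v - e_k)

  dvk <- v - e_k
  a_k1 <- 0.1 / (1 + exp(0.06 * (dvk - 200)))
  b_k1 <- (3 * exp(2e-4 * (dvk + 100)) + exp(0.1 * (dvk - 10))) /
    (1 + exp(-0.5 * dvk))
  i_k1 <- p$g_k1f * a_k1 / (a_k1 + b_k1) * dvk

  i_nak <- p$i_nakf_max * (p$k_o / (p$k_o + p$km_kof)) *
    state$na_f^1.5 / (state$na_f^1.5 + p$km_naif^1.5) *
    (v + 150) / (v + 200)
  i_bna <- p$g_bna * (v - e_na)

  i_junc <- p$g_f_gap * (v - v_myocyte)   # pA (nS * mV)

  vol_f <- 1.0  # pL
  conv <- p$c_f / (.FARADAY * vol_f)
  deriv <- list(
    v_f = -(i_kv + i_k1 + i_nak + i_bna) - i_junc / p$c_f,
    r_f = (r_inf - state$r_f) / tau_r,
    s_f = (s_inf - state$s_f) / tau_s,
    na_f = -(i_bna + 3 * i_nak) * conv,
    k_f = -(i_kv + i_k1 - 2 * i_nak) * conv
  )
  list(deriv = deriv, i_junc = i_junc,
       currents = list(i_kv = i_kv, i_k1 = i_k1, i_nak = i_nak, i_bna = i_bna))
}
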