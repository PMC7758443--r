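# Spatial couplings inside one myocyte: inter-CRU calcium diffusion,
# membrane-potential conduction with stimulus, and inter-sarcomere
# mechanical coupling.

#' Fiber geometry of one myocyte
#'
#' @param n_cru number of calcium-release units (default 50)
#' @param resting_sl per-sarcomere resting lengths (um); recycled to
#'   `n_cru`. See [generateRestingLengths()] for the heterogeneous case.
#' @param spacing inter-CRU distance used for position/velocity conversion
#'   (um); defaults to the local resting sarcomere length
#' @return object of class `fiberGeometry`
#' @export
fiberGeometry <- function(n_cru = 50, resting_sl = 1.89, spacing = resting_sl) {
  if (n_cru < 2) stop("fiberGeometry: n_cru must be >= 2")
  g <- list(n_cru = as.integer(n_cru),
            resting_sl = rep_len(as.numeric(resting_sl), n_cru),
            spacing = rep_len(as.numeric(spacing), n_cru))
  stopifnot(all(g$resting_sl > 0), all(g$spacing > 0))
  structure(g, class = "fiberGeometry")
}

#' CRU centre positions along the fiber
#'
#' CRU `i` is centred at the midpoint of its sarcomere, i.e. at the
#' cumulative sum of the preceding spacings plus half its own (1-based CRU
#' indexing).
#'
#' @param geometry a [fiberGeometry()]
#' @return numeric vector of positions (um)
#' @export
cruPositions <- function(geometry) {
  cumsum(geometry$spacing) - geometry$spacing / 2
}

#' Calcium diffusion parameters between adjacent CRUs
#'
#' Exchange time constants for the three calcium compartments:
#' subsarcolemmal space, SR, and cytosol.
#'
#' @param tau_ss,tau_sr,tau_cyto time constants (ms)
#' @return object of class `diffusionParams`
#' @export
diffusionParams <- function(tau_ss = 0.4533, tau_sr = 150, tau_cyto = 1.2) {
  stopifnot(tau_ss > 0, tau_sr > 0, tau_cyto > 0)
  structure(list(tau_ss = tau_ss, tau_sr = tau_sr, tau_cyto = tau_cyto),
            class = "diffusionParams")
}

#' Membrane-potential conduction and stimulus parameters
#'
#' `tau_vm` is the resistive transfer time constant between adjacent CRUs;
#' its very small default makes the 50 CRUs of one myocyte nearly
#' isopotential while still supporting a propagating upstroke. The stimulus
#' is an additive term on the first CRU's dVm/dt: `stim_amplitude /
#' stim_duration` (mV/ms) while `t` modulo `stim_period` lies inside the
#' pulse and fewer than `stim_n_beats` pulses have been delivered, i.e. a
#' depolarising impulse whose time integral is `stim_amplitude` mV.
#'
#' @param tau_vm inter-CRU voltage transfer time constant (ms)
#' @param stim_amplitude integrated stimulus magnitude (mV)
#' @param stim_duration pulse duration (ms)
#' @param stim_target stimulated CRU index (1-based)
#' @param stim_period pacing cycle length (ms)
#' @param stim_n_beats number of pulses delivered before the stimulus is
#'   silenced (Inf = pace forever)
#' @return object of class `conductionParams`
#' @export
conductionParams <- function(tau_vm = 1e-5, stim_amplitude = 1000,
                             stim_duration = 3, stim_target = 1L,
                             stim_period = 1000, stim_n_beats = Inf) {
  stopifnot(tau_vm > 0, stim_duration > 0, stim_period > 0)
  structure(list(tau_vm = tau_vm, stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration,
                 stim_target = as.integer(stim_target),
                 stim_period = stim_period, stim_n_beats = stim_n_beats),
            class = "conductionParams")
}

#' Nearest-neighbour exchange stencil for one calcium compartment
#'
#' Interior CRUs: `(ca[i+1] + ca[i-1] - 2 ca[i]) / tau`; end CRUs exchange
#' with their single neighbour. The stencil is symmetric and zero-sum, so
#' total compartment calcium is conserved by the coupling alone.
#'
#' @param ca per-CRU concentration vector (mM) for one compartment
#' @param tau exchange time constant (ms)
#' @return per-CRU coupling rates (mM/ms)
#' @export
caCouplingTerm <- function(ca, tau) {
  n <- length(ca)
  if (n < 2) stop("caCouplingTerm: need at least 2 CRUs")
  left <- c(ca[1], ca[-n])    # reflecting ends: self-neighbour
  right <- c(ca[-1], ca[n])
  (left + right - 2 * ca) / tau
}

#' Resistive membrane-potential coupling with stimulus
#'
#' Same zero-sum nearest-neighbour stencil as [caCouplingTerm()], divided by
#' `cp$tau_vm`, plus the stimulus contribution on the target CRU while `t`
#' lies inside an active stimulus window.
#'
#' @param vm per-CRU membrane potential (mV)
#' @param cp a [conductionParams()]
#' @param t time (ms)
#' @return per-CRU coupling + stimulus rates (mV/ms)
#' @export
vmCouplingTerm <- function(vm, cp, t) {
  out <- caCouplingTerm(vm, cp$tau_vm)
  if (stimulusActive(cp, t))
    out[cp$stim_target] <- out[cp$stim_target] +
      cp$stim_amplitude / cp$stim_duration
  out
}

#' Is the pacing stimulus active at time t?
#'
#' @param cp a [conductionParams()]
#' @param t time (ms)
#' @return logical
#' @export
stimulusActive <- function(cp, t) {
  beat <- floor(t / cp$stim_period)
  phase <- t - beat * cp$stim_period
  (beat < cp$stim_n_beats) && (phase < cp$stim_duration)
}

#' Inter-sarcomere mechanical coupling of isotonic length-change rates
#'
#' Combines per-sarcomere isotonic rates `dSL^` into effective `dSL/dt`.
#' The default `"verbatim"` mode uses, for interior sarcomeres,
#' `2*own - (left + right)` and for boundary sarcomeres `own - neighbour`.
#' Note this form freezes a homogeneous fiber (uniform rates map to zero);
#' the `"relaxed"` mode `own + kappa*(neighbour mean - own)` is a smoothing
#' alternative without that degeneracy (`kappa = 0` is the identity).
#'
#' @param iso_rates per-sarcomere isotonic length-change rates (um/ms)
#' @param mode `"verbatim"` or `"relaxed"`
#' @param kappa relaxation weight in `[0, 1]` (relaxed mode only)
#' @return effective dSL/dt per sarcomere (um/ms)
#' @export
sarcomereCoupling <- function(iso_rates, mode = c("verbatim", "relaxed"),
                              kappa = 0.5) {
  n <- length(iso_rates)
  if (n < 2) stop("sarcomereCoupling: need at least 2 sarcomeres")
  mode <- match.arg(mode)
  left <- c(NA, iso_rates[-n])
  right <- c(iso_rates[-1], NA)
  if (mode == "verbatim") {
    out <- 2 * iso_rates - (left + right)
    out[1] <- iso_rates[1] - iso_rates[2]
    out[n] <- iso_rates[n] - iso_rates[n - 1]
  } else {
    nb <- (left + right) / 2
    nb[1] <- iso_rates[2]
    nb[n] <- iso_rates[n - 1]
    out <- iso_rates + kappa * (nb - iso_rates)
  }
  out
}

# state-vector block layout (per CRU), used by the engine and the C core
.CRU_FIELDS <- c("vm", "m", "h", "j", "d", "f", "xto", "yto", "xks", "xkr",
                 "ryr_o", "ryr_r", "ca_ss", "ca_sr", "ca_cyto", "na_i", "k_i",
                 "sl", "tnc", "xb")
.N_CRU_STATES <- length(.CRU_FIELDS)
.FIB_FIELDS <- c("v_f", "r_f", "s_f", "na_f", "k_f")
.N_FIB_STATES <- length(.FIB_FIELDS)

#' Assemble the right-hand side of one myocyte fiber
#'
#' Builds a callable `f(t, y)` mapping the packed fiber state (per-CRU
#' blocks of the 17 ionic + 3 mechanical states, concatenated in CRU order)
#' to its time derivative: local CRU dynamics from the ionic and myofilament
#' models plus inter-CRU calcium diffusion, resistive membrane-potential
#' coupling with stimulus, and inter-sarcomere mechanical coupling. The
#' stretch protocol (if any) prescribes the sarcomere length command as
#' `resting_sl * scale(t)` while `t < stretch_stop`.
#'
#' @param geometry a [fiberGeometry()]
#' @param diffusion a [diffusionParams()]
#' @param conduction a [conductionParams()]
#' @param ionic an [ionicParams()]
#' @param mech a [sarcomereParams()]
#' @param stretch a [stretchProtocol()] or `NULL` (isometric at rest)
#' @param stretch_stop time after which the length command returns to the
#'   resting length (ms)
#' @param sl_mode sarcomere coupling mode, see [sarcomereCoupling()]
#' @param sl_kappa relaxation weight for `"relaxed"` mode
#' @param ca_coupling,vm_coupling logical switches for the two couplings
#'   (used by decoupling-limit tests)
#' @return function `f(t, y)` returning `dy/dt`
#' @export
assembleFiberRHS <- function(geometry, diffusion = diffusionParams(),
                             conduction = conductionParams(),
                             ionic = ionicParams(), mech = sarcomereParams(),
                             stretch = NULL, stretch_stop = Inf,
                             sl_mode = "verbatim", sl_kappa = 0.5,
                             ca_coupling = TRUE, vm_coupling = TRUE) {
  n <- geometry$n_cru
  nf <- .N_CRU_STATES
  idx <- matrix(seq_len(n * nf), nrow = nf)  # [field, cru]
  rownames(idx) <- .CRU_FIELDS
  force(diffusion); force(conduction); force(ionic); force(mech)

  function(t, y) {
    if (length(y) != n * nf)
      stop(sprintf("fiber RHS: state length %d != %d CRUs x %d fields",
                   length(y), n, nf))
    st <- lapply(.CRU_FIELDS, function(f) y[idx[f, ]])
    names(st) <- .CRU_FIELDS
    ion <- st[names(ionicState(1))]
    class(ion) <- "ionicState"
    mec <- list(sl = st$sl, tnc = st$tnc, xb = st$xb)
    class(mec) <- "sarcomereState"

    # mechanics first: coupled dSL/dt defines the strain rate for MEC
    scale <- if (!is.null(stretch) && t < stretch_stop)
      stretchScaling(stretch, t)$scale else 1
    sl_cmd <- geometry$resting_sl * scale
    iso <- (sl_cmd - st$sl) / mech$tau_sl
    dsl <- sarcomereCoupling(iso, mode = sl_mode, kappa = sl_kappa)
    strain_rate <- dsl / geometry$resting_sl

    myo <- myofilamentRHS(mec, ca_cyto = st$ca_cyto,
                          strain_rate = strain_rate, params = mech,
                          sl_cmd = sl_cmd)
    cel <- ionicRHS(ion, ionic, tnc_flux = myo$tnc_flux)

    d <- cel$deriv
    d$sl <- dsl
    d$tnc <- myo$deriv$tnc
    d$xb <- myo$deriv$xb
    if (ca_coupling) {
      d$ca_ss <- d$ca_ss + caCouplingTerm(st$ca_ss, diffusion$tau_ss)
      d$ca_sr <- d$ca_sr + caCouplingTerm(st$ca_sr, diffusion$tau_sr)
      d$ca_cyto <- d$ca_cyto + caCouplingTerm(st$ca_cyto, diffusion$tau_cyto)
    }
    if (vm_coupling)
      d$vm <- d$vm + vmCouplingTerm(st$vm, conduction, t)

    dy <- numeric(n * nf)
    for (f in .CRU_FIELDS) dy[idx[f, ]] <- d[[f]]
    dy
  }
}

#' Pack per-field state lists into the engine's flat state vector
#'
#' @param ion an [ionicState()] of n CRUs
#' @param mec a [sarcomereState()] of n sarcomeres
#' @return numeric vector in per-CRU block layout
#' @export
packFiberState <- function(ion, mec) {
  n <- length(ion$vm)
  st <- c(unclass(ion), unclass(mec))
  as.vector(vapply(seq_len(n), function(i)
    vapply(.CRU_FIELDS, function(f) st[[f]][i], numeric(1)), numeric(.N_CRU_STATES)))
}

#' Unpack the flat fiber state vector into named per-CRU matrices
#'
#' @param y packed state vector (possibly a trace matrix row)
#' @param n_cru number of CRUs
#' @return named list of length-`n_cru` numeric vectors
#' @export
unpackFiberState <- function(y, n_cru) {
  nf <- .N_CRU_STATES
  stopifnot(length(y) >= n_cru * nf)
  m <- matrix(y[seq_len(n_cru * nf)], nrow = nf)
  out <- lapply(seq_len(nf), function(i) m[i, ])
  names(out) <- .CRU_FIELDS
  out
}
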