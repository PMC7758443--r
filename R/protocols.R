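# Stretch waveforms H/I/S/P, pacing schedules, the extracellular-calcium
# sweep, and the limit-cycle criterion.

#' Stretch protocol definition
#'
#' Four length-command waveforms, periodic with the pacing cycle, that
#' multiply the per-sarcomere resting length:
#' \describe{
#'   \item{H}{normal isotonic shortening: sinusoid dipping to 20%
#'     compression, `1 - 0.20*(1 - cos(2*pi*t/CL))/2` (minimum 0.80).}
#'   \item{I}{isometric: constant 1.}
#'   \item{S}{late-systolic stretch: sinusoid spanning \[0.90, 1.10\] with
#'     stretch in systole (early cycle) and compression in diastole,
#'     `1 + 0.10*sin(2*pi*t/CL)`.}
#'   \item{P}{systolic lengthening (acute-ischaemia-like): exponential rise
#'     from 1.00 toward the 1.15 plateau at contraction onset (time
#'     constant `tau_rise`), hold, then exponential decay back to 1.00
#'     starting at `decay_start_frac` of the cycle (time constant
#'     `tau_decay`).}
#' }
#'
#' @param pattern one of `"H"`, `"I"`, `"S"`, `"P"`
#' @param cycle_length pacing cycle length (ms)
#' @param compression peak compression fraction for H (0.20) and S (0.10)
#' @param stretch peak stretch fraction for S (0.10)
#' @param plateau plateau stretch fraction for P (0.15)
#' @param tau_rise,tau_decay P-pattern exponential time constants (ms)
#' @param decay_start_frac fraction of the cycle at which P starts to decay
#' @return object of class `stretchProtocol`
#' @export
stretchProtocol <- function(pattern = c("I", "H", "S", "P"),
                            cycle_length = 1000,
                            compression = NULL, stretch = 0.10,
                            plateau = 0.15, tau_rise = 20, tau_decay = 40,
                            decay_start_frac = 0.5) {
  pattern <- match.arg(pattern)
  if (is.null(compression)) compression <- if (pattern == "H") 0.20 else 0.10
  stopifnot(cycle_length > 0, tau_rise > 0, tau_decay > 0,
            decay_start_frac > 0, decay_start_frac < 1)
  structure(list(pattern = pattern, cycle_length = cycle_length,
                 compression = compression, stretch = stretch,
                 plateau = plateau, tau_rise = tau_rise,
                 tau_decay = tau_decay,
                 decay_start_frac = decay_start_frac),
            class = "stretchProtocol")
}

#' Evaluate a stretch protocol at time t
#'
#' Returns the sarcomere-length command multiplier and its analytic time
#' derivative (used for the strain-rate-dependent TnC kinetics).
#' Vectorised over `t`.
#'
#' @param protocol a [stretchProtocol()]
#' @param t time (ms, >= 0); reduced modulo the cycle length
#' @return list with numeric elements `scale` and `dscale` (1/ms)
#' @export
stretchScaling <- function(protocol, t) {
  if (any(t < 0)) stop("stretchScaling: t must be >= 0")
  p <- protocol
  cl <- p$cycle_length
  tc <- t - floor(t / cl) * cl
  w <- 2 * pi / cl
  switch(p$pattern,
    I = list(scale = rep_len(1, length(t)), dscale = rep_len(0, length(t))),
    H = list(scale = 1 - p$compression * (1 - cos(w * tc)) / 2,
             dscale = -p$compression * w * sin(w * tc) / 2),
    S = list(scale = 1 + p$stretch * sin(w * tc),
             dscale = p$stretch * w * cos(w * tc)),
    P = {
      td <- p$decay_start_frac * cl
      up <- tc < td
      s_at_td <- 1 + p$plateau * (1 - exp(-td / p$tau_rise))
      scale <- ifelse(up,
                      1 + p$plateau * (1 - exp(-tc / p$tau_rise)),
                      1 + (s_at_td - 1) * exp(-(tc - td) / p$tau_decay))
      dscale <- ifelse(up,
                       p$plateau / p$tau_rise * exp(-tc / p$tau_rise),
                       -(s_at_td - 1) / p$tau_decay * exp(-(tc - td) / p$tau_decay))
      list(scale = scale, dscale = dscale)
    }
  )
}

#' Pacing protocol
#'
#' @param cycle_length pacing cycle length (ms)
#' @param n_beats number of paced beats before pacing stops
#' @param stim a [conductionParams()] carrying the stimulus description;
#'   its period and beat count are overridden by this protocol
#' @return object of class `pacingProtocol`
#' @export
pacingProtocol <- function(cycle_length = 1000, n_beats = 200,
                           stim = conductionParams()) {
  stopifnot(cycle_length > 0, n_beats >= 1)
  stim$stim_period <- cycle_length
  stim$stim_n_beats <- n_beats
  structure(list(cycle_length = cycle_length, n_beats = as.integer(n_beats),
                 stim = stim),
            class = "pacingProtocol")
}

#' Limit-cycle criterion: mean squared error between consecutive APs
#'
#' Two sampled AP traces (upstroke, plateau and repolarisation on a common
#' per-beat time grid) are compared by their mean squared error; the limit
#' cycle is declared reached when MSE < `tol` (mV^2). Traces of unequal
#' length are linearly resampled onto the shorter trace's relative grid.
#'
#' @param ap_prev,ap_last numeric vectors: consecutive per-beat AP traces (mV)
#' @param tol MSE threshold (mV^2)
#' @return list with `reached` (logical) and `mse`
#' @export
limitCycleReached <- function(ap_prev, ap_last, tol = 0.01) {
  if (length(ap_prev) == 0 || length(ap_last) == 0)
    stop("limitCycleReached: empty trace")
  if (length(ap_prev) != length(ap_last)) {
    n <- min(length(ap_prev), length(ap_last))
    grid <- seq(0, 1, length.out = n)
    ap_prev <- stats::approx(seq(0, 1, length.out = length(ap_prev)),
                             ap_prev, grid)$y
    ap_last <- stats::approx(seq(0, 1, length.out = length(ap_last)),
                             ap_last, grid)$y
  }
  mse <- mean((ap_prev - ap_last)^2)
  list(reached = mse < tol, mse = mse)
}

#' Extracellular-calcium sweep configuration
#'
#' @param cao_start,cao_stop,cao_step sweep range and step (mM)
#' @param observation_window quiescent observation time after pacing and
#'   stretching stop (ms), during which spontaneous events are scored
#' @return object of class `sweepConfig`
#' @export
sweepConfig <- function(cao_start = 2.0, cao_stop = 4.5, cao_step = 0.1,
                        observation_window = 5000) {
  stopifnot(cao_step > 0, cao_start <= cao_stop, observation_window > 0)
  structure(list(cao_start = cao_start, cao_stop = cao_stop,
                 cao_step = cao_step,
                 observation_window = observation_window),
            class = "sweepConfig")
}

#' Build the ordered experiment schedule of a calcium sweep
#'
#' One descriptor per extracellular-calcium step: pace (and stretch) to the
#' limit cycle for at most `pacing$n_beats` beats, then stop both and
#' observe quiescently for the observation window. Deterministic given the
#' configuration.
#'
#' @param sweep a [sweepConfig()]
#' @param pacing a [pacingProtocol()]
#' @param stretch a [stretchProtocol()]
#' @param seed seed recorded into each descriptor (provenance)
#' @return data.frame with one row per experiment
#' @export
runSweepSchedule <- function(sweep, pacing = pacingProtocol(),
                             stretch = stretchProtocol("I"), seed = 1L) {
  cao <- seq(sweep$cao_start, sweep$cao_stop, by = sweep$cao_step)
  data.frame(
    ca_o = cao,
    pattern = stretch$pattern,
    cycle_length = pacing$cycle_length,
    n_beats = pacing$n_beats,
    observation_window = sweep$observation_window,
    seed = seed
  )
}
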