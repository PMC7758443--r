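# Shared fixtures built in code.

# small homogeneous single-myocyte spec
smallSpec <- function(n_cru = 2, sl = 1.89) tissueSpec(fiberGeometry(n_cru, sl))

# heterogeneous 10-CRU spec used by the scaled replication runs
hetSpec <- function(seed = 11, n_cru = 10)
  tissueSpec(fiberGeometry(n_cru, generateRestingLengths(seed = seed, n = n_cru)))

# a mildly perturbed but physiological packed state (for RHS parity checks)
perturbedState <- function(spec, seed = 1, sd = 0.02) {
  y <- tissueInitialState(spec)
  set.seed(seed)
  y * exp(rnorm(length(y), 0, sd))
}

# synthetic trapezoid action potential: rest -85 mV, instant rise to
# +35 mV at t = 100 ms, linear fall over `fall` ms, then rest
trapezoidAP <- function(dt = 0.5, fall = 300, t_up = 100, t_end = 600) {
  tt <- seq(0, t_end, by = dt)
  vm <- rep(-85, length(tt))
  ramp <- tt >= t_up & tt < t_up + fall
  vm[ramp] <- 35 - 120 * (tt[ramp] - t_up) / fall
  list(time = tt, vm = vm)
}

# synthetic traces of a planar calcium wave translating at `speed` (um/s)
# over an n-CRU fiber with uniform spacing (um); Gaussian pulse in time.
syntheticWaveTraces <- function(speed = 100, n_cru = 10, spacing = 1.89,
                                dt = 0.5, t_end = 2000, t0 = 300,
                                amp = 5e-4, width = 40, dia = 1e-4,
                                noise_sd = 0, seed = 1) {
  tt <- seq(0, t_end, by = dt)
  pos <- (seq_len(n_cru) - 0.5) * spacing
  ca <- sapply(seq_len(n_cru), function(i) {
    t_arr <- t0 + pos[i] / (speed / 1000)  # speed um/s -> um/ms
    dia + amp * exp(-((tt - t_arr) / width)^2)
  })
  if (noise_sd > 0) {
    set.seed(seed)
    ca <- ca + matrix(rnorm(length(ca), 0, noise_sd * amp), nrow = length(tt))
  }
  list(time = tt, ca = ca, pos = pos)
}

# wrap synthetic traces into a minimal simulationResult for detectEvents
syntheticResult <- function(time, ca, vm = NULL, resting_sl = 1.89) {
  n <- ncol(ca)
  if (is.null(vm)) vm <- matrix(-85, nrow = length(time), ncol = n)
  structure(list(
    time = time, ca_cyto = ca, vm = vm,
    ca_sr = matrix(1, length(time), n), ca_ss = ca,
    sl = matrix(resting_sl, length(time), n),
    force = matrix(0, length(time), n), v_f = NULL,
    t_obs_start = time[1], beats_run = 0L, mse = numeric(0),
    meta = list(n_cells = 1L, n_crus = n,
                cell_of_cru = rep(1L, n),
                resting_sl = rep(resting_sl, n))),
    class = "simulationResult")
}

# per-speed fixture settings for velocity-recovery checks: fiber length and
# pulse width chosen so pulses overlap between neighbouring CRUs (one
# contiguous event) and the activation-time spread spans enough CRUs for a
# stable fit at every speed
velocityFixture <- function(speed, noise_sd = 0, seed = 1) {
  n <- if (speed >= 5000) 150 else if (speed >= 1000) 60 else 16
  w <- if (speed >= 5000) 15 else max(20, min(150, 18000 / speed))
  dt <- if (speed >= 1000) 0.25 else 0.5
  t_end <- 300 + n * 1.89 / (speed / 1000) + 6 * w
  syntheticWaveTraces(speed = speed, n_cru = n, spacing = 1.89, dt = dt,
                      t_end = t_end, width = w, noise_sd = noise_sd,
                      seed = seed)
}

# largest (most complete) detected event of a synthetic trace set
mainEvent <- function(tr) {
  ev <- detectEvents(syntheticResult(tr$time, tr$ca))
  ev[[which.max(vapply(ev, function(x) sum(is.finite(x$activation_times)),
                       1))]]
}
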