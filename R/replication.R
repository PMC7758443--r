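# Scaled replication experiments: the pace-stretch-observe protocol of the
# study, run over stretch patterns, extracellular-calcium grids, fibroblast
# counts and heterogeneity replicates, with event measurements collected
# into tidy tables.

#' Stimulus amplitude that reliably captures a fiber of a given size
#'
#' The stimulus charge equalises over the (nearly isopotential) fiber, so
#' capture requires an amplitude proportional to the number of CRUs; 40 mV
#' per CRU depolarises the fiber safely past the sodium threshold.
#'
#' @param n_cru_total total number of CRUs across all coupled myocytes
#' @return stimulus amplitude (mV)
#' @export
defaultStimAmplitude <- function(n_cru_total) 40 * n_cru_total

#' Run one pace-stretch-observe experiment
#'
#' Builds a (possibly heterogeneous) myocyte chain, paces it with the given
#' stretch pattern at the given extracellular calcium, stops pacing and
#' stretching, and observes quiescently; returns the simulation result.
#'
#' @param pattern stretch pattern (`"I"`, `"H"`, `"S"`, `"P"`)
#' @param ca_o extracellular calcium (mM)
#' @param n_cells number of gap-junction-coupled myocytes
#' @param n_cru CRUs per myocyte
#' @param seed base seed: heterogeneity draws use `seed + cell index`,
#'   fibroblast placement uses `seed + 100 + cell index`
#' @param n_fib fibroblasts per myocyte (0-3)
#' @param n_beats paced beats (at most; the limit-cycle criterion can stop
#'   pacing earlier when `early_exit`)
#' @param observation quiescent observation window (ms)
#' @param cycle_length pacing cycle length (ms)
#' @param g_gap inter-myocyte junction conductance (nS)
#' @param heterogeneous draw resting lengths from the heterogeneity
#'   interval (`FALSE` = uniform 1.89 um)
#' @param early_exit stop pacing at the limit cycle
#' @param ... further arguments to [runSimulation()]
#' @return a `simulationResult`
#' @export
runStretchExperiment <- function(pattern = "I", ca_o = 2.0, n_cells = 1,
                                 n_cru = 10, seed = 1, n_fib = 0,
                                 n_beats = 15, observation = 10000,
                                 cycle_length = 1000, g_gap = 400,
                                 heterogeneous = TRUE, early_exit = FALSE,
                                 ...) {
  geos <- lapply(seq_len(n_cells), function(j) {
    sl <- if (heterogeneous)
      generateRestingLengths(seed = seed + j, n = n_cru) else 1.89
    fiberGeometry(n_cru, sl)
  })
  fibs <- if (n_fib > 0)
    lapply(seq_len(n_cells), function(j)
      attachFibroblasts(n_fib, seed = seed + 100 + j, n_cru = n_cru))
  else NULL
  spec <- tissueSpec(geos, g_gap = g_gap, fibroblasts = fibs,
                     seeds = list(base = seed))
  pac <- pacingProtocol(cycle_length, n_beats,
                        conductionParams(
                          stim_amplitude = defaultStimAmplitude(n_cells * n_cru),
                          stim_period = cycle_length))
  runSimulation(spec, pac, stretch = stretchProtocol(pattern, cycle_length),
                ca_o = ca_o, observation = observation,
                early_exit = early_exit, ...)
}

# one summary row per experiment
.experimentRow <- function(res, thresholds = eventThresholds()) {
  ev <- detectEvents(res, thresholds)
  first <- if (length(ev)) ev[[1]] else NULL
  vels <- vapply(ev, function(e) ifelse(is.na(e$velocity), NA_real_,
                                        e$velocity), numeric(1))
  data.frame(
    pattern = res$meta$pattern,
    ca_o = res$meta$ca_o,
    n_events = length(ev),
    first_amplitude = if (!is.null(first)) first$amplitude else NA_real_,
    first_velocity = if (!is.null(first)) first$velocity else NA_real_,
    first_class = if (!is.null(first)) first$vm_class else NA_character_,
    max_vm_deflection = if (length(ev))
      max(vapply(ev, `[[`, 1, "vm_deflection")) else NA_real_,
    mean_velocity = if (any(!is.na(vels))) mean(vels, na.rm = TRUE) else NA_real_,
    max_amplitude = if (length(ev))
      max(vapply(ev, `[[`, 1, "amplitude")) else NA_real_,
    beats_run = res$beats_run
  )
}

#' Sweep extracellular calcium for one stretch pattern and find the wave
#' threshold
#'
#' Runs [runStretchExperiment()] at each calcium step and returns the
#' per-step event summary plus the first (lowest) calcium at which a
#' spontaneous event is detected.
#'
#' @param pattern stretch pattern
#' @param cao_grid extracellular-calcium grid (mM)
#' @param thresholds an [eventThresholds()] list
#' @param ... passed to [runStretchExperiment()]
#' @return list with `table` (data.frame, one row per calcium step) and
#'   `threshold` (mM; `NA` if no step produced an event)
#' @export
waveThreshold <- function(pattern, cao_grid = seq(2.0, 4.5, by = 0.5),
                          thresholds = eventThresholds(), ...) {
  rows <- lapply(cao_grid, function(cao) {
    res <- runStretchExperiment(pattern = pattern, ca_o = cao, ...)
    .experimentRow(res, thresholds)
  })
  tab <- do.call(rbind, rows)
  hit <- tab$ca_o[tab$n_events > 0]
  list(table = tab, threshold = if (length(hit)) min(hit) else NA_real_)
}

#' Scaled replication study over patterns, calcium and replicates
#'
#' The study design of the full experiment at configurable scale: for each
#' heterogeneity replicate and stretch pattern, a calcium sweep is run and
#' the event measurements are collected. The default sizes are desk-scale;
#' the full-scale study (50 CRUs, 200 beats, 26 calcium steps, 10
#' replicates) uses the same code path.
#'
#' @param patterns stretch patterns to run
#' @param cao_grid extracellular-calcium grid (mM)
#' @param n_replicates heterogeneity replicates (seeds `seed_base + 1..n`)
#' @param seed_base base RNG seed
#' @param ... passed to [runStretchExperiment()]
#' @return data.frame with one row per (replicate, pattern, calcium step)
#' @export
replicationStudy <- function(patterns = c("I", "H", "S", "P"),
                             cao_grid = c(2.0, 3.7, 4.2),
                             n_replicates = 1, seed_base = 0, ...) {
  out <- list()
  for (r in seq_len(n_replicates)) {
    for (pat in patterns) {
      sw <- waveThreshold(pat, cao_grid, seed = seed_base + r, ...)
      tab <- sw$table
      tab$replicate <- r
      tab$threshold_ca_o <- sw$threshold
      out[[length(out) + 1]] <- tab
    }
  }
  do.call(rbind, out)
}

#' Measure APD90 under fibroblast loading
#'
#' Runs paced (no-stretch) experiments with increasing numbers of attached
#' fibroblasts and returns the steady-state APD90 of a mid-fiber CRU.
#'
#' @param n_fib_values fibroblast counts to run
#' @param ca_o extracellular calcium (mM)
#' @param ... passed to [runStretchExperiment()]
#' @return data.frame with columns `n_fib`, `apd90`
#' @export
fibroblastAPDStudy <- function(n_fib_values = c(0, 1, 3), ca_o = 2.0, ...) {
  rows <- lapply(n_fib_values, function(nf) {
    res <- runStretchExperiment(pattern = "I", ca_o = ca_o, n_fib = nf,
                                observation = 0, ...)
    mid <- ceiling(sum(res$meta$n_crus) / 2)
    apd <- apd90(res$vm[, mid], res$time)
    data.frame(n_fib = nf, apd90 = if (length(apd)) tail(apd, 1) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Dyssynchrony of coupled versus isolated myocytes
#'
#' Runs one gap-junction-coupled chain and, with the same heterogeneity
#' seeds, the corresponding isolated (individually paced) myocytes, and
#' measures the inter-cellular dyssynchrony of the time-to-peak calcium in
#' the observation window, plus the largest membrane-potential deflection
#' of the detected spontaneous events.
#'
#' @param n_cells chain length
#' @param ca_o extracellular calcium (mM)
#' @param seed base seed (same heterogeneity draws in both arms)
#' @param ... passed to [runStretchExperiment()]
#' @return list with `coupled` and `isolated`, each carrying
#'   `dyssynchrony` (ms) and `max_vm_deflection` (mV)
#' @export
couplingStudy <- function(n_cells = 3, ca_o = 4.0, seed = 10, ...) {
  coupled <- runStretchExperiment(pattern = "I", ca_o = ca_o,
                                  n_cells = n_cells, seed = seed, ...)
  ev_c <- detectEvents(coupled)
  iso_ttp <- numeric(0); iso_defl <- numeric(0)
  for (j in seq_len(n_cells)) {
    ri <- runStretchExperiment(pattern = "I", ca_o = ca_o, n_cells = 1,
                               seed = seed + j - 1, ...)
    # seed offset: cell j of the chain drew with seed + j, so isolated run
    # with base seed + j - 1 gives its single cell the same lengths
    iso_ttp <- c(iso_ttp, firstEventTimeToPeak(ri))
    ei <- detectEvents(ri)
    if (length(ei))
      iso_defl <- c(iso_defl, max(vapply(ei, `[[`, 1, "vm_deflection")))
  }
  ttp_c <- firstEventTimeToPeak(coupled)
  list(
    coupled = list(
      dyssynchrony = dyssynchrony(ttp_c[is.finite(ttp_c)]),
      max_vm_deflection = if (length(ev_c))
        max(vapply(ev_c, `[[`, 1, "vm_deflection")) else NA_real_),
    isolated = list(
      dyssynchrony = dyssynchrony(iso_ttp[is.finite(iso_ttp)]),
      max_vm_deflection = if (length(iso_defl)) max(iso_defl) else NA_real_)
  )
}
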