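# Measurement machinery: APD90, spontaneous-event detection and
# classification, wave velocity and amplitude, inter-cellular dyssynchrony,
# and group statistics.

#' Action potential duration at 90% repolarisation
#'
#' Detects action potentials by a dV/dt upstroke threshold and measures,
#' for each, the time from the maximum-upstroke instant until the membrane
#' potential has recovered 90% of the way from the AP peak back to the
#' pre-upstroke diastolic potential (baseline-relative, so constant offsets
#' do not change the result). Crossing times are linearly interpolated
#' between samples.
#'
#' @param vm membrane-potential trace (mV)
#' @param time sampling times (ms)
#' @param dvdt_threshold upstroke detection threshold (mV/ms)
#' @return numeric vector of APD90 values (ms), one per detected AP that
#'   completes repolarisation inside the trace; empty if no AP is found
#' @export
apd90 <- function(vm, time, dvdt_threshold = 5) {
  stopifnot(length(vm) == length(time), length(vm) >= 2)
  dv <- diff(vm) / diff(time)
  above <- dv > dvdt_threshold
  if (!any(above)) return(numeric(0))
  starts <- which(diff(c(FALSE, above)) == 1)
  ends <- which(diff(c(above, FALSE)) == -1)
  out <- numeric(0)
  for (k in seq_along(starts)) {
    # dv[j] is the rise between samples j and j+1; the maximum-upstroke
    # time is taken at the top of the steepest inter-sample rise
    i_up <- starts[k] + which.max(dv[starts[k]:ends[k]])
    diastolic <- vm[max(1, starts[k] - 1)]
    # AP peak: maximum before the next upstroke (or trace end)
    stop_i <- if (k < length(starts)) starts[k + 1] else length(vm)
    seg <- i_up:stop_i
    peak <- max(vm[seg])
    target <- peak - 0.9 * (peak - diastolic)
    i_pk <- seg[which.max(vm[seg])]
    below <- which(vm[i_pk:stop_i] <= target)
    if (!length(below)) next  # repolarisation not completed in trace
    i2 <- i_pk + below[1] - 1
    if (i2 == i_pk) {
      t_cross <- time[i2]
    } else {
      i1 <- i2 - 1
      frac <- (vm[i1] - target) / (vm[i1] - vm[i2])
      t_cross <- time[i1] + frac * (time[i2] - time[i1])
    }
    out <- c(out, t_cross - time[i_up])
  }
  out
}

#' Event-detection thresholds
#'
#' @param ca_threshold calcium excursion above per-CRU diastolic level that
#'   marks a spontaneous event (mM; default 0.05 uM)
#' @param activation_fraction per-CRU activation is the crossing of this
#'   fraction of the CRU's own event amplitude
#' @param vm_deflection minimum membrane-potential deflection to call a DAD
#'   (mV)
#' @param vm_supra deflection above which a DAD is called suprathreshold
#'   even without a regenerative upstroke (mV)
#' @param dvdt_regen regenerative-upstroke criterion (mV/ms): beyond it the
#'   event is a triggered beat (full AP)
#' @param fast_wave_cutoff velocity separating slow from fast waves (um/s)
#' @return list of thresholds
#' @export
eventThresholds <- function(ca_threshold = 5e-5, activation_fraction = 0.5,
                            vm_deflection = 2, vm_supra = 15,
                            dvdt_regen = 20, fast_wave_cutoff = 1000) {
  if (ca_threshold <= 0 || activation_fraction <= 0 ||
      activation_fraction >= 1 || vm_deflection <= 0 || dvdt_regen <= 0)
    stop("eventThresholds: thresholds must be positive (and 0 < activation_fraction < 1)")
  list(ca_threshold = ca_threshold,
       activation_fraction = activation_fraction,
       vm_deflection = vm_deflection, vm_supra = vm_supra,
       dvdt_regen = dvdt_regen, fast_wave_cutoff = fast_wave_cutoff)
}

# detect events on one cell's observation-window traces
.detectEventsCell <- function(time, ca, vm, geometry, thr, cell = 1L) {
  n_cru <- ncol(ca)
  diastolic <- ca[1, ]
  above <- sweep(ca, 2, diastolic + thr$ca_threshold, `>`)
  any_above <- rowSums(above) > 0
  if (!any(any_above)) return(list())
  # contiguous stretches of "some CRU above threshold" = events
  runs <- rle(any_above)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1
  ev_rows <- which(runs$values)
  events <- list()
  for (r in ev_rows) {
    i0 <- idx_start[r]; i1 <- idx_end[r]
    if (i1 - i0 < 2) next
    seg <- i0:i1
    amp_cru <- apply(ca[seg, , drop = FALSE], 2, max) - diastolic  # mM
    act <- rep(NA_real_, n_cru)
    for (c in seq_len(n_cru)) {
      if (amp_cru[c] < thr$ca_threshold) next
      lvl <- diastolic[c] + thr$activation_fraction * amp_cru[c]
      cross <- which(ca[seg, c] >= lvl)
      if (!length(cross)) next
      i2 <- seg[cross[1]]
      if (i2 > seg[1] && ca[i2 - 1, c] < lvl) {
        frac <- (lvl - ca[i2 - 1, c]) / (ca[i2, c] - ca[i2 - 1, c])
        act[c] <- time[i2 - 1] + frac * (time[i2] - time[i2 - 1])
      } else act[c] <- time[i2]
    }
    # membrane-potential class over the event window
    vm_cell <- rowMeans(vm[seg, , drop = FALSE])
    vm_base <- vm_cell[1]
    defl <- max(vm_cell) - vm_base
    dvdt <- if (length(seg) > 1)
      max(diff(vm_cell) / diff(time[seg])) else 0
    vm_class <- if (defl < thr$vm_deflection) "none"
      else if (dvdt >= thr$dvdt_regen && max(vm_cell) > 0) "triggered_beat"
      else if (defl >= thr$vm_supra) "suprathreshold_dad"
      else "subthreshold_dad"
    ev <- list(cell = cell,
               onset = min(act, na.rm = TRUE),
               t_start = time[i0], t_end = time[i1],
               activation_times = act,
               amplitude = max(amp_cru) * 1000,  # uM
               vm_class = vm_class,
               vm_deflection = defl)
    vel <- waveVelocity(ev, geometry)
    ev$velocity <- vel$velocity
    ev$propagating <- vel$propagating
    ev$synchronous <- vel$synchronous
    ev$wave_class <- if (!vel$propagating) {
      if (vel$synchronous) "synchronous" else NA_character_
    } else if (vel$velocity >= thr$fast_wave_cutoff) "fast_wave" else "slow_wave"
    events[[length(events) + 1]] <- structure(ev, class = "waveEvent")
  }
  events
}

#' Detect spontaneous calcium-release events in the observation window
#'
#' A spontaneous event is a cytosolic-calcium excursion exceeding the
#' per-CRU diastolic level by `thresholds$ca_threshold` in at least one CRU
#' after pacing stops. Within each event, per-CRU activation times are the
#' crossings of `activation_fraction` of that CRU's own event amplitude;
#' wave velocity is fitted from the activation map; the event class is read
#' from the simultaneous membrane-potential trace (no deflection, a
#' subthreshold or suprathreshold DAD, or a triggered beat) and waves are
#' co-classified fast/slow by the velocity cutoff. Events are returned in
#' order of occurrence per cell, so the first spontaneous event of a cell
#' can be distinguished from the following ones.
#'
#' @param result a `simulationResult` with an observation window
#' @param thresholds an [eventThresholds()] list
#' @return list of `waveEvent` objects
#' @export
detectEvents <- function(result, thresholds = eventThresholds()) {
  stopifnot(inherits(result, "simulationResult"))
  if (is.na(result$t_obs_start))
    stop("detectEvents: result has no observation window")
  thr <- thresholds
  sel <- result$time >= result$t_obs_start
  time <- result$time[sel]
  cells <- unique(result$meta$cell_of_cru)
  out <- list()
  for (j in cells) {
    cols <- which(result$meta$cell_of_cru == j)
    geom <- fiberGeometry(length(cols),
                          resting_sl = result$meta$resting_sl[cols])
    evs <- .detectEventsCell(time,
                             result$ca_cyto[sel, cols, drop = FALSE],
                             result$vm[sel, cols, drop = FALSE],
                             geom, thr, cell = j)
    if (length(evs)) {
      for (k in seq_along(evs)) evs[[k]]$event_index <- k
      out <- c(out, evs)
    }
  }
  out
}

#' @export
print.waveEvent <- function(x, ...) {
  cat(sprintf("<waveEvent: cell %d, onset %.1f ms, amp %.3f uM, %s%s>\n",
              x$cell, x$onset, x$amplitude,
              x$vm_class,
              if (!is.na(x$wave_class))
                paste0(", ", x$wave_class,
                       if (x$propagating)
                         sprintf(" (%.0f um/s)", x$velocity) else "")
              else ""))
  invisible(x)
}

#' Calcium wave velocity from an activation map
#'
#' Least-squares fit of CRU centre position against activation time; the
#' absolute slope is the propagation speed. Events activating fewer than 3
#' CRUs are non-propagating; events with zero time spread are flagged
#' synchronous (no finite velocity).
#'
#' @param event a `waveEvent` (or any list with `activation_times`)
#' @param geometry the [fiberGeometry()] of the cell
#' @return list with `velocity` (um/s, `NA` if not propagating),
#'   `propagating`, `synchronous`
#' @export
waveVelocity <- function(event, geometry) {
  act <- event$activation_times
  ok <- is.finite(act)
  if (sum(ok) < 3)
    return(list(velocity = NA_real_, propagating = FALSE,
                synchronous = FALSE))
  pos <- cruPositions(geometry)[ok]
  tt <- act[ok]
  if (diff(range(tt)) < 1e-9)
    return(list(velocity = NA_real_, propagating = FALSE,
                synchronous = TRUE))
  slope <- stats::coef(stats::lm(pos ~ tt))[2]  # um/ms
  if (!is.finite(slope))
    return(list(velocity = NA_real_, propagating = FALSE,
                synchronous = TRUE))
  list(velocity = abs(unname(slope)) * 1000, propagating = TRUE,
       synchronous = FALSE)
}

#' Maximal calcium wave amplitude of an event
#'
#' Maximum over CRUs of (peak cytosolic calcium during the event minus that
#' CRU's pre-event diastolic level), in uM. Baseline-relative, so constant
#' offsets cancel.
#'
#' @param event a `waveEvent`
#' @param result the `simulationResult` it was detected in (optional: the
#'   amplitude recorded at detection time is returned if omitted)
#' @return amplitude (uM)
#' @export
waveAmplitude <- function(event, result = NULL) {
  if (is.null(result)) return(event$amplitude)
  sel <- result$time >= event$t_start & result$time <= event$t_end
  base_sel <- which(result$time >= result$t_obs_start)[1]
  cols <- which(result$meta$cell_of_cru == event$cell)
  ca <- result$ca_cyto[sel, cols, drop = FALSE]
  dia <- result$ca_cyto[base_sel, cols]
  max(apply(ca, 2, max) - dia) * 1000
}

#' Inter-cellular dyssynchrony of intra-cellular calcium dynamics
#'
#' Per cell, the mean over CRUs of the time-to-peak of cytosolic calcium
#' (relative to `onset`); returned is the sample (n-1) standard deviation
#' of these per-cell means across cells. A numeric vector input is taken
#' directly as per-cell mean times-to-peak (ms).
#'
#' @param x either a list of per-cell calcium trace matrices
#'   (time x CRU), or a numeric vector of per-cell mean times-to-peak (ms)
#' @param time sampling times (ms), required for trace input
#' @param onset reference time (ms) subtracted from the peak times
#' @return dyssynchrony (ms)
#' @export
dyssynchrony <- function(x, time = NULL, onset = 0) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) < 2) stop("dyssynchrony: need at least 2 cells")
    return(stats::sd(x))
  }
  if (!is.list(x) || length(x) < 2)
    stop("dyssynchrony: need at least 2 cells")
  stopifnot(!is.null(time))
  ttp <- vapply(x, function(ca) {
    mean(time[apply(ca, 2, which.max)] - onset)
  }, numeric(1))
  stats::sd(ttp)
}

#' Per-cell mean time-to-peak of the first spontaneous event
#'
#' For each cell, the mean over CRUs of the time at which cytosolic calcium
#' peaks within that cell's *first* detected spontaneous event, relative to
#' the start of the observation window. Anchoring on the first event keeps
#' the measure comparable between runs with different numbers of repetitive
#' events. Cells without any event return `NA`.
#'
#' @param result a `simulationResult` with an observation window
#' @param thresholds an [eventThresholds()] list
#' @return numeric vector, one value (ms) per cell
#' @export
firstEventTimeToPeak <- function(result, thresholds = eventThresholds()) {
  ev <- detectEvents(result, thresholds)
  sel <- result$time >= result$t_obs_start
  time <- result$time[sel]
  cells <- unique(result$meta$cell_of_cru)
  vapply(cells, function(j) {
    mine <- Filter(function(e) e$cell == j && e$event_index == 1, ev)
    if (!length(mine)) return(NA_real_)
    e <- mine[[1]]
    cols <- which(result$meta$cell_of_cru == j)
    win <- sel & result$time >= e$t_start & result$time <= e$t_end
    ca <- result$ca_cyto[win, cols, drop = FALSE]
    tw <- result$time[win]
    mean(tw[apply(ca, 2, which.max)]) - result$t_obs_start
  }, numeric(1))
}

#' Per-cell mean time-to-peak calcium in the observation window
#'
#' @param result a `simulationResult` with an observation window
#' @return numeric vector, one mean time-to-peak (ms, relative to the start
#'   of the observation window) per cell
#' @export
meanTimeToPeak <- function(result) {
  sel <- result$time >= result$t_obs_start
  time <- result$time[sel]
  vapply(unique(result$meta$cell_of_cru), function(j) {
    ca <- result$ca_cyto[sel, result$meta$cell_of_cru == j, drop = FALSE]
    mean(time[apply(ca, 2, which.max)] - result$t_obs_start)
  }, numeric(1))
}

#' Group statistics: three-sigma outlier removal, one-way ANOVA, pairwise
#' Bonferroni comparisons
#'
#' Values farther than three (group) standard deviations from their group
#' mean are removed first; a one-way analysis of variance is then run
#' across groups, followed by all-pairs comparisons of group means with
#' Bonferroni adjustment (pooled SD). Significance tiers are reported at
#' p < 0.01, < 0.05 and < 0.1.
#'
#' @param groups named list of numeric vectors
#' @return object of class `statsReport`: `labels`, `mean`, `sd`, `n`,
#'   `anova_p`, `pairwise` (data.frame with raw and adjusted p and tier),
#'   `outliers` (list of removed indices per group)
#' @export
groupStats <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("groupStats: need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  outliers <- lapply(groups, function(x) {
    if (length(x) < 2) return(integer(0))
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(integer(0))
    which(abs(x - m) > 3 * s)
  })
  kept <- Map(function(x, o) if (length(o)) x[-o] else x, groups, outliers)
  if (any(vapply(kept, length, 1L) < 2))
    stop("groupStats: a group has fewer than 2 values after outlier removal")
  values <- unlist(kept, use.names = FALSE)
  labels <- factor(rep(names(kept), vapply(kept, length, 1L)),
                   levels = names(kept))
  anova_p <- stats::anova(stats::aov(values ~ labels))[["Pr(>F)"]][1]
  pw_raw <- stats::pairwise.t.test(values, labels, p.adjust.method = "none",
                                   pool.sd = TRUE)$p.value
  pw_adj <- stats::pairwise.t.test(values, labels,
                                   p.adjust.method = "bonferroni",
                                   pool.sd = TRUE)$p.value
  pairs <- which(!is.na(pw_raw), arr.ind = TRUE)
  tier <- function(p) ifelse(p < 0.01, "p<0.01",
                      ifelse(p < 0.05, "p<0.05",
                      ifelse(p < 0.1, "p<0.1", "ns")))
  pairwise <- data.frame(
    group1 = rownames(pw_raw)[pairs[, 1]],
    group2 = colnames(pw_raw)[pairs[, 2]],
    p_raw = pw_raw[pairs],
    p_adj = pw_adj[pairs],
    tier = tier(pw_adj[pairs]))
  structure(list(labels = names(kept),
                 mean = vapply(kept, mean, numeric(1)),
                 sd = vapply(kept, stats::sd, numeric(1)),
                 n = vapply(kept, length, 1L),
                 anova_p = anova_p,
                 pairwise = pairwise,
                 outliers = outliers),
            class = "statsReport")
}

#' @export
print.statsReport <- function(x, ...) {
  cat("<statsReport>\n")
  for (i in seq_along(x$labels))
    cat(sprintf("  %s: %.4g +/- %.4g (n = %d)\n", x$labels[i], x$mean[i],
                x$sd[i], x$n[i]))
  cat(sprintf("  one-way ANOVA p = %.4g\n", x$anova_p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
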