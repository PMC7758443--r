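# Global ODE integration, result capture and provenance.

.RESULT_VERSION <- 1L

#' Stiff-solver configuration
#'
#' One stiff adaptive solver (lsoda, switching to BDF on stiffness) is used
#' for all simulations, with a banded internally generated Jacobian whose
#' bandwidth comes from the tissue state layout. Absolute tolerances are
#' scaled per state field (calcium concentrations live around 1e-4 mM and
#' need far tighter absolute tolerances than the membrane potential).
#'
#' @param rtol relative tolerance
#' @param atol_scale multiplier on the per-field absolute tolerance profile
#' @param max_step maximum step (ms)
#' @param sample_interval dense-output sampling interval during pacing (ms)
#' @param obs_sample_interval sampling interval during the quiescent
#'   observation window (ms); wave timing needs the finer grid
#' @param use_compiled use the compiled RHS (fast path); the pure-R
#'   reference RHS is used when `FALSE`
#' @return object of class `solverConfig`
#' @export
solverConfig <- function(rtol = 1e-6, atol_scale = 1, max_step = 1,
                         sample_interval = 1, obs_sample_interval = 0.5,
                         use_compiled = TRUE) {
  stopifnot(rtol > 0, atol_scale > 0, sample_interval > 0,
            obs_sample_interval > 0)
  structure(list(rtol = rtol, atol_scale = atol_scale, max_step = max_step,
                 sample_interval = sample_interval,
                 obs_sample_interval = obs_sample_interval,
                 use_compiled = use_compiled),
            class = "solverConfig")
}

# absolute tolerance profile per CRU state field (units of each state)
.ATOL_CRU <- c(vm = 1e-4, m = 1e-7, h = 1e-7, j = 1e-7, d = 1e-9, f = 1e-7,
               xto = 1e-8, yto = 1e-7, xks = 1e-8, xkr = 1e-8,
               ryr_o = 1e-8, ryr_r = 1e-7,
               ca_ss = 1e-9, ca_sr = 1e-7, ca_cyto = 1e-9,
               na_i = 1e-5, k_i = 1e-4, sl = 1e-6, tnc = 1e-7, xb = 1e-7)
.ATOL_FIB <- c(v_f = 1e-4, r_f = 1e-7, s_f = 1e-7, na_f = 1e-5, k_f = 1e-4)

.atolVector <- function(lay, scale = 1) {
  atol <- numeric(lay$n_states)
  IDX <- outer(lay$cru_off, seq_len(.N_CRU_STATES), `+`)
  for (i in seq_len(.N_CRU_STATES)) atol[IDX[, i]] <- .ATOL_CRU[i]
  if (nrow(lay$fib)) {
    FIDX <- outer(lay$fib$off, seq_len(.N_FIB_STATES), `+`)
    for (i in seq_len(.N_FIB_STATES)) atol[FIDX[, i]] <- .ATOL_FIB[i]
  }
  atol * scale
}

# locate the field name and CRU of a flat state index (for diagnostics)
.describeStateIndex <- function(lay, i) {
  k <- findInterval(i - 1, lay$cru_off)
  if (k >= 1 && k <= lay$n_cru_total) {
    rel <- i - lay$cru_off[k]
    if (rel <= .N_CRU_STATES)
      return(sprintf("%s of CRU %d", .CRU_FIELDS[rel], k))
  }
  if (nrow(lay$fib)) {
    for (q in seq_len(nrow(lay$fib))) {
      rel <- i - lay$fib$off[q]
      if (rel >= 1 && rel <= .N_FIB_STATES)
        return(sprintf("%s of fibroblast %d", .FIB_FIELDS[rel], q))
    }
  }
  sprintf("state %d", i)
}

# one ode() call with NaN/failure diagnostics
.integrate <- function(rhs, y, times, lay, solver, parms = NULL) {
  atol <- .atolVector(lay, solver$atol_scale)
  bw <- min(lay$bandwidth, lay$n_states - 1L)
  out <- deSolve::lsoda(y = y, times = times, func = rhs, parms = parms,
                        rtol = solver$rtol, atol = atol,
                        hmax = solver$max_step,
                        jactype = "bandint", bandup = bw, banddown = bw,
                        maxsteps = 50000)
  istate <- attr(out, "istate")[1]
  last <- out[nrow(out), -1]
  if (any(!is.finite(last))) {
    bad <- which(!is.finite(last))[1]
    ok <- which(apply(is.finite(out[, -1, drop = FALSE]), 1, all))
    t_last <- if (length(ok)) out[max(ok), 1] else NA_real_
    stop(sprintf(
      "simulation aborted: non-finite %s at t = %.3f ms (last valid t = %.3f ms)",
      .describeStateIndex(lay, bad), out[nrow(out), 1], t_last))
  }
  if (!is.null(istate) && istate < 0)
    stop(sprintf("stiff solver failed (istate = %d) at t = %.3f ms",
                 istate, out[nrow(out), 1]))
  out
}

# gather a field trace matrix [time x cru] from an ode output matrix
.fieldTrace <- function(out, lay, field) {
  pos <- match(field, .CRU_FIELDS)
  out[, 1 + lay$cru_off + pos, drop = FALSE]
}

.fibTrace <- function(out, lay) {
  if (!nrow(lay$fib)) return(NULL)
  out[, 1 + lay$fib$off + 1, drop = FALSE]
}

#' Run a tissue simulation: pacing (with stretch) then quiescent observation
#'
#' Integrates the assembled tissue right-hand side through the pacing phase
#' (at most `pacing$n_beats` beats; optionally exiting early once the
#' limit-cycle criterion of [limitCycleReached()] is met) and then through a
#' quiescent observation window with both pacing and stretching stopped.
#' Traces are sampled on fixed grids; the stored window covers the last
#' `keep_beats` paced beats plus the whole observation window.
#'
#' @param spec a [tissueSpec()]
#' @param pacing a [pacingProtocol()]
#' @param stretch a [stretchProtocol()] (pattern `"I"` means no stretch)
#' @param ca_o extracellular calcium (mM)
#' @param observation quiescent observation window after pacing stops (ms)
#' @param solver a [solverConfig()]
#' @param ionic an [ionicParams()]; by default the remodeled parameter set
#'   at `ca_o`
#' @param mech a [sarcomereParams()]
#' @param diffusion a [diffusionParams()]
#' @param sl_mode,sl_kappa sarcomere coupling mode
#' @param early_exit stop pacing once the limit cycle is reached
#' @param keep_beats number of trailing paced beats to keep in the stored
#'   traces
#' @return object of class `simulationResult`: sampled traces (`time`,
#'   matrices `vm`, `ca_cyto`, `ca_sr`, `ca_ss`, `sl`, `force`, optional
#'   `v_f`), `t_obs_start`, `beats_run`, per-beat limit-cycle `mse`, and
#'   `meta` (full configuration and provenance)
#' @export
runSimulation <- function(spec, pacing = pacingProtocol(),
                          stretch = stretchProtocol("I"), ca_o = 2.0,
                          observation = 0, solver = solverConfig(),
                          ionic = NULL, mech = sarcomereParams(),
                          diffusion = diffusionParams(),
                          sl_mode = "relaxed", sl_kappa = 0.5,
                          early_exit = TRUE, keep_beats = 2) {
  stopifnot(inherits(spec, "tissueSpec"))
  if (is.null(ionic)) ionic <- applyRemodeling(ionicParams(ca_o = ca_o))
  else ionic$ca_o <- ca_o
  lay <- tissueLayout(spec)
  cl <- pacing$cycle_length
  conduction <- pacing$stim
  t_pace_end <- pacing$n_beats * cl
  stretch_arg <- if (stretch$pattern == "I") NULL else stretch

  mkrhs <- function(stim_n, stretch_stop) {
    cond <- conduction; cond$stim_n_beats <- stim_n
    if (solver$use_compiled)
      compiledTissueRHS(spec, diffusion, cond, ionic, mech,
                        stretch = stretch_arg, stretch_stop = stretch_stop,
                        sl_mode = sl_mode, sl_kappa = sl_kappa)
    else
      assembleTissueRHS(spec, diffusion, cond, ionic, mech,
                        stretch = stretch_arg, stretch_stop = stretch_stop,
                        sl_mode = sl_mode, sl_kappa = sl_kappa)
  }
  # deSolve wants list-returning functions
  aslist <- function(f) function(t, y, parms) list(f(t, y))

  y <- tissueInitialState(spec)
  rhs <- aslist(mkrhs(pacing$n_beats, Inf))
  mse <- rep(NA_real_, pacing$n_beats)
  kept <- list()
  prev_vm1 <- NULL
  beats_run <- 0L
  for (b in seq_len(pacing$n_beats)) {
    times <- seq((b - 1) * cl, b * cl, by = solver$sample_interval)
    out <- .integrate(rhs, y, times, lay, solver)
    y <- out[nrow(out), -1]
    vm1 <- out[, 1 + lay$cru_off[1] + 1]
    if (!is.null(prev_vm1))
      mse[b] <- limitCycleReached(prev_vm1, vm1)$mse
    prev_vm1 <- vm1
    kept[[1 + (b - 1) %% max(1, keep_beats)]] <- out
    beats_run <- b
    if (early_exit && b >= 2 && mse[b] < 0.01) break
  }
  t_pace_end <- beats_run * cl
  # order kept beats chronologically
  kept <- kept[order(vapply(kept, function(o) o[1, 1], numeric(1)))]
  pace_out <- do.call(rbind, lapply(seq_along(kept), function(i) {
    o <- kept[[i]]
    if (i < length(kept)) o[-nrow(o), , drop = FALSE] else o
  }))

  obs_out <- NULL
  if (observation > 0) {
    rhs_obs <- aslist(mkrhs(beats_run, t_pace_end))
    times <- seq(t_pace_end, t_pace_end + observation,
                 by = solver$obs_sample_interval)
    obs_out <- .integrate(rhs_obs, y, times, lay, solver)
    y <- obs_out[nrow(obs_out), -1]
    obs_out <- obs_out[-1, , drop = FALSE]  # avoid duplicated boundary row
  }
  all_out <- rbind(pace_out, obs_out)

  sl <- .fieldTrace(all_out, lay, "sl")
  xb <- .fieldTrace(all_out, lay, "xb")
  res <- list(
    time = all_out[, 1],
    vm = .fieldTrace(all_out, lay, "vm"),
    ca_cyto = .fieldTrace(all_out, lay, "ca_cyto"),
    ca_sr = .fieldTrace(all_out, lay, "ca_sr"),
    ca_ss = .fieldTrace(all_out, lay, "ca_ss"),
    sl = sl,
    force = mech$f_max * xb * .overlap(sl),
    v_f = .fibTrace(all_out, lay),
    t_obs_start = if (observation > 0) t_pace_end else NA_real_,
    beats_run = beats_run,
    mse = mse[seq_len(beats_run)],
    final_state = y,
    meta = list(
      version = .RESULT_VERSION,
      package_version = as.character(utils::packageVersion("mecwave")),
      n_cells = spec$n_cells,
      n_crus = vapply(spec$geometries, `[[`, 1L, "n_cru"),
      resting_sl = lay$resting_sl,
      cell_of_cru = lay$cell_of_cru,
      g_gap = spec$g_gap,
      fibroblasts = lay$fib,
      pattern = stretch$pattern,
      cycle_length = cl,
      n_beats_max = pacing$n_beats,
      ca_o = ca_o,
      observation = observation,
      sl_mode = sl_mode, sl_kappa = sl_kappa,
      eq6_verbatim_signs = spec$eq6_verbatim_signs,
      seeds = spec$seeds,
      solver = unclass(solver),
      ionic = unclass(ionic),
      mech = unclass(mech)[setdiff(names(mech), "coupling")],
      strain_coupling = unclass(mech$coupling),
      stretch = unclass(stretch)
    )
  )
  class(res) <- "simulationResult"
  res
}

#' @export
print.simulationResult <- function(x, ...) {
  cat(sprintf("<simulationResult: %d cell%s, %d CRUs, pattern %s, Ca_o %.1f mM>\n",
              x$meta$n_cells, if (x$meta$n_cells == 1) "" else "s",
              sum(x$meta$n_crus), x$meta$pattern, x$meta$ca_o))
  cat(sprintf("  %d beats run (final AP MSE %.2e); stored t = [%.0f, %.0f] ms%s\n",
              x$beats_run, tail(x$mse, 1), min(x$time), max(x$time),
              if (!is.na(x$t_obs_start))
                sprintf("; observation from %.0f ms", x$t_obs_start) else ""))
  invisible(x)
}

#' Save a simulation result (with optional CSV summary)
#'
#' The result is serialised losslessly with a format-version field. If
#' `csv` is `TRUE` a per-sample summary table (`<path>.csv`) is written
#' alongside: one row per sampled time with mean/extreme traces.
#'
#' @param result a `simulationResult`
#' @param path output file path (conventionally `.rds`)
#' @param csv also export the CSV summary table
#' @return `path`, invisibly
#' @export
saveResult <- function(result, path, csv = FALSE) {
  stopifnot(inherits(result, "simulationResult"))
  saveRDS(list(format = "mecwave-result", version = .RESULT_VERSION,
               result = result), path)
  if (csv) {
    utils::write.csv(resultSummaryTable(result),
                     paste0(sub("\\.rds$", "", path), ".csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Per-sample summary table of a simulation result
#'
#' @param result a `simulationResult`
#' @return data.frame with one row per sampled time
#' @export
resultSummaryTable <- function(result) {
  data.frame(time = result$time,
             vm_mean = rowMeans(result$vm),
             vm_max = apply(result$vm, 1, max),
             ca_cyto_mean = rowMeans(result$ca_cyto),
             ca_cyto_max = apply(result$ca_cyto, 1, max),
             ca_sr_mean = rowMeans(result$ca_sr),
             sl_mean = rowMeans(result$sl),
             force_mean = rowMeans(result$force))
}

#' Load a saved simulation result
#'
#' @param path file written by [saveResult()]
#' @return the `simulationResult`
#' @export
loadResult <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("loadResult: cannot read '", path,
                                           "' (corrupt or truncated file): ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "mecwave-result"))
    stop("loadResult: '", path, "' is not a mecwave result file")
  if (!identical(as.integer(obj$version), .RESULT_VERSION))
    stop(sprintf("loadResult: format version mismatch (file %s, package %s)",
                 obj$version, .RESULT_VERSION))
  obj$result
}
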