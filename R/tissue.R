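# Multi-myocyte assembly: gap-junction electrical coupling, inter-myocyte
# mechanical boundary coupling, resting-length heterogeneity, and fibroblast
# attachment.

#' Linear gap-junction current between two boundary CRUs
#'
#' `I = g_gap * (v_up - v_down)` in pA (nS x mV). Applied with the
#' charge-conserving orientation: the higher-potential side loses
#' depolarising charge and the lower-potential side gains it. The
#' alternative orientation in which both boundary derivatives follow the
#' upstream sign is available through the `eq6_verbatim_signs` flag of
#' [tissueSpec()] for auditing; it is anti-conservative and blocks
#' conduction.
#'
#' @param v_up membrane potential of the last CRU of the upstream cell (mV)
#' @param v_down membrane potential of the first CRU of the downstream cell
#' @param g_gap junction conductance (nS)
#' @return junctional current (pA), positive when flowing downstream
#' @export
gapJunctionCurrent <- function(v_up, v_down, g_gap = 400) {
  g_gap * (v_up - v_down)
}

#' Heterogeneity configuration for sarcomere resting lengths
#'
#' Resting lengths are sampled uniformly from
#' `[mean_sl * (1 - fraction), mean_sl * (1 + fraction)]`,
#' i.e. `[1.701, 2.079]` um at the defaults.
#'
#' @param mean_sl mean resting sarcomere length (um)
#' @param fraction half-width of the uniform interval as a fraction of the
#'   mean
#' @param n_replicates number of heterogeneous myocyte variants in a study
#' @return object of class `heterogeneityConfig`
#' @export
heterogeneityConfig <- function(mean_sl = 1.89, fraction = 0.10,
                                n_replicates = 10) {
  stopifnot(mean_sl > 0, fraction >= 0, fraction < 1, n_replicates >= 1)
  structure(list(mean_sl = mean_sl, fraction = fraction,
                 n_replicates = as.integer(n_replicates)),
            class = "heterogeneityConfig")
}

# run fn with a local RNG stream seeded by `seed`, restoring global state
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Draw heterogeneous sarcomere resting lengths
#'
#' `n` i.i.d. uniform draws on the heterogeneity interval, reproducible per
#' seed (the global RNG state is left untouched).
#'
#' @param cfg a [heterogeneityConfig()]
#' @param seed RNG seed (required)
#' @param n number of sarcomeres
#' @return numeric vector of resting lengths (um)
#' @export
generateRestingLengths <- function(cfg = heterogeneityConfig(), seed, n = 50) {
  if (missing(seed)) stop("generateRestingLengths: a seed is required")
  lo <- cfg$mean_sl * (1 - cfg$fraction)
  hi <- cfg$mean_sl * (1 + cfg$fraction)
  .withSeed(seed, function() stats::runif(n, lo, hi))
}

#' Randomly attach fibroblasts to a myocyte
#'
#' Each fibroblast is assigned to one CRU among the terminal five CRUs of
#' one (or either) end of the myocyte, with gap-junction conductance drawn
#' uniformly from `g_range` (nS). Reproducible per seed.
#'
#' @param n_fib number of fibroblasts (0-3)
#' @param seed RNG seed (required)
#' @param n_cru number of CRUs in the myocyte
#' @param ends `"both"` (default) or `"distal"`: which ends are eligible
#' @param g_range conductance range (nS)
#' @return data.frame with columns `cru`, `g_f_gap` (0 rows if `n_fib = 0`)
#' @export
attachFibroblasts <- function(n_fib, seed, n_cru = 50,
                              ends = c("both", "distal"),
                              g_range = c(0.5, 8.0)) {
  if (length(n_fib) != 1 || !n_fib %in% 0:3)
    stop("attachFibroblasts: n_fib must be 0, 1, 2 or 3")
  if (missing(seed)) stop("attachFibroblasts: a seed is required")
  ends <- match.arg(ends)
  if (n_fib == 0)
    return(data.frame(cru = integer(0), g_f_gap = numeric(0)))
  k <- min(5L, n_cru %/% 2)
  eligible <- if (ends == "both")
    c(seq_len(k), seq(n_cru - k + 1L, n_cru)) else seq(n_cru - k + 1L, n_cru)
  .withSeed(seed, function()
    data.frame(cru = sample(eligible, n_fib, replace = TRUE),
               g_f_gap = stats::runif(n_fib, g_range[1], g_range[2])))
}

#' Tissue specification: a chain of myocytes with junctions and fibroblasts
#'
#' @param geometries list of [fiberGeometry()] objects, one per myocyte
#'   (typically 1, 3 or 6 cells)
#' @param g_gap inter-myocyte gap junction conductance (nS); scalar or one
#'   value per junction
#' @param fibroblasts list (one element per myocyte) of data.frames as
#'   returned by [attachFibroblasts()], or `NULL` for none
#' @param fibroblast_params a [fibroblastParams()] template; per-attachment
#'   `g_f_gap` overrides its conductance
#' @param eq6_verbatim_signs use the anti-conservative junction sign
#'   orientation (auditing only)
#' @param seeds named list of RNG seeds used to generate the spec (recorded
#'   for provenance)
#' @return object of class `tissueSpec`
#' @export
tissueSpec <- function(geometries, g_gap = 400, fibroblasts = NULL,
                       fibroblast_params = fibroblastParams(),
                       eq6_verbatim_signs = FALSE, seeds = list()) {
  if (inherits(geometries, "fiberGeometry")) geometries <- list(geometries)
  n_cells <- length(geometries)
  stopifnot(n_cells >= 1,
            all(vapply(geometries, inherits, TRUE, "fiberGeometry")))
  if (is.null(fibroblasts))
    fibroblasts <- replicate(n_cells, data.frame(cru = integer(0),
                                                 g_f_gap = numeric(0)),
                             simplify = FALSE)
  stopifnot(length(fibroblasts) == n_cells)
  for (i in seq_len(n_cells)) {
    fb <- fibroblasts[[i]]
    nc <- geometries[[i]]$n_cru
    k <- min(5L, nc %/% 2)
    ok <- fb$cru %in% c(seq_len(k), seq(nc - k + 1L, nc))
    if (!all(ok))
      stop("tissueSpec: fibroblast CRU indices must lie in the terminal ",
           k, " CRUs of an end (cell ", i, ")")
  }
  g_gap <- rep_len(g_gap, max(1, n_cells - 1))
  stopifnot(all(g_gap >= 0))
  structure(list(n_cells = n_cells, geometries = geometries, g_gap = g_gap,
                 fibroblasts = fibroblasts,
                 fibroblast_params = fibroblast_params,
                 eq6_verbatim_signs = eq6_verbatim_signs, seeds = seeds),
            class = "tissueSpec")
}

#' @export
print.tissueSpec <- function(x, ...) {
  cat(sprintf("<tissueSpec: %d myocyte%s (%s CRUs), %d fibroblast%s, g_gap %s nS>\n",
              x$n_cells, if (x$n_cells == 1) "" else "s",
              paste(vapply(x$geometries, `[[`, 1L, "n_cru"), collapse = "+"),
              sum(vapply(x$fibroblasts, nrow, 1L)),
              if (sum(vapply(x$fibroblasts, nrow, 1L)) == 1) "" else "s",
              paste(unique(x$g_gap), collapse = "/")))
  invisible(x)
}

#' State-vector layout of a tissue simulation
#'
#' The solver state is packed as consecutive 20-value CRU blocks in global
#' CRU order (cell 1 CRUs 1..n, cell 2, ...), with each fibroblast's 5-value
#' block inserted immediately after its host CRU's block. Keeping
#' fibroblasts next to their hosts bounds the Jacobian bandwidth, which the
#' stiff banded solver exploits.
#'
#' @param spec a [tissueSpec()]
#' @return list with `n_states`, `n_cru_total`, `cru_off` (0-based state
#'   offset of each global CRU block), `cell_of_cru`, `cell_cru_idx` (list
#'   of global CRU indices per cell), `resting_sl` (concatenated), `fib`
#'   (data.frame: `cell`, `cru` (global), `g_f_gap`, `off`), and
#'   `bandwidth` (max coupled index distance)
#' @export
tissueLayout <- function(spec) {
  n_crus <- vapply(spec$geometries, `[[`, 1L, "n_cru")
  n_cru_total <- sum(n_crus)
  cell_of_cru <- rep(seq_len(spec$n_cells), n_crus)
  cell_cru_idx <- split(seq_len(n_cru_total), cell_of_cru)
  # fibroblasts per global cru
  fib <- do.call(rbind, lapply(seq_len(spec$n_cells), function(j) {
    fb <- spec$fibroblasts[[j]]
    if (nrow(fb) == 0) return(NULL)
    data.frame(cell = j, cru = fb$cru + c(0, cumsum(n_crus))[j],
               g_f_gap = fb$g_f_gap)
  }))
  if (is.null(fib))
    fib <- data.frame(cell = integer(0), cru = integer(0),
                      g_f_gap = numeric(0))
  fib <- fib[order(fib$cru), , drop = FALSE]
  nfib_at <- tabulate(fib$cru, nbins = n_cru_total)
  block_len <- .N_CRU_STATES + .N_FIB_STATES * nfib_at
  cru_off <- c(0, cumsum(block_len))[seq_len(n_cru_total)]
  fib$off <- if (nrow(fib)) {
    within_host <- unlist(lapply(split(seq_len(nrow(fib)), fib$cru),
                                 function(i) seq_along(i) - 1L),
                          use.names = FALSE)
    cru_off[fib$cru] + .N_CRU_STATES + .N_FIB_STATES * within_host
  } else integer(0)
  n_states <- n_cru_total * .N_CRU_STATES + nrow(fib) * .N_FIB_STATES
  # max coupled index distance: neighbouring CRU blocks (incl. inserted
  # fibroblast blocks) and fibroblast<->host links
  bw <- 0L
  if (n_cru_total > 1)
    bw <- max(diff(cru_off)) + .N_CRU_STATES
  if (nrow(fib))
    bw <- max(bw, max(fib$off - cru_off[fib$cru]) + .N_FIB_STATES)
  list(n_states = n_states, n_cru_total = n_cru_total, cru_off = cru_off,
       cell_of_cru = cell_of_cru, cell_cru_idx = cell_cru_idx,
       resting_sl = unlist(lapply(spec$geometries, `[[`, "resting_sl"),
                           use.names = FALSE),
       fib = fib, bandwidth = as.integer(bw))
}

#' Assemble the global right-hand side of a multi-myocyte tissue
#'
#' Builds a callable `f(t, y)` over the packed tissue state (see
#' [tissueLayout()]): per-CRU ionic and myofilament dynamics (vectorised
#' over all cells), inter-CRU calcium diffusion and resistive
#' membrane-potential coupling within each myocyte, the stimulus on CRU 1
#' of cell 1 only, gap-junction currents between the boundary CRUs of
#' adjacent myocytes (scaled by the per-CRU capacitance), inter-myocyte
#' mechanical boundary coupling, and fibroblast junctional currents.
#'
#' This is the reference (pure R) implementation; the engine's compiled
#' fast path is checked against it.
#'
#' @param spec a [tissueSpec()]
#' @param diffusion a [diffusionParams()]
#' @param conduction a [conductionParams()]
#' @param ionic an [ionicParams()]
#' @param mech a [sarcomereParams()]
#' @param stretch a [stretchProtocol()] or `NULL` (no stretch)
#' @param stretch_stop time after which the length command returns to the
#'   resting length (ms)
#' @param sl_mode,sl_kappa sarcomere coupling mode, see [sarcomereCoupling()]
#' @param ca_coupling,vm_coupling logical switches for the two couplings
#' @return function `f(t, y)` returning `dy/dt`
#' @export
assembleTissueRHS <- function(spec, diffusion = diffusionParams(),
                              conduction = conductionParams(),
                              ionic = ionicParams(), mech = sarcomereParams(),
                              stretch = NULL, stretch_stop = Inf,
                              sl_mode = "verbatim", sl_kappa = 0.5,
                              ca_coupling = TRUE, vm_coupling = TRUE) {
  lay <- tissueLayout(spec)
  n <- lay$n_cru_total
  IDX <- outer(lay$cru_off, seq_len(.N_CRU_STATES), `+`)  # [cru, field]
  colnames(IDX) <- .CRU_FIELDS
  rest <- lay$resting_sl
  fib <- lay$fib
  FIDX <- if (nrow(fib))
    outer(fib$off, seq_len(.N_FIB_STATES), `+`) else NULL
  fp <- spec$fibroblast_params
  if (nrow(fib)) fp$g_f_gap <- fib$g_f_gap
  first_cru <- vapply(lay$cell_cru_idx, min, 1L)
  last_cru <- vapply(lay$cell_cru_idx, max, 1L)

  function(t, y) {
    if (length(y) != lay$n_states)
      stop(sprintf("tissue RHS: state length %d != expected %d",
                   length(y), lay$n_states))
    st <- lapply(seq_len(.N_CRU_STATES), function(i) y[IDX[, i]])
    names(st) <- .CRU_FIELDS
    ion <- st[names(ionicState(1))]
    class(ion) <- "ionicState"
    mec <- list(sl = st$sl, tnc = st$tnc, xb = st$xb)
    class(mec) <- "sarcomereState"

    scale <- if (!is.null(stretch) && t < stretch_stop)
      stretchScaling(stretch, t)$scale else 1
    sl_cmd <- rest * scale
    iso <- (sl_cmd - st$sl) / mech$tau_sl
    dsl <- numeric(n)
    for (j in seq_len(spec$n_cells)) {
      ii <- lay$cell_cru_idx[[j]]
      dsl[ii] <- sarcomereCoupling(iso[ii], mode = sl_mode, kappa = sl_kappa)
    }
    if (spec$n_cells > 1) {
      for (j in seq_len(spec$n_cells - 1)) {
        u <- last_cru[j]; d0 <- first_cru[j + 1]
        dsl[u] <- dsl[u] - iso[d0]
        dsl[d0] <- dsl[d0] - iso[u]
      }
    }
    strain_rate <- dsl / rest

    myo <- myofilamentRHS(mec, ca_cyto = st$ca_cyto,
                          strain_rate = strain_rate, params = mech,
                          sl_cmd = sl_cmd)
    cel <- ionicRHS(ion, ionic, tnc_flux = myo$tnc_flux)
    d <- cel$deriv
    d$sl <- dsl
    d$tnc <- myo$deriv$tnc
    d$xb <- myo$deriv$xb

    for (j in seq_len(spec$n_cells)) {
      ii <- lay$cell_cru_idx[[j]]
      if (ca_coupling) {
        d$ca_ss[ii] <- d$ca_ss[ii] + caCouplingTerm(st$ca_ss[ii], diffusion$tau_ss)
        d$ca_sr[ii] <- d$ca_sr[ii] + caCouplingTerm(st$ca_sr[ii], diffusion$tau_sr)
        d$ca_cyto[ii] <- d$ca_cyto[ii] +
          caCouplingTerm(st$ca_cyto[ii], diffusion$tau_cyto)
      }
      if (vm_coupling) {
        d$vm[ii] <- d$vm[ii] + caCouplingTerm(st$vm[ii], conduction$tau_vm)
      }
    }
    if (vm_coupling && stimulusActive(conduction, t)) {
      tgt <- first_cru[1] + conduction$stim_target - 1L
      d$vm[tgt] <- d$vm[tgt] + conduction$stim_amplitude / conduction$stim_duration
    }
    if (spec$n_cells > 1) {
      for (j in seq_len(spec$n_cells - 1)) {
        u <- last_cru[j]; d0 <- first_cru[j + 1]
        i_gap <- gapJunctionCurrent(st$vm[u], st$vm[d0], spec$g_gap[j])
        dv <- i_gap / ionic$cm_cru
        if (spec$eq6_verbatim_signs) {
          d$vm[u] <- d$vm[u] + dv
          d$vm[d0] <- d$vm[d0] - dv
        } else {
          d$vm[u] <- d$vm[u] - dv
          d$vm[d0] <- d$vm[d0] + dv
        }
      }
    }

    dy <- numeric(lay$n_states)
    for (i in seq_len(.N_CRU_STATES)) dy[IDX[, i]] <- d[[i]]
    if (nrow(fib)) {
      fs <- lapply(seq_len(.N_FIB_STATES), function(i) y[FIDX[, i]])
      names(fs) <- .FIB_FIELDS
      class(fs) <- "fibroblastState"
      res <- fibroblastRHS(fs, fp, v_myocyte = st$vm[fib$cru])
      for (i in seq_len(.N_FIB_STATES)) dy[FIDX[, i]] <- res$deriv[[i]]
      dvm <- res$i_junc / ionic$cm_cru
      for (q in seq_len(nrow(fib))) {
        iv <- IDX[fib$cru[q], 1]
        dy[iv] <- dy[iv] + dvm[q]
      }
    }
    dy
  }
}

#' Initial packed state vector for a tissue spec
#'
#' CRUs start from the ionic resting state with sarcomeres at their
#' (possibly heterogeneous) resting lengths; fibroblasts start at their
#' resting state.
#'
#' @param spec a [tissueSpec()]
#' @return numeric state vector in the engine's block layout
#' @export
tissueInitialState <- function(spec) {
  lay <- tissueLayout(spec)
  y <- numeric(lay$n_states)
  IDX <- outer(lay$cru_off, seq_len(.N_CRU_STATES), `+`)
  ion <- ionicState(lay$n_cru_total)
  mec <- sarcomereState(lay$n_cru_total, sl = lay$resting_sl)
  st <- c(unclass(ion), unclass(mec))
  for (i in seq_len(.N_CRU_STATES)) y[IDX[, i]] <- st[[.CRU_FIELDS[i]]]
  if (nrow(lay$fib)) {
    FIDX <- outer(lay$fib$off, seq_len(.N_FIB_STATES), `+`)
    fs <- fibroblastState(nrow(lay$fib))
    for (i in seq_len(.N_FIB_STATES)) y[FIDX[, i]] <- fs[[.FIB_FIELDS[i]]]
  }
  y
}
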