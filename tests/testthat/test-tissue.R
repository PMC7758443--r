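# Gap junctions, heterogeneity generation, fibroblast attachment, and
# tissue assembly.

test_that("gap-junction current follows Ohm's law with antisymmetry", {
  expect_equal(gapJunctionCurrent(-80, -80, 400), 0)
  expect_equal(gapJunctionCurrent(-70, -80, 400), 4000)  # 400 nS x 10 mV
  set.seed(5)
  for (k in 1:10) {
    a <- runif(1, -90, 40); b <- runif(1, -90, 40); g <- runif(1, 0, 800)
    expect_equal(gapJunctionCurrent(a, b, g), -gapJunctionCurrent(b, a, g))
  }
})

test_that("heterogeneous resting lengths are uniform on the stated interval", {
  sl <- generateRestingLengths(seed = 1, n = 50)
  expect_length(sl, 50)
  expect_true(all(sl >= 1.701 & sl <= 2.079))
  expect_identical(sl, generateRestingLengths(seed = 1, n = 50))
  expect_false(identical(sl, generateRestingLengths(seed = 2, n = 50)))
  # law of large numbers on the mean
  big <- generateRestingLengths(seed = 3, n = 1e5)
  expect_equal(mean(big), 1.89, tolerance = 0.01 / 1.89)
  expect_error(generateRestingLengths(n = 5), "seed")
})

test_that("fibroblast attachment respects placement and conductance rules", {
  draws <- do.call(rbind, lapply(1:400, function(s)
    attachFibroblasts(3, seed = s, n_cru = 50)))
  expect_true(all(draws$cru %in% c(1:5, 46:50)))
  expect_true(all(draws$g_f_gap >= 0.5 & draws$g_f_gap <= 8.0))
  # both ends are actually used
  expect_true(any(draws$cru <= 5) && any(draws$cru >= 46))
  distal <- do.call(rbind, lapply(1:50, function(s)
    attachFibroblasts(3, seed = s, n_cru = 50, ends = "distal")))
  expect_true(all(distal$cru >= 46))
  expect_identical(attachFibroblasts(2, seed = 9, n_cru = 50),
                   attachFibroblasts(2, seed = 9, n_cru = 50))
  expect_equal(nrow(attachFibroblasts(0, seed = 1)), 0)
  expect_error(attachFibroblasts(4, seed = 1), "0, 1, 2 or 3")
})

test_that("tissueSpec validates fibroblast placement and junction layout", {
  expect_error(tissueSpec(fiberGeometry(20),
                          fibroblasts = list(data.frame(cru = 10L,
                                                        g_f_gap = 1))),
               "terminal")
  sp <- tissueSpec(list(fiberGeometry(4), fiberGeometry(4)), g_gap = 400)
  expect_equal(sp$n_cells, 2)
  lay <- tissueLayout(sp)
  expect_equal(lay$n_states, 8 * 20)
  expect_equal(lay$cell_of_cru, rep(1:2, each = 4))
})

test_that("tissue layout keeps fibroblast blocks beside their hosts", {
  sp <- tissueSpec(fiberGeometry(10),
                   fibroblasts = list(data.frame(cru = c(2L, 9L),
                                                 g_f_gap = c(1, 2))))
  lay <- tissueLayout(sp)
  expect_equal(lay$n_states, 10 * 20 + 2 * 5)
  for (q in seq_len(nrow(lay$fib))) {
    host_off <- lay$cru_off[lay$fib$cru[q]]
    expect_lte(lay$fib$off[q] - host_off, lay$bandwidth)
  }
})

test_that("decoupled multi-cell tissue reproduces independent single cells", {
  geoA <- fiberGeometry(4, generateRestingLengths(seed = 31, n = 4))
  geoB <- fiberGeometry(4, generateRestingLengths(seed = 32, n = 4))
  pac <- pacingProtocol(500, 2, conductionParams(stim_amplitude = 160,
                                                 stim_period = 500))
  duo <- runSimulation(tissueSpec(list(geoA, geoB), g_gap = 0), pac,
                       ca_o = 2.0, early_exit = FALSE)
  solo_a <- runSimulation(tissueSpec(geoA), pac, ca_o = 2.0,
                          early_exit = FALSE)
  solo_b <- runSimulation(tissueSpec(geoB),
                          pacingProtocol(500, 2,
                            conductionParams(stim_amplitude = 0,
                                             stim_period = 500)),
                          ca_o = 2.0, early_exit = FALSE)
  expect_equal(unname(duo$vm[, 1:4]), unname(solo_a$vm), tolerance = 1e-6)
  expect_equal(unname(duo$ca_cyto[, 1:4]), unname(solo_a$ca_cyto),
               tolerance = 1e-6)
  expect_equal(unname(duo$vm[, 5:8]), unname(solo_b$vm), tolerance = 1e-6)
})

test_that("gap junctions conduct the action potential to unstimulated cells", {
  geos <- lapply(c(41, 42, 43), function(s)
    fiberGeometry(4, generateRestingLengths(seed = s, n = 4)))
  pac <- pacingProtocol(1000, 2, conductionParams(stim_amplitude = 480))
  res <- runSimulation(tissueSpec(geos, g_gap = 400), pac, ca_o = 2.0,
                       early_exit = FALSE)
  # cells 2 and 3 fire full APs without a direct stimulus
  expect_gt(max(res$vm[, 6]), 0)
  expect_gt(max(res$vm[, 10]), 0)
  # with the junctions removed they stay at rest
  res0 <- runSimulation(tissueSpec(geos, g_gap = 0), pac, ca_o = 2.0,
                        early_exit = FALSE)
  expect_lt(max(res0$vm[, 6]), -60)
})

test_that("junctional charge exchange is antisymmetric in the assembled RHS", {
  geos <- list(fiberGeometry(3, 1.89), fiberGeometry(3, 1.89))
  sp <- tissueSpec(geos, g_gap = 400)
  sp0 <- tissueSpec(geos, g_gap = 0)
  y <- perturbedState(sp, seed = 2)
  d <- compiledTissueRHS(sp)(0.5, y) - compiledTissueRHS(sp0)(0.5, y)
  lay <- tissueLayout(sp)
  dv_up <- d[lay$cru_off[3] + 1]
  dv_down <- d[lay$cru_off[4] + 1]
  expect_equal(dv_up, -dv_down)           # equal and opposite on the boundary
  expect_equal(sum(abs(d)) - abs(dv_up) - abs(dv_down), 0)  # nowhere else
})

test_that("the audited alternative junction orientation is anti-conservative", {
  geos <- list(fiberGeometry(3, 1.89), fiberGeometry(3, 1.89))
  y <- perturbedState(tissueSpec(geos), seed = 8)
  lay <- tissueLayout(tissueSpec(geos))
  iu <- lay$cru_off[3] + 1; id <- lay$cru_off[4] + 1
  y[iu] <- -60; y[id] <- -80   # upstream depolarised
  d_std <- compiledTissueRHS(tissueSpec(geos, g_gap = 400))(0.5, y)
  d_ver <- compiledTissueRHS(tissueSpec(geos, g_gap = 400,
                                        eq6_verbatim_signs = TRUE))(0.5, y)
  # conventional orientation discharges the depolarised side; the audited
  # orientation charges it further (positive feedback)
  d_off <- compiledTissueRHS(tissueSpec(geos, g_gap = 0))(0.5, y)
  expect_lt(d_std[iu] - d_off[iu], 0)
  expect_gt(d_ver[iu] - d_off[iu], 0)
})

test_that("inter-myocyte conduction delay shrinks monotonically with g_gap", {
  geos <- list(fiberGeometry(3, 1.89), fiberGeometry(3, 1.89))
  pac <- pacingProtocol(1000, 1, conductionParams(stim_amplitude = 240))
  delay <- vapply(c(2, 5, 20), function(g) {
    res <- runSimulation(tissueSpec(geos, g_gap = g), pac, ca_o = 2.0,
                         early_exit = FALSE,
                         solver = solverConfig(sample_interval = 0.1))
    t1 <- res$time[which(res$vm[, 1] > -40)[1]]
    t2 <- res$time[which(res$vm[, 4] > -40)[1]]
    t2 - t1
  }, numeric(1))
  expect_true(all(is.finite(delay)))
  expect_true(all(diff(delay) < 0))   # 10x conductance range, shrinking delay
})
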