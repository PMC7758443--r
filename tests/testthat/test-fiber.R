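# Stencils, fiber assembly, and the R/compiled parity contract.

test_that("calcium exchange stencil matches the discrete Laplacian forms", {
  expect_equal(caCouplingTerm(c(1.0, 0.5, 0.0), tau = 1.2),
               c(-0.41667, 0, 0.41667), tolerance = 1e-4)
  expect_equal(caCouplingTerm(rep(0.7, 9), tau = 0.4533), rep(0, 9))
  expect_error(caCouplingTerm(1, tau = 1), "at least 2")
})

test_that("both diffusion stencils are zero-sum for arbitrary inputs", {
  set.seed(42)
  for (k in 1:20) {
    ca <- runif(sample(2:50, 1), 0, 2)
    expect_equal(sum(caCouplingTerm(ca, tau = runif(1, 0.1, 200))), 0,
                 tolerance = 1e-12 * length(ca) * max(ca))
  }
})

test_that("membrane-potential coupling equalises near-instantly and stimulates", {
  cp <- conductionParams()
  out <- vmCouplingTerm(c(-85, -20), cp, t = 500)  # outside stimulus window
  expect_equal(out, c(6.5e6, -6.5e6))
  # stimulus adds amplitude/duration on the target CRU inside the window
  expect_true(stimulusActive(cp, 1))
  expect_false(stimulusActive(cp, 3.5))
  with_stim <- vmCouplingTerm(c(-85, -85), cp, t = 1)
  expect_equal(with_stim, c(cp$stim_amplitude / cp$stim_duration, 0))
  # zero-sum stencil conserves the mean absent the stimulus
  set.seed(7)
  vm <- rnorm(20, -60, 30)
  expect_equal(sum(vmCouplingTerm(vm, cp, t = 500)) * cp$tau_vm, 0,
               tolerance = 1e-9)
})

test_that("sarcomere coupling implements the strict and relaxed forms", {
  # uniform rates: interior frozen by the strict difference form (its
  # known common-mode degeneracy)
  u <- sarcomereCoupling(rep(1.5, 5), mode = "verbatim")
  expect_equal(u[2:4], rep(0, 3))
  expect_equal(u[c(1, 5)], c(0, 0))
  expect_equal(sarcomereCoupling(c(0, 1, 0), mode = "verbatim")[2], 2)
  # relaxed mode with kappa = 0 is the identity
  r <- runif(6)
  expect_equal(sarcomereCoupling(r, mode = "relaxed", kappa = 0), r)
  expect_error(sarcomereCoupling(r, mode = "nonsense"))
  expect_error(sarcomereCoupling(0.1), "at least 2")
})

test_that("pure-diffusion relaxation matches the matrix-exponential solution", {
  # cell dynamics off: evolve one compartment under the stencil alone and
  # compare with the analytic solution of the linear system
  n <- 8; tau <- 1.2
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    L[i, i] <- -2 / tau
    if (i > 1) L[i, i - 1] <- 1 / tau
    if (i < n) L[i, i + 1] <- 1 / tau
  }
  L[1, 1] <- -1 / tau; L[n, n] <- -1 / tau
  set.seed(3)
  ca0 <- runif(n, 0.1, 1)
  f <- function(t, y, parms) list(caCouplingTerm(y, tau))
  out <- deSolve::lsoda(ca0, c(0, 5, 20), f, rtol = 1e-10, atol = 1e-12)
  for (k in 2:3) {
    t_k <- out[k, 1]
    analytic <- as.vector(Matrix::expm(L * t_k) %*% ca0)
    expect_equal(unname(out[k, -1]), analytic, tolerance = 1e-8)
  }
  # total calcium conserved
  expect_equal(sum(out[3, -1]), sum(ca0), tolerance = 1e-10)
})

test_that("homogeneous fiber with identical CRUs stays identical", {
  spec <- smallSpec(n_cru = 4)
  pac <- pacingProtocol(1000, 2, conductionParams(stim_amplitude = 0))
  res <- runSimulation(spec, pac, ca_o = 2.0, early_exit = FALSE)
  for (tr in list(res$vm, res$ca_cyto, res$ca_sr, res$sl)) {
    spread <- apply(tr, 1, function(x) diff(range(x)))
    expect_lt(max(spread), 1e-6 * max(abs(tr)))
  }
})

test_that("stimulated fiber activates monotonically along the cable", {
  # a slower voltage-transfer constant makes the conduction delay visible
  geo <- fiberGeometry(10, 1.89)
  spec <- tissueSpec(geo)
  pac <- pacingProtocol(1000, 2,
                        conductionParams(tau_vm = 0.5, stim_amplitude = 120))
  res <- runSimulation(spec, pac, ca_o = 2.0, early_exit = FALSE,
                       keep_beats = 1)
  up <- vapply(seq_len(10), function(c) {
    vm <- res$vm[, c]
    res$time[which(vm > -40)[1]]
  }, numeric(1))
  expect_true(all(is.finite(up)))          # every CRU fires
  expect_true(all(diff(up) >= 0))          # ordered away from the stimulus
  expect_gt(up[10], up[1])                 # strictly delayed at the far end
})

test_that("fiber AP upstroke magnitude is close to the uncoupled cell's", {
  # 1D conduction retains a similar upstroke magnitude to the 0D model
  spec1 <- smallSpec(n_cru = 2)
  res1 <- runSimulation(spec1, pacingProtocol(1000, 3,
            conductionParams(stim_amplitude = 80)), ca_o = 2.0,
            early_exit = FALSE)
  spec2 <- tissueSpec(fiberGeometry(10, 1.89))
  res2 <- runSimulation(spec2, pacingProtocol(1000, 3,
            conductionParams(stim_amplitude = 400)), ca_o = 2.0,
            early_exit = FALSE)
  amp1 <- max(res1$vm[, 1]) - min(res1$vm[, 1])
  amp2 <- max(res2$vm[, 5]) - min(res2$vm[, 5])
  expect_lt(abs(amp2 - amp1) / amp1, 0.10)
})

test_that("RHS evaluation is deterministic and the compiled kernel matches R", {
  for (cfg in list(
    list(spec = smallSpec(3), stretch = NULL, mode = "verbatim"),
    list(spec = hetSpec(5, 6), stretch = stretchProtocol("P"),
         mode = "relaxed"),
    list(spec = tissueSpec(list(fiberGeometry(4, 1.8), fiberGeometry(4, 2.0)),
                           g_gap = 400,
                           fibroblasts = list(
                             data.frame(cru = 1L, g_f_gap = 3),
                             data.frame(cru = 4L, g_f_gap = 6))),
         stretch = stretchProtocol("S"), mode = "relaxed"))) {
    rr <- assembleTissueRHS(cfg$spec, stretch = cfg$stretch,
                            sl_mode = cfg$mode)
    rc <- compiledTissueRHS(cfg$spec, stretch = cfg$stretch,
                            sl_mode = cfg$mode)
    y <- perturbedState(cfg$spec, seed = 11)
    t0 <- 137.5
    d_r <- rr(t0, y)
    expect_identical(d_r, rr(t0, y))              # bit-identical re-evaluation
    expect_equal(rc(t0, y), d_r, tolerance = 1e-12)
  }
})

test_that("fiber state packing round-trips", {
  ion <- ionicState(5, vm = seq(-85, -65, length.out = 5))
  mec <- sarcomereState(5, sl = seq(1.7, 2.0, length.out = 5))
  y <- packFiberState(ion, mec)
  back <- unpackFiberState(y, 5)
  expect_equal(back$vm, ion$vm)
  expect_equal(back$sl, mec$sl)
  expect_equal(back$tnc, mec$tnc)
})
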