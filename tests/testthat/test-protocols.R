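# Stretch waveforms, pacing, limit-cycle criterion and sweep schedule.

test_that("stretch waveforms hit their defining amplitudes", {
  tt <- seq(0, 1000, by = 0.5)
  i <- stretchScaling(stretchProtocol("I"), tt)
  expect_true(all(i$scale == 1) && all(i$dscale == 0))
  h <- stretchScaling(stretchProtocol("H"), tt)
  expect_equal(min(h$scale), 0.80)            # 20% compression
  expect_equal(max(h$scale), 1.00)
  s <- stretchScaling(stretchProtocol("S"), tt)
  expect_equal(range(s$scale), c(0.90, 1.10)) # 10% compression / stretch
  expect_gt(s$scale[which.min(abs(tt - 250))], 1)  # stretch in systole
  expect_lt(s$scale[which.min(abs(tt - 750))], 1)  # compression in diastole
  p <- stretchScaling(stretchProtocol("P"), tt)
  expect_equal(max(p$scale), 1.15, tolerance = 1e-6)  # plateau
  expect_equal(p$scale[1], 1.00)
})

test_that("stretch waveforms are cycle-periodic and continuous", {
  for (pat in c("H", "S", "P")) {
    pr <- stretchProtocol(pat)
    tt <- seq(0, 3000, by = 0.25)
    sc <- stretchScaling(pr, tt)$scale
    expect_equal(stretchScaling(pr, tt + 1000)$scale, sc, tolerance = 1e-5)
    expect_lt(max(abs(diff(sc))), 0.01)   # no jumps at this resolution
  }
  expect_error(stretchScaling(stretchProtocol("H"), -1), ">= 0")
})

test_that("analytic stretch derivatives match finite differences", {
  eps <- 1e-3
  for (pat in c("H", "S", "P")) {
    pr <- stretchProtocol(pat)
    # probe away from P's piecewise joints
    tt <- c(37, 211, 404, 622, 903)
    an <- stretchScaling(pr, tt)$dscale
    fd <- (stretchScaling(pr, tt + eps)$scale -
             stretchScaling(pr, tt - eps)$scale) / (2 * eps)
    expect_equal(an, fd, tolerance = 1e-6)
  }
})

test_that("limit-cycle criterion thresholds the AP mean squared error", {
  ap <- trapezoidAP()$vm
  same <- limitCycleReached(ap, ap)
  expect_true(same$reached)
  expect_equal(same$mse, 0)
  off1 <- limitCycleReached(ap, ap + 0.2)
  expect_false(off1$reached)
  expect_equal(off1$mse, 0.04)
  off2 <- limitCycleReached(ap, ap + 0.05)
  expect_true(off2$reached)
  expect_equal(off2$mse, 0.0025)
  # unequal grids are resampled rather than rejected
  expect_equal(limitCycleReached(ap, ap[seq(1, length(ap), 2)])$mse, 0,
               tolerance = 1e-3)
  expect_error(limitCycleReached(numeric(0), ap), "empty")
})

test_that("sweep schedule enumerates the calcium steps deterministically", {
  sched <- runSweepSchedule(sweepConfig(), pacingProtocol(),
                            stretchProtocol("H"))
  expect_equal(nrow(sched), 26)                      # 2.0, 2.1, ..., 4.5
  expect_equal(sched$ca_o[1], 2.0)
  expect_equal(sched$ca_o[26], 4.5)
  expect_true(all(sched$n_beats <= 200))
  expect_identical(sched, runSweepSchedule(sweepConfig(), pacingProtocol(),
                                           stretchProtocol("H")))
})

test_that("the engine can stop pacing early at the limit cycle", {
  spec <- smallSpec()
  pac <- pacingProtocol(1000, 12, conductionParams(stim_amplitude = 80))
  res <- runSimulation(spec, pac, ca_o = 2.0, early_exit = TRUE)
  expect_lt(res$beats_run, 12)
  expect_lt(tail(res$mse, 1), 0.01)
})
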