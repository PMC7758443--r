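# Measurement machinery: APD90, event detection, velocity, amplitude,
# dyssynchrony, group statistics.

test_that("APD90 on the trapezoid fixture is 270 ms and offset-invariant", {
  tr <- trapezoidAP()
  expect_equal(apd90(tr$vm, tr$time), 270, tolerance = 1e-6)
  expect_equal(apd90(tr$vm + 5, tr$time), 270, tolerance = 1e-6)
  expect_length(apd90(rep(-85, 100), seq(0, 99)), 0)   # flat trace: no APs
})

test_that("wave velocity estimator inverts a constructed activation map", {
  geom <- fiberGeometry(10, 1.89)
  # activation times spaced so the generating speed is exactly 100 um/s
  act <- (seq_len(10) - 1) * 1.89 / 100 * 1000   # ms
  v <- waveVelocity(list(activation_times = act), geom)
  expect_true(v$propagating)
  expect_equal(v$velocity, 100, tolerance = 1e-9)
  # reversing the direction leaves the speed unchanged
  vr <- waveVelocity(list(activation_times = rev(act)), geom)
  expect_equal(vr$velocity, 100, tolerance = 1e-9)
  # simultaneous activation is flagged synchronous, not given a velocity
  vs <- waveVelocity(list(activation_times = rep(3, 10)), geom)
  expect_false(vs$propagating); expect_true(vs$synchronous)
  # fewer than three activated CRUs: non-propagating
  v2 <- waveVelocity(list(activation_times = c(1, 2, rep(NA, 8))), geom)
  expect_false(v2$propagating); expect_false(v2$synchronous)
})

test_that("velocity recovery is within 2% across speeds and noise", {
  for (speed in c(50, 100, 1000, 5000)) {
    for (noise in c(0, 0.1)) {
      e <- mainEvent(velocityFixture(speed, noise, seed = speed + 1))
      expect_true(e$propagating)
      expect_lt(abs(e$velocity - speed) / speed, 0.02)
    }
  }
})

test_that("metrics are stable under time-grid refinement", {
  coarse <- syntheticWaveTraces(speed = 100, dt = 1)
  fine <- syntheticWaveTraces(speed = 100, dt = 0.5)
  ev_c <- detectEvents(syntheticResult(coarse$time, coarse$ca))[[1]]
  ev_f <- detectEvents(syntheticResult(fine$time, fine$ca))[[1]]
  expect_lt(abs(ev_c$velocity - ev_f$velocity) / ev_f$velocity, 0.01)
  expect_lt(abs(ev_c$amplitude - ev_f$amplitude) / ev_f$amplitude, 0.01)
  tr <- trapezoidAP(dt = 1); tr2 <- trapezoidAP(dt = 0.5)
  expect_lt(abs(apd90(tr$vm, tr$time) - apd90(tr2$vm, tr2$time)) /
              apd90(tr2$vm, tr2$time), 0.01)
})

test_that("event classification reads the membrane potential", {
  tr <- syntheticWaveTraces(speed = 100, n_cru = 8, t_end = 2000)
  # quiescent Vm: a propagating calcium event with no electrical signature
  ev <- detectEvents(syntheticResult(tr$time, tr$ca))
  expect_gte(length(ev), 1)
  expect_equal(ev[[1]]$vm_class, "none")
  expect_equal(ev[[1]]$wave_class, "slow_wave")
  # simultaneous whole-cell release with a full AP: triggered beat
  tt <- seq(0, 2000, by = 0.5)
  ca <- matrix(1e-4, length(tt), 8)
  ca[tt > 500 & tt < 700, ] <- 6e-4
  vm <- matrix(-85, length(tt), 8)
  up <- tt >= 500 & tt < 502
  vm[up, ] <- -85 + (tt[up] - 500) * 60          # 60 mV/ms regenerative rise
  vm[tt >= 502 & tt < 700, ] <- 35
  ev2 <- detectEvents(syntheticResult(tt, ca, vm))
  expect_equal(ev2[[1]]$vm_class, "triggered_beat")
  expect_true(ev2[[1]]$synchronous)
  # quiescent decay produces no events at all
  flat <- syntheticResult(tt, matrix(1e-4, length(tt), 8))
  expect_length(detectEvents(flat), 0)
  expect_error(detectEvents(flat, eventThresholds(ca_threshold = -1)),
               "positive")
})

test_that("wave amplitude is the baseline-relative maximal excursion in uM", {
  tr <- syntheticWaveTraces(speed = 100, amp = 5e-4)   # 0.5 uM above rest
  res <- syntheticResult(tr$time, tr$ca)
  ev <- detectEvents(res)[[1]]
  expect_equal(ev$amplitude, 0.5, tolerance = 0.01)
  expect_equal(waveAmplitude(ev, res), 0.5, tolerance = 0.01)
  # invariant to a constant offset on all traces
  res2 <- syntheticResult(tr$time, tr$ca + 2e-4)
  ev2 <- detectEvents(res2)[[1]]
  expect_equal(ev2$amplitude, ev$amplitude, tolerance = 1e-6)
})

test_that("dyssynchrony is the sample SD of per-cell mean times-to-peak", {
  expect_equal(dyssynchrony(c(10, 20, 30)), 10)           # sample (n-1) SD
  expect_equal(dyssynchrony(c(30, 10, 20)), 10)           # order-invariant
  expect_equal(dyssynchrony(c(5, 5, 5, 5)), 0)            # identical cells
  expect_error(dyssynchrony(7), "at least 2")
  # trace input: two cells whose peaks differ by a known lag
  tt <- seq(0, 100, by = 0.5)
  mk <- function(lag) sapply(1:4, function(i)
    exp(-((tt - 50 - lag) / 10)^2))
  expect_equal(dyssynchrony(list(mk(0), mk(10)), time = tt),
               sd(c(50, 60)), tolerance = 0.01)
})

test_that("group statistics: outliers, ANOVA and Bonferroni adjustment", {
  set.seed(1)
  g1 <- c(rnorm(8, 0, 0.1))
  g2 <- c(rnorm(8, 10, 0.1))
  rep_sig <- groupStats(list(a = g1, b = g2))
  expect_lt(rep_sig$anova_p, 0.01)
  expect_true(all(rep_sig$pairwise$tier == "p<0.01"))
  # identical groups: nothing significant
  rep_ns <- groupStats(list(a = g1, b = g1 + rnorm(8, 0, 0.05)))
  expect_gt(rep_ns$pairwise$p_adj[1], 0.1)
  # a point at mean + 4 sigma is removed by the three-sigma rule
  g3 <- c(rnorm(20, 0, 1))
  g3 <- c(g3, mean(g3) + 4.5 * sd(g3))
  rep_out <- groupStats(list(a = g3, b = rnorm(20)))
  expect_true(length(rep_out$outliers$a) >= 1)
  expect_equal(rep_out$n[["a"]], length(g3) - length(rep_out$outliers$a))
  # Bonferroni equals min(1, m * p_raw) (brute-force oracle)
  set.seed(2)
  gs <- list(a = rnorm(6), b = rnorm(6, 0.5), c = rnorm(6, 1), d = rnorm(6, 0.2))
  rp <- groupStats(gs)
  m <- nrow(rp$pairwise)
  expect_equal(rp$pairwise$p_adj, pmin(1, m * rp$pairwise$p_raw),
               tolerance = 1e-12)
  expect_true(all(rp$pairwise$p_adj >= rp$pairwise$p_raw))
  expect_error(groupStats(list(a = 1:5)), "at least 2")
})
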