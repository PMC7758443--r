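# Unit tests of the ionic, myofilament and fibroblast cell models.

test_that("conductance remodeling multiplies the four target currents once", {
  p <- ionicParams(g_to = 0.06)
  r <- applyRemodeling(p)
  expect_equal(r$g_to, 0.078)             # +30%
  expect_equal(r$g_ks, p$g_ks * 0.85)
  expect_equal(r$g_k1, p$g_k1 * 0.70)
  expect_equal(r$i_nak_max, p$i_nak_max * 1.15)
  expect_false(p$remodeled)               # original untouched
  expect_error(applyRemodeling(r), "twice")
  ident <- applyRemodeling(p, remodelingSpec(1, 1, 1, 1))
  for (f in c("g_to", "g_ks", "g_k1", "i_nak_max"))
    expect_equal(ident[[f]], p[[f]])
})

test_that("strain-modulated TnC rates obey the exponential law", {
  cp <- strainCouplingParams(kon0 = 1, koff0 = 1, alpha_on = 2, alpha_off = 2)
  expect_equal(strainModulatedRates(cp, 0),
               list(kon = cp$kon0, koff = cp$koff0))   # exp(0) = 1 exactly
  expect_equal(strainModulatedRates(cp, 0.5)$kon, exp(1))
  # positive alpha_off: stretch-rate promotes dissociation
  cp2 <- strainCouplingParams()
  expect_gt(strainModulatedRates(cp2, 1e-3)$koff, cp2$koff0)
  # continuity and strict monotonicity over the unclamped range
  sr <- seq(-1e-3, 1e-3, length.out = 101)
  ko <- strainModulatedRates(cp2, sr)$koff
  expect_true(all(diff(ko) > 0))
  expect_true(all(ko > 0))
  # clamp bounds the modulation
  expect_equal(strainModulatedRates(cp2, 1)$koff,
               cp2$koff0 * exp(cp2$max_log_mod))
})

test_that("ionic RHS has zero voltage/concentration flux with all sources off", {
  p <- ionicParams(g_na = 0, p_cal = 0, g_to = 0, g_ks = 0, g_kr = 0,
                   g_k1 = 0, i_nak_max = 0, v_ncx = 0, g_cab = 0, g_nab = 0,
                   v_pca = 0, v_rel = 0, v_up = 0, v_leak = 0, v_leak_ss = 0)
  s <- ionicState(1, ca_ss = 1e-4, ca_cyto = 1e-4)  # subspace == cytosol
  d <- ionicRHS(s, p)$deriv
  expect_identical(d$vm, 0)
  expect_identical(d$ca_sr, 0)
  expect_equal(d$ca_ss, 0)
  expect_equal(d$ca_cyto, 0)
  expect_identical(d$na_i, 0)
  expect_identical(d$k_i, 0)
})

test_that("ionic RHS rejects non-finite state naming the variable", {
  s <- ionicState(2)
  s$ca_sr[2] <- NaN
  expect_error(ionicRHS(s, ionicParams()), "ca_sr")
  expect_error(ionicRHS(ionicState(1), ionicParams(), tnc_flux = Inf),
               "tnc_flux")
})

test_that("myocyte rests stably near -85 mV (quiescent drift is small)", {
  spec <- smallSpec()
  pac <- pacingProtocol(5000, 1, conductionParams(stim_amplitude = 0))
  res <- runSimulation(spec, pac, ca_o = 2.0, early_exit = FALSE)
  vm <- res$vm[, 1]
  expect_lt(abs(vm[length(vm)] + 85), 5)       # rests in the -80..-90 band
  last_s <- res$time >= max(res$time) - 1000   # drift over the final second
  expect_lt(diff(range(vm[last_s])), 0.5)
  # gates in [0,1], concentrations positive throughout (invariant check on
  # every stored sample)
  expect_true(all(res$ca_cyto > 0) && all(res$ca_sr > 0) && all(res$ca_ss > 0))
})

test_that("paced action potential has physiological shape and calcium transient", {
  spec <- smallSpec()
  pac <- pacingProtocol(1000, 8, conductionParams(stim_amplitude = 80))
  res <- runSimulation(spec, pac, ca_o = 2.0, early_exit = FALSE)
  vm <- res$vm[, 1]
  apd <- apd90(vm, res$time)
  expect_gte(length(apd), 1)
  expect_true(all(apd > 100 & apd < 350))      # rabbit ventricular range
  expect_gt(max(vm), 10)                       # overshooting upstroke
  ca <- res$ca_cyto[, 1]
  expect_gt(max(ca) / min(ca), 2)              # systolic transient present
})

test_that("myofilament relaxes to zero force without activator calcium", {
  p <- sarcomereParams()
  st <- sarcomereState(1, tnc = 0.2, xb = 0.1)
  # integrate the uncoupled mechanics at vanishing calcium
  dt <- 0.5
  for (i in seq_len(4000)) {
    d <- myofilamentRHS(st, ca_cyto = 1e-9, strain_rate = 0, params = p)
    st$tnc <- st$tnc + dt * d$deriv$tnc
    st$xb <- st$xb + dt * d$deriv$xb
  }
  expect_lt(myofilamentRHS(st, 1e-9, 0, p)$force, 1e-4)
})

test_that("zero strain rate reproduces the unmodulated myofilament model", {
  p <- sarcomereParams()
  st <- sarcomereState(1, sl = 1.95, tnc = 0.3, xb = 0.05)
  a <- myofilamentRHS(st, ca_cyto = 5e-4, strain_rate = 0, params = p)
  # baseline model: same expressions with kon0/koff0 directly
  kon <- p$coupling$kon0 * (1 + p$beta_lda * (1.95 - p$sl_ref) / p$sl_ref)
  koff <- p$coupling$koff0 * (1 - p$gamma_xb * 0.05)
  dtnc <- kon * 5e-4 * (1 - 0.3) - koff * 0.3
  expect_equal(a$deriv$tnc, dtnc)
  expect_equal(a$tnc_flux, p$b_tnc * dtnc)
})

test_that("myofilament warns and clamps outside the sarcomere validity range", {
  p <- sarcomereParams()
  st <- sarcomereState(1, sl = 3.0)
  expect_warning(myofilamentRHS(st, 1e-4, 0, p), "validity range")
})

test_that("fibroblast junctional current is antisymmetric and conservative", {
  fp <- fibroblastParams(g_f_gap = 4)
  s <- fibroblastState(1, v_f = -30)
  r1 <- fibroblastRHS(s, fp, v_myocyte = -80)
  expect_equal(r1$i_junc, 4 * (-30 - -80))
  # equal potentials -> zero junctional current
  expect_equal(fibroblastRHS(fibroblastState(1, v_f = -80), fp, -80)$i_junc, 0)
  # antisymmetry under exchange of the two potentials
  s2 <- fibroblastState(1, v_f = -80)
  r2 <- fibroblastRHS(s2, fp, v_myocyte = -30)
  expect_equal(r1$i_junc, -r2$i_junc)
  # the same current (scaled by C_f) leaves the fibroblast membrane:
  # switching the junction off changes dV_f/dt by exactly i_junc / C_f
  r0 <- fibroblastRHS(s, fibroblastParams(g_f_gap = 0), v_myocyte = -80)
  expect_equal(r0$deriv$v_f - r1$deriv$v_f, r1$i_junc / fp$c_f)
})

test_that("uncoupled fibroblast relaxes to its resting potential near -50 mV", {
  fp <- fibroblastParams(g_f_gap = 0)
  relax <- function(v0) {
    s <- fibroblastState(1, v_f = v0)
    nm <- names(s)
    f <- function(t, y, parms) {
      st <- as.list(y); names(st) <- nm; class(st) <- "fibroblastState"
      list(unlist(fibroblastRHS(st, fp, v_myocyte = -80)$deriv,
                  use.names = FALSE))
    }
    out <- deSolve::lsoda(unlist(s), c(0, 20000), f, rtol = 1e-8, atol = 1e-10)
    out[nrow(out), 2]
  }
  v_rest <- relax(-20)
  expect_lt(abs(v_rest + 50), 5)
  expect_equal(relax(-80), v_rest, tolerance = 1e-3)  # same from both sides
})
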