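# Channel kinetics, ionic currents and the calcium pool.

test_that("rate functions are finite at removable singularities", {
  # the (V - V0)/(exp(.) - 1) forms have removable singularities at the
  # half-activation voltages; the limits are the leading coefficients
  r <- rate_functions(c(-30, -40, -90, -13))
  expect_true(all(is.finite(r)))
  expect_equal(unname(r[1, "alpha_m"]), 6)
  expect_equal(unname(r[2, "alpha_n"]), 0.2)
  expect_equal(unname(r[3, "alpha_a"]), 0.06)
  expect_equal(unname(r[4, "alpha_c"]), 3)
  expect_true(all(rate_functions(seq(-120, 80, by = 0.5)) >= 0))
})

test_that("steady-state activation saturates and is 1/2 where rates cross", {
  s <- gate_steady(100)
  expect_gt(s$inf[1, "m"], 0.99)
  vstar <- uniroot(function(v) {
    r <- rate_functions(v)
    r[1, "alpha_m"] - r[1, "beta_m"]
  }, c(-60, 0), tol = 1e-10)$root
  expect_equal(unname(gate_steady(vstar)$inf[1, "m"]), 0.5, tolerance = 1e-6)
})

test_that("rate scaling multiplies every rate uniformly", {
  expect_equal(rate_functions(-50, rate_scale = 2.5),
               2.5 * rate_functions(-50), ignore_attr = TRUE)
})

test_that("gate updates are exact exponential relaxations", {
  v <- -48
  s <- gate_steady(v)
  at_ss <- as.list(s$inf[1, ])
  names(at_ss) <- c("m", "h", "n", "a", "hA", "c")
  expect_equal(gate_step(at_ss, v, dt = 0.5), unlist(at_ss),
               tolerance = 1e-12)                 # fixed point
  off <- lapply(at_ss, function(x) 0.9 * x)
  expect_equal(gate_step(off, v, dt = 1e4), unlist(at_ss),
               tolerance = 1e-9)                  # long-time limit
  # two half steps compose exactly to one full step under clamped V
  one <- gate_step(off, v, dt = 0.05)
  two <- gate_step(as.list(gate_step(off, v, dt = 0.025)), v, dt = 0.025)
  expect_equal(one, two, tolerance = 1e-12)
  expect_true(all(one >= 0 & one <= 1))
})

test_that("ionic current composes the six conductances correctly", {
  spec <- membrane_spec()
  g_k_only <- list(gna = 0, gk = 18, ga = 54, gca = 0, gkca = 0.065,
                   gl = 0.005)
  st <- list(m = 0.3, h = 0.4, n = 0.5, a = 0.2, hA = 0.6, c = 0.1,
             ca = spec$ca_res_mM)
  # at V = EK every K-type driving force vanishes
  out <- ionic_current(spec$ek, st, g_k_only, spec)
  expect_equal(out$total, 0.005 * (spec$ek - spec$el))
  # leak-only membrane at V = EL carries no current
  g_l_only <- list(gna = 0, gk = 0, ga = 0, gca = 0, gkca = 0, gl = 0.005)
  expect_equal(ionic_current(spec$el, st, g_l_only, spec)$total, 0)
  # the reported breakdown sums to the total for arbitrary states
  set.seed(1)
  for (i in 1:5) {
    st2 <- list(m = runif(1), h = runif(1), n = runif(1), a = runif(1),
                hA = runif(1), c = runif(1), ca = runif(1, 1e-4, 1e-2))
    gd <- as.list(membrane_spec()$regions[2, -1])
    out2 <- ionic_current(runif(1, -80, 40), st2, gd, spec)
    expect_equal(out2$total, sum(out2$breakdown))
  }
})

test_that("calcium pool relaxes exactly and floors at the residual", {
  spec <- membrane_spec()
  res <- spec$ca_res_mM
  expect_equal(calcium_step(res, 0, 0.025, spec), res)       # fixed point
  above <- calcium_step(5 * res, 0, 0.025, spec)
  expect_lt(above, 5 * res); expect_gt(above, res)           # monotone decay
  # constant inward current: steady state is residual + source * tau
  ica <- -10 # uA/cm2, inward
  conv <- 1e-3 / (2 * 96485.33212 * spec$ca_depth_um * 1e-4)
  target <- res + (-ica) * conv * spec$ca_tau_ms
  ca <- res
  for (i in 1:4000) ca <- calcium_step(ca, ica, 0.025, spec)
  expect_equal(ca, target, tolerance = 1e-6)
  # exact one-step solution of the linear ODE
  one <- calcium_step(res, ica, 0.5, spec)
  analytic <- target + (res - target) * exp(-0.5 / spec$ca_tau_ms)
  expect_equal(one, analytic, tolerance = 1e-12)
})

test_that("calcium reversal potential is finite and falls as calcium rises", {
  e1 <- nernst_eca(1e-4); e2 <- nernst_eca(1e-3); e3 <- nernst_eca(1e-2)
  expect_true(all(is.finite(c(e1, e2, e3))))
  expect_gt(e1, e2); expect_gt(e2, e3)
})

test_that("conductance tables carry the region-specific channel densities", {
  spec <- membrane_spec()
  r <- spec$regions
  rownames(r) <- r$region
  expect_equal(unlist(r["dendrite", -1]),
               c(gna = 40, gk = 12, ga = 36, gca = 2, gkca = 0.05,
                 gl = 0.005))
  expect_equal(unlist(r["ais", -1]),
               c(gna = 700, gk = 18, ga = 54, gca = 1.5, gkca = 0.065,
                 gl = 0.005))
  expect_equal(r["soma", -1], r["hillock", -1], ignore_attr = TRUE)
  expect_equal(unlist(r["axon", c("ga", "gca")]), c(ga = 0, gca = 0))
  expect_equal(c(spec$ena, spec$ek, spec$el), c(35, -75, -62.5))
  expect_equal(c(spec$cm, spec$ra), c(1, 110))
  # raising dendritic gNa is a pure table override
  s80 <- membrane_spec(dendrite_gna = 80)
  expect_equal(s80$regions$gna[s80$regions$region == "dendrite"], 80)
  expect_identical(s80$regions[s80$regions$region != "dendrite", ],
                   spec$regions[spec$regions$region != "dendrite", ])
})

test_that("a somatic patch rests quiescent yet fires under injection", {
  sys <- assemble(segmentize(soma_patch()))
  rest <- cable_run(sys, sim_config(duration = 300))
  v_end <- tail(rest$vm[, 1], 1)
  expect_length(detect_spikes(rest), 0)           # quiescent
  expect_lt(abs(v_end - tail(rest$vm[, 1], 40)[1]), 0.5)  # stable
  # resting K(Ca) holds the patch below EL, within 10 mV
  expect_lt(v_end, -62.5)
  expect_gt(v_end, -72.5)
  # sustained depolarizing current evokes repetitive firing with
  # amplitude-dependent rate
  isis <- sapply(c(20, 40, 60), function(amp) {
    tr <- cable_run(sys, sim_config(duration = 520),
                    injections = inject_current("soma", amp, onset_ms = 10))
    expect_gte(length(detect_spikes(tr)), 2)
    isi_curve(tr)
  })
  expect_true(all(diff(isis) < 0))                # ISI falls as drive rises
})
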