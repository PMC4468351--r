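test_that("the origin is a fixed point and nonnegativity is preserved at y = 0", {
  p <- light_params()
  expect_equal(transduction_rhs(c(0, 0), 0, 0, p), c(0, 0))
  d <- transduction_rhs(c(0, 0), 15, 5, p)
  expect_gte(d[2], 0)
  expect_error(transduction_rhs(c(0, 0), -1, 0, p), "nonnegative")
})

test_that("slow corrections are small, continuous and bypassable", {
  p <- light_params()
  cc30 <- apply_corrections(p, 30)
  expect_equal(cc30$theta_eff, p$theta)           # boundary continuity
  expect_equal(cc30$beta4_eff, (1 + 0.023 / 2) * p$beta4)
  cc_inf <- apply_corrections(p, 1e6)
  expect_equal(cc_inf$beta4_eff, 1.023 * p$beta4, tolerance = 1e-6)
  expect_lt(cc_inf$theta_eff, 1e-6)
  expect_equal(apply_corrections(p, 0)$beta4_eff, p$beta4)
  p0 <- light_params(corrections_enabled = FALSE)
  expect_equal(apply_corrections(p0, 100)$beta4_eff, p$beta4)
  expect_equal(apply_corrections(p0, 100)$theta_eff, p$theta)
})

test_that("steady state solves rhs = 0 and matches long integration", {
  p <- light_params(corrections_enabled = FALSE)
  expect_equal(steady_state(p, 0), list(u = 0, y = 0))
  ss <- steady_state(p, 15)
  d <- transduction_rhs(c(ss$u, ss$y), 15, 24, p)
  expect_lt(max(abs(d)), 1e-6)
  ## long-horizon integration converges to the root
  tt <- seq(0, 200, by = 1 / 30)
  const <- stimulus_trace(tt, rep(15, length(tt)), "light")
  sol <- integrate_transduction(p, const, init = "zero", method = "rk4")
  expect_equal(tail(sol$y, 1), ss$y, tolerance = 1e-3)
})

test_that("steady-state rate is nondecreasing in odor concentration", {
  p <- odor_iff_params()
  xs <- seq(0, 600, by = 25)
  ys <- vapply(xs, function(x) steady_state(p, x)$y, 0)
  expect_true(all(diff(ys) > -1e-8))
})

test_that("constant stimulus from steady-state init stays constant", {
  p <- light_params()
  tt <- seq(0, 10, by = 1 / 30)
  const <- stimulus_trace(tt, rep(100, length(tt)), "light")
  sol <- integrate_transduction(p, const)
  ## corrections drift beta4 slowly; over 10 s the change is ~0.3%
  expect_lt(diff(range(sol$y)), 0.15)
  expect_true(all(sol$y >= 0))
})

test_that("peak rate scales with the rising slope across linear ramps", {
  p <- light_params()
  suite <- ramp_suite("light")
  peaks <- vapply(c("linear4_low", "linear4_med", "linear4_high"),
                  function(nm) {
    max(integrate_transduction(p, make_ramp(suite[[nm]]),
                               method = "rk4")$y)
  }, 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("offset inhibition: rate dips below baseline after an abrupt fall", {
  p <- light_params()
  tr <- make_ramp(ramp_spec("exponential", 8, 0, 15, 207, "light"),
                  pad_before = 1, pad_after = 5)
  sol <- integrate_transduction(p, tr)
  y_base <- sol$y[1]
  after <- sol$t > 9.1 & sol$t < 11
  expect_lt(min(sol$y[after]), 0.5 * y_base)
})

test_that("fast RK4 integrator agrees with the stiff reference solver", {
  p <- light_params()
  for (shape in c("linear", "exponential", "sigmoid")) {
    tr <- make_ramp(ramp_spec(shape, 8, 8, 15, 207, "light"))
    a <- integrate_transduction(p, tr)
    b <- integrate_transduction(p, tr, method = "rk4")
    expect_lt(max(abs(a$y - b$y)), 0.02)
  }
  ## halving the reference tolerances barely moves the solution
  tr <- make_ramp(ramp_spec("linear", 8, 8, 15, 207, "light"))
  a <- integrate_transduction(p, tr, rtol = 1e-6, atol = 1e-8)
  b <- integrate_transduction(p, tr, rtol = 5e-7, atol = 5e-9)
  expect_lt(max(abs(a$y - b$y)), 1e-4)
})

test_that("nonnegativity holds across the ramp suite", {
  p <- light_params()
  suite <- ramp_suite("light")
  for (nm in c("linear4_fast", "exponential", "sigmoid")) {
    sol <- integrate_transduction(p, make_ramp(suite[[nm]]), method = "rk4")
    expect_true(all(sol$y >= 0))
    expect_true(all(sol$u >= 0))
  }
})

test_that("pathway decomposition conserves du/dt and isolates the IFB share", {
  p <- composite_params()
  tr <- make_ramp(ramp_spec("linear", 8, 8, 52, 522, "odor"))
  pc <- pathway_contributions(p, tr, method = "rk4")
  ## reconstruction: du/dt = iff + ifb - decay
  du_rec <- with(pc$pathways, iff + ifb - decay)
  du_num <- c(diff(pc$solution$u) / diff(pc$solution$t), NA)
  ok <- seq_len(nrow(pc$pathways) - 30)
  expect_lt(stats::median(abs(du_rec[ok] - du_num[ok])), 0.5)
  ## with the feedback removed the IFB trace vanishes
  p0 <- composite_params(alpha3 = 0)
  pc0 <- pathway_contributions(p0, tr, method = "rk4")
  expect_true(all(pc0$pathways$ifb == 0))
  expect_error(pathway_contributions(light_params(), tr), "IFF_IFB")
})

test_that("gas-phase prediction is the liquid model after the 26.73 scaling", {
  p <- composite_params()
  tt <- seq(0, 6, by = 1 / 30)
  gas <- stimulus_trace(tt, rep(2.2, length(tt)) + 18 * (tt > 2), "odor")
  a <- predict_rate_for_gas(p, gas, method = "rk4")
  liq <- stimulus_trace(tt, gas_to_liquid(gas$x), "odor",
                        baseline = gas_to_liquid(2.2))
  b <- integrate_transduction(p, liq, method = "rk4")
  expect_equal(a$y, b$y)
  expect_error(predict_rate_for_gas(light_params(), gas), "odor")
})

test_that("parameter containers validate and round-trip through config files", {
  expect_error(transduction_params("light_iff", beta5 = -1), "nonnegative")
  expect_error(transduction_params("light_iff", n = 0.5), "Hill")
  p <- composite_params()
  f <- tempfile(fileext = ".yaml")
  write_params(p, f)
  q <- read_params(f)
  expect_equal(q$beta1, p$beta1)
  expect_equal(q$variant, "IFF_IFB")
  g <- test_glm()
  fj <- tempfile(fileext = ".json")
  write_params(g, fj)
  g2 <- read_params(fj)
  expect_equal(g2$gamma1, g$gamma1)
})
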