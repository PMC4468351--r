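test_that("landscape profiles honor their defining geometry", {
  vol <- make_landscape("volcano")
  ## rim at 8 mm carries the maximum, foot at 16 mm the baseline
  expect_equal(sample_intensity(vol, c(8, 0)), 207, tolerance = 0.5)
  expect_equal(sample_intensity(vol, c(17, 0)), 15)
  expect_equal(sample_intensity(vol, c(0, 0)), 15, tolerance = 0.5)
  well <- make_landscape("well")
  expect_equal(sample_intensity(well, c(3, 0)), 15)        # inside: baseline
  mesa <- make_landscape("mesa")
  expect_equal(sample_intensity(mesa, c(0, 0)), 207)       # plateau
  hat <- make_landscape("linear_hat")
  expect_gt(sample_intensity(hat, c(0.5, 0)),
            sample_intensity(hat, c(7, 0)))                # rises inward
  ## radial symmetry
  for (L in list(vol, mesa)) {
    expect_equal(sample_intensity(L, c(0, 11)),
                 sample_intensity(L, c(11, 0)), tolerance = 1e-9)
  }
  expect_error(make_landscape("volcano", annulus_width = 0), "rim")
})

test_that("an inward volcano transect at 1 mm/s replays the 8-s exponential ramp", {
  vol <- make_landscape("volcano")
  dt <- 1 / 30
  tt <- seq(0, 16, by = dt)
  r <- pmax(16 - tt, 0)       # foot at 16 mm to the center
  traj <- trajectory(tt, head_x = r, head_y = 0, mid_x = r + 1.5,
                     mid_y = 0, tail_x = r + 3, tail_y = 0)
  replayed <- replay_from_trajectory(traj, vol, point = "head")
  ramp <- make_ramp(ramp_spec("exponential", 8, 8, 15, 207, "light"),
                    pad_before = 0, pad_after = 0)
  ref <- stats::approx(ramp$t, ramp$x, xout = tt, rule = 2)$y
  ## agreement within the 1-mm bilinear grid error
  expect_lt(max(abs(replayed$x - ref)) / 192, 0.12)
  expect_gt(pearson_rho(replayed$x, ref), 0.995)
})

test_that("bilinear sampling is exact on nodes and on linear fields", {
  L <- make_landscape("mesa", half_width = 20)
  ## grid nodes return stored values
  expect_equal(sample_intensity(L, c(3, -4)),
               L$grid[which(L$xs == 3), which(L$ys == -4)])
  ## a linear synthetic field is reproduced exactly everywhere
  L2 <- L
  L2$grid <- outer(L$xs, L$ys, function(x, y) 2 + 0.5 * x - 0.25 * y)
  pts <- cbind(stats::runif(20, -9, 9), stats::runif(20, -9, 9))
  expect_equal(sample_intensity(L2, pts),
               2 + 0.5 * pts[, 1] - 0.25 * pts[, 2], tolerance = 1e-12)
  expect_error(sample_intensity(L, c(99, 0)), "outside")
  ## midpoint of four equal nodes returns that value
  expect_equal(sample_intensity(L, c(0.5, 0.5)),
               sample_intensity(L, c(0, 0)), tolerance = 1e-9)
})

test_that("landscape text round-trip preserves the grid", {
  L <- make_landscape("well", half_width = 18)
  base <- tempfile()
  write_landscape(L, base)
  back <- read_landscape(base)
  expect_equal(back$grid, L$grid, tolerance = 1e-8)
  expect_equal(back$profile, "well")
})

test_that("simulations are bit-reproducible and closed-loop consistent", {
  p <- light_params()
  glm <- test_glm()
  L <- make_landscape("exponential", half_width = 30)
  a <- simulate_larva(L, p, glm, agent_config(duration = 60, seed = 5))
  b <- simulate_larva(L, p, glm, agent_config(duration = 60, seed = 5))
  expect_identical(a$frames, b$frames)
  ## replaying the logged trajectory reproduces the logged stimulus
  rep_x <- replay_from_trajectory(a$trajectory, L, point = "head")
  expect_equal(rep_x$x, a$frames$x, tolerance = 1e-9)
})

test_that("uniform landscape gives exponential run durations at the baseline rate", {
  ## corrections off so the baseline firing rate is truly stationary
  p <- light_params(corrections_enabled = FALSE)
  glm <- test_glm()
  L <- make_landscape("mesa", half_width = 20)
  L$grid[] <- 15   # flat field at the baseline intensity
  sims <- lapply(1:12, function(s) {
    simulate_larva(L, p, glm, agent_config(duration = 120, seed = 40 + s,
                                           start_distance = 2))
  })
  ## keep censored runs: dropping them would bias the hazard estimate up
  runs <- do.call(rbind, lapply(sims, `[[`, "runs"))
  ## expected constant hazard: lambda at the baseline steady-state rate
  y0 <- steady_state(p, 15)$y
  lam <- lambda_of(glm, y0)
  ens <- run_ensemble(runs$duration, runs$turn == 1, min_duration = 0)
  est <- estimate_turn_probability(ens)
  sel <- est$reliable & est$t > 0.5 & est$t < 4
  ## binomial CI at ~350 runs (plus a small end-of-session censoring
  ## contribution to the numerator) is about +/- 0.025
  expect_lt(abs(mean(est$lambda[sel]) - lam), 0.025)
  ## gamma1 = 0 decouples behavior from the landscape
  glm0 <- turn_glm_params(preset = NULL, gamma0 = -1, gamma1 = 0)
  s1 <- simulate_larva(make_landscape("well"), p, glm0,
                       agent_config(duration = 40, seed = 2))
  s2 <- simulate_larva(make_landscape("mesa"), p, glm0,
                       agent_config(duration = 40, seed = 2))
  expect_equal(s1$runs$duration, s2$runs$duration)
})

test_that("open-loop ensembles terminate instantly under certain hazard", {
  g1 <- turn_glm_params(preset = NULL, gamma0 = 50, gamma1 = 0) # lambda ~ 1
  e <- make_turn_ensemble(g1, rep(0, 300), 50, seed = 6, min_duration = 0)
  expect_true(all(e$durations <= 1 / 30 + 1e-9))
  expect_true(all(e$turn_terminal))
  ## doubling the ensemble roughly halves the lambda-hat variance
  g <- turn_glm_params(preset = NULL, gamma0 = -1, gamma1 = 0)
  sds <- vapply(c(400, 1600), function(n) {
    e <- make_turn_ensemble(g, rep(0, 200), n, seed = 11, min_duration = 0)
    est <- estimate_turn_probability(e)
    stats::sd(est$lambda[est$reliable & est$t > 1 & est$t < 3])
  }, 0)
  expect_lt(sds[2], sds[1])
})

test_that("agents accumulate near the peak of the exponential gradient", {
  p <- light_params()
  glm <- test_glm()
  L <- make_landscape("exponential", half_width = 30)
  finals <- vapply(1:25, function(s) {
    f <- simulate_larva(L, p, glm,
                        agent_config(duration = 180, seed = s))$frames
    sqrt(utils::tail(f$mid_x, 1)^2 + utils::tail(f$mid_y, 1)^2)
  }, 0)
  expect_lt(stats::median(finals), 9.6)
})

test_that("agent config validates its inputs", {
  expect_error(agent_config(speed = 0), "speed")
  expect_error(agent_config(turn_bias = 1.5), "turn_bias")
})
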