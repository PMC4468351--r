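test_that("kinematic features on a straight crawl: zero head angle, forward dot", {
  traj <- straight_trajectory(n = 120, speed = 1)
  f <- kinematic_features(traj)
  expect_true(all(f$head_angle < 1e-6))
  core <- 10:110
  expect_equal(mean(f$dot[core]), 1 / 30, tolerance = 1e-6)
  ## perpendicular head
  t2 <- trajectory(c(0, 1 / 30, 2 / 30),
                   head_x = c(1, 1, 1), head_y = c(1, 1, 1),
                   mid_x = c(1, 1, 1), mid_y = c(0, 0, 0),
                   tail_x = c(0, 0, 0), tail_y = c(0, 0, 0))
  f2 <- kinematic_features(t2, smooth_window = 1)
  expect_equal(f2$head_angle, rep(90, 3), tolerance = 1e-6)
  expect_error(kinematic_features(
    trajectory(c(0, 1/30, 2/30), c(0,0,0), c(0,0,0), c(0,0,0), c(0,0,0),
               c(0,0,0), c(0,0,0)), smooth_window = 1), "coincident")
})

test_that("state machine applies both interruption conditions and hysteresis", {
  thr <- classifier_thresholds()
  mk <- function(angle, dot) data.frame(head_angle = angle, dot = dot)
  n <- 10
  ## constant 25 degrees: never a run
  expect_true(all(classify_states(mk(rep(25, n), rep(0.03, n)), thr) ==
                  "non_run"))
  ## hysteresis: 20 deg interrupts, re-entry only below 13 deg
  ang <- c(5, 5, 20, 20, 15, 15, 10, 10)
  st <- classify_states(mk(ang, rep(0.03, 8)), thr)
  expect_equal(st, c("run", "run", "non_run", "non_run", "non_run",
                     "non_run", "run", "run"))
  ## backward motion with straight posture: condition (ii)
  st2 <- classify_states(mk(rep(2, n), rep(-0.02, n)), thr)
  expect_true(all(st2 == "non_run"))
  ## initial state follows C2 at the first frame
  expect_equal(classify_states(mk(c(5, 5), c(0.03, 0.03)), thr)[1], "run")
  expect_equal(classify_states(mk(c(15, 5), c(0.03, 0.03)), thr)[1],
               "non_run")
  expect_error(classifier_thresholds(tau1 = 10, tau3 = 12), "hysteresis")
})

test_that("geometric turn detector finds single bends and ignores shallow zigzags", {
  ## straight path: nothing
  expect_equal(nrow(detect_turns_geometric(seq(0, 50, 0.5),
                                           rep(0, 101))), 0)
  ## one 90-degree bend between two 20-mm legs
  px <- c(seq(0, 20, 0.5), rep(20, 40))
  py <- c(rep(0, 41), seq(0.5, 20, 0.5))
  turns <- detect_turns_geometric(px, py)
  expect_equal(nrow(turns), 1)
  expect_equal(turns$x, 20, tolerance = 2.6)
  expect_equal(turns$angle, 90, tolerance = 25)
  ## shallow 10-degree zigzag stays below the 20-degree threshold
  ang <- rep(c(5, -5), 10) * pi / 180
  steps <- cbind(cos(cumsum(ang)), sin(cumsum(ang))) * 6
  pz <- rbind(c(0, 0), apply(steps, 2, cumsum))
  expect_equal(nrow(detect_turns_geometric(pz[, 1], pz[, 2])), 0)
  ## path shorter than two segments: empty
  expect_equal(nrow(detect_turns_geometric(c(0, 3), c(0, 0))), 0)
})

test_that("state machine output is invariant to rigid motions of the trajectory", {
  set.seed(14)
  px <- cumsum(c(0, stats::runif(40, 0.5, 2)))
  py <- cumsum(c(0, stats::rnorm(40, 0, 0.8)))
  traj <- path_trajectory(px, py)
  st0 <- classify_states(traj)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(x, y) cbind(x, y) %*% R
  m <- rot(traj$mid_x, traj$mid_y); h <- rot(traj$head_x, traj$head_y)
  tl <- rot(traj$tail_x, traj$tail_y)
  traj2 <- trajectory(traj$t, h[, 1] + 5, h[, 2] - 3, m[, 1] + 5,
                      m[, 2] - 3, tl[, 1] + 5, tl[, 2] - 3)
  expect_equal(classify_states(traj2), st0)
})

test_that("runs are cut from state sequences with correct termination flags", {
  ## one turn in the middle: first run turn-terminated, second censored
  st <- c(rep("run", 60), rep("non_run", 30), rep("run", 60))
  ens <- runs_from_states(st, inputs = seq_along(st))
  expect_equal(length(ens), 2)
  expect_equal(ens$durations, c(2, 2))
  expect_equal(ens$turn_terminal, c(TRUE, FALSE))
  expect_equal(ens$inputs[[1]][1], 1)
  ## no turns: single censored run
  ens2 <- runs_from_states(rep("run", 90))
  expect_equal(length(ens2), 1)
  expect_false(ens2$turn_terminal)
  ## alternating 3-s runs / 1-s non-runs
  st3 <- rep(c(rep("run", 90), rep("non_run", 30)), 4)
  ens3 <- runs_from_states(st3)
  expect_equal(length(ens3), 4)
  expect_equal(ens3$durations, rep(3, 4))
  expect_true(all(ens3$turn_terminal))
})

test_that("classifier and geometric detector agree with simulator ground truth", {
  p <- light_params()
  glm <- test_glm()
  L <- make_landscape("exponential", half_width = 30)
  sim <- simulate_larva(L, p, glm, agent_config(duration = 120, seed = 17))
  truth <- ifelse(sim$frames$state == "run", "run", "non_run")
  ## simulated positions carry no tracker jitter: light smoothing only
  st <- classify_states(kinematic_features(sim$trajectory,
                                           smooth_window = 5))
  expect_gt(mean(st == truth), 0.9)
  ## geometric detector: its 5-mm arc resolution requires runs long on
  ## that scale, so use a low-hazard agent (runs ~10 mm) on a flat field
  glm_slow <- turn_glm_params(preset = NULL, gamma0 = -3, gamma1 = 0)
  flat <- make_landscape("mesa", half_width = 40)
  flat$grid[] <- 15
  sim2 <- simulate_larva(flat, p, glm_slow,
                         agent_config(duration = 300, seed = 23,
                                      start_distance = 2))
  n_true <- sum(sim2$runs$turn == 1)
  turns <- detect_turns_geometric(sim2$trajectory)
  expect_gt(nrow(turns), 0)
  tx <- sim2$frames$mid_x[sim2$runs$end[sim2$runs$turn == 1]]
  ty <- sim2$frames$mid_y[sim2$runs$end[sim2$runs$turn == 1]]
  near <- vapply(seq_len(nrow(turns)), function(i) {
    min(sqrt((turns$x[i] - tx)^2 + (turns$y[i] - ty)^2))
  }, 0)
  expect_gt(mean(near < 3), 0.7)
  expect_lte(abs(nrow(turns) - n_true) / max(n_true, 1), 0.5)
})

test_that("trajectory I/O round-trips", {
  traj <- straight_trajectory(30)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(back$mid_x, traj$mid_x)
  expect_equal(back$t, traj$t)
})
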