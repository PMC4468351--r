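# Shared fixtures: parameter sets and small stimuli used across tests.

light_params <- function(...) transduction_params("light_iff", ...)
odor_iff_params <- function(...) transduction_params("odor_iff", ...)
composite_params <- function(...) transduction_params("odor_iff_ifb", ...)

test_glm <- function() turn_glm_params("test")

# a short light ramp on a coarse grid, cheap enough for repeated integration
quick_ramp <- function(shape = "linear", rise = 4, fall = 4, lo = 15,
                       hi = 207, dt = 1 / 30, pad_before = 1,
                       pad_after = 3) {
  make_ramp(ramp_spec(shape, rise, fall, lo, hi, "light"), dt = dt,
            pad_before = pad_before, pad_after = pad_after)
}

# straight-crawl trajectory fixture: constant speed along +x, collinear body
straight_trajectory <- function(n = 90, speed = 1, dt = 1 / 30) {
  t <- (seq_len(n) - 1) * dt
  mx <- speed * t
  trajectory(t, head_x = mx + 1, head_y = 0, mid_x = mx, mid_y = 0,
             tail_x = mx - 1, tail_y = 0)
}

# trajectory following a piecewise-straight midpoint path with collinear
# body aligned to the local direction of motion
path_trajectory <- function(px, py, speed = 1, dt = 1 / 30) {
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  s_grid <- seq(0, sum(seg), by = speed * dt)
  s_cum <- c(0, cumsum(seg))
  mx <- stats::approx(s_cum, px, xout = s_grid)$y
  my <- stats::approx(s_cum, py, xout = s_grid)$y
  n <- length(mx)
  dx <- c(mx[2] - mx[1], diff(mx)); dy <- c(my[2] - my[1], diff(my))
  nrm <- sqrt(dx^2 + dy^2); nrm[nrm == 0] <- 1
  hx <- dx / nrm; hy <- dy / nrm
  trajectory((seq_len(n) - 1) * dt,
             head_x = mx + hx, head_y = my + hy,
             mid_x = mx, mid_y = my,
             tail_x = mx - hx, tail_y = my - hy)
}
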