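#' Agent configuration for the closed-loop larva simulator
#'
#' @param speed crawling speed (mm/s, default 1 — the paper family of
#'   landscapes is calibrated for this speed).
#' @param dt frame interval (s, default 1/30).
#' @param duration session length (s).
#' @param start_distance distance from the landscape center at t = 0 (mm);
#'   default 9.6 for the exponential gradient and 17.1 for the
#'   volcano/well/mesa/linear family.
#' @param turn_duration non-run duration of a turn (s).
#' @param turn_angle_range magnitude range (degrees) of the heading change
#'   drawn uniformly at each turn.
#' @param turn_bias probability that the turn is directed toward the
#'   brighter of the two candidate headings (larvae resolve the gradient
#'   with lateral head casts before committing to a turn; 0.5 gives fully
#'   undirected turns).
#' @param seed integer seed; the simulation is bit-reproducible for a fixed
#'   seed.
#' @return An `agent_config` list.
#' @export
agent_config <- function(speed = 1, dt = 1 / 30, duration = 180,
                         start_distance = NULL, turn_duration = 1.5,
                         turn_angle_range = c(30, 120), turn_bias = 0.75,
                         seed = 1) {
  if (speed <= 0) stop("speed must be positive")
  if (turn_bias < 0 || turn_bias > 1) stop("turn_bias must be in [0, 1]")
  structure(list(speed = speed, dt = dt, duration = duration,
                 start_distance = start_distance,
                 turn_duration = turn_duration,
                 turn_angle_range = turn_angle_range,
                 turn_bias = turn_bias, seed = seed),
            class = "agent_config")
}

#' Closed-loop agent-based larva simulation
#'
#' Simulates a larva in a virtual light landscape with the full
#' stimulus-to-behavior loop: at every frame the light intensity is sampled
#' at the head position (bilinear interpolation), the transduction ODE is
#' advanced one Runge-Kutta step, the turn GLM converts the firing rate
#' into a 1-s turn probability lambda, and a Bernoulli draw with the
#' per-frame hazard `1 - (1 - lambda)^dt` decides whether the run is
#' interrupted. A turn holds the body in place for the turn duration while
#' the heading rotates to a new direction (uniform magnitude in
#' `turn_angle_range`, random sign); the run then resumes. The larva starts
#' at `start_distance` from the center, facing it. If the head would leave
#' the landscape grid the simulation is truncated and flagged.
#'
#' @param landscape a [make_landscape()] object.
#' @param params a [transduction_params()] (light modality for the virtual
#'   gradients).
#' @param glm a [turn_glm_params()] with `input_kind = "rate"` (the
#'   coupled test model). With `gamma1 = 0` behavior is
#'   landscape-independent.
#' @param config an [agent_config()].
#' @return List: `frames` (per-frame log: `t`, positions, `x`, `u`, `y`,
#'   `lambda`, `state`), `trajectory` (a [trajectory()]), `ensemble`
#'   (a [run_ensemble()] whose inputs are the per-run lambda traces),
#'   `runs` (start/end/turn table with rim-crossing times), `truncated`.
#' @export
simulate_larva <- function(landscape, params, glm, config = agent_config()) {
  set.seed(config$seed)
  dt <- config$dt
  n_f <- ceiling(config$duration / dt)
  start_d <- config$start_distance %||%
    if (landscape$profile == "exponential") 9.6 else 17.1
  body <- 1.5  # head offset from the midpoint along the heading (mm)
  margin <- body + landscape$resolution
  lim <- max(landscape$xs) - margin
  ## start on the +x axis, facing the center
  pos <- c(start_d, 0)
  heading <- pi
  head_pos <- pos + body * c(cos(heading), sin(heading))
  x0 <- sample_intensity(landscape, head_pos)
  ss <- steady_state(params, x0, t_ref = 0)
  u <- ss$u; y <- ss$y
  log_t <- numeric(n_f); log_x <- numeric(n_f); log_u <- numeric(n_f)
  log_y <- numeric(n_f); log_l <- numeric(n_f)
  log_mx <- numeric(n_f); log_my <- numeric(n_f)
  log_hx <- numeric(n_f); log_hy <- numeric(n_f)
  log_state <- character(n_f)
  state <- "run"
  turn_left <- 0
  heading_target <- heading
  run_start <- 1L
  runs <- list()
  truncated <- FALSE
  i <- 1L
  x_cur <- x0
  while (i <= n_f) {
    t_cur <- (i - 1L) * dt
    lam <- lambda_of(glm, y)
    log_t[i] <- t_cur; log_x[i] <- x_cur; log_u[i] <- u; log_y[i] <- y
    log_l[i] <- lam
    log_mx[i] <- pos[1]; log_my[i] <- pos[2]
    log_hx[i] <- head_pos[1]; log_hy[i] <- head_pos[2]
    log_state[i] <- state
    if (state == "run") {
      if (stats::runif(1) < 1 - (1 - lam)^dt) {
        ## run interrupted: record it, start the turn
        runs[[length(runs) + 1L]] <- c(start = run_start, end = i,
                                       turn = 1)
        state <- "turn"
        turn_left <- config$turn_duration
        delta <- stats::runif(1, config$turn_angle_range[1],
                              config$turn_angle_range[2]) * pi / 180
        ## lateral head casts: sample both candidate headings a body length
        ## ahead and commit to the brighter side with prob turn_bias
        cast <- 2 * body
        look <- function(hd) {
          pp <- pos + cast * c(cos(hd), sin(hd))
          if (any(abs(pp) > lim)) -Inf else sample_intensity(landscape, pp)
        }
        i_l <- look(heading + delta)
        i_r <- look(heading - delta)
        toward <- if (i_l >= i_r) 1 else -1
        sgn <- if (stats::runif(1) < config$turn_bias) toward else -toward
        heading_target <- heading + sgn * delta
      }
    }
    ## advance position / heading
    if (state == "run") {
      step <- config$speed * dt
      new_pos <- pos + step * c(cos(heading), sin(heading))
    } else {
      ## body stays, heading swings toward the target
      frac <- dt / max(turn_left, dt)
      heading <- heading + frac * (heading_target - heading)
      turn_left <- turn_left - dt
      new_pos <- pos
      if (turn_left <= 0) {
        heading <- heading_target
        state <- "run"
        run_start <- i + 1L
      }
    }
    new_head <- new_pos + body * c(cos(heading), sin(heading))
    if (any(abs(new_head) > lim) || any(abs(new_pos) > lim)) {
      truncated <- TRUE
      i <- i + 1L
      break
    }
    x_next <- sample_intensity(landscape, new_head)
    ## one RK4 step of the transduction ODE with x linear over the frame
    st <- integrate_rk4(params, c(t_cur, t_cur + dt), c(x_cur, x_next),
                        c(u, y))
    u <- st$u[2]; y <- st$y[2]
    pos <- new_pos; head_pos <- new_head; x_cur <- x_next
    i <- i + 1L
  }
  n_used <- min(i - 1L, n_f)
  if (state == "run" && run_start <= n_used) {
    runs[[length(runs) + 1L]] <- c(start = run_start, end = n_used, turn = 0)
  }
  idx <- seq_len(n_used)
  runs_df <- as.data.frame(do.call(rbind, runs))
  frames <- data.frame(t = log_t[idx], x = log_x[idx], u = log_u[idx],
                       y = log_y[idx], lambda = log_l[idx],
                       mid_x = log_mx[idx], mid_y = log_my[idx],
                       head_x = log_hx[idx], head_y = log_hy[idx],
                       state = log_state[idx])
  ## rim crossings are referenced to the head: the closed-loop stimulus is
  ## defined by the head position, so the sensory event is the head crossing
  r_dist <- sqrt(frames$head_x^2 + frames$head_y^2)
  if (nrow(runs_df)) {
    runs_df$t_start <- (runs_df$start - 1L) * dt
    runs_df$t_end <- (runs_df$end - 1L) * dt
    runs_df$duration <- runs_df$t_end - runs_df$t_start
    ## first inward rim crossing within each run (head-based distance)
    rim <- landscape$rim_radius
    runs_df$t_rim <- vapply(seq_len(nrow(runs_df)), function(k) {
      seg <- runs_df$start[k]:runs_df$end[k]
      rs <- r_dist[seg]
      cross <- which(rs[-1] < rim & rs[-length(rs)] >= rim)
      if (length(cross)) (seg[cross[1]] - 1L) * dt else NA_real_
    }, 0)
  }
  ens <- run_ensemble(
    durations = runs_df$duration,
    turn_terminal = runs_df$turn == 1,
    inputs = lapply(seq_len(nrow(runs_df)), function(k) {
      frames$lambda[runs_df$start[k]:runs_df$end[k]]
    }),
    dt = dt, min_duration = 1)
  tail_pos <- cbind(2 * frames$mid_x - frames$head_x,
                    2 * frames$mid_y - frames$head_y)
  traj <- trajectory(frames$t, frames$head_x, frames$head_y,
                     frames$mid_x, frames$mid_y,
                     tail_pos[, 1], tail_pos[, 2])
  list(frames = frames, trajectory = traj, ensemble = ens, runs = runs_df,
       truncated = truncated)
}

#' Run durations following an inward rim crossing
#'
#' For each turn-terminated run that crosses the landscape's rim moving
#' inward, the latency from the crossing to the run's end. This is the
#' statistic that separates the landscape family: an abrupt intensity fall
#' (well) inhibits the OSN and releases turning almost immediately, while
#' sustained stimulation (mesa, linear hat) elongates runs.
#'
#' @param sims list of [simulate_larva()] results (or a single one).
#' @return Numeric vector of post-rim durations (s).
#' @export
post_rim_run_durations <- function(sims) {
  if (!is.null(sims$runs)) sims <- list(sims)
  out <- unlist(lapply(sims, function(s) {
    rd <- s$runs
    rd <- rd[!is.na(rd$t_rim) & rd$turn == 1 & rd$duration >= 1, ,
             drop = FALSE]
    rd$t_end - rd$t_rim
  }))
  if (!length(out)) stop("no runs crossed the rim inward")
  out
}

#' Synthetic spike trains and PSTH from a firing-rate trace
#'
#' Emulates repeated extracellular recordings: each trial is an
#' inhomogeneous Poisson process with the given rate (thinning algorithm),
#' and the trial set is summarized by the standard sliding-window PSTH.
#'
#' @param rate a [rate_trace()] (or data frame `t`, `rate`).
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param window PSTH window (s).
#' @return List `spikes` (list of spike-time vectors) and `psth`
#'   (a [rate_trace()] with std).
#' @export
synthetic_psth <- function(rate, n_trials, seed = NULL, window = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  tt <- rate$t
  rr <- pmax(rate$rate, 0)
  rmax <- max(rr)
  t0 <- tt[1]; t1 <- tt[length(tt)]
  rfun <- stats::approxfun(tt, rr, rule = 2)
  spikes <- lapply(seq_len(n_trials), function(i) {
    if (rmax == 0) return(numeric(0))
    n_cand <- stats::rpois(1, rmax * (t1 - t0))
    cand <- sort(stats::runif(n_cand, t0, t1))
    cand[stats::runif(n_cand) < rfun(cand) / rmax]
  })
  list(spikes = spikes,
       psth = psth_from_spikes(spikes, tt, window = window))
}

#' Open-loop run ensemble generated by a turn GLM
#'
#' Emulates the open-loop behavioral paradigm: each simulated run replays
#' the same input trace (e.g. the model-predicted firing rate for a light
#' ramp); at every frame the run terminates in a turn with the per-frame
#' hazard `1 - (1 - lambda)^dt`; runs surviving the whole trace are
#' censored.
#'
#' @param glm a [turn_glm_params()].
#' @param input numeric input trace sampled at `dt` (rate or stimulus,
#'   matching the model's `input_kind`).
#' @param n_runs number of runs.
#' @param seed integer seed.
#' @param dt frame interval (s).
#' @param min_duration ensemble filter (s).
#' @return A [run_ensemble()]; inputs are the per-run slices of `input`.
#' @export
make_turn_ensemble <- function(glm, input, n_runs, seed = NULL, dt = 1 / 30,
                               min_duration = 1) {
  if (!is.null(seed)) set.seed(seed)
  lam <- lambda_of(glm, input)
  p_f <- 1 - (1 - lam)^dt
  surv <- cumprod(1 - p_f)
  u <- stats::runif(n_runs)
  ## termination at the first frame where cumulative survival drops below u;
  ## -surv is nondecreasing, so findInterval counts frames with surv >= u
  k0 <- findInterval(-u, -surv)
  censored <- k0 >= length(surv)
  frame <- ifelse(censored, length(surv), k0 + 1L)
  durations <- frame * dt
  inputs <- lapply(frame, function(k) input[seq_len(k)])
  run_ensemble(durations, !censored, inputs = inputs, dt = dt,
               min_duration = min_duration)
}
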