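#' Larva trajectory container
#'
#' A trajectory is a 30-Hz table of head, midpoint and tail positions in mm.
#' The midpoint is the skeleton point located at a third of the distance
#' from the head, and is the reference point for turn detection.
#'
#' @param t frame times (s), uniform.
#' @param head_x,head_y,mid_x,mid_y,tail_x,tail_y coordinates (mm).
#' @return A `trajectory` data frame.
#' @export
trajectory <- function(t, head_x, head_y, mid_x, mid_y, tail_x, tail_y) {
  out <- data.frame(t = t, head_x = head_x, head_y = head_y,
                    mid_x = mid_x, mid_y = mid_y,
                    tail_x = tail_x, tail_y = tail_y)
  if (any(!is.finite(as.matrix(out)))) stop("non-finite coordinates")
  structure(out, class = c("trajectory", "data.frame"))
}

#' Read/write trajectories as delimited tables
#' @param traj a [trajectory()].
#' @param path file path.
#' @rdname trajectory_io
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @rdname trajectory_io
#' @export
read_trajectory <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  trajectory(d$t, d$head_x, d$head_y, d$mid_x, d$mid_y, d$tail_x, d$tail_y)
}

sg_smooth <- function(v, window, degree) {
  n <- length(v)
  w <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (w %% 2L == 0L) w <- w - 1L
  if (w < degree + 2) return(v)
  signal::sgolayfilt(v, p = degree, n = w)
}

#' Per-frame kinematic features of a trajectory
#'
#' Computes the three sensorimotor features the run/non-run classifier is
#' built on: (1) the head angle — the unsigned angle between the neck axis
#' (midpoint to head) and the body axis (tail to midpoint); (2) the
#' instantaneous tail velocity (central difference, mm per frame); (3) the
#' dot product of the tail velocity with the unit body-axis vector
#' (positive for forward crawling, near zero for stops, negative for
#' backward motion). Positions are pre-smoothed with a Savitzky-Golay
#' filter (default half-second window, order 3) to remove tracker jitter.
#'
#' @param traj a [trajectory()].
#' @param smooth_window smoothing window (frames, odd).
#' @param smooth_degree polynomial degree.
#' @return Data frame `t`, `head_angle` (degrees), `v_tail_x`, `v_tail_y`
#'   (mm/frame), `dot` (mm/frame projected on the body axis).
#' @export
kinematic_features <- function(traj, smooth_window = 15, smooth_degree = 3) {
  n <- nrow(traj)
  if (n < 3L) stop("need at least 3 frames")
  cols <- c("head_x", "head_y", "mid_x", "mid_y", "tail_x", "tail_y")
  sm <- traj
  for (cl in cols) sm[[cl]] <- sg_smooth(traj[[cl]], smooth_window,
                                         smooth_degree)
  neck_x <- sm$head_x - sm$mid_x
  neck_y <- sm$head_y - sm$mid_y
  body_x <- sm$mid_x - sm$tail_x
  body_y <- sm$mid_y - sm$tail_y
  nb <- sqrt(body_x^2 + body_y^2)
  nn <- sqrt(neck_x^2 + neck_y^2)
  if (any(nb == 0 | nn == 0)) {
    stop(sprintf("coincident body points at frame %d",
                 which(nb == 0 | nn == 0)[1]))
  }
  cosang <- pmin(pmax((neck_x * body_x + neck_y * body_y) / (nb * nn), -1), 1)
  head_angle <- acos(cosang) * 180 / pi
  ## central-difference tail velocity in mm per frame
  vx <- c(sm$tail_x[2] - sm$tail_x[1],
          (sm$tail_x[-(1:2)] - sm$tail_x[-((n - 1):n)]) / 2,
          sm$tail_x[n] - sm$tail_x[n - 1])
  vy <- c(sm$tail_y[2] - sm$tail_y[1],
          (sm$tail_y[-(1:2)] - sm$tail_y[-((n - 1):n)]) / 2,
          sm$tail_y[n] - sm$tail_y[n - 1])
  dotp <- (vx * body_x + vy * body_y) / nb
  data.frame(t = traj$t, head_angle = head_angle,
             v_tail_x = vx, v_tail_y = vy, dot = dotp)
}

#' Run/non-run classifier thresholds
#'
#' @param tau1 head angle (degrees) above which a run is interrupted
#'   (default 18).
#' @param tau2 dot-product threshold (tail velocity in mm/frame projected
#'   on the body axis) below which the larva is considered stopped or
#'   moving backwards (default 0.0065).
#' @param tau3 head angle (degrees) below which a run may resume
#'   (default 13; `tau3 < tau1` gives the hysteresis).
#' @return A `classifier_thresholds` list.
#' @export
classifier_thresholds <- function(tau1 = 18, tau2 = 0.0065, tau3 = 13) {
  if (!(tau3 < tau1)) stop("need tau3 < tau1 (hysteresis)")
  structure(list(tau1 = tau1, tau2 = tau2, tau3 = tau3),
            class = "classifier_thresholds")
}

#' Two-state run/non-run classification
#'
#' Finite-state machine with hysteresis. A run is interrupted as soon as
#' (i) the head angle exceeds `tau1` (head cast) or (ii) the body-axis dot
#' product of the tail velocity falls below `tau2` (stop or backward run) —
#' condition C1. A run resumes only when (iii) the head angle is below
#' `tau3` and (iv) the dot product is above `tau2` — condition C2. The
#' initial state is `run` iff C2 holds at the first frame.
#'
#' @param traj a [trajectory()] (features are computed internally), or a
#'   feature data frame from [kinematic_features()].
#' @param thresholds a [classifier_thresholds()].
#' @return Character vector (`"run"`/`"non_run"`) per frame.
#' @export
classify_states <- function(traj, thresholds = classifier_thresholds()) {
  feats <- if (!is.null(traj$head_angle)) traj else kinematic_features(traj)
  c1 <- feats$head_angle > thresholds$tau1 | feats$dot < thresholds$tau2
  c2 <- feats$head_angle < thresholds$tau3 & feats$dot > thresholds$tau2
  n <- nrow(feats)
  state <- character(n)
  cur <- if (c2[1]) "run" else "non_run"
  for (i in seq_len(n)) {
    if (cur == "run" && c1[i]) cur <- "non_run"
    else if (cur == "non_run" && c2[i]) cur <- "run"
    state[i] <- cur
  }
  state
}

## resample a polyline at equal arc-length steps (linear interpolation);
## the trailing partial segment is dropped
resample_arclength <- function(x, y, step) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- c(TRUE, seg > 1e-12)   # drop stationary frames (zero arc length)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(cbind(x = x[1], y = y[1]))
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < step) return(cbind(x = x[1], y = y[1]))
  ss <- seq(0, total, by = step)
  cbind(x = stats::approx(s, x, xout = ss)$y,
        y = stats::approx(s, y, xout = ss)$y)
}

#' Offline geometric turn detection
#'
#' Parses the midpoint path into equal arc-length segments and flags
#' positions where the angle between successive segments exceeds a
#' threshold; contiguous super-threshold positions are merged into a single
#' turn event located at the maximum-angle position. Defaults (5-mm
#' segments, 20 degrees) correspond to the kink of the long-tailed
#' turn-angle distribution of real trajectories.
#'
#' @param x,y midpoint coordinates (mm), or a [trajectory()] as `x`.
#' @param segment_length arc-length segment (mm).
#' @param angle_threshold turning angle threshold (degrees).
#' @return Data frame `x`, `y`, `angle`, `arc_index` of turn events (zero
#'   rows if the path is shorter than two segments).
#' @export
detect_turns_geometric <- function(x, y = NULL, segment_length = 5,
                                   angle_threshold = 20) {
  if (is.null(y)) {
    stopifnot(inherits(x, "trajectory"))
    y <- x$mid_y
    x <- x$mid_x
  }
  pts <- resample_arclength(x, y, segment_length)
  if (nrow(pts) < 3L) {
    return(data.frame(x = numeric(0), y = numeric(0), angle = numeric(0),
                      arc_index = integer(0)))
  }
  vx <- diff(pts[, "x"]); vy <- diff(pts[, "y"])
  n_seg <- length(vx)
  ang <- numeric(n_seg - 1L)
  for (i in seq_len(n_seg - 1L)) {
    c_ <- (vx[i] * vx[i + 1] + vy[i] * vy[i + 1]) /
      (sqrt(vx[i]^2 + vy[i]^2) * sqrt(vx[i + 1]^2 + vy[i + 1]^2))
    ang[i] <- acos(pmin(pmax(c_, -1), 1)) * 180 / pi
  }
  over <- ang > angle_threshold
  if (!any(over)) {
    return(data.frame(x = numeric(0), y = numeric(0), angle = numeric(0),
                      arc_index = integer(0)))
  }
  ## merge contiguous detections, keep the max-angle vertex of each block
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  idx <- vapply(keep, function(k) {
    block <- starts[k]:ends[k]
    block[which.max(ang[block])]
  }, 0L)
  vert <- idx + 1L  # angle i is at resampled vertex i+1
  data.frame(x = pts[vert, "x"], y = pts[vert, "y"], angle = ang[idx],
             arc_index = vert)
}

#' Runs from a state sequence or turn list
#'
#' Converts a per-frame run/non-run classification into a [run_ensemble()]:
#' maximal stretches of `run` frames become runs; a run is marked
#' turn-terminated when it is followed by a non-run episode, and censored
#' when it reaches the end of the trajectory.
#'
#' @param states character vector from [classify_states()].
#' @param dt frame interval (s).
#' @param inputs optional full-session numeric trace from which per-run
#'   input traces are cut.
#' @param min_duration minimum run duration (s) retained.
#' @return A [run_ensemble()] with attribute `frames` (start/end frame per
#'   retained run).
#' @export
runs_from_states <- function(states, dt = 1 / 30, inputs = NULL,
                             min_duration = 1) {
  r <- rle(states == "run")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) {
    return(run_ensemble(numeric(0), logical(0), dt = dt,
                        min_duration = min_duration))
  }
  dur <- r$lengths[runs] * dt
  terminal <- ends[runs] < length(states)
  tr <- if (!is.null(inputs)) {
    lapply(runs, function(k) inputs[starts[k]:ends[k]])
  }
  keep <- dur >= min_duration
  out <- run_ensemble(dur, terminal, inputs = tr, dt = dt,
                      min_duration = min_duration)
  attr(out, "frames") <- data.frame(start = starts[runs][keep],
                                    end = ends[runs][keep])
  out
}
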