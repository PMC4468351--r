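#' Ramp stimulus specification
#'
#' Describes one member of the ramp families used to probe the OSN: a rise
#' from `min_intensity` to `max_intensity` following a named temporal
#' profile, then a fall back to the minimum. The rising profiles are, on
#' normalized time s = 8 t / rise_duration (so that the printed forms apply
#' to the canonical 8-s ramps):
#' linear (s), exponential (e^-8 (e^s - 1)), sigmoid (s^3/(s^3 + 4^3)),
#' quadratic (s^2) and asymptotic (1 - e^(-3 s / 8)). Each profile is
#' normalized so that its value at the end of the rise maps to
#' `max_intensity`. The quadratic and asymptotic shapes are surrogate forms:
#' they are only required to exercise the transduction model with convex and
#' saturating accelerations, respectively.
#'
#' @param shape one of `"linear"`, `"exponential"`, `"sigmoid"`,
#'   `"quadratic"`, `"asymptotic"`.
#' @param rise_duration,fall_duration durations (s) of the rising and
#'   falling phases; `fall_duration = 0` gives an abrupt return to the
#'   minimum (the profile of the "well" landscape transect).
#' @param min_intensity,max_intensity intensity bounds; `max > min >= 0`.
#' @param modality `"light"` or `"odor"`.
#' @param fall_shape profile of the falling phase (time-mirrored); defaults
#'   to the rising shape.
#' @return A `ramp_spec` list.
#' @export
ramp_spec <- function(shape = c("linear", "exponential", "sigmoid",
                                "quadratic", "asymptotic"),
                      rise_duration = 8, fall_duration = rise_duration,
                      min_intensity = 15, max_intensity = 207,
                      modality = c("light", "odor"),
                      fall_shape = NULL) {
  shape <- match.arg(shape)
  modality <- match.arg(modality)
  if (rise_duration <= 0) stop("rise_duration must be positive")
  if (fall_duration < 0) stop("fall_duration must be nonnegative")
  if (!(max_intensity > min_intensity && min_intensity >= 0)) {
    stop("need max_intensity > min_intensity >= 0")
  }
  if (is.null(fall_shape)) fall_shape <- shape
  structure(list(shape = shape, rise_duration = rise_duration,
                 fall_duration = fall_duration,
                 min_intensity = min_intensity,
                 max_intensity = max_intensity,
                 modality = modality, fall_shape = fall_shape),
            class = "ramp_spec")
}

## raw (unnormalized) rising profiles on canonical time s in [0, 8]
ramp_profile_raw <- function(shape, s) {
  switch(shape,
         linear      = s,
         exponential = exp(-8) * (exp(s) - 1),
         sigmoid     = s^3 / (s^3 + 4^3),
         quadratic   = s^2,
         asymptotic  = 1 - exp(-3 * s / 8),
         stop(sprintf("unknown ramp shape '%s'", shape)))
}

## normalized profile: 0 at phase start, 1 at phase end, on t in [0, duration]
ramp_profile <- function(shape, t, duration) {
  s <- 8 * t / duration
  ramp_profile_raw(shape, s) / ramp_profile_raw(shape, 8)
}

#' Generate a ramp stimulus trace
#'
#' Builds the stimulus waveform described by a [ramp_spec()]: baseline
#' padding, the rising profile, the (mirrored) falling profile, and trailing
#' baseline. The trace is continuous except when `fall_duration = 0`, where
#' the intensity drops abruptly to the minimum.
#'
#' @param spec a [ramp_spec()].
#' @param dt sampling interval (s), default 1/30 (the tracker frame rate).
#' @param pad_before,pad_after baseline padding (s) before the rise and after
#'   the fall.
#' @return A [stimulus_trace()].
#' @export
make_ramp <- function(spec, dt = 1 / 30, pad_before = 2, pad_after = 6) {
  stopifnot(inherits(spec, "ramp_spec"))
  if (dt <= 0) stop("dt must be positive")
  total <- pad_before + spec$rise_duration + spec$fall_duration + pad_after
  tt <- seq(0, total, by = dt)
  x <- ramp_value(spec, tt - pad_before)
  stimulus_trace(tt, x, modality = spec$modality,
                 baseline = spec$min_intensity)
}

## intensity of the ramp at time s relative to the start of the rise;
## vectorized, baseline outside the stimulation episode
ramp_value <- function(spec, s) {
  lo <- spec$min_intensity
  amp <- spec$max_intensity - spec$min_intensity
  x <- rep(lo, length(s))
  rising <- s > 0 & s <= spec$rise_duration
  x[rising] <- lo + amp * ramp_profile(spec$shape, s[rising],
                                       spec$rise_duration)
  if (spec$fall_duration > 0) {
    falling <- s > spec$rise_duration &
      s <= spec$rise_duration + spec$fall_duration
    x[falling] <- lo + amp *
      ramp_profile(spec$fall_shape,
                   spec$rise_duration + spec$fall_duration - s[falling],
                   spec$fall_duration)
  }
  x
}

#' The canonical ramp families
#'
#' Returns the list of ten [ramp_spec()]s used to characterize and fit the
#' OSN response. All five 4-s linear ramps keep a 4-s rising phase; the
#' "low"/"high" members halve/double the medium rising slope by scaling the
#' peak (peaks at 1/4, 1/2 and the full intensity range), while
#' "slow"/"fast" share the medium rise and halve/double the falling slope
#' (8-s and 2-s falls). The 8-s family adds the linear, quadratic,
#' exponential, sigmoid and asymptotic shapes over the full range.
#'
#' @param modality `"light"` (15-207 W/m^2) or `"odor"` (52-522 uM).
#' @return Named list of `ramp_spec` objects.
#' @export
ramp_suite <- function(modality = c("light", "odor")) {
  modality <- match.arg(modality)
  lo <- if (modality == "light") 15 else 52
  hi <- if (modality == "light") 207 else 522
  q1 <- lo + (hi - lo) / 4
  mid <- lo + (hi - lo) / 2
  list(
    linear4_low  = ramp_spec("linear", 4, 4, lo, q1, modality),
    linear4_med  = ramp_spec("linear", 4, 4, lo, mid, modality),
    linear4_high = ramp_spec("linear", 4, 4, lo, hi, modality),
    linear4_slow = ramp_spec("linear", 4, 8, lo, mid, modality),
    linear4_fast = ramp_spec("linear", 4, 2, lo, mid, modality),
    linear8      = ramp_spec("linear", 8, 8, lo, hi, modality),
    quadratic    = ramp_spec("quadratic", 8, 8, lo, hi, modality),
    exponential  = ramp_spec("exponential", 8, 8, lo, hi, modality),
    sigmoid      = ramp_spec("sigmoid", 8, 8, lo, hi, modality),
    asymptotic   = ramp_spec("asymptotic", 8, 8, lo, hi, modality)
  )
}

## ---------------------------------------------------------------------------

#' De Bruijn stimulus sequence for reverse correlation
#'
#' Builds a maximum-coverage pseudorandom stimulus: a de Bruijn sequence
#' B(k, `order`) over the supplied intensity levels, in which every ordered
#' `order`-tuple of levels occurs exactly once cyclically. With the default
#' five levels and order 4 this gives 5^4 = 625 symbols, each held for
#' `step` seconds.
#'
#' @param levels intensity levels (>= 2 distinct values).
#' @param step hold time per symbol (s), default 33 ms.
#' @param order tuple length covered exhaustively (default 4).
#' @param seed optional integer; controls the rotation of the cyclic
#'   sequence.
#' @param dt sampling interval of the returned trace.
#' @param modality passed to [stimulus_trace()].
#' @return A [stimulus_trace()] with attribute `symbols` (the level index
#'   sequence).
#' @export
make_msequence <- function(levels = c(15, 50, 100, 150, 207), step = 0.033,
                           order = 4, seed = NULL, dt = step,
                           modality = "light") {
  levels <- as.numeric(levels)
  if (length(unique(levels)) < 2L) stop("need at least 2 distinct levels")
  if (step <= 0) stop("step must be positive")
  k <- length(levels)
  seq_idx <- de_bruijn(k, order)
  if (!is.null(seed)) {
    rot <- (seed %% length(seq_idx))
    if (rot > 0) seq_idx <- c(seq_idx[-seq_len(rot)], seq_idx[seq_len(rot)])
  }
  n_per <- max(1L, round(step / dt))
  x <- rep(levels[seq_idx], each = n_per)
  tt <- seq_along(x) * dt - dt
  out <- stimulus_trace(tt, x, modality = modality, baseline = x[1])
  attr(out, "symbols") <- seq_idx
  attr(out, "step") <- step
  out
}

## standard "prefer-largest" greedy de Bruijn construction: B(k, n) via
## Lyndon word concatenation (Fredricksen & Maiorana)
de_bruijn <- function(k, n) {
  a <- integer(k * n)
  sequence <- integer(0)
  db <- function(t, p) {
    if (t > n) {
      if (n %% p == 0L) sequence <<- c(sequence, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j <= k - 1L) {
        a[t + 1L] <<- j
        db(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  sequence + 1L
}

## ---------------------------------------------------------------------------

#' Stimulus experienced along a trajectory
#'
#' Replays the sensory experience of a larva moving through an intensity
#' landscape: the landscape is sampled by bilinear interpolation at the
#' chosen body point for every frame.
#'
#' @param traj a trajectory data frame (see [trajectory()]).
#' @param landscape a [make_landscape()] object.
#' @param point `"head"` or `"midpoint"`.
#' @return A [stimulus_trace()] on the trajectory's frame grid.
#' @export
replay_from_trajectory <- function(traj, landscape,
                                   point = c("head", "midpoint")) {
  point <- match.arg(point)
  if (point == "head") {
    xs <- traj$head_x; ys <- traj$head_y
  } else {
    xs <- traj$mid_x; ys <- traj$mid_y
  }
  x <- numeric(nrow(traj))
  for (i in seq_len(nrow(traj))) {
    v <- tryCatch(sample_intensity(landscape, c(xs[i], ys[i])),
                  error = function(e) NA_real_)
    if (is.na(v)) {
      stop(sprintf("trajectory leaves the landscape grid at frame %d", i))
    }
    x[i] <- v
  }
  stimulus_trace(traj$t, x, modality = landscape$modality, baseline = x[1])
}

#' Smoothed stimulus derivative
#'
#' Differentiates a stimulus after mild Savitzky-Golay smoothing. For GLM
#' controls the raw single-frame backward difference (change over the 33-ms
#' frame preceding each time point, expressed per second) is also available.
#'
#' @param trace a [stimulus_trace()] (or any data frame with `t`, `x`).
#' @param method `"savgol"` (smooth, central) or `"frame"` (single-frame
#'   backward difference).
#' @param window,degree Savitzky-Golay window (odd number of samples) and
#'   polynomial degree.
#' @return Data frame with columns `t` and `dxdt` (intensity units per s).
#' @export
stimulus_derivative <- function(trace, method = c("savgol", "frame"),
                                window = 15, degree = 3) {
  method <- match.arg(method)
  n <- nrow(trace)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  dt <- trace_dt(trace)
  if (method == "frame") {
    dxdt <- c(0, diff(trace$x)) / dt
  } else {
    window <- min(window, if (n %% 2L == 1L) n else n - 1L)
    if (window %% 2L == 0L) window <- window - 1L
    xs <- if (window >= degree + 2) {
      signal::sgolayfilt(trace$x, p = min(degree, window - 2L), n = window)
    } else trace$x
    dxdt <- c(xs[2] - xs[1], (xs[-(1:2)] - xs[-((n - 1):n)]) / 2,
              xs[n] - xs[n - 1]) / dt
  }
  data.frame(t = trace$t, dxdt = dxdt)
}

#' Run-gated open-loop stimulation protocol
#'
#' Reconstructs the stimulus delivered under the open-loop paradigm: while a
#' larva is in a run, a predefined temporal ramp is played from the run
#' onset; as soon as the run is interrupted the intensity is reset to the
#' baseline. Runs assigned to the control condition receive constant
#' baseline light.
#'
#' @param run_events data frame with columns `start`, `end` (s) and
#'   optionally logical `control`; runs must not overlap.
#' @param ramp the test [stimulus_trace()], played from each run's onset
#'   (its own leading baseline padding should be zero; see
#'   `pad_before = 0` in [make_ramp()]).
#' @param baseline intensity between runs and for control runs
#'   (15 W/m^2 in the light paradigm).
#' @param duration total protocol duration (s); default covers the last run.
#' @param dt sampling interval.
#' @return A [stimulus_trace()] for the whole session.
#' @export
open_loop_protocol <- function(run_events, ramp, baseline = 15,
                               duration = NULL, dt = 1 / 30) {
  ev <- run_events[order(run_events$start), , drop = FALSE]
  if (nrow(ev) > 1L && any(ev$start[-1] < ev$end[-nrow(ev)])) {
    stop("runs overlap")
  }
  if (is.null(ev$control)) ev$control <- FALSE
  if (is.null(duration)) duration <- max(ev$end) + 1
  tt <- seq(0, duration, by = dt)
  x <- rep(baseline, length(tt))
  ramp_fun <- stats::approxfun(ramp$t, ramp$x, rule = 2)
  for (i in seq_len(nrow(ev))) {
    if (ev$control[i]) next
    sel <- tt >= ev$start[i] & tt < ev$end[i]
    x[sel] <- ramp_fun(tt[sel] - ev$start[i])
  }
  stimulus_trace(tt, x, modality = attr(ramp, "modality"),
                 baseline = baseline)
}

#' Gas- to liquid-phase odor concentration conversion
#'
#' The transduction model is parameterized for liquid-phase stimulation of
#' the dorsal organ; airborne concentrations are mapped onto the equivalent
#' liquid-phase scale with the calibration scalar rho(liquid->gas) = 26.73.
#'
#' @param x_gas gas-phase concentration(s), uM; must be nonnegative.
#' @return Liquid-phase equivalent concentration(s), uM.
#' @export
gas_to_liquid <- function(x_gas) {
  if (any(x_gas < 0)) stop("gas-phase concentration must be nonnegative")
  26.73 * x_gas
}
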