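#' Transduction model parameters
#'
#' Parameters of the phenomenological olfactory transduction ODE. The model
#' has three variables: the stimulus intensity x (input), an intermediate
#' variable u (possibly intracellular calcium; units undefined, which is why
#' alpha1 is fixed at 0.1 for the pure IFF model), and the OSN firing rate y
#' (Hz, output). Three regulatory pathways produce or remove u:
#' \itemize{
#'   \item IFF production: du/dt gains `alpha1 * x` (incoherent feed-forward
#'     — the stimulus both excites y directly and, via u, inhibits it);
#'   \item first-order decay `- alpha2 * u`;
#'   \item IFB production: `alpha3 * y` (integral feedback — the output
#'     drives its own inhibitor).
#' }
#' The firing rate obeys
#' `dy/dt = beta1*x/(beta2 + x + beta3*u) - beta4(t)*y^n/(y^n + theta'(t)^n)
#'  - beta5*y`:
#' a saturating depolarizing drive divided down by u, a constitutive offset
#' decay gated by a Hill term (exponent `n`, threshold `theta`), and a
#' first-order decay.
#'
#' Two slow corrections improve long-recording fits and are applied by
#' default (see [apply_corrections()]): the offset amplitude beta4 grows by
#' 2.3% on a 30-s timescale, and the Hill threshold relaxes as
#' `theta * (30/t)^2` for t > 30 s.
#'
#' The default parameter sets are the fitted columns for light-driven
#' (pure IFF), odor-driven pure IFF, and odor-driven composite IFF+IFB
#' stimulation.
#'
#' @param preset `"light_iff"`, `"odor_iff"` or `"odor_iff_ifb"` for the
#'   fitted defaults, or `NULL` to pass every value explicitly.
#' @param alpha1,alpha2,alpha3,beta1,beta2,beta3,beta4,beta5,theta,n model
#'   parameters (all >= 0, `n >= 1`); override individual preset values.
#' @param modality `"light"` or `"odor"`.
#' @param variant `"IFF"`, `"IFB"`, or `"IFF_IFB"`. For `"IFF"` the alpha3
#'   pathway is dropped; for `"IFB"` the alpha1 pathway is dropped.
#' @param corrections_enabled apply the slow beta4/theta corrections.
#' @return A `transduction_params` list.
#' @export
transduction_params <- function(preset = c("light_iff", "odor_iff",
                                           "odor_iff_ifb"),
                                alpha1 = NULL, alpha2 = NULL, alpha3 = NULL,
                                beta1 = NULL, beta2 = NULL, beta3 = NULL,
                                beta4 = NULL, beta5 = NULL, theta = NULL,
                                n = NULL, modality = NULL, variant = NULL,
                                corrections_enabled = TRUE) {
  presets <- list(
    light_iff = list(alpha1 = 0.1, alpha2 = 0.88, alpha3 = 0,
                     beta1 = 1731.41, beta2 = 1.27, beta3 = 2.48,
                     beta4 = 1214.08, beta5 = 13.03, theta = 0.3, n = 2,
                     modality = "light", variant = "IFF"),
    odor_iff = list(alpha1 = 0.1, alpha2 = 0.6, alpha3 = 0,
                    beta1 = 1002.25, beta2 = 8.63, beta3 = 2.39,
                    beta4 = 624.69, beta5 = 6.44, theta = 1.01, n = 2,
                    modality = "odor", variant = "IFF"),
    odor_iff_ifb = list(alpha1 = 0.13, alpha2 = 0.26, alpha3 = 1.1,
                        beta1 = 2903.36, beta2 = 0.01, beta3 = 2.65,
                        beta4 = 795.62, beta5 = 23.79, theta = 1.88, n = 2,
                        modality = "odor", variant = "IFF_IFB")
  )
  p <- if (is.null(preset)) {
    list(alpha1 = 0.1, alpha2 = 1, alpha3 = 0, beta1 = 1000, beta2 = 1,
         beta3 = 1, beta4 = 100, beta5 = 10, theta = 1, n = 2,
         modality = "light", variant = "IFF")
  } else {
    presets[[match.arg(preset)]]
  }
  override <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                   beta1 = beta1, beta2 = beta2, beta3 = beta3,
                   beta4 = beta4, beta5 = beta5, theta = theta, n = n,
                   modality = modality, variant = variant)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) p[[nm]] <- override[[nm]]
  }
  p$variant <- match.arg(p$variant, c("IFF", "IFB", "IFF_IFB"))
  p$modality <- match.arg(p$modality, c("light", "odor"))
  p$corrections_enabled <- isTRUE(corrections_enabled)
  num <- c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3",
           "beta4", "beta5", "theta", "n")
  if (any(unlist(p[num]) < 0)) stop("all parameters must be nonnegative")
  if (p$n < 1) stop("Hill exponent n must be >= 1")
  structure(p, class = "transduction_params")
}

#' Slow corrections of the offset-decay parameters
#'
#' The offset amplitude beta4 undergoes a small slow increase,
#' `beta4_eff(t) = (1 + 0.023 t^4/(t^4 + 30^4)) * beta4`, and the Hill
#' threshold relaxes for long recordings, `theta_eff = theta * (30/t)^2` for
#' t > 30 s. Both are bypassed when `corrections_enabled` is `FALSE`.
#'
#' @param params a [transduction_params()].
#' @param t time since stimulus onset (s), scalar or vector, >= 0.
#' @return List with numeric `beta4_eff` and `theta_eff`.
#' @export
apply_corrections <- function(params, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (!isTRUE(params$corrections_enabled)) {
    return(list(beta4_eff = rep(params$beta4, length(t)),
                theta_eff = rep(params$theta, length(t))))
  }
  tau <- 30
  b4 <- (1 + 0.023 * t^4 / (t^4 + tau^4)) * params$beta4
  th <- ifelse(t > tau, params$theta * (tau / t)^2, params$theta)
  list(beta4_eff = b4, theta_eff = th)
}

## effective alpha1/alpha3 under the variant
variant_alphas <- function(params) {
  a1 <- if (params$variant == "IFB") 0 else params$alpha1
  a3 <- if (params$variant == "IFF") 0 else params$alpha3
  c(a1 = a1, a3 = a3)
}

#' Right-hand side of the transduction ODE
#'
#' @param state numeric `c(u, y)`.
#' @param x stimulus intensity (scalar, >= 0).
#' @param t time (s), used by the slow corrections.
#' @param params a [transduction_params()].
#' @return Numeric `c(du, dy)` (derivatives per second).
#' @export
transduction_rhs <- function(state, x, t, params) {
  if (x < 0) stop("stimulus intensity must be nonnegative")
  u <- state[[1]]
  y <- max(state[[2]], 0)
  a <- variant_alphas(params)
  cc <- apply_corrections(params, t)
  du <- a[["a1"]] * x + a[["a3"]] * y - params$alpha2 * u
  hill <- if (y > 0) y^params$n / (y^params$n + cc$theta_eff^params$n) else 0
  dy <- params$beta1 * x / (params$beta2 + x + params$beta3 * u) -
    cc$beta4_eff * hill - params$beta5 * y
  c(du, dy)
}

#' Integrate the transduction model against a stimulus
#'
#' Solves the two-variable ODE on the stimulus grid. The stimulus is
#' interpolated linearly between samples. Two integrators are available: a
#' stiff implicit solver (`deSolve::ode`, lsoda, rtol 1e-6 / atol 1e-8; the
#' reference) and a fast fixed-step classical Runge-Kutta scheme stepping
#' once per stimulus sample (used inside parameter fitting, where the
#' 33-ms grid resolves the fastest ~1/beta5 time constant comfortably).
#'
#' @param params a [transduction_params()].
#' @param stimulus a [stimulus_trace()].
#' @param init `"steady_state"` (default: the fixed point at the stimulus
#'   baseline — recordings start under sustained baseline flow), `"zero"`,
#'   or a numeric `c(u, y)`.
#' @param method `"lsoda"` or `"rk4"`.
#' @param rtol,atol solver tolerances for `"lsoda"`.
#' @return Data frame with columns `t`, `x`, `u`, `y` (class
#'   `transduction_solution`).
#' @export
integrate_transduction <- function(params, stimulus, init = "steady_state",
                                   method = c("lsoda", "rk4"),
                                   rtol = 1e-6, atol = 1e-8) {
  method <- match.arg(method)
  tt <- stimulus$t
  xx <- stimulus$x
  state0 <- resolve_init(params, stimulus, init)
  if (method == "rk4") {
    sol <- integrate_rk4(params, tt, xx, state0)
  } else {
    xfun <- stats::approxfun(tt, xx, rule = 2)
    f <- function(t, st, parms) {
      list(transduction_rhs(st, xfun(t), t, params))
    }
    out <- deSolve::ode(y = state0, times = tt, func = f, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0) {
      stop("ODE solver failed: ", paste(attr(out, "istate"), collapse = " "))
    }
    sol <- list(u = out[, 2], y = out[, 3])
  }
  res <- data.frame(t = tt, x = xx, u = sol$u, y = pmax(sol$y, 0))
  class(res) <- c("transduction_solution", "data.frame")
  res
}

resolve_init <- function(params, stimulus, init) {
  if (is.numeric(init)) {
    stopifnot(length(init) == 2L)
    return(as.numeric(init))
  }
  init <- match.arg(init, c("steady_state", "zero"))
  if (init == "zero") return(c(0, 0))
  ss <- steady_state(params, attr(stimulus, "baseline") %||% stimulus$x[1],
                     t_ref = 0)
  c(ss$u, ss$y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## fixed-grid RK4 over the stimulus samples, with adaptive substepping where
## the Hill gate of the offset decay makes the y-equation locally stiff
## (its Jacobian peaks at beta4 * 0.6495/theta near y = theta/sqrt(3)).
## x (and the slow corrections) are interpolated linearly within a frame.
integrate_rk4 <- function(params, tt, xx, state0) {
  a <- variant_alphas(params)
  a1 <- a[["a1"]]; a3 <- a[["a3"]]; a2 <- params$alpha2
  b1 <- params$beta1; b2 <- params$beta2; b3 <- params$beta3
  b5 <- params$beta5; nn <- params$n
  n_t <- length(tt)
  cc <- apply_corrections(params, tt)
  b4v <- cc$beta4_eff; thv <- cc$theta_eff
  u <- numeric(n_t); y <- numeric(n_t)
  u[1] <- state0[1]; y[1] <- max(state0[2], 0)
  l_stiff <- 0.6495 * max(b4v) / max(min(thv), 1e-3) + b5 + a2
  for (i in seq_len(n_t - 1L)) {
    h_f <- tt[i + 1L] - tt[i]
    ## substep count from the stiffness along this frame's excursion: the
    ## Hill gate's Jacobian peaks near y ~ theta/sqrt(3), so the full
    ## worst-case rate l_stiff is only needed when the frame can reach
    ## that band (cheap Euler probe); elsewhere the local Jacobian rules
    th_i <- thv[i]
    yi0 <- y[i]
    hill0 <- if (yi0 > 0) yi0^nn / (yi0^nn + th_i^nn) else 0
    dy0 <- b1 * xx[i] / (b2 + xx[i] + b3 * u[i]) - b4v[i] * hill0 -
      b5 * yi0
    y_lo <- max(min(yi0, yi0 + h_f * dy0), 0)
    lam <- if (y_lo < 8 * th_i) l_stiff else {
      b4v[i] * (nn * th_i^nn * y_lo^(nn - 1) / (y_lo^nn + th_i^nn)^2) +
        b5 + a2
    }
    m <- min(max(ceiling(h_f * lam / 1.5), 1L), 150L)
    ui <- u[i]; yi <- y[i]
    dx <- xx[i + 1L] - xx[i]
    db4 <- b4v[i + 1L] - b4v[i]
    dth <- thv[i + 1L] - thv[i]
    if (m > 16L) {
      ## heavily stiff frame (y dwelling on the steep Hill flank): a
      ## semi-implicit scheme — explicit nonstiff u, implicit Euler with
      ## Newton iterations on the stiff y equation — is far cheaper than
      ## resolving the flank explicitly
      m2 <- 12L
      h <- h_f / m2
      for (s in seq_len(m2)) {
        f1 <- s / m2; fm <- f1 - 0.5 / m2
        xm2 <- xx[i] + fm * dx; b4m2 <- b4v[i] + fm * db4
        thm2 <- thv[i] + fm * dth
        yp <- if (yi > 0) yi else 0
        ui_new <- ui + h * (a1 * xm2 + a3 * yp - a2 * ui)
        D <- b1 * xm2 / (b2 + xm2 + b3 * (ui + ui_new) / 2)
        Y <- yp
        for (it in 1:3) {
          Yp <- if (Y > 0) Y else 1e-12
          hillY <- Yp^nn / (Yp^nn + thm2^nn)
          fY <- Y - yp - h * (D - b4m2 * hillY - b5 * Y)
          dfY <- 1 + h * (b4m2 * nn * thm2^nn * Yp^(nn - 1) /
                            (Yp^nn + thm2^nn)^2 + b5)
          Y <- Y - fY / dfY
        }
        yi <- if (Y > 0) Y else 0
        ui <- ui_new
      }
      u[i + 1L] <- ui
      y[i + 1L] <- yi
      next
    }
    h <- h_f / m
    for (s in seq_len(m)) {
      f0 <- (s - 1) / m; fm <- f0 + 0.5 / m; f1 <- s / m
      x0 <- xx[i] + f0 * dx; xm <- xx[i] + fm * dx; x1 <- xx[i] + f1 * dx
      b40 <- b4v[i] + f0 * db4; b4m <- b4v[i] + fm * db4
      b41 <- b4v[i] + f1 * db4
      th0 <- thv[i] + f0 * dth; thm <- thv[i] + fm * dth
      th1 <- thv[i] + f1 * dth
      ## k1
      yp <- if (yi > 0) yi else 0
      k1u <- a1 * x0 + a3 * yp - a2 * ui
      k1y <- b1 * x0 / (b2 + x0 + b3 * ui) -
        (if (yp > 0) b40 * yp^nn / (yp^nn + th0^nn) else 0) - b5 * yp
      ## k2
      u2 <- ui + h / 2 * k1u; y2 <- yi + h / 2 * k1y
      yp <- if (y2 > 0) y2 else 0
      k2u <- a1 * xm + a3 * yp - a2 * u2
      k2y <- b1 * xm / (b2 + xm + b3 * u2) -
        (if (yp > 0) b4m * yp^nn / (yp^nn + thm^nn) else 0) - b5 * yp
      ## k3
      u3 <- ui + h / 2 * k2u; y3 <- yi + h / 2 * k2y
      yp <- if (y3 > 0) y3 else 0
      k3u <- a1 * xm + a3 * yp - a2 * u3
      k3y <- b1 * xm / (b2 + xm + b3 * u3) -
        (if (yp > 0) b4m * yp^nn / (yp^nn + thm^nn) else 0) - b5 * yp
      ## k4
      u4 <- ui + h * k3u; y4 <- yi + h * k3y
      yp <- if (y4 > 0) y4 else 0
      k4u <- a1 * x1 + a3 * yp - a2 * u4
      k4y <- b1 * x1 / (b2 + x1 + b3 * u4) -
        (if (yp > 0) b41 * yp^nn / (yp^nn + th1^nn) else 0) - b5 * yp
      ui <- ui + h / 6 * (k1u + 2 * k2u + 2 * k3u + k4u)
      yi <- yi + h / 6 * (k1y + 2 * k2y + 2 * k3y + k4y)
      if (yi < 0) yi <- 0
    }
    u[i + 1L] <- ui
    y[i + 1L] <- yi
  }
  list(u = u, y = y)
}

#' Fixed point of the transduction model at constant stimulus
#'
#' Solves `rhs = 0` for nonnegative (u, y) at a constant intensity. Because
#' the slow beta4 correction never plateaus exactly, corrections are
#' evaluated at a fixed reference time (default 24 s, the end of the
#' dose-response measurement window).
#'
#' @param params a [transduction_params()].
#' @param x constant stimulus intensity (>= 0).
#' @param t_ref reference time (s) at which the corrections are evaluated.
#' @return List with elements `u` and `y`.
#' @export
steady_state <- function(params, x, t_ref = 24) {
  if (x < 0) stop("stimulus intensity must be nonnegative")
  a <- variant_alphas(params)
  cc <- apply_corrections(params, t_ref)
  if (x == 0) return(list(u = 0, y = 0))
  f <- function(y) {
    u <- (a[["a1"]] * x + a[["a3"]] * y) / params$alpha2
    params$beta1 * x / (params$beta2 + x + params$beta3 * u) -
      cc$beta4_eff * y^params$n / (y^params$n + cc$theta_eff^params$n) -
      params$beta5 * y
  }
  y_max <- params$beta1 * x / (params$beta2 + x) / params$beta5
  if (f(0) < 0) {
    ## drive cannot lift y off zero against the decay terms
    return(list(u = a[["a1"]] * x / params$alpha2, y = 0))
  }
  if (f(y_max + 1e-9) > 0) stop("no nonnegative steady state found")
  y <- stats::uniroot(f, c(0, y_max + 1e-9), tol = 1e-10)$root
  list(u = (a[["a1"]] * x + a[["a3"]] * y) / params$alpha2, y = y)
}

#' Pathway decomposition of the intermediate-variable dynamics
#'
#' Integrates the composite IFF+IFB model and decomposes du/dt into its
#' three pathways: (1) IFF production `alpha1 * x`, (2) decay `alpha2 * u`,
#' (3) IFB production `alpha3 * y`. The IFB/IFF ratio summarizes the
#' relative contribution of the feedback pathway to the dynamics of u: each
#' production trace is referenced to its pre-stimulus baseline (the standing
#' baseline production does not contribute to the evoked dynamics) and the
#' ratio of the time-averaged evoked modulations is taken over the
#' stimulation episode. The raw ratio of the unreferenced time averages is
#' returned alongside.
#'
#' @param params composite (`variant = "IFF_IFB"`) [transduction_params()].
#' @param stimulus a [stimulus_trace()]; the stimulation episode is the set
#'   of samples where the intensity exceeds the baseline (closed between the
#'   first and last such sample).
#' @param ... passed to [integrate_transduction()].
#' @return List with the solution, a data frame `pathways` (columns `t`,
#'   `iff`, `decay`, `ifb`), `ifb_iff_ratio`, and `ifb_iff_ratio_raw`.
#' @export
pathway_contributions <- function(params, stimulus, ...) {
  if (params$variant != "IFF_IFB") {
    stop("pathway decomposition requires the composite IFF_IFB variant")
  }
  sol <- integrate_transduction(params, stimulus, ...)
  p1 <- params$alpha1 * sol$x
  p2 <- params$alpha2 * sol$u
  p3 <- params$alpha3 * sol$y
  base <- attr(stimulus, "baseline")
  above <- which(sol$x > base + 1e-9 * max(base, 1))
  stim <- if (length(above)) seq(min(above), max(above)) else seq_len(nrow(sol))
  ratio_raw <- mean(p3[stim]) / mean(p1[stim])
  ratio <- (mean(p3[stim]) - p3[1]) / (mean(p1[stim]) - p1[1])
  list(solution = sol,
       pathways = data.frame(t = sol$t, iff = p1, decay = p2, ifb = p3),
       ifb_iff_ratio = ratio,
       ifb_iff_ratio_raw = ratio_raw)
}

#' Predicted firing rate for gas-phase odor stimulation
#'
#' Converts a gas-phase concentration time course to its liquid-phase
#' equivalent ([gas_to_liquid()], factor 26.73) and integrates the
#' liquid-phase transduction model.
#'
#' @param params odor-modality [transduction_params()] (liquid-phase fit).
#' @param stimulus_gas gas-phase odor [stimulus_trace()].
#' @param ... passed to [integrate_transduction()].
#' @return A `transduction_solution` (on the liquid-phase intensity scale).
#' @export
predict_rate_for_gas <- function(params, stimulus_gas, ...) {
  if (!identical(params$modality, "odor") ||
      !identical(attr(stimulus_gas, "modality"), "odor")) {
    stop("gas-to-liquid prediction applies to odor stimulation only")
  }
  liq <- stimulus_trace(stimulus_gas$t, gas_to_liquid(stimulus_gas$x),
                        modality = "odor",
                        baseline = gas_to_liquid(attr(stimulus_gas,
                                                      "baseline")))
  integrate_transduction(params, liq, ...)
}
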