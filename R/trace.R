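#' Uniformly sampled stimulus time series
#'
#' A `stimulus_trace` is the basic input container of the package: a stimulus
#' intensity sampled on a uniform time grid. For light stimulation the
#' intensity is in W/m^2 (optogenetic drive of the Or42a>ChR2 OSN); for odor
#' stimulation it is a concentration in uM.
#'
#' @param t numeric vector of times (s), strictly increasing with constant
#'   step.
#' @param x numeric vector of intensities, same length as `t`; must be
#'   nonnegative.
#' @param modality `"light"` or `"odor"`.
#' @param baseline intensity at and before the first sample; defaults to
#'   `x[1]`.
#' @return An object of class `stimulus_trace`: a data frame with columns
#'   `t` and `x` and attributes `modality` and `baseline`.
#' @export
stimulus_trace <- function(t, x, modality = c("light", "odor"),
                           baseline = x[1]) {
  modality <- match.arg(modality)
  if (length(t) != length(x)) stop("`t` and `x` must have the same length")
  if (length(t) < 2L) stop("a stimulus trace needs at least two samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop("`t` must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8 * mean(dt)) {
    stop("`t` must be a uniform grid")
  }
  if (any(x < 0)) stop("stimulus intensity must be nonnegative")
  out <- data.frame(t = as.numeric(t), x = as.numeric(x))
  structure(out,
            class = c("stimulus_trace", "data.frame"),
            modality = modality,
            baseline = as.numeric(baseline))
}

#' Firing-rate time series
#'
#' Container for an OSN firing rate (a model prediction or a PSTH), with an
#' optional per-bin standard deviation used to weight model fits.
#'
#' @param t time grid (s).
#' @param rate firing rate (Hz), nonnegative.
#' @param std optional per-bin standard deviation (Hz) across trials.
#' @return An object of class `rate_trace` (a data frame).
#' @export
rate_trace <- function(t, rate, std = NULL) {
  if (length(t) != length(rate)) stop("`t` and `rate` lengths differ")
  out <- data.frame(t = as.numeric(t), rate = as.numeric(rate))
  if (!is.null(std)) {
    if (length(std) != length(t)) stop("`std` length differs from `t`")
    out$std <- as.numeric(std)
  }
  structure(out, class = c("rate_trace", "data.frame"))
}

trace_dt <- function(trace) {
  tt <- trace$t
  (tt[length(tt)] - tt[1]) / (length(tt) - 1L)
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("<stimulus_trace> %s, %d samples, dt = %.4g s, range [%.3g, %.3g] %s\n",
              attr(x, "modality"), nrow(x), trace_dt(x), min(x$x), max(x$x),
              if (identical(attr(x, "modality"), "light")) "W/m^2" else "uM"))
  invisible(x)
}

#' Read and write stimulus/rate traces as delimited text
#'
#' Traces are stored as 2-column (or 3-column, with std) tab-separated text
#' with a `#` header line naming the modality and units, so that files remain
#' readable by any plotting tool.
#'
#' @param trace a `stimulus_trace` or `rate_trace`.
#' @param path file path.
#' @rdname trace_io
#' @export
write_trace <- function(trace, path) {
  if (inherits(trace, "stimulus_trace")) {
    units <- if (identical(attr(trace, "modality"), "light")) "W/m^2" else "uM"
    header <- sprintf("# stimulus_trace modality=%s units=%s baseline=%.10g",
                      attr(trace, "modality"), units, attr(trace, "baseline"))
  } else {
    header <- "# rate_trace units=Hz"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(trace), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @rdname trace_io
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1L)
  dat <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (grepl("stimulus_trace", header)) {
    modality <- sub(".*modality=(\\w+).*", "\\1", header)
    baseline <- as.numeric(sub(".*baseline=([0-9.eE+-]+).*", "\\1", header))
    stimulus_trace(dat$t, dat$x, modality = modality, baseline = baseline)
  } else {
    rate_trace(dat$t, dat$rate, std = dat$std)
  }
}
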