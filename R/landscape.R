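#' Radially symmetric light landscapes
#'
#' Builds the virtual sensory landscapes used for closed-loop stimulation:
#' intensity matrices at 1 x 1 mm resolution, radially symmetric around a
#' center, engineered so that a larva crawling inward at 1 mm/s across the
#' 8-mm annulus between the foot and the rim experiences the 8-s
#' exponential rise (15 to 207 W/m^2). Inside the rim the profiles differ:
#' \describe{
#'   \item{exponential}{a broad point-source-like gradient,
#'     `I(r) = I_min + (I_max - I_min) exp(-r/decay_length)`, peaking at the
#'     center (rim radius 0). An inward transect is an exponential intensity
#'     rise with time constant `decay_length` seconds at 1 mm/s; the default
#'     4-mm decay length makes the gradient perceptible over the ~10-mm
#'     starting distance of the virtual-reality assay.}
#'   \item{volcano}{mirrored exponential fall back to the baseline at the
#'     center.}
#'   \item{well}{abrupt drop to the baseline (the only discontinuity in the
#'     family).}
#'   \item{mesa}{the maximum intensity is held over the whole central
#'     area.}
#'   \item{linear_hat}{gentle linear rise continuing to an apex at the
#'     center — a deceleration of the stimulus after the exponential rise.
#'     The default apex (1.15 x the rim intensity) exceeds the nominal
#'     range: what matters behaviorally is the sharp drop in d(intensity)/dt
#'     at the rim.}
#' }
#'
#' @param profile one of `"exponential"`, `"volcano"`, `"well"`, `"mesa"`,
#'   `"linear_hat"`.
#' @param i_min,i_max intensity bounds (W/m^2).
#' @param rim_radius radius (mm) at which the inward exponential rise ends
#'   (8 for the volcano/well/mesa/linear family; 0 for the exponential
#'   gradient).
#' @param annulus_width width (mm) of the rising annulus (8 mm = 8 s at
#'   1 mm/s).
#' @param half_width half-extent (mm) of the square grid.
#' @param resolution grid spacing (mm); 1 mm, matching the tracker's
#'   landscape representation.
#' @param hat_apex apex intensity of the linear hat.
#' @param decay_length radial decay length (mm) of the exponential
#'   gradient.
#' @param modality stored for replay bookkeeping.
#' @return A `landscape` list: `grid` (matrix), `xs`, `ys` (node
#'   coordinates, mm), `center`, `profile`, geometry fields.
#' @export
make_landscape <- function(profile = c("exponential", "volcano", "well",
                                       "mesa", "linear_hat"),
                           i_min = 15, i_max = 207,
                           rim_radius = NULL, annulus_width = 8,
                           half_width = 24, resolution = 1,
                           hat_apex = NULL, decay_length = 4,
                           modality = "light") {
  profile <- match.arg(profile)
  if (is.null(rim_radius)) {
    rim_radius <- if (profile == "exponential") 0 else 8
  }
  foot_radius <- rim_radius + annulus_width
  if (foot_radius > half_width) stop("grid too small for the landscape foot")
  if (annulus_width <= 0) stop("rim must lie inside the foot")
  if (is.null(hat_apex)) hat_apex <- i_max * 1.15
  xs <- seq(-half_width, half_width, by = resolution)
  ys <- xs
  rise <- function(r) {
    ## inward transect at 1 mm/s: time within the rise = foot_radius - r
    s <- 8 * (foot_radius - r) / annulus_width
    i_min + (i_max - i_min) * exp(-8) * (exp(s) - 1) / (1 - exp(-8))
  }
  radial <- function(r) {
    if (profile == "exponential") {
      return(i_min + (i_max - i_min) * exp(-r / decay_length))
    }
    v <- numeric(length(r))
    outside <- r >= foot_radius
    annulus <- r < foot_radius & r >= rim_radius
    inside <- r < rim_radius
    v[outside] <- i_min
    v[annulus] <- rise(r[annulus])
    v[inside] <- switch(profile,
      volcano = rise(rim_radius + (rim_radius - r[inside])),
      well = i_min,
      mesa = i_max,
      linear_hat = i_max + (hat_apex - i_max) *
        (rim_radius - r[inside]) / rim_radius)
    v
  }
  rr <- sqrt(outer(xs^2, ys^2, `+`))
  grid <- matrix(radial(as.vector(rr)), nrow = length(xs))
  structure(list(grid = grid, xs = xs, ys = ys, center = c(0, 0),
                 profile = profile, i_min = i_min, i_max = i_max,
                 rim_radius = rim_radius, foot_radius = foot_radius,
                 resolution = resolution, modality = modality),
            class = "landscape")
}

#' Bilinear landscape sampling
#'
#' Intensity at an arbitrary position, interpolated bilinearly between the
#' four surrounding 1-mm grid nodes (exact on the nodes, as in the tracker
#' software).
#'
#' @param landscape a [make_landscape()] object.
#' @param position numeric `c(x, y)` in mm, or an n x 2 matrix.
#' @return Intensity value(s).
#' @export
sample_intensity <- function(landscape, position) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  xs <- landscape$xs; ys <- landscape$ys
  res <- landscape$resolution
  if (any(pos[, 1] < xs[1] | pos[, 1] > xs[length(xs)] |
          pos[, 2] < ys[1] | pos[, 2] > ys[length(ys)])) {
    stop("position outside the landscape grid")
  }
  fx <- (pos[, 1] - xs[1]) / res
  fy <- (pos[, 2] - ys[1]) / res
  i0 <- pmin(floor(fx), length(xs) - 2L)
  j0 <- pmin(floor(fy), length(ys) - 2L)
  tx <- fx - i0
  ty <- fy - j0
  g <- landscape$grid
  idx <- function(i, j) g[cbind(i + 1L, j + 1L)]
  v <- (1 - tx) * (1 - ty) * idx(i0, j0) +
    tx * (1 - ty) * idx(i0 + 1L, j0) +
    (1 - tx) * ty * idx(i0, j0 + 1L) +
    tx * ty * idx(i0 + 1L, j0 + 1L)
  unname(v)
}

#' Write/read a landscape as plain-text matrix plus JSON sidecar
#' @param landscape a [make_landscape()] object.
#' @param path base path; writes `<path>.txt` and `<path>.json`.
#' @rdname landscape_io
#' @export
write_landscape <- function(landscape, path) {
  utils::write.table(landscape$grid, paste0(path, ".txt"),
                     row.names = FALSE, col.names = FALSE)
  meta <- landscape[c("profile", "i_min", "i_max", "rim_radius",
                      "foot_radius", "resolution", "modality")]
  meta$half_width <- max(landscape$xs)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
}

#' @rdname landscape_io
#' @export
read_landscape <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ls <- make_landscape(meta$profile, i_min = meta$i_min, i_max = meta$i_max,
                       rim_radius = meta$rim_radius,
                       annulus_width = meta$foot_radius - meta$rim_radius,
                       half_width = meta$half_width,
                       resolution = meta$resolution,
                       modality = meta$modality)
  ls$grid <- as.matrix(utils::read.table(paste0(path, ".txt")))
  dimnames(ls$grid) <- NULL
  ls
}
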