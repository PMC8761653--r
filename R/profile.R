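# Transverse intensity-profile primitives shared by vessel detection and
# RBC column-width measurement.
#
# Image convention used throughout the package: a frame is a numeric matrix
# with rows indexed by y and columns by x; the centre of pixel [i, j] sits at
# (x, y) = ((j - 0.5) * pixel_size_um, (i - 0.5) * pixel_size_um).

# Vectorised bilinear interpolation of frame intensities at physical
# coordinates (micrometres).  Points outside the frame are clamped to the
# border; callers that care about containment test with `in_frame()` first.
bilinear_sample <- function(frame, x_um, y_um, pixel_size_um) {
  nr <- nrow(frame)
  nc <- ncol(frame)
  cx <- x_um / pixel_size_um + 0.5
  cy <- y_um / pixel_size_um + 0.5
  cx <- pmin(pmax(cx, 1), nc)
  cy <- pmin(pmax(cy, 1), nr)
  c0 <- pmin(floor(cx), nc - 1L)
  r0 <- pmin(floor(cy), nr - 1L)
  fc <- cx - c0
  fr <- cy - r0
  i00 <- (c0 - 1L) * nr + r0
  v00 <- frame[i00]
  v10 <- frame[i00 + 1L]
  v01 <- frame[i00 + nr]
  v11 <- frame[i00 + nr + 1L]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

in_frame <- function(frame, x_um, y_um, pixel_size_um, margin_um = 0) {
  x_um >= margin_um & y_um >= margin_um &
    x_um <= ncol(frame) * pixel_size_um - margin_um &
    y_um <= nrow(frame) * pixel_size_um - margin_um
}

#' Full width of a dark profile at a fractional depth
#'
#' Computes the width of an intensity dip at `level` times its depth below the
#' local background: the distance between the two points, found by linear
#' interpolation around the profile minimum, where the profile crosses
#' `background - level * depth`.  With the default `level = 0.5` this is the
#' full width at half depth, the package's working definition of an RBC
#' column width and of a local vessel diameter.
#'
#' @param offsets_um Transverse offsets of the samples (micrometres), any
#'   order; typically centred on a vessel centerline.
#' @param values Intensities sampled at `offsets_um`.
#' @param background Local background intensity.  Default: median of the
#'   samples in the outer quarter of the offset range.
#' @param level Fractional depth at which the width is read, in (0, 1).
#' @return A list with elements `width_um`, `center_um` (midpoint of the two
#'   crossings), `depth` (background minus profile minimum), `background`,
#'   `truncated` (`TRUE` when a crossing was not reached inside the sampled
#'   window) and `found` (`FALSE` when the profile has no dip at all).
#' @examples
#' off <- seq(-10, 10, by = 0.25)
#' # trapezoidal dip: 6 um plateau, 2 um linear shoulders -> width 8 at half depth
#' prof <- 1 - 0.5 * pmin(pmax((5 - abs(off)) / 2, 0), 1)
#' half_depth_width(off, prof, background = 1)$width_um
#' @export
half_depth_width <- function(offsets_um, values, background = NULL,
                             level = 0.5) {
  stopifnot(length(offsets_um) == length(values), length(values) >= 5,
            level > 0, level < 1)
  o <- order(offsets_um)
  off <- offsets_um[o]
  v <- values[o]
  if (is.null(background)) {
    outer_band <- abs(off) >= 0.75 * max(abs(off))
    background <- stats::median(v[outer_band])
  }
  imin <- which.min(v)
  depth <- background - v[imin]
  if (!is.finite(depth) || depth <= 0) {
    return(list(width_um = 0, center_um = NA_real_, depth = max(depth, 0),
                background = background, truncated = FALSE, found = FALSE))
  }
  lev <- background - level * depth
  n <- length(v)
  li <- imin
  while (li > 1L && v[li] < lev) li <- li - 1L
  ri <- imin
  while (ri < n && v[ri] < lev) ri <- ri + 1L
  truncated <- FALSE
  if (v[li] < lev) {
    left <- off[1L]
    truncated <- TRUE
  } else {
    left <- off[li] + (v[li] - lev) / (v[li] - v[li + 1L]) *
      (off[li + 1L] - off[li])
  }
  if (v[ri] < lev) {
    right <- off[n]
    truncated <- TRUE
  } else {
    right <- off[ri] - (v[ri] - lev) / (v[ri] - v[ri - 1L]) *
      (off[ri] - off[ri - 1L])
  }
  list(width_um = right - left, center_um = (left + right) / 2,
       depth = depth, background = background,
       truncated = truncated, found = TRUE)
}

# Transverse sampling geometry for a set of anchor points with unit normals:
# returns x/y coordinate matrices (points x offsets) ready for
# `bilinear_sample()`.
transverse_grid <- function(x_um, y_um, nx, ny, offsets_um) {
  xs <- outer(x_um, offsets_um, function(x, o) x) +
    outer(nx, offsets_um)
  ys <- outer(y_um, offsets_um, function(y, o) y) +
    outer(ny, offsets_um)
  list(x = xs, y = ys)
}
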