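#' Rasterize an analytic reference shape
#'
#' Exact pixel-centre rasterization of a disk, axis-rotatable ellipse or
#' axis-aligned square, returned as a flat-colour [grain_region]. These
#' shapes have closed-form area, extent and moments, which makes them the
#' reference fixtures for validating the geometric and shape descriptors.
#'
#' A pixel `(i, j)` (1-based row/col) has centre `(i - 0.5, j - 0.5)` in
#' continuous coordinates; a pixel belongs to the shape iff its centre does.
#'
#' @param kind `"disk"`, `"ellipse"` or `"square"`.
#' @param r Disk radius in pixels.
#' @param a,b Ellipse semi-major / semi-minor axes in pixels.
#' @param rotation Ellipse rotation in radians (counter-clockwise, 0 =
#'   major axis along image columns).
#' @param side Square side in pixels (integer recommended for exact counts).
#' @param margin Background margin around the shape, pixels.
#' @param color RGB fill colour, 0-255.
#'
#' @return A [grain_region] with the shape's mask and a flat-colour crop.
#' @examples
#' reg <- render_analytic_shape("disk", r = 20)
#' sum(reg$mask) / (pi * 20^2)  # ~ 1
#' @export
render_analytic_shape <- function(kind = c("disk", "ellipse", "square"),
                                  r = NULL, a = NULL, b = NULL, rotation = 0,
                                  side = NULL, margin = 4,
                                  color = c(190, 160, 95)) {
  kind <- match.arg(kind)
  half_extent <- switch(kind,
    disk = {
      if (is.null(r) || r <= 0) stop("disk requires positive `r`")
      r
    },
    ellipse = {
      if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
        stop("ellipse requires positive `a` and `b`")
      if (b > a) stop("require a >= b")
      max(a, b)
    },
    square = {
      if (is.null(side) || side <= 0) stop("square requires positive `side`")
      side / 2
    }
  )
  n <- 2L * ceiling(half_extent + margin)
  cx <- n / 2
  # pixel-centre coordinate grids (row -> y, col -> x)
  yc <- matrix(seq_len(n) - 0.5, n, n) - cx
  xc <- matrix(rep(seq_len(n) - 0.5, each = n), n, n) - cx
  mask <- switch(kind,
    disk = xc^2 + yc^2 <= r^2,
    ellipse = {
      u <- xc * cos(rotation) + yc * sin(rotation)
      v <- -xc * sin(rotation) + yc * cos(rotation)
      (u / a)^2 + (v / b)^2 <= 1
    },
    square = abs(xc) <= side / 2 & abs(yc) <= side / 2
  )
  region_from_mask(mask, color = color, grain_id = kind)
}
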