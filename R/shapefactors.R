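# Classical shape coefficients of the descriptor bank. All are
# dimensionless combinations of area S, contour length P, Feret extents,
# centroid distances and the interior distance transform, normalized so a
# disk sits at (or near) a reference value.

# Feret extents of the boundary pixel centres over rotation angles,
# 1-degree step. Returns max and min diameter.
feret_diameters <- function(mask, step_deg = 1) {
  bp <- boundary_pixels(mask)
  pts <- cbind(bp[, 2] - 0.5, bp[, 1] - 0.5)  # (x, y)
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  proj <- pts %*% rbind(cos(th), sin(th))
  ext <- apply(proj, 2, function(p) max(p) - min(p))
  c(max = max(ext), min = min(ext))
}

# sentinel returned for the Haralick ratio when the boundary-distance
# spread vanishes (an ideal circle at coarse raster)
HARALICK_SENTINEL <- 1e6

#' Shape coefficients of a grain region
#'
#' With `S` the area and `P` the contour length (both as in
#' [compute_geometric()]):
#'
#' * `C.Feret` — ratio of maximal to minimal Feret diameter over rotations
#'   (1 degree step);
#' * `C.Malinowska` — `P / (2 * sqrt(pi * S)) - 1` (0 for a disk);
#' * `C.Circularity1` — `4 * pi * S / P^2` (1 for a disk);
#' * `C.Circularity2` — `P / (2 * sqrt(pi * S))`;
#' * `C.Ellipsicity` — `S / (pi * a * b)` with `a`, `b` the moment-fitted
#'   semi-axes;
#' * `C.BlairBliss` — `S / sqrt(2 * pi * sum(r_i^2))` over the foreground
#'   pixels' squared centroid distances (1 for a disk);
#' * `C.Haralick` — mean over standard deviation of the boundary pixels'
#'   centroid distances (population sd; sentinel `1e6` if the sd is 0);
#' * `C.Danielsson` — `S^3 / sum(l_i)^2` with `l_i` the Euclidean distance
#'   of each foreground pixel to the background (distance transform).
#'
#' @param region A [grain_region].
#' @return Named numeric vector of 8 values.
#' @export
compute_shape_factors <- function(region) {
  mask <- region$mask
  S <- sum(mask)
  if (S == 0L) stop("degenerate-region error: empty mask")
  P <- circumference_from_contour(trace_contour(mask))

  fer <- feret_diameters(mask)
  me <- moment_ellipse(mask)

  idx <- which(mask, arr.ind = TRUE)
  r2 <- (idx[, 1] - 0.5 - me$centroid[1])^2 +
    (idx[, 2] - 0.5 - me$centroid[2])^2

  bp <- boundary_pixels(mask)
  d <- sqrt((bp[, 1] - 0.5 - me$centroid[1])^2 +
              (bp[, 2] - 0.5 - me$centroid[2])^2)
  sd_d <- sqrt(mean((d - mean(d))^2))
  haralick <- if (sd_d < 1e-12) HARALICK_SENTINEL else mean(d) / sd_d

  # distance transform with an explicit background frame so that pixels on
  # the crop edge measure their distance to the outside correctly
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  dm <- EBImage::distmap(pad)[2:(H + 1), 2:(W + 1)]
  sum_l <- sum(dm[mask])

  c(C.Feret = fer["max"] / fer["min"],
    C.Malinowska = P / (2 * sqrt(pi * S)) - 1,
    C.Circularity1 = 4 * pi * S / P^2,
    C.Circularity2 = P / (2 * sqrt(pi * S)),
    C.Ellipsicity = S / (pi * (me$major / 2) * (me$minor / 2)),
    C.BlairBliss = S / sqrt(2 * pi * sum(r2)),
    C.Haralick = haralick,
    C.Danielsson = S^3 / sum_l^2,
    use.names = FALSE) -> vals
  names(vals) <- c("C.Feret", "C.Malinowska", "C.Circularity1",
                   "C.Circularity2", "C.Ellipsicity", "C.BlairBliss",
                   "C.Haralick", "C.Danielsson")
  vals
}
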