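#' RGB and HSV colour statistics of a grain region
#'
#' For each of the six channels R, G, B (0-255 scale) and H, S, V (each on
#' the 0-1 scale, hue of achromatic pixels defined as 0) over the
#' foreground pixels only: maximum, minimum, mean, median and standard
#' deviation (population form, denominator n).
#'
#' @param region A [grain_region].
#' @return Named numeric vector of 30 values, `R.Max` ... `V.STD`.
#' @export
compute_color_stats <- function(region) {
  mask <- region$mask
  if (sum(mask) == 0L) stop("degenerate-region error: empty mask")
  r <- region$crop[, , 1][mask]
  g <- region$crop[, , 2][mask]
  b <- region$crop[, , 3][mask]
  hsv <- rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  chans <- list(R = r, G = g, B = b,
                H = hsv[1, ], S = hsv[2, ], V = hsv[3, ])
  out <- unlist(lapply(chans, function(x) {
    c(Max = max(x), Min = min(x), Mean = mean(x), Median = median(x),
      STD = sqrt(mean((x - mean(x))^2)))
  }))
  out
}
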