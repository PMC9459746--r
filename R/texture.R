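# Texture identifier block: grey-level quantization, co-occurrence (GLCM),
# run-length and gradient-magnitude features, all restricted to the
# foreground mask.

# direction offsets (row, col) for distance-1 co-occurrence / runs
TEXTURE_DIRECTIONS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                           `90` = c(-1L, 0L), `135` = c(-1L, -1L))

#' Quantize foreground luminance into grey levels
#'
#' Luminance (`0.299 R + 0.587 G + 0.114 B`) of the foreground pixels is
#' min-max scaled and binned into `levels` equal-width bins labelled
#' `0 .. levels - 1`. A constant foreground maps entirely to level 0.
#' Background pixels are `NA`.
#'
#' @param region A [grain_region].
#' @param levels Number of grey levels (>= 2); default 8.
#' @return Integer matrix of the crop's shape with levels on the
#'   foreground and `NA` elsewhere.
#' @export
quantize_gray <- function(region, levels = 8L) {
  levels <- as.integer(levels)
  stopifnot(levels >= 2L)
  mask <- region$mask
  if (sum(mask) == 0L) stop("degenerate-region error: empty mask")
  lum <- region_luminance(region$crop)
  q <- matrix(NA_integer_, nrow(mask), ncol(mask))
  v <- lum[mask]
  rng <- range(v)
  if (diff(rng) == 0) {
    q[mask] <- 0L
  } else {
    scaled <- (v - rng[1]) / diff(rng)
    q[mask] <- pmin(as.integer(floor(scaled * levels)), levels - 1L)
  }
  q
}

# normalized symmetric co-occurrence matrix for one direction offset
glcm_matrix_dir <- function(q, offset, levels) {
  H <- nrow(q); W <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1L, 1L - dr):min(H, H - dr)
  c1 <- max(1L, 1L - dc):min(W, W - dc)
  aa <- q[r1, c1, drop = FALSE]
  bb <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(aa) & !is.na(bb)
  if (!any(ok)) return(NULL)
  counts <- matrix(tabulate(aa[ok] * levels + bb[ok] + 1L,
                            nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  sym <- counts + t(counts)
  sym / sum(sym)
}

#' Grey-level co-occurrence features
#'
#' Builds the symmetric, normalized co-occurrence matrix at pixel distance
#' 1 for the requested directions (pairs counted only when both pixels are
#' foreground), averages the per-direction matrices, and computes the four
#' classical Haralick features: contrast `sum (i-j)^2 p`, correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)`, energy `sum p^2` and
#' homogeneity `sum p / (1 + |i-j|)`. A field whose marginal variance
#' vanishes (single grey level) has correlation defined as 1.
#'
#' @param quantized Integer level matrix from [quantize_gray()] (`NA` =
#'   background).
#' @param levels Number of grey levels used in the quantization.
#' @param directions Subset of `c("0", "45", "90", "135")` (degrees).
#' @return Named numeric vector: `GLCMContrast`, `GLCMCorrelation`,
#'   `GLCMEnergy`, `GLCMHomogeneity`.
#' @export
compute_glcm_features <- function(quantized, levels = 8L,
                                  directions = names(TEXTURE_DIRECTIONS)) {
  directions <- match.arg(directions, names(TEXTURE_DIRECTIONS),
                          several.ok = TRUE)
  mats <- lapply(TEXTURE_DIRECTIONS[directions],
                 function(d) glcm_matrix_dir(quantized, d, levels))
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (length(mats) == 0L)
    stop("degenerate-texture error: no valid pixel pairs")
  P <- Reduce(`+`, mats) / length(mats)

  i <- matrix(0:(levels - 1L), levels, levels)
  j <- t(i)
  pi_m <- rowSums(P)  # marginals (symmetric: row = col marginal)
  mu <- sum((0:(levels - 1L)) * pi_m)
  sigma2 <- sum(((0:(levels - 1L)) - mu)^2 * pi_m)
  corr <- if (sigma2 < 1e-15) 1 else
    sum((i - mu) * (j - mu) * P) / sigma2

  c(GLCMContrast = sum((i - j)^2 * P),
    GLCMCorrelation = corr,
    GLCMEnergy = sum(P^2),
    GLCMHomogeneity = sum(P / (1 + abs(i - j))))
}

# maximal constant-level runs along one direction; returns a data frame of
# (level, length) pairs for every run
runs_for_direction <- function(q, dir) {
  H <- nrow(q); W <- ncol(q)
  lines <- switch(dir,
    `0` = lapply(seq_len(H), function(r) q[r, ]),
    `90` = lapply(seq_len(W), function(cc) q[, cc]),
    # 45 degrees: anti-diagonals (r + c constant), traversed up-right
    `45` = lapply(seq_len(H + W - 1L), function(s) {
      r <- seq(min(s, H), max(1L, s - W + 1L))
      q[cbind(r, s - r + 1L)]
    }),
    # 135 degrees: diagonals (c - r constant), traversed down-right
    `135` = lapply(seq_len(H + W - 1L), function(s) {
      d <- s - H
      r <- seq(max(1L, 1L - d), min(H, W - d))
      q[cbind(r, r + d)]
    })
  )
  gs <- integer(0); ls <- integer(0)
  for (ln in lines) {
    if (length(ln) == 0L) next
    rl <- rle(ln)  # NA runs (background) are produced but dropped below
    keep <- !is.na(rl$values)
    gs <- c(gs, rl$values[keep]); ls <- c(ls, rl$lengths[keep])
  }
  list(level = gs, length = ls)
}

#' Run-length texture features
#'
#' Enumerates maximal constant-level runs of foreground pixels along each
#' requested direction, then averages the per-direction features: short-run
#' emphasis `rSRE`, long-run emphasis `rLRE`, run-length non-uniformity
#' `rRLN`, grey-level non-uniformity `rGLN` (each normalized by the total
#' run count) and run percentage `rFIR` (runs per foreground pixel).
#'
#' @inheritParams compute_glcm_features
#' @return Named numeric vector: `rSRE`, `rLRE`, `rRLN`, `rFIR`, `rGLN`.
#' @export
compute_runlength_features <- function(quantized,
                                       directions = names(TEXTURE_DIRECTIONS)) {
  directions <- match.arg(directions, names(TEXTURE_DIRECTIONS),
                          several.ok = TRUE)
  np <- sum(!is.na(quantized))
  if (np == 0L) stop("degenerate-texture error: empty foreground")
  feats <- vapply(directions, function(dir) {
    rr <- runs_for_direction(quantized, dir)
    nr <- length(rr$length)
    lens <- rr$length
    len_marg <- tapply(rep(1L, nr), lens, sum)          # runs per length
    lev_marg <- tapply(rep(1L, nr), rr$level, sum)      # runs per level
    c(SRE = sum(1 / lens^2) / nr,
      LRE = sum(lens^2) / nr,
      RLN = sum(len_marg^2) / nr,
      FIR = nr / np,
      GLN = sum(lev_marg^2) / nr)
  }, numeric(5))
  avg <- rowMeans(feats)
  c(rSRE = avg[["SRE"]], rLRE = avg[["LRE"]], rRLN = avg[["RLN"]],
    rFIR = avg[["FIR"]], rGLN = avg[["GLN"]])
}

#' Gradient-magnitude texture features
#'
#' Sobel gradient magnitude of the luminance, evaluated at interior
#' foreground pixels (foreground eroded by one pixel, 8-neighbourhood, so
#' every 3x3 Sobel window lies inside the object). The Sobel responses are
#' normalized by 8, making the magnitude an estimate of the local
#' luminance slope in grey levels per pixel. Reported are the mean,
#' population variance, skewness and (non-excess) kurtosis of the
#' magnitudes plus `ZeroPercent`, the percentage of interior pixels with
#' magnitude below 1e-9. Zero variance yields skewness = kurtosis = 0.
#'
#' @param region A [grain_region].
#' @return Named numeric vector: `MGmean`, `MGvar`, `MGskew`, `MGkurto`,
#'   `ZeroPercent`.
#' @export
compute_gradient_features <- function(region) {
  mask <- region$mask
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  interior <- mask
  for (dr in -1:1) for (dc in -1:1)
    interior <- interior & pad[2:(H + 1) + dr, 2:(W + 1) + dc]
  if (sum(interior) < 9L)
    stop("degenerate-region error: foreground too small for gradients")

  lum <- region_luminance(region$crop)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  rr <- 2:(H - 1); cc <- 2:(W - 1)
  gx[rr, cc] <- (lum[rr - 1, cc + 1] + 2 * lum[rr, cc + 1] + lum[rr + 1, cc + 1] -
                   lum[rr - 1, cc - 1] - 2 * lum[rr, cc - 1] - lum[rr + 1, cc - 1]) / 8
  gy[rr, cc] <- (lum[rr + 1, cc - 1] + 2 * lum[rr + 1, cc] + lum[rr + 1, cc + 1] -
                   lum[rr - 1, cc - 1] - 2 * lum[rr - 1, cc] - lum[rr - 1, cc + 1]) / 8
  mag <- sqrt(gx^2 + gy^2)[interior]

  m <- mean(mag)
  v <- mean((mag - m)^2)
  if (v < 1e-24) {
    skew <- 0; kurto <- 0
  } else {
    skew <- mean((mag - m)^3) / v^1.5
    kurto <- mean((mag - m)^4) / v^2
  }
  c(MGmean = m, MGvar = v, MGskew = skew, MGkurto = kurto,
    ZeroPercent = 100 * mean(mag < 1e-9))
}
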