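# Geometric parameter block of the descriptor bank, plus the boundary and
# contour machinery shared with the shape coefficients.

# Boundary pixels: foreground pixels with at least one 4-neighbour outside
# the object (image edge counts as outside). Returns (row, col) matrix.
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  inner <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(mask & !inner, arr.ind = TRUE)
}

# Moore-neighbour contour tracing with Jacob's stopping criterion.
# Returns the closed contour as (row, col) plus counts of axial and
# diagonal chain steps. Assumes a single 8-connected component.
trace_contour <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  # clockwise Moore neighbourhood starting west (row, col offsets)
  off <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                ncol = 2, byrow = TRUE)
  start <- which(t(pad), arr.ind = TRUE)[1, ]  # row-major scan
  start <- c(start[2], start[1])
  if (length(start) == 0L) stop("degenerate-region error: empty mask")
  # entered the start pixel from the west
  path <- matrix(NA_integer_, 4L * sum(mask) + 8L, 2L)
  path[1, ] <- start
  np <- 1L
  n_ax <- 0L; n_di <- 0L
  p <- start
  bdir <- 1L  # index into `off` of the backtrack position
  first_move <- NULL
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- ((bdir - 1L + k) %% 8L) + 1L
      q <- p + off[d, ]
      if (pad[q[1], q[2]]) {
        diag_step <- all(off[d, ] != 0L)
        if (diag_step) n_di <- n_di + 1L else n_ax <- n_ax + 1L
        # new backtrack: position just before the found neighbour,
        # relative to the new pixel
        prev <- p + off[((d - 2L) %% 8L) + 1L, ]
        rel <- prev - q
        bdir <- which(off[, 1] == rel[1] & off[, 2] == rel[2])
        p <- q
        np <- np + 1L
        path[np, ] <- p
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (is.null(first_move)) {
      first_move <- p
    } else if (all(p == first_move) && all(path[np - 1L, ] == start)) {
      # re-entered the start pixel with the same initial move: the last
      # recorded step (start -> first_move) duplicates the first one
      step <- path[np, ] - path[np - 1L, ]
      if (all(step != 0L)) n_di <- n_di - 1L else n_ax <- n_ax - 1L
      np <- np - 2L  # drop repeated first_move and the closing start
      break
    }
    if (np >= nrow(path)) break  # safety
  }
  list(path = path[seq_len(np), , drop = FALSE] - 1L,  # unpad
       n_axial = n_ax, n_diagonal = n_di)
}

# Contour length from chain steps: sqrt(2)-weighted diagonal steps with
# Kulpa's 0.948 correction factor, which removes the systematic
# overestimation of smooth-perimeter length by 8-connected chain codes.
circumference_from_contour <- function(ct) {
  if (ct$n_axial + ct$n_diagonal == 0L) return(1)
  0.948 * (ct$n_axial + sqrt(2) * ct$n_diagonal)
}

# Second central moments of pixel centres -> fitted-ellipse axes.
moment_ellipse <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  y <- idx[, 1] - 0.5; x <- idx[, 2] - 0.5
  my <- mean(y); mx <- mean(x)
  mu20 <- mean((x - mx)^2); mu02 <- mean((y - my)^2)
  mu11 <- mean((x - mx) * (y - my))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  l2 <- max(l2, 0)
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       lambda = c(l1, l2), centroid = c(my, mx))
}

# Pixel count of the rasterized convex hull (pixel centre inside or on the
# hull polygon of the boundary pixel centres).
convex_hull_area <- function(mask) {
  bp <- boundary_pixels(mask)
  y <- bp[, 1] - 0.5; x <- bp[, 2] - 0.5
  h <- chull(x, y)
  hx <- x[h]; hy <- y[h]
  nh <- length(h)
  if (nh < 3L) return(sum(mask))
  idx <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  py <- idx[, 1] - 0.5; px <- idx[, 2] - 0.5
  inside <- rep(TRUE, length(px))
  for (k in seq_len(nh)) {
    k2 <- if (k == nh) 1L else k + 1L
    cross <- (hx[k2] - hx[k]) * (py - hy[k]) - (hy[k2] - hy[k]) * (px - hx[k])
    inside <- inside & cross <= 1e-9  # chull vertices are clockwise
  }
  sum(inside)
}

#' Geometric parameters of a grain region
#'
#' Computes the geometric descriptor block from the region's binary mask:
#' `Area` (pixel count), `Circumference` (corrected 8-connected contour
#' length), `Max.height` / `Max.width` (bounding-box extents in rows /
#' columns), `Rmax` / `Rmin` (largest / smallest centroid-to-boundary
#' distance), `OAR` (area over bounding-box area), `Circle.diameter`
#' (diameter of the equal-area circle), `Eccentricity` of the moment-fitted
#' ellipse, `Ellipse` (area of that fitted ellipse),
#' `MajorAxisLength` / `MinorAxisLength` (fitted-ellipse axes, regionprops
#' convention) and `Solidity` (area over rasterized convex-hull area).
#'
#' `Ellipse` duplicates the information in the two axis lengths
#' (`pi/4 * Major * Minor` exactly) and is therefore not part of the
#' canonical 64-descriptor record; it is still returned here.
#'
#' @param region A [grain_region].
#' @return Named numeric vector of 13 values.
#' @export
compute_geometric <- function(region) {
  mask <- region$mask
  area <- sum(mask)
  if (area == 0L) stop("degenerate-region error: empty mask")

  ct <- trace_contour(mask)
  P <- circumference_from_contour(ct)

  rows <- which(rowSums(mask) > 0); cols <- which(colSums(mask) > 0)
  max_h <- diff(range(rows)) + 1L
  max_w <- diff(range(cols)) + 1L

  me <- moment_ellipse(mask)
  bp <- boundary_pixels(mask)
  d <- sqrt((bp[, 1] - 0.5 - me$centroid[1])^2 +
              (bp[, 2] - 0.5 - me$centroid[2])^2)

  ecc <- if (me$lambda[1] > 0) sqrt(1 - me$lambda[2] / me$lambda[1]) else 0

  c(Area = area,
    Circumference = P,
    Max.height = max_h,
    Max.width = max_w,
    Rmax = max(d),
    Rmin = min(d),
    OAR = area / (max_h * max_w),
    Circle.diameter = 2 * sqrt(area / pi),
    Eccentricity = ecc,
    Ellipse = pi * (me$major / 2) * (me$minor / 2),
    MajorAxisLength = me$major,
    MinorAxisLength = me$minor,
    Solidity = area / convex_hull_area(mask))
}
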