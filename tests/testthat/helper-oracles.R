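# Independent brute-force oracles. Every function here recomputes a
# package quantity with explicit loops and the most literal reading of its
# definition; none shares code with the implementation under test.

# --- co-occurrence -----------------------------------------------------

oracle_glcm <- function(q, levels, directions = c("0", "45", "90", "135")) {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  mats <- list()
  for (d in directions) {
    o <- offs[[d]]
    counts <- matrix(0, levels, levels)
    for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
      i2 <- i + o[1]; j2 <- j + o[2]
      if (i2 < 1 || i2 > nrow(q) || j2 < 1 || j2 > ncol(q)) next
      a <- q[i, j]; b <- q[i2, j2]
      if (is.na(a) || is.na(b)) next
      counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1  # symmetric
    }
    if (sum(counts) > 0) mats[[d]] <- counts / sum(counts)
  }
  P <- Reduce(`+`, mats) / length(mats)
  contrast <- 0; energy <- 0; homog <- 0
  mu <- 0; marg <- rowSums(P)
  for (i in 0:(levels - 1)) mu <- mu + i * marg[i + 1]
  sig2 <- 0
  for (i in 0:(levels - 1)) sig2 <- sig2 + (i - mu)^2 * marg[i + 1]
  corr_num <- 0
  for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
    p <- P[i + 1, j + 1]
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    homog <- homog + p / (1 + abs(i - j))
    corr_num <- corr_num + (i - mu) * (j - mu) * p
  }
  corr <- if (sig2 < 1e-15) 1 else corr_num / sig2
  c(GLCMContrast = contrast, GLCMCorrelation = corr,
    GLCMEnergy = energy, GLCMHomogeneity = homog)
}

# --- run length --------------------------------------------------------

oracle_lines <- function(q, dir) {
  H <- nrow(q); W <- ncol(q)
  out <- list()
  if (dir == "0") {
    for (i in seq_len(H)) out[[length(out) + 1]] <- q[i, ]
  } else if (dir == "90") {
    for (j in seq_len(W)) out[[length(out) + 1]] <- q[, j]
  } else if (dir == "45") {
    for (s in 2:(H + W)) {  # i + j = s, traversed with increasing j
      cells <- c()
      for (j in seq_len(W)) {
        i <- s - j
        if (i >= 1 && i <= H) cells <- c(cells, q[i, j])
      }
      out[[length(out) + 1]] <- cells
    }
  } else {
    for (s in (1 - W):(H - 1)) {  # i - j = s, increasing j
      cells <- c()
      for (j in seq_len(W)) {
        i <- s + j
        if (i >= 1 && i <= H) cells <- c(cells, q[i, j])
      }
      out[[length(out) + 1]] <- cells
    }
  }
  out
}

oracle_runlength <- function(q, directions = c("0", "45", "90", "135")) {
  np <- sum(!is.na(q))
  per_dir <- sapply(directions, function(dir) {
    runs <- list()
    for (line in oracle_lines(q, dir)) {
      k <- 1
      while (k <= length(line)) {
        if (is.na(line[k])) { k <- k + 1; next }
        len <- 1
        while (k + len <= length(line) && !is.na(line[k + len]) &&
                 line[k + len] == line[k]) len <- len + 1
        runs[[length(runs) + 1]] <- c(line[k], len)
        k <- k + len
      }
    }
    g <- sapply(runs, `[`, 1); l <- sapply(runs, `[`, 2)
    nr <- length(l)
    sre <- sum(1 / l^2) / nr
    lre <- sum(l^2) / nr
    rln <- sum(sapply(unique(l), function(L) sum(l == L)^2)) / nr
    gln <- sum(sapply(unique(g), function(G) sum(g == G)^2)) / nr
    c(SRE = sre, LRE = lre, RLN = rln, FIR = nr / np, GLN = gln)
  })
  avg <- rowMeans(per_dir)
  c(rSRE = avg[["SRE"]], rLRE = avg[["LRE"]], rRLN = avg[["RLN"]],
    rFIR = avg[["FIR"]], rGLN = avg[["GLN"]])
}

# --- colour ------------------------------------------------------------

oracle_color_stats <- function(region) {
  mask <- region$mask
  vals <- list(R = c(), G = c(), B = c(), H = c(), S = c(), V = c())
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j]) next
    r <- region$crop[i, j, 1] / 255
    g <- region$crop[i, j, 2] / 255
    b <- region$crop[i, j, 3] / 255
    mx <- max(r, g, b); mn <- min(r, g, b); dl <- mx - mn
    v <- mx
    s <- if (mx == 0) 0 else dl / mx
    h <- if (dl == 0) 0
    else if (mx == r) (((g - b) / dl) %% 6) / 6
    else if (mx == g) ((b - r) / dl + 2) / 6
    else ((r - g) / dl + 4) / 6
    vals$R <- c(vals$R, r * 255); vals$G <- c(vals$G, g * 255)
    vals$B <- c(vals$B, b * 255)
    vals$H <- c(vals$H, h); vals$S <- c(vals$S, s); vals$V <- c(vals$V, v)
  }
  unlist(lapply(vals, function(x)
    c(Max = max(x), Min = min(x), Mean = mean(x), Median = median(x),
      STD = sqrt(mean((x - mean(x))^2)))))
}

# --- gradient ----------------------------------------------------------

oracle_gradient <- function(region) {
  mask <- region$mask
  H <- nrow(mask); W <- ncol(mask)
  lum <- 0.299 * region$crop[, , 1] + 0.587 * region$crop[, , 2] +
    0.114 * region$crop[, , 3]
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3)   # columns = x
  ky <- t(kx)
  mags <- c()
  for (i in 2:(H - 1)) for (j in 2:(W - 1)) {
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) if (!mask[i + di, j + dj]) ok <- FALSE
    if (!ok) next
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      gx <- gx + kx[di + 2, dj + 2] * lum[i + di, j + dj]
      gy <- gy + ky[di + 2, dj + 2] * lum[i + di, j + dj]
    }
    mags <- c(mags, sqrt((gx / 8)^2 + (gy / 8)^2))
  }
  m <- mean(mags); v <- mean((mags - m)^2)
  c(MGmean = m, MGvar = v,
    MGskew = if (v < 1e-24) 0 else mean((mags - m)^3) / v^1.5,
    MGkurto = if (v < 1e-24) 0 else mean((mags - m)^4) / v^2,
    ZeroPercent = 100 * mean(mags < 1e-9))
}

# --- shape coefficients ------------------------------------------------

# Same definitions as the implementation, computed the pedestrian way:
# the contour length is re-derived from the traced path coordinates
# (step-by-step Euclidean distances) rather than the step-type counters,
# and every other ingredient is an explicit loop or exhaustive scan.
oracle_shape_factors <- function(region) {
  mask <- region$mask
  S <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j]) S <- S + 1

  ct <- grainscan:::trace_contour(mask)
  path <- rbind(ct$path, ct$path[1, ])  # close the loop
  P <- 0
  for (k in seq_len(nrow(path) - 1))
    P <- P + sqrt(sum((path[k + 1, ] - path[k, ])^2))
  P <- 0.948 * P

  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1] - 0.5); cx <- mean(idx[, 2] - 0.5)
  mu20 <- mean((idx[, 2] - 0.5 - cx)^2)
  mu02 <- mean((idx[, 1] - 0.5 - cy)^2)
  mu11 <- mean((idx[, 2] - 0.5 - cx) * (idx[, 1] - 0.5 - cy))
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2; l2 <- (mu20 + mu02 - disc) / 2
  a <- 2 * sqrt(l1); b <- 2 * sqrt(max(l2, 0))

  # boundary pixels: 4-neighbour definition
  bpts <- NULL
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j]) next
    nb <- c(
      if (i > 1) mask[i - 1, j] else FALSE,
      if (i < nrow(mask)) mask[i + 1, j] else FALSE,
      if (j > 1) mask[i, j - 1] else FALSE,
      if (j < ncol(mask)) mask[i, j + 1] else FALSE
    )
    if (!all(nb)) bpts <- rbind(bpts, c(i - 0.5, j - 0.5))
  }
  d <- sqrt((bpts[, 1] - cy)^2 + (bpts[, 2] - cx)^2)

  # Feret: scan 1-degree directions
  exts <- sapply(seq(0, 179), function(deg) {
    th <- deg * pi / 180
    pr <- (bpts[, 2]) * cos(th) + (bpts[, 1]) * sin(th)
    max(pr) - min(pr)
  })

  r2sum <- sum((idx[, 1] - 0.5 - cy)^2 + (idx[, 2] - 0.5 - cx)^2)

  # distance transform: exhaustive nearest-background search on the
  # padded mask
  pad <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  pad[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  bg <- which(!pad, arr.ind = TRUE)
  fg <- which(pad, arr.ind = TRUE)
  lsum <- 0
  for (k in seq_len(nrow(fg)))
    lsum <- lsum + sqrt(min((bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2))

  sd_d <- sqrt(mean((d - mean(d))^2))
  c(C.Feret = max(exts) / min(exts),
    C.Malinowska = P / (2 * sqrt(pi * S)) - 1,
    C.Circularity1 = 4 * pi * S / P^2,
    C.Circularity2 = P / (2 * sqrt(pi * S)),
    C.Ellipsicity = S / (pi * a * b),
    C.BlairBliss = S / sqrt(2 * pi * r2sum),
    C.Haralick = if (sd_d < 1e-12) 1e6 else mean(d) / sd_d,
    C.Danielsson = S^3 / lsum^2)
}

# --- covariance --------------------------------------------------------

oracle_covariance <- function(X) {
  n <- nrow(X); p <- ncol(X)
  mu <- numeric(p)
  for (j in seq_len(p)) mu[j] <- sum(X[, j]) / n
  C <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    s <- 0
    for (k in seq_len(n)) s <- s + (X[k, i] - mu[i]) * (X[k, j] - mu[j])
    C[i, j] <- s / (n - 1)
  }
  C
}

# --- network -----------------------------------------------------------

oracle_forward <- function(model, x) {
  h <- numeric(model$n_hidden)
  for (k in seq_len(model$n_hidden)) {
    s <- model$b1[k]
    for (j in seq_len(model$n_in)) s <- s + model$W1[k, j] * x[j]
    h[k] <- 1 / (1 + exp(-s))
  }
  s <- model$b2
  for (k in seq_len(model$n_hidden)) s <- s + model$W2[1, k] * h[k]
  1 / (1 + exp(-s))
}

numeric_gradient <- function(model, X, y, eps = 1e-6) {
  par <- grainscan:::flatten_params(model)
  fn <- function(p) {
    m <- grainscan:::unflatten_params(model, p)
    0.5 * sum((mlp_forward(m, X) - y)^2)
  }
  g <- numeric(length(par))
  for (i in seq_along(par)) {
    up <- par; up[i] <- up[i] + eps
    dn <- par; dn[i] <- dn[i] - eps
    g[i] <- (fn(up) - fn(dn)) / (2 * eps)
  }
  g
}

# random quantized patch with a sprinkling of background pixels
random_patch <- function(seed, size = 16L, levels = 8L, bg_frac = 0.15) {
  set.seed(seed)
  q <- matrix(sample(0:(levels - 1L), size * size, replace = TRUE),
              size, size)
  q[sample(size * size, round(bg_frac * size * size))] <- NA_integer_
  q
}

# random speckled grain region (single blob mask, noisy colour crop)
random_region <- function(seed, size = 24L) {
  set.seed(seed)
  r <- size / 2 - 2
  reg <- render_analytic_shape("disk", r = r, margin = 2)
  n <- prod(dim(reg$mask))
  crop <- reg$crop
  for (ch in 1:3)
    crop[, , ch] <- pmin(pmax(crop[, , ch] +
                                matrix(round(rnorm(n, sd = 25)),
                                       dim(reg$mask)[1]), 0), 255)
  grain_region(reg$mask, crop, grain_id = sprintf("rr%03d", seed))
}
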