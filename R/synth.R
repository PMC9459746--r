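#' Damage classes rendered by the synthetic generator
#'
#' `good` plus the four visually distinctive damage modes of malting barley
#' that the generator can draw: mold darkening, grain halves, partial
#' dehulling and darkened ends. The binary target used by the classifier is
#' 1 for `good`, 0 for every damage mode.
#' @export
DAMAGE_CLASSES <- c("good", "mold", "half", "dehulled", "dark_ends")

# nominal semi-minor axis (px) per sieve-size fraction, at ~10 px/mm:
# 2.2 / 2.5 / 2.8 mm grain width classes
FRACTION_SEMI_MINOR <- c(F22 = 11, F25 = 12.5, F28 = 14)

#' Configuration for the synthetic grain-image generator
#'
#' Bundles everything that determines a synthetic dataset. Two calls to
#' [render_dataset()] with equal configurations (including `rng_seed`)
#' produce byte-identical images and truth tables.
#'
#' @param n_grains Number of grains to draw (>= 1).
#' @param fraction Sieve-size fraction: `"F22"`, `"F25"` or `"F28"`
#'   (nominal 2.2 / 2.5 / 2.8 mm width classes; controls the pixel scale of
#'   the rendered ellipses).
#' @param damage_mix Named numeric vector of class proportions over
#'   [DAMAGE_CLASSES]; must sum to 1 (tolerance 1e-9).
#' @param image_size `(height, width)` in pixels of each grain image (or of
#'   the sheet when `sheet = TRUE`).
#' @param background_gray Uniform background grey level, 0-255.
#' @param noise_sd Standard deviation of per-pixel Gaussian noise, in grey
#'   levels.
#' @param rng_seed Integer seed; the only source of randomness.
#' @param sheet If `TRUE`, place all grains on one image (non-overlapping
#'   grid); otherwise render one image per grain.
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_grains, fraction = "F25",
                         damage_mix = c(good = 1),
                         image_size = c(128L, 128L),
                         background_gray = 40, noise_sd = 2,
                         rng_seed = 1L, sheet = FALSE) {
  stopifnot(n_grains >= 1, noise_sd >= 0)
  fraction <- match.arg(fraction, names(FRACTION_SEMI_MINOR))
  if (is.null(names(damage_mix)) ||
      !all(names(damage_mix) %in% DAMAGE_CLASSES))
    stop("`damage_mix` must be named with classes among: ",
         paste(DAMAGE_CLASSES, collapse = ", "))
  if (abs(sum(damage_mix) - 1) > 1e-9)
    stop("`damage_mix` proportions must sum to 1")
  structure(
    list(n_grains = as.integer(n_grains), fraction = fraction,
         damage_mix = damage_mix, image_size = as.integer(image_size),
         background_gray = background_gray, noise_sd = noise_sd,
         rng_seed = as.integer(rng_seed), sheet = isTRUE(sheet)),
    class = "synth_config"
  )
}

#' Render a labelled synthetic grain dataset
#'
#' Draws grains as rotated filled ellipses in the yellow-tan colour range
#' with per-grain colour jitter, a lengthwise shading profile, a darker
#' crease along the major axis and Gaussian pixel noise, then applies the
#' configured damage mode:
#'
#' * `mold` — multiplicative darkening patches inside the kernel;
#' * `half` — the ellipse clipped by a chord through its centre;
#' * `dehulled` — a brighter smooth (noise-free) region where the hull is
#'   missing;
#' * `dark_ends` — darkened caps at both tips of the major axis.
#'
#' Immediately after seeding the RNG, the damage classes of all grains are
#' drawn with a single `sample()` call over `names(damage_mix)`; per-grain
#' geometry, colour and noise are drawn afterwards, grain by grain. This
#' fixed draw order is part of the function's contract.
#'
#' @param cfg A [synth_config()].
#' @return A list with elements
#'   * `images` — list of `H x W x 3` arrays (0-255); length `n_grains`, or
#'     1 in sheet mode;
#'   * `truth` — data frame with one row per grain: `grain_id`,
#'     `damage_class`, `label` (1 = good, 0 = damaged), ellipse parameters
#'     `a`, `b`, `rotation`, image-local centre `center_row`, `center_col`
#'     (0-based), `image` (index into `images`) and `fraction`.
#' @export
render_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$rng_seed)
  n <- cfg$n_grains
  classes <- sample(names(cfg$damage_mix), n, replace = TRUE,
                    prob = cfg$damage_mix)

  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  b0 <- FRACTION_SEMI_MINOR[[cfg$fraction]]

  if (cfg$sheet) {
    # grid placement: cell size from the largest possible grain
    cell <- ceiling(2 * (b0 + 3) * 2.6) + 8
    ncol_g <- W %/% cell; nrow_g <- H %/% cell
    if (ncol_g * nrow_g < n)
      stop("placement error: image too small for ", n,
           " non-overlapping grains (fits ", ncol_g * nrow_g, ")")
    sheet_img <- array(cfg$background_gray, dim = c(H, W, 3L))
  }

  images <- vector("list", if (cfg$sheet) 1L else n)
  truth <- data.frame(
    grain_id = sprintf("g%04d", seq_len(n)), damage_class = classes,
    label = as.integer(classes == "good"),
    a = 0, b = 0, rotation = 0, center_row = 0, center_col = 0,
    image = if (cfg$sheet) 1L else seq_len(n),
    fraction = cfg$fraction, stringsAsFactors = FALSE
  )

  for (i in seq_len(n)) {
    b <- max(3, b0 + rnorm(1, sd = 0.8))
    a <- b * runif(1, 2.0, 2.6)
    rot <- runif(1, -0.3, 0.3)
    base <- c(190 + runif(1, -15, 15),
              160 + runif(1, -15, 15),
              95 + runif(1, -10, 10))
    if (cfg$sheet) {
      gi <- (i - 1L) %/% ncol_g; gj <- (i - 1L) %% ncol_g
      ctr <- c(gi * cell + cell / 2 + runif(1, -2, 2),
               gj * cell + cell / 2 + runif(1, -2, 2))
    } else {
      ctr <- c(H / 2 + runif(1, -3, 3), W / 2 + runif(1, -3, 3))
    }
    gr <- draw_grain(if (cfg$sheet) c(H, W) else cfg$image_size,
                     ctr, a, b, rot, base, classes[i],
                     cfg$background_gray, cfg$noise_sd)
    if (cfg$sheet) {
      sel <- gr$touched
      for (ch in 1:3) {
        plane <- sheet_img[, , ch]; plane[sel] <- gr$img[, , ch][sel]
        sheet_img[, , ch] <- plane
      }
    } else {
      images[[i]] <- gr$img
    }
    truth$a[i] <- a; truth$b[i] <- b; truth$rotation[i] <- rot
    truth$center_row[i] <- ctr[1] - 0.5  # 0-based pixel coordinates
    truth$center_col[i] <- ctr[2] - 0.5
  }
  if (cfg$sheet) images[[1]] <- sheet_img
  list(images = images, truth = truth)
}

# Render one grain onto a fresh background canvas. Returns the canvas and
# the set of pixels it painted (used for sheet compositing).
draw_grain <- function(size, ctr, a, b, rot, base, damage,
                       background_gray, noise_sd) {
  H <- size[1]; W <- size[2]
  yc <- matrix(seq_len(H) - 0.5, H, W) - ctr[1]
  xc <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - ctr[2]
  # ellipse-local frame: u along major axis, v along minor
  u <- xc * cos(rot) + yc * sin(rot)
  v <- -xc * sin(rot) + yc * cos(rot)
  inside <- (u / a)^2 + (v / b)^2 <= 1

  # multiplicative shading: lengthwise profile + crease along major axis
  shade <- matrix(1, H, W)
  shade[inside] <- (1 - 0.10 * (u[inside] / a)^2) *
    (1 - 0.15 * exp(-(v[inside] / (0.18 * b))^2))
  noise_scale <- matrix(1, H, W)

  # damage modes, drawn in the local frame
  if (damage == "half") {
    phi <- runif(1, 0, 2 * pi)
    inside <- inside & (u * cos(phi) + v * sin(phi) >= 0)
  } else if (damage == "mold") {
    for (k in seq_len(2L)) {
      pu <- runif(1, -0.6 * a, 0.6 * a); pv <- runif(1, -0.5 * b, 0.5 * b)
      pr <- runif(1, 0.35 * b, 0.6 * b)
      patch <- inside & ((u - pu)^2 + (v - pv)^2 <= pr^2)
      shade[patch] <- shade[patch] * 0.45
    }
  } else if (damage == "dehulled") {
    pu <- runif(1, -0.5 * a, 0.5 * a); pv <- runif(1, -0.4 * b, 0.4 * b)
    pr <- runif(1, 0.5 * b, 0.9 * b)
    patch <- inside & ((u - pu)^2 + (v - pv)^2 <= pr^2)
    shade[patch] <- shade[patch] * 1.30
    noise_scale[patch] <- 0  # exposed endosperm is smooth
  } else if (damage == "dark_ends") {
    caps <- abs(u) > 0.72 * a
    shade[inside & caps] <- shade[inside & caps] * 0.45
  }

  img <- array(background_gray, dim = c(H, W, 3L))
  npix <- sum(inside)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- base[ch] * shade[inside]
    img[, , ch] <- plane
  }
  if (noise_sd > 0) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- plane[inside] +
        rnorm(npix, sd = noise_sd) * noise_scale[inside]
      img[, , ch] <- plane
    }
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(img = img, touched = inside)
}

#' Write a rendered dataset to disk
#'
#' Writes one PNG per image, the truth table as `truth.csv` and the
#' generating configuration as `config.yaml`.
#'
#' @param ds Result of [render_dataset()].
#' @param dir Output directory (created if missing).
#' @param cfg The [synth_config()] used, stored alongside for provenance.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$images))
    write_image(ds$images[[i]], file.path(dir, sprintf("img%04d.png", i)))
  write.csv(ds$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(cfg))
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
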