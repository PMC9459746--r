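#' The canonical 64-descriptor name list
#'
#' Fixed name set and order of the descriptor bank: 12 geometric
#' parameters, 8 shape coefficients, 30 colour statistics (RGB and HSV,
#' five statistics per channel) and 14 texture identifiers. Every
#' descriptor table in the package uses exactly these names in exactly
#' this order.
#'
#' The geometric block of the bank nominally contains 13 quantities; the
#' fitted-ellipse area (`Ellipse`) is an exact function of the two axis
#' lengths (`pi/4 * Major * Minor`) and is excluded from the canonical
#' record so that the bank totals 64 informative descriptors.
#'
#' @return Character vector of length 64.
#' @export
canonical_descriptors <- function() {
  c(
    # geometric (12)
    "Area", "Circumference", "Max.height", "Max.width", "Rmax", "Rmin",
    "OAR", "Circle.diameter", "Eccentricity", "MajorAxisLength",
    "MinorAxisLength", "Solidity",
    # shape coefficients (8)
    "C.Feret", "C.Malinowska", "C.Circularity1", "C.Circularity2",
    "C.Ellipsicity", "C.BlairBliss", "C.Haralick", "C.Danielsson",
    # colour statistics (30)
    as.vector(t(outer(c("R", "G", "B", "H", "S", "V"),
                      c("Max", "Min", "Mean", "Median", "STD"),
                      paste, sep = "."))),
    # texture identifiers (14)
    "MGmean", "MGvar", "MGskew", "MGkurto", "ZeroPercent",
    "rSRE", "rLRE", "rRLN", "rFIR", "rGLN",
    "GLCMContrast", "GLCMCorrelation", "GLCMEnergy", "GLCMHomogeneity"
  )
}

#' Extract the full descriptor record of one grain
#'
#' Runs every descriptor block ([compute_geometric()],
#' [compute_shape_factors()], [compute_color_stats()],
#' [quantize_gray()] + [compute_glcm_features()] +
#' [compute_runlength_features()], [compute_gradient_features()]) and
#' assembles the canonical 64-value record.
#'
#' @param region A [grain_region].
#' @param levels Grey levels for the texture quantization (default 8).
#' @return Named numeric vector of length 64 in canonical order.
#' @export
extract_all <- function(region, levels = 8L) {
  geo <- compute_geometric(region)
  shp <- compute_shape_factors(region)
  col <- compute_color_stats(region)
  q <- quantize_gray(region, levels = levels)
  glcm <- compute_glcm_features(q, levels = levels)
  rl <- compute_runlength_features(q)
  grad <- compute_gradient_features(region)
  vals <- c(geo, shp, col, grad, rl, glcm)
  out <- vals[canonical_descriptors()]
  stopifnot(!anyNA(out), all(is.finite(out)))
  out
}

#' Build a descriptor table for a set of regions
#'
#' @param regions List of [grain_region] objects.
#' @param labels Optional integer vector (1 = good, 0 = damaged), one per
#'   region.
#' @param fraction Optional fraction tag recycled across rows.
#' @inheritParams extract_all
#' @return Data frame: `grain_id`, the 64 canonical descriptor columns,
#'   `label`, `fraction`.
#' @export
descriptor_table <- function(regions, labels = NULL, fraction = NA_character_,
                             levels = 8L) {
  mat <- t(vapply(regions, extract_all, numeric(64), levels = levels))
  df <- data.frame(
    grain_id = vapply(regions, function(r) r$grain_id, character(1)),
    mat, check.names = FALSE, stringsAsFactors = FALSE
  )
  df$label <- if (is.null(labels)) NA_integer_ else as.integer(labels)
  df$fraction <- fraction
  df
}

#' Write / read a descriptor table as CSV
#'
#' The CSV header is `grain_id`, the 64 canonical names, `label`,
#' `fraction`; numeric values are written with 15 significant digits so a
#' round trip is lossless well beyond 12 significant digits.
#'
#' @param df Descriptor table from [descriptor_table()].
#' @param path CSV path.
#' @return `path` (write) / the table (read).
#' @export
write_descriptors <- function(df, path) {
  fmt <- df
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.17g", x))
  write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(canonical_descriptors(), names(df))
  if (length(missing) > 0)
    stop("descriptor CSV is missing columns: ",
         paste(head(missing, 5), collapse = ", "))
  df
}
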