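#' Construct a grain region
#'
#' A `grain_region` couples a binary foreground mask with the matching RGB
#' crop of a single segmented kernel, plus provenance of where the crop sits
#' in its source image. It is the unit every descriptor operates on.
#'
#' @param mask Logical matrix; `TRUE` marks kernel pixels. Must contain a
#'   single connected foreground component (not re-checked here; the
#'   segmenter guarantees it).
#' @param crop Numeric array `nrow(mask) x ncol(mask) x 3`, 8-bit RGB on the
#'   0-255 scale.
#' @param offset Integer length-2 vector, 0-based `(row, col)` of the crop's
#'   top-left pixel in the source image (half-open window convention).
#' @param source_id,grain_id Character identifiers carried through reports.
#'
#' @return An object of class `grain_region`.
#' @export
grain_region <- function(mask, crop, offset = c(0L, 0L),
                         source_id = NA_character_, grain_id = NA_character_) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (length(dim(crop)) != 3L || dim(crop)[3] != 3L)
    stop("`crop` must be an H x W x 3 RGB array")
  if (!all(dim(crop)[1:2] == dim(mask)))
    stop("`mask` and `crop` must have identical height and width")
  if (any(crop < 0) || any(crop > 255))
    stop("`crop` must be on the 0-255 scale")
  structure(
    list(mask = mask, crop = crop, offset = as.integer(offset),
         source_id = source_id, grain_id = grain_id),
    class = "grain_region"
  )
}

#' @export
print.grain_region <- function(x, ...) {
  cat(sprintf("<grain_region %s> %d x %d px, area %d, offset (%d, %d), source %s\n",
              x$grain_id, nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$offset[1], x$offset[2], x$source_id))
  invisible(x)
}

#' @rdname grain_region
#' @param x Object to test.
#' @export
is_grain_region <- function(x) inherits(x, "grain_region")

# Flat-colour region straight from a mask; used by fixtures and the
# analytic-shape renderer.
region_from_mask <- function(mask, color = c(190, 160, 95),
                             grain_id = NA_character_) {
  crop <- array(0, dim = c(dim(mask), 3L))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(mask), ncol(mask))
    plane[mask] <- color[ch]
    crop[, , ch] <- plane
  }
  grain_region(mask, crop, grain_id = grain_id)
}

# Foreground luminance (ITU-R BT.601 weights), full crop, 0-255 scale.
region_luminance <- function(crop) {
  0.299 * crop[, , 1] + 0.587 * crop[, , 2] + 0.114 * crop[, , 3]
}
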