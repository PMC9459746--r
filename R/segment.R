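#' Segment individual grains from an image
#'
#' Converts the image to luminance, thresholds it (Otsu by default, with the
#' foreground polarity auto-detected by comparing the border median to the
#' threshold), labels 8-connected foreground components, fills internal
#' holes, discards components below `min_area` and returns one
#' [grain_region] per surviving component, ordered row-major by centroid.
#'
#' @param image Numeric `H x W x 3` RGB array on the 0-255 scale (arrays on
#'   0-1 are rescaled).
#' @param min_area Minimum component area in pixels (default 50).
#' @param threshold_mode `"otsu"` or `"fixed"`.
#' @param threshold Grey level 0-255, required when `threshold_mode =
#'   "fixed"`.
#' @param source_id Identifier recorded in each region's provenance.
#'
#' @return List of [grain_region] objects; empty list when nothing survives
#'   the area filter.
#' @export
segment_image <- function(image, min_area = 50,
                          threshold_mode = c("otsu", "fixed"),
                          threshold = NULL, source_id = NA_character_) {
  threshold_mode <- match.arg(threshold_mode)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("format error: expected an H x W x 3 RGB array")
  if (max(image) <= 1) image <- image * 255
  gray <- region_luminance(image) / 255

  thr <- if (threshold_mode == "otsu") {
    EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  } else {
    if (is.null(threshold)) stop("fixed mode requires `threshold`")
    threshold / 255
  }
  border <- c(gray[1, ], gray[nrow(gray), ], gray[, 1], gray[, ncol(gray)])
  object_brighter <- median(border) <= thr
  fg <- if (object_brighter) gray > thr else gray < thr

  lab <- label_components8(fg)
  if (max(lab) == 0L) return(list())
  lab <- EBImage::fillHull(lab)

  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) return(list())

  # centroids for row-major ordering
  idx <- which(lab > 0L & lab %in% keep, arr.ind = TRUE)
  labs <- lab[lab > 0L & lab %in% keep]
  cr <- vapply(keep, function(k) mean(idx[labs == k, 1]), numeric(1))
  cc <- vapply(keep, function(k) mean(idx[labs == k, 2]), numeric(1))
  keep <- keep[order(cr, cc)]

  regions <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    sel <- lab == keep[i]
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    mask <- sel[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    crop <- image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
    regions[[i]] <- grain_region(
      mask, crop, offset = c(rows[1] - 1L, cols[1] - 1L),
      source_id = source_id, grain_id = sprintf("g%04d", i)
    )
  }
  regions
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels touching only diagonally are merged through a union-find pass.
label_components8 <- function(fg) {
  lab <- EBImage::bwlabel(fg)
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-H, -1]), as.vector(lab[-1, -W]))   # down-left
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Centroids of segmented regions in source coordinates
#'
#' Convenience for matching segmentation output against a generator truth
#' table: 0-based `(row, col)` foreground centroid of each region in the
#' coordinates of the source image.
#'
#' @param regions List of [grain_region] objects.
#' @return Data frame with `grain_id`, `row`, `col`, `area`.
#' @export
region_centroids <- function(regions) {
  do.call(rbind, lapply(regions, function(r) {
    idx <- which(r$mask, arr.ind = TRUE)
    data.frame(grain_id = r$grain_id,
               row = mean(idx[, 1]) - 0.5 + r$offset[1] - 0.5,
               col = mean(idx[, 2]) - 0.5 + r$offset[2] - 0.5,
               area = nrow(idx))
  }))
}
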