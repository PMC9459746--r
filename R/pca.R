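#' Covariance (or correlation) matrix of a descriptor matrix
#'
#' Sample covariance with denominator `n - 1`; with `standardize = TRUE`
#' the correlation matrix is returned instead, which is the scale on which
#' the Kaiser eigenvalue-above-1 retention rule is meaningful.
#' Zero-variance columns cannot be standardized; they are dropped with a
#' warning and recorded in the `"dropped"` attribute.
#'
#' @param data Numeric matrix or data frame, observations in rows (n >= 2).
#' @param standardize Return the correlation matrix?
#' @return `p x p` symmetric matrix (possibly with columns dropped), with
#'   attribute `"dropped"` naming removed columns.
#' @export
covariance_matrix <- function(data, standardize = TRUE) {
  X <- as.matrix(data)
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (!all(is.finite(X))) stop("non-finite values in descriptor matrix")
  dropped <- character(0)
  if (standardize) {
    v <- apply(X, 2, stats::var)
    zero <- v <= .Machine$double.eps * max(v, 1)
    if (any(zero)) {
      dropped <- colnames(X)[zero]
      warning("dropping zero-variance column(s): ",
              paste(dropped, collapse = ", "))
      X <- X[, !zero, drop = FALSE]
    }
    C <- cor(X)
  } else {
    C <- cov(X)
  }
  attr(C, "dropped") <- dropped
  C
}

#' Spectral decomposition of a covariance matrix
#'
#' Eigendecomposition of a symmetric matrix with eigenvalues sorted
#' non-increasing and a deterministic sign convention: the
#' largest-magnitude entry of each eigenvector is positive.
#'
#' @param cov Symmetric numeric matrix (asymmetry beyond 1e-9 is an error).
#' @return List with `values` (sorted eigenvalues) and `vectors`
#'   (orthonormal columns).
#' @export
spectral_decomposition <- function(cov) {
  cov <- as.matrix(cov)
  if (max(abs(cov - t(cov))) > 1e-9)
    stop("argument error: matrix is not symmetric")
  e <- eigen((cov + t(cov)) / 2, symmetric = TRUE)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- rownames(cov)
  list(values = e$values, vectors = V)
}

#' Choose the number of retained principal components
#'
#' `"kaiser"` counts eigenvalues above 1, which presumes the
#' correlation-matrix scale (an error is raised otherwise); `"fixed_k"`
#' retains `min(k, p)` components. The pipeline default is a fixed 8.
#'
#' @param eigenvalues Eigenvalues sorted non-increasing.
#' @param rule `"kaiser"` or `"fixed_k"`.
#' @param k Component count for `"fixed_k"`.
#' @param standardized Was the model fitted on the correlation scale?
#' @return Integer count of retained components (at least 1).
#' @export
select_components <- function(eigenvalues, rule = c("fixed_k", "kaiser"),
                              k = 8L, standardized = TRUE) {
  rule <- match.arg(rule)
  if (rule == "kaiser") {
    if (!standardized)
      stop("Kaiser criterion requires correlation-scale (standardized) PCA")
    max(1L, sum(eigenvalues > 1))
  } else {
    min(as.integer(k), length(eigenvalues))
  }
}

#' Fit a principal component model to a descriptor table
#'
#' Centres (and by default standardizes) the descriptor columns, builds the
#' covariance/correlation matrix, decomposes it and selects the retained
#' components. Standardization is the default because the 64 descriptors
#' mix incommensurable units (px, px^2, ratios, grey levels).
#'
#' @param data Numeric matrix or data frame of descriptors (observations
#'   in rows; non-numeric columns such as `grain_id`, `label`, `fraction`
#'   are ignored automatically for data frames).
#' @param standardize Use the correlation scale (default `TRUE`).
#' @param rule,k Component selection, see [select_components()].
#' @return An object of class `pca_model`: `center`, `scale`,
#'   `eigenvalues`, `vectors`, `k_retained`, `explained_pct`, `names`,
#'   `standardized`, `dropped`.
#' @export
fit_pca <- function(data, standardize = TRUE,
                    rule = c("fixed_k", "kaiser"), k = 8L) {
  rule <- match.arg(rule)
  X <- descriptor_matrix(data)
  C <- covariance_matrix(X, standardize = standardize)
  dropped <- attr(C, "dropped")
  if (length(dropped) > 0) X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  dec <- spectral_decomposition(C)
  ctr <- colMeans(X)
  scl <- if (standardize) apply(X, 2, stats::sd) else rep(1, ncol(X))
  kr <- select_components(dec$values, rule = rule, k = k,
                          standardized = standardize)
  ev <- pmax(dec$values, 0)
  structure(
    list(center = ctr, scale = scl, eigenvalues = dec$values,
         vectors = dec$vectors, k_retained = kr,
         explained_pct = 100 * ev / sum(ev),
         names = colnames(X), standardized = standardize,
         dropped = dropped),
    class = "pca_model"
  )
}

# pull the numeric descriptor columns out of whatever the caller passed
descriptor_matrix <- function(data) {
  if (is.data.frame(data)) {
    keep <- intersect(canonical_descriptors(), names(data))
    if (length(keep) > 0) data <- data[keep]
    else data <- data[vapply(data, is.numeric, logical(1))]
  }
  X <- as.matrix(data)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d descriptors, %d retained component(s), %s scale\n",
              length(x$names), x$k_retained,
              if (x$standardized) "correlation" else "covariance"))
  cat("explained %:",
      paste(sprintf("%.2f", head(x$explained_pct, x$k_retained)),
            collapse = " "), "\n")
  invisible(x)
}

#' Project descriptor data onto the retained principal components
#'
#' Applies the orthogonal transform `Y = P' (U - mu) / s` for the retained
#' components. On the training data the score columns are uncorrelated
#' with variances equal to the eigenvalues.
#'
#' @param object A `pca_model`.
#' @param data Descriptor matrix or table with the model's columns.
#' @param k Number of components (default: the model's `k_retained`).
#' @param ... Unused.
#' @return Matrix of scores with columns `PC1..PCk`; row labels carried
#'   over when `data` has a `label` column (attribute `"label"`).
#' @export
predict.pca_model <- function(object, data, k = object$k_retained, ...) {
  X <- descriptor_matrix(data)
  if (!all(object$names %in% colnames(X)))
    stop("schema error: data lack the model's descriptor columns")
  X <- X[, object$names, drop = FALSE]
  k <- min(k, length(object$eigenvalues))
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  scores <- Z %*% object$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  if (is.data.frame(data) && "label" %in% names(data))
    attr(scores, "label") <- data$label
  scores
}

#' Rank descriptors by loading on one component
#'
#' Loadings are eigenvector entries scaled by the square root of the
#' eigenvalue; descriptors are ordered by absolute loading, descending —
#' the order of significance of assignment to that component.
#'
#' @param model A `pca_model`.
#' @param component Component index (<= `k_retained`).
#' @param top_m Optional cut: return only the `top_m` strongest names.
#' @return Data frame `descriptor`, `loading`, ordered by `|loading|`.
#' @export
rank_descriptors <- function(model, component = 1L, top_m = NULL) {
  if (component > model$k_retained)
    stop("index error: component exceeds retained count")
  loading <- model$vectors[, component] * sqrt(max(model$eigenvalues[component], 0))
  ord <- order(abs(loading), decreasing = TRUE)
  out <- data.frame(descriptor = model$names[ord], loading = loading[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(top_m)) out <- head(out, top_m)
  out
}

#' Explained-variance report
#'
#' @param model A `pca_model`.
#' @param k Number of components to report (default: retained).
#' @return Data frame `component`, `eigenvalue`, `explained_pct`,
#'   `cumulative_pct`.
#' @export
explained_variance_table <- function(model, k = model$k_retained) {
  k <- min(k, length(model$eigenvalues))
  data.frame(component = paste0("PC", seq_len(k)),
             eigenvalue = model$eigenvalues[seq_len(k)],
             explained_pct = model$explained_pct[seq_len(k)],
             cumulative_pct = cumsum(model$explained_pct)[seq_len(k)])
}

#' Serialize / restore a PCA model as JSON
#'
#' @param model A `pca_model`.
#' @param path JSON file path.
#' @return `path` (write) / the restored `pca_model` (read).
#' @export
pca_write_json <- function(model, path) {
  jsonlite::write_json(
    list(center = model$center, scale = model$scale,
         eigenvalues = model$eigenvalues,
         vectors = model$vectors, k_retained = model$k_retained,
         explained_pct = model$explained_pct, names = model$names,
         standardized = model$standardized, dropped = model$dropped),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname pca_write_json
#' @export
pca_read_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  o$center <- unlist(o$center); o$scale <- unlist(o$scale)
  o$vectors <- as.matrix(o$vectors)
  o$k_retained <- as.integer(o$k_retained)
  structure(o, class = "pca_model")
}
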