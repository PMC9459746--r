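#' Configuration of an end-to-end pipeline run
#'
#' Exactly one input source must be given: a [synth_config()] (generate
#' images on the fly), a directory of grain images with an optional
#' `truth.csv`, or a pre-computed descriptor CSV (which skips the
#' segmentation and extraction stages).
#'
#' @param synth A [synth_config()], or `NULL`.
#' @param image_dir Directory of PNG images (with `truth.csv` for labels),
#'   or `NULL`.
#' @param descriptor_csv Path to a descriptor table CSV, or `NULL`.
#' @param fraction Fraction tag recorded in reports.
#' @param standardize Correlation-scale PCA (default `TRUE`).
#' @param rule,k Component retention, see [select_components()].
#' @param train A [train_config()].
#' @param hidden_sizes Topology-search candidates (default 2..31).
#' @param min_area Segmentation area filter, px.
#' @param out_dir Parent directory for run artifacts.
#' @param rng_seed Master seed fanned out to every stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, image_dir = NULL,
                            descriptor_csv = NULL,
                            fraction = if (!is.null(synth)) synth$fraction else NA_character_,
                            standardize = TRUE,
                            rule = "fixed_k", k = 8L,
                            train = NULL, hidden_sizes = 2:31,
                            min_area = 50, out_dir = tempdir(),
                            rng_seed = 1L) {
  sources <- !c(is.null(synth), is.null(image_dir), is.null(descriptor_csv))
  if (sum(sources) != 1L)
    stop("exactly one input source (synth / image_dir / descriptor_csv) required")
  if (is.null(train)) train <- train_config(rng_seed = rng_seed + 1L)
  structure(
    list(synth = synth, image_dir = image_dir,
         descriptor_csv = descriptor_csv, fraction = fraction,
         standardize = standardize, rule = rule, k = as.integer(k),
         train = train, hidden_sizes = hidden_sizes, min_area = min_area,
         out_dir = out_dir, rng_seed = as.integer(rng_seed)),
    class = "pipeline_config"
  )
}

#' Run the full grain-quality pipeline
#'
#' Generate or ingest images, segment them into grain regions, extract
#' the 64-descriptor bank, reduce it by PCA, train the perceptron
#' topology search, and write all artifacts to a fresh run directory:
#' `descriptors.csv`, `pca_model.json`, `explained_variance.csv`,
#' `descriptor_ranking.csv`, `mlp_model.json`, `evaluation.csv` and
#' `run.log`. Tabular artifacts are byte-stable under a fixed seed; only
#' the run-directory name and log timestamps vary.
#'
#' @param cfg A [pipeline_config()].
#' @return The run directory path, invisibly, with the stage results
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  run_dir <- file.path(cfg$out_dir,
                       sprintf("run_%s_seed%d",
                               format(Sys.time(), "%Y%m%d-%H%M%S"),
                               cfg$rng_seed))
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(run_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  log_line("pipeline start, seed ", cfg$rng_seed,
           ", grainscan ", as.character(utils::packageVersion("grainscan")),
           ", R ", getRversion())

  stage <- "input"
  result <- try({
    if (!is.null(cfg$descriptor_csv)) {
      log_line("stage input: reading descriptor table ", cfg$descriptor_csv)
      desc <- read_descriptors(cfg$descriptor_csv)
      truth <- NULL
    } else {
      if (!is.null(cfg$synth)) {
        stage <- "synth"
        log_line("stage synth: rendering ", cfg$synth$n_grains, " grains")
        ds <- render_dataset(cfg$synth)
        images <- ds$images
        truth <- ds$truth
      } else {
        stage <- "ingest"
        files <- sort(list.files(cfg$image_dir, pattern = "\\.(png|tif|tiff)$",
                                 full.names = TRUE))
        log_line("stage ingest: ", length(files), " images from ",
                 cfg$image_dir)
        images <- lapply(files, read_image)
        tf <- file.path(cfg$image_dir, "truth.csv")
        truth <- if (file.exists(tf))
          read.csv(tf, stringsAsFactors = FALSE) else NULL
      }
      stage <- "segment"
      regions <- list()
      region_image <- integer(0)
      for (i in seq_along(images)) {
        regs <- segment_image(images[[i]], min_area = cfg$min_area,
                              source_id = sprintf("img%04d", i))
        regions <- c(regions, regs)
        region_image <- c(region_image, rep(i, length(regs)))
      }
      for (i in seq_along(regions))
        regions[[i]]$grain_id <- sprintf("g%04d", i)
      log_line("stage segment: ", length(regions), " regions")

      labels <- match_truth_labels(regions, region_image, truth)
      stage <- "descriptors"
      desc <- descriptor_table(regions, labels = labels,
                               fraction = cfg$fraction)
      log_line("stage descriptors: ", nrow(desc), " x 64 table")
    }
    write_descriptors(desc, file.path(run_dir, "descriptors.csv"))

    stage <- "pca"
    pca <- fit_pca(desc, standardize = cfg$standardize,
                   rule = cfg$rule, k = cfg$k)
    log_line("stage pca: ", pca$k_retained, " components, ",
             sprintf("%.1f", sum(pca$explained_pct[seq_len(pca$k_retained)])),
             "% variance")
    pca_write_json(pca, file.path(run_dir, "pca_model.json"))
    write.csv(explained_variance_table(pca),
              file.path(run_dir, "explained_variance.csv"), row.names = FALSE)
    write.csv(rank_descriptors(pca, component = 1L),
              file.path(run_dir, "descriptor_ranking.csv"), row.names = FALSE)

    stage <- "mlp"
    scores <- predict(pca, desc)
    y <- desc$label
    if (is.null(y) || anyNA(y))
      stop("labels are required to train the classifier")
    search <- topology_search(scores, y, hidden_sizes = cfg$hidden_sizes,
                              cfg = cfg$train)
    log_line("stage mlp: best ", attr(search$report, "topology"),
             ", test quality ",
             sprintf("%.2f", search$report$value[6]), "%")
    mlp_write_json(search$model, file.path(run_dir, "mlp_model.json"))
    eval_out <- search$report
    eval_out$topology <- attr(search$report, "topology")
    write.csv(eval_out, file.path(run_dir, "evaluation.csv"),
              row.names = FALSE)
    write.csv(search$leaderboard, file.path(run_dir, "leaderboard.csv"),
              row.names = FALSE)

    list(descriptors = desc, pca = pca, scores = scores, search = search,
         truth = if (exists("truth")) truth else NULL,
         n_regions = if (exists("regions")) length(regions) else NA_integer_)
  }, silent = TRUE)

  if (inherits(result, "try-error")) {
    log_line("FAILED at stage ", stage, ": ",
             conditionMessage(attr(result, "condition")))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(attr(result, "condition")))
  }
  log_line("pipeline done")
  invisible(structure(run_dir, results = result))
}

# Attach generator truth labels to segmented regions by nearest centroid
# within the source image; returns NA labels when no truth is available.
match_truth_labels <- function(regions, region_image, truth) {
  if (is.null(truth) || length(regions) == 0L)
    return(NULL)
  cent <- region_centroids(regions)
  labels <- rep(NA_integer_, length(regions))
  for (i in seq_along(regions)) {
    cand <- which(truth$image == region_image[i])
    if (length(cand) == 0L) next
    dd <- (truth$center_row[cand] - cent$row[i])^2 +
      (truth$center_col[cand] - cent$col[i])^2
    labels[i] <- truth$label[cand[which.min(dd)]]
  }
  labels
}

#' Contamination report from a truth table
#'
#' Percentage of grains per damage class within each size fraction;
#' every fraction column sums to 100.
#'
#' @param truth Data frame with `damage_class` and `fraction` columns
#'   (the generator's truth table).
#' @return Data frame with `damage_class` rows and one percentage column
#'   per fraction.
#' @export
report_contamination <- function(truth) {
  if (is.null(truth) || nrow(truth) == 0L) stop("empty truth table")
  fr <- unique(truth$fraction)
  classes <- sort(unique(truth$damage_class))
  out <- data.frame(damage_class = classes, stringsAsFactors = FALSE)
  for (f in fr) {
    sub <- truth$damage_class[truth$fraction == f]
    out[[f]] <- 100 * vapply(classes, function(cl) mean(sub == cl),
                             numeric(1))
  }
  out
}
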