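#' Construct an n-h-1 multilayer perceptron
#'
#' Input units are linear pass-throughs; the hidden layer and the single
#' output unit aggregate by weighted sum (linear postsynaptic function) and
#' fire through the logistic activation, so the output is a probability in
#' (0, 1) interpreted as "good grain". Weights and biases are initialized
#' uniformly on (-0.5, 0.5) under the given seed.
#'
#' @param n_in Number of inputs (8 in the default pipeline: the retained
#'   principal components).
#' @param n_hidden Hidden-layer size.
#' @param rng_seed Integer seed controlling the initialization.
#' @return An object of class `mlp_model` with `W1` (`n_hidden x n_in`),
#'   `b1`, `W2` (`1 x n_hidden`), `b2`.
#' @export
mlp_model <- function(n_in, n_hidden, rng_seed = 1L) {
  stopifnot(n_in >= 1, n_hidden >= 1)
  set.seed(rng_seed)
  structure(
    list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
         W1 = matrix(runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
         b1 = runif(n_hidden, -0.5, 0.5),
         W2 = matrix(runif(n_hidden, -0.5, 0.5), 1L, n_hidden),
         b2 = runif(1L, -0.5, 0.5)),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(topology_string(x), "\n")
  invisible(x)
}

#' Topology label of a model, e.g. `"MLP: 8-14-1"`
#' @param model An `mlp_model`.
#' @export
topology_string <- function(model) {
  sprintf("MLP: %d-%d-1", model$n_in, model$n_hidden)
}

logistic <- function(t) 1 / (1 + exp(-t))

#' Forward pass
#'
#' `z = sigma(W2 sigma(W1 x + b1) + b2)` with the logistic
#' `sigma(t) = 1 / (1 + exp(-t))`, vectorized over the rows of `X`.
#'
#' @param model An `mlp_model`.
#' @param X Numeric matrix (`n x n_in`) or a single input vector.
#' @return Numeric vector of `n` outputs in (0, 1).
#' @export
mlp_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$n_in) stop("dimension mismatch: expected ",
                                  model$n_in, " inputs")
  H <- logistic(tcrossprod(X, model$W1) +
                  rep(model$b1, each = nrow(X)))
  as.vector(logistic(tcrossprod(H, model$W2) + model$b2))
}

#' Root-mean-square error of a model on a labelled dataset
#'
#' `sqrt(sum((y_i - z_i)^2) / n)` with `y` the 0/1 target labels and `z`
#' the network outputs.
#'
#' @param model An `mlp_model`.
#' @param X Input matrix.
#' @param y 0/1 label vector.
#' @return Non-negative scalar.
#' @export
rms_error <- function(model, X, y) {
  if (length(y) == 0L) stop("empty dataset")
  z <- mlp_forward(model, X)
  sqrt(mean((y - z)^2))
}

#' Exact back-propagated gradients of the sum-of-squares loss
#'
#' Gradients of `E = 1/2 sum((z - y)^2)` with respect to every weight and
#' bias, computed by back-propagation over the full batch.
#'
#' @inheritParams rms_error
#' @return List `W1`, `b1`, `W2`, `b2` of the same shapes as the model,
#'   plus the scalar `loss`.
#' @export
backprop_gradient <- function(model, X, y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  H <- logistic(tcrossprod(X, model$W1) + rep(model$b1, each = nrow(X)))
  z <- as.vector(logistic(tcrossprod(H, model$W2) + model$b2))
  err <- z - y
  d2 <- err * z * (1 - z)                     # n
  d1 <- (d2 %*% model$W2) * H * (1 - H)       # n x h
  list(W1 = crossprod(d1, X), b1 = colSums(d1),
       W2 = matrix(crossprod(d2, H), 1L), b2 = sum(d2),
       loss = 0.5 * sum(err^2))
}

#' Training configuration for the back-propagation / conjugate-gradient
#' protocol
#'
#' Defaults reproduce the reference protocol: 10 cycles of 1000 full-batch
#' back-propagation epochs with the learning rate decreasing linearly from
#' 0.2 to 0.1 over the whole run and momentum 0.4, followed by 600
#' conjugate-gradient epochs; data split 50/25/25 into training,
#' validation and test files, stratified by label.
#'
#' @param bp_cycles,bp_epochs_per_cycle Back-propagation schedule; the
#'   trace records one row per cycle.
#' @param eta_start,eta_end Learning-rate endpoints (linear decay).
#' @param momentum Momentum factor in `[0, 1)`.
#' @param cg_epochs Conjugate-gradient refinement epochs.
#' @param rng_seed Seed fanned out to splits and per-topology inits.
#' @param split Named fractions `train`, `valid`, `test` summing to 1.
#' @return An object of class `train_config`.
#' @export
train_config <- function(bp_cycles = 10L, bp_epochs_per_cycle = 1000L,
                         eta_start = 0.2, eta_end = 0.1, momentum = 0.4,
                         cg_epochs = 600L, rng_seed = 1L,
                         split = c(train = 0.5, valid = 0.25, test = 0.25)) {
  stopifnot(eta_end > 0, eta_end <= eta_start,
            momentum >= 0, momentum < 1,
            abs(sum(split) - 1) < 1e-9)
  structure(list(bp_cycles = as.integer(bp_cycles),
                 bp_epochs_per_cycle = as.integer(bp_epochs_per_cycle),
                 eta_start = eta_start, eta_end = eta_end,
                 momentum = momentum, cg_epochs = as.integer(cg_epochs),
                 rng_seed = as.integer(rng_seed), split = split),
            class = "train_config")
}

#' Train by full-batch back-propagation with momentum
#'
#' Classic gradient descent on the sum-of-squares loss with momentum
#' `Delta w(t) = -eta(t) grad E + alpha Delta w(t-1)` and the learning
#' rate decreasing linearly from `eta_start` to `eta_end` across all
#' `bp_cycles * bp_epochs_per_cycle` epochs. Deterministic: the only
#' randomness is the model's initialization seed.
#'
#' @param model An `mlp_model` (freshly initialized or pre-trained).
#' @param X,y Training inputs and 0/1 labels.
#' @param cfg A [train_config()].
#' @return List `model` (trained) and `trace` (data frame with one row per
#'   cycle: `cycle`, `epoch`, `eta`, `rms`).
#' @export
train_bp <- function(model, X, y, cfg = train_config()) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  total <- cfg$bp_cycles * cfg$bp_epochs_per_cycle
  etas <- if (total == 1L) cfg$eta_start else
    seq(cfg$eta_start, cfg$eta_end, length.out = total)
  vW1 <- model$W1 * 0; vb1 <- model$b1 * 0
  vW2 <- model$W2 * 0; vb2 <- 0
  al <- cfg$momentum
  rms0 <- rms_error(model, X, y)
  trace <- data.frame(cycle = seq_len(cfg$bp_cycles), epoch = NA_integer_,
                      eta = NA_real_, rms = NA_real_)
  ep <- 0L
  for (cyc in seq_len(cfg$bp_cycles)) {
    for (k in seq_len(cfg$bp_epochs_per_cycle)) {
      ep <- ep + 1L
      g <- backprop_gradient(model, X, y)
      eta <- etas[ep]
      vW1 <- -eta * g$W1 + al * vW1; model$W1 <- model$W1 + vW1
      vb1 <- -eta * g$b1 + al * vb1; model$b1 <- model$b1 + vb1
      vW2 <- -eta * g$W2 + al * vW2; model$W2 <- model$W2 + vW2
      vb2 <- -eta * g$b2 + al * vb2; model$b2 <- model$b2 + vb2
    }
    r <- rms_error(model, X, y)
    trace$epoch[cyc] <- ep; trace$eta[cyc] <- etas[ep]; trace$rms[cyc] <- r
    if (!is.finite(r) || r > 10 * max(rms0, 0.1))
      stop("divergence: RMS ", signif(r, 4), " exceeded 10x the initial ",
           signif(rms0, 4), " at epoch ", ep)
  }
  list(model = model, trace = trace)
}

#' Polak-Ribiere conjugate-gradient minimizer
#'
#' General-purpose nonlinear CG with the PR+ update (negative beta is
#' clipped to a steepest-descent restart), backtracking Armijo line
#' search, and a forced restart every `restart_every` iterations. The
#' objective never increases; if the line search fails even along the
#' steepest-descent direction, iteration stops with a warning.
#'
#' @param par Initial parameter vector.
#' @param fn,gr Objective and gradient functions of `par`.
#' @param maxit Maximum iterations.
#' @param restart_every Forced steepest-descent restart period (default:
#'   number of parameters).
#' @return List `par`, `value`, `iterations`.
#' @export
cg_minimize <- function(par, fn, gr, maxit = 600L,
                        restart_every = length(par)) {
  f <- fn(par)
  g <- gr(par)
  d <- -g
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    gnorm2 <- sum(g^2)
    if (gnorm2 < 1e-20) break
    slope <- sum(g * d)
    if (slope >= 0) { d <- -g; slope <- -gnorm2 }
    # backtracking Armijo search
    step_ok <- FALSE
    alpha <- 1
    for (half in 1:40) {
      fnew <- fn(par + alpha * d)
      if (is.finite(fnew) && fnew <= f + 1e-4 * alpha * slope) {
        step_ok <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!step_ok) {
      if (all(d == -g)) {
        warning("conjugate-gradient line search failed; returning current point")
        break
      }
      d <- -g  # steepest-descent restart, retry this iteration
      it <- it - 1L
      next
    }
    par <- par + alpha * d
    f <- fnew
    gnew <- gr(par)
    beta <- if (it %% restart_every == 0L) 0 else
      max(0, sum(gnew * (gnew - g)) / gnorm2)
    d <- -gnew + beta * d
    g <- gnew
  }
  list(par = par, value = f, iterations = it)
}

flatten_params <- function(model)
  c(as.vector(model$W1), model$b1, as.vector(model$W2), model$b2)

unflatten_params <- function(model, par) {
  h <- model$n_hidden; p <- model$n_in
  model$W1 <- matrix(par[seq_len(h * p)], h, p)
  model$b1 <- par[h * p + seq_len(h)]
  model$W2 <- matrix(par[h * p + h + seq_len(h)], 1L, h)
  model$b2 <- par[h * p + 2L * h + 1L]
  model
}

#' Refine a trained perceptron by conjugate gradients
#'
#' Minimizes the same sum-of-squares loss as [train_bp()] with
#' [cg_minimize()]; the loss never increases relative to the input model,
#' and a zero-epoch call returns the model unchanged.
#'
#' @inheritParams train_bp
#' @param epochs Maximum CG iterations (default 600).
#' @return The refined `mlp_model`.
#' @export
train_cg <- function(model, X, y, epochs = 600L) {
  if (epochs <= 0L) return(model)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  fn <- function(par) {
    m <- unflatten_params(model, par)
    z <- mlp_forward(m, X)
    0.5 * sum((z - y)^2)
  }
  gr <- function(par) {
    m <- unflatten_params(model, par)
    g <- backprop_gradient(m, X, y)
    c(as.vector(g$W1), g$b1, as.vector(g$W2), g$b2)
  }
  res <- cg_minimize(flatten_params(model), fn, gr, maxit = epochs)
  unflatten_params(model, res$par)
}

#' Threshold network outputs into good/damaged labels
#'
#' @param model A fitted `mlp_model`.
#' @param X Input matrix.
#' @param threshold Decision threshold; outputs greater than or equal to
#'   it (boundary inclusive) are labelled 1 = good.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(model, X, threshold = 0.5) {
  as.integer(mlp_forward(model, X) >= threshold)
}

percent_correct <- function(model, X, y, threshold = 0.5) {
  100 * mean(classify(model, X, threshold) == y)
}

#' Stratified train/validation/test split
#'
#' Shuffles within each label class under the given seed and deals cases
#' into the three files at the configured fractions.
#'
#' @param y Label vector.
#' @param split Named fractions `train`, `valid`, `test`.
#' @param rng_seed Integer seed.
#' @return List of integer index vectors `train`, `valid`, `test`.
#' @export
stratified_split <- function(y, split = c(train = 0.5, valid = 0.25, test = 0.25),
                             rng_seed = 1L) {
  set.seed(rng_seed)
  idx <- list(train = integer(0), valid = integer(0), test = integer(0))
  for (cl in unique(y)) {
    pool <- sample(which(y == cl))
    n <- length(pool)
    n_tr <- round(split[["train"]] * n)
    n_va <- round(split[["valid"]] * n)
    idx$train <- c(idx$train, pool[seq_len(n_tr)])
    idx$valid <- c(idx$valid, pool[n_tr + seq_len(min(n_va, n - n_tr))])
    idx$test <- c(idx$test, pool[seq_len(n) > n_tr + n_va])
  }
  if (any(vapply(idx, length, integer(1)) == 0L) ||
      any(vapply(idx, function(i) length(unique(y[i])), integer(1)) <
            length(unique(y))))
    stop("stratification error: a class is absent from one of the splits")
  lapply(idx, sort)
}

#' Search hidden-layer topologies and select the best classifier
#'
#' Trains one perceptron per candidate hidden size (default 2..31, i.e.
#' 30 topologies) under the full protocol — back-propagation with momentum
#' followed by conjugate-gradient refinement — on a stratified
#' train/validation/test split. Each topology gets its own deterministic
#' initialization seed (`cfg$rng_seed + h`). The winner maximizes
#' validation percent-correct, with ties broken by smaller validation RMS
#' and then by fewer hidden units; the test file plays no part in the
#' selection.
#'
#' @param X Input matrix (typically principal-component scores).
#' @param y 0/1 labels.
#' @param hidden_sizes Candidate hidden-layer sizes.
#' @param cfg A [train_config()].
#' @return List: `model` (best `mlp_model`), `report` (evaluation of the
#'   winner, see [evaluation_report()]), `leaderboard` (one row per
#'   topology), `split` (the index lists).
#' @export
topology_search <- function(X, y, hidden_sizes = 2:31,
                            cfg = train_config()) {
  X <- as.matrix(X)
  split <- stratified_split(y, cfg$split, cfg$rng_seed)
  lb <- data.frame(h = hidden_sizes,
                   topology = sprintf("MLP: %d-%d-1", ncol(X), hidden_sizes),
                   rms_train = NA_real_, rms_valid = NA_real_,
                   rms_test = NA_real_, pct_train = NA_real_,
                   pct_valid = NA_real_, pct_test = NA_real_,
                   stringsAsFactors = FALSE)
  models <- vector("list", length(hidden_sizes))
  for (i in seq_along(hidden_sizes)) {
    h <- hidden_sizes[i]
    m <- mlp_model(ncol(X), h, rng_seed = cfg$rng_seed + h)
    m <- train_bp(m, X[split$train, , drop = FALSE], y[split$train], cfg)$model
    m <- train_cg(m, X[split$train, , drop = FALSE], y[split$train],
                  epochs = cfg$cg_epochs)
    models[[i]] <- m
    for (s in names(split)) {
      lb[[paste0("rms_", s)]][i] <-
        rms_error(m, X[split[[s]], , drop = FALSE], y[split[[s]]])
      lb[[paste0("pct_", s)]][i] <-
        percent_correct(m, X[split[[s]], , drop = FALSE], y[split[[s]]])
    }
  }
  best <- order(-lb$pct_valid, lb$rms_valid, lb$h)[1]
  list(model = models[[best]],
       report = evaluation_report(models[[best]], X, y, split),
       leaderboard = lb, split = split)
}

#' Per-split evaluation report of a classifier
#'
#' RMS error and percent-correct (threshold 0.5) on the training,
#' validation and test files, in the layout of the reference quality
#' tables.
#'
#' @param model A fitted `mlp_model`.
#' @param X,y Full dataset.
#' @param split Index lists from [stratified_split()].
#' @return Data frame with `measure` and one column per file, plus the
#'   topology string as attribute `"topology"`.
#' @export
evaluation_report <- function(model, X, y, split) {
  val <- function(s, f) f(model, X[split[[s]], , drop = FALSE], y[split[[s]]])
  out <- data.frame(
    measure = c("RMS (training file)", "RMS (validation file)",
                "RMS (testing file)", "Quality of the training file [%]",
                "Quality of the validation file [%]",
                "Quality of the testing file [%]"),
    value = c(val("train", rms_error), val("valid", rms_error),
              val("test", rms_error),
              val("train", percent_correct), val("valid", percent_correct),
              val("test", percent_correct)),
    stringsAsFactors = FALSE
  )
  attr(out, "topology") <- topology_string(model)
  out
}

#' Serialize / restore a perceptron as JSON
#'
#' @param model An `mlp_model`.
#' @param path JSON file path.
#' @export
mlp_write_json <- function(model, path) {
  jsonlite::write_json(
    list(n_in = model$n_in, n_hidden = model$n_hidden,
         W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname mlp_write_json
#' @export
mlp_read_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n_in = as.integer(o$n_in), n_hidden = as.integer(o$n_hidden),
                 W1 = as.matrix(o$W1), b1 = as.numeric(o$b1),
                 W2 = matrix(as.numeric(o$W2), 1L), b2 = as.numeric(o$b2)),
            class = "mlp_model")
}
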