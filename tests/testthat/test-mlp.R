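xor_data <- function() {
  list(X = matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE),
       y = c(0, 1, 1, 0))
}

test_that("forward pass matches closed forms and the per-neuron loop oracle", {
  m <- mlp_model(3, 4, rng_seed = 1)
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2 <- 0
  expect_equal(mlp_forward(m, c(1, -2, 3)), 0.5)

  m1 <- mlp_model(2, 1, rng_seed = 1)
  m1$W1[] <- 0; m1$b1[] <- 0; m1$W2[] <- 1; m1$b2 <- 0
  expect_equal(mlp_forward(m1, c(9, -9)), 1 / (1 + exp(-0.5)))

  set.seed(42)
  for (k in 1:20) {
    m <- mlp_model(5, 7, rng_seed = k)
    x <- rnorm(5)
    expect_equal(mlp_forward(m, x), oracle_forward(m, x), tolerance = 1e-12)
  }
  expect_error(mlp_forward(m, rnorm(4)), "dimension mismatch")
})

test_that("RMS error reproduces its definition", {
  m <- mlp_model(2, 2, rng_seed = 3)
  X <- matrix(rnorm(200), 100, 2)
  y <- rep(c(0, 1), 50)
  z <- mlp_forward(m, X)
  expect_equal(rms_error(m, X, y), sqrt(mean((y - z)^2)), tolerance = 1e-12)
  expect_error(rms_error(m, X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("back-propagated gradients match central finite differences", {
  set.seed(50)
  for (h in c(1, 8, 14, 19)) {
    for (rep in 1:3) {
      m <- mlp_model(4, h, rng_seed = h * 10 + rep)
      X <- matrix(rnorm(32), 8, 4)
      y <- sample(0:1, 8, replace = TRUE)
      g <- backprop_gradient(m, X, y)
      ana <- c(as.vector(g$W1), g$b1, as.vector(g$W2), g$b2)
      num <- numeric_gradient(m, X, y)
      expect_lt(max(abs(ana - num)) / max(abs(num), 1e-8), 1e-6)
    }
  }
})

test_that("gradient contributions are additive over samples", {
  m <- mlp_model(3, 5, rng_seed = 6)
  set.seed(6)
  X <- matrix(rnorm(9), 3, 3)
  y <- c(1, 0, 1)
  g1 <- backprop_gradient(m, X, y)
  Xd <- rbind(X, X[2, ]); yd <- c(y, y[2])
  gd <- backprop_gradient(m, Xd, yd)
  gs <- backprop_gradient(m, X[2, , drop = FALSE], y[2])
  expect_equal(gd$W1, g1$W1 + gs$W1, tolerance = 1e-12)
  expect_equal(gd$b2, g1$b2 + gs$b2, tolerance = 1e-12)
})

test_that("gradient vanishes where the fit is perfect", {
  m <- mlp_model(1, 2, rng_seed = 2)
  m$W1[] <- 10; m$b1[] <- 0
  m$W2[] <- 20; m$b2 <- -20  # drive outputs to saturation
  X <- matrix(c(5, 5), 2, 1)
  y <- round(mlp_forward(m, X))
  g <- backprop_gradient(m, X, y)
  expect_lt(sqrt(sum(unlist(g[c("W1", "b1", "W2", "b2")])^2)), 1e-3)
})

test_that("momentum-free training reduces to plain gradient descent", {
  d <- xor_data()
  cfg <- train_config(bp_cycles = 1, bp_epochs_per_cycle = 3,
                      eta_start = 0.1, eta_end = 0.1, momentum = 0)
  m0 <- mlp_model(2, 3, rng_seed = 4)
  trained <- train_bp(m0, d$X, d$y, cfg)$model
  m <- m0
  for (i in 1:3) {
    g <- backprop_gradient(m, d$X, d$y)
    m$W1 <- m$W1 - 0.1 * g$W1; m$b1 <- m$b1 - 0.1 * g$b1
    m$W2 <- m$W2 - 0.1 * g$W2; m$b2 <- m$b2 - 0.1 * g$b2
  }
  expect_equal(trained$W1, m$W1, tolerance = 1e-14)
  expect_equal(trained$W2, m$W2, tolerance = 1e-14)
  expect_equal(trained$b2, m$b2, tolerance = 1e-14)
})

test_that("the learning-rate schedule spans its configured endpoints", {
  d <- xor_data()
  cfg <- train_config(bp_cycles = 2, bp_epochs_per_cycle = 5)
  tr <- train_bp(mlp_model(2, 2, rng_seed = 1), d$X, d$y, cfg)$trace
  etas <- seq(0.2, 0.1, length.out = 10)
  expect_equal(tr$eta, etas[c(5, 10)], tolerance = 1e-12)
  expect_equal(tr$eta[2], 0.1, tolerance = 1e-12)
  expect_identical(tr$epoch, c(5L, 10L))
  one <- train_config(bp_cycles = 1, bp_epochs_per_cycle = 1)
  tr1 <- train_bp(mlp_model(2, 2, rng_seed = 1), d$X, d$y, one)$trace
  expect_equal(tr1$eta, 0.2)
})

test_that("training is bit-stable under a fixed seed", {
  d <- xor_data()
  cfg <- train_config(bp_cycles = 2, bp_epochs_per_cycle = 100)
  run <- function() {
    m <- mlp_model(2, 4, rng_seed = 9)
    m <- train_bp(m, d$X, d$y, cfg)$model
    train_cg(m, d$X, d$y, epochs = 50)
  }
  expect_identical(run(), run())
})

test_that("the full protocol learns XOR on a sample of seeds", {
  d <- xor_data()
  ok <- 0L
  for (s in 1:10) {
    m <- mlp_model(2, 4, rng_seed = s)
    m <- train_bp(m, d$X, d$y, train_config())$model
    m <- train_cg(m, d$X, d$y, 600)
    if (rms_error(m, d$X, d$y) < 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("conjugate gradients never increase the loss and honour 0 epochs", {
  d <- xor_data()
  for (s in c(2, 13, 77)) {
    m <- mlp_model(2, 4, rng_seed = s)
    short <- train_config(bp_cycles = 1, bp_epochs_per_cycle = 200)
    m <- train_bp(m, d$X, d$y, short)$model
    before <- rms_error(m, d$X, d$y)
    m2 <- train_cg(m, d$X, d$y, 600)
    expect_lte(rms_error(m2, d$X, d$y), before + 1e-12)
  }
  expect_identical(train_cg(m, d$X, d$y, 0), m)
})

test_that("the CG minimizer solves a convex least-squares probe", {
  set.seed(64)
  A <- matrix(rnorm(60), 20, 3)
  b <- rnorm(20)
  fn <- function(w) 0.5 * sum((A %*% w - b)^2)
  gr <- function(w) as.vector(crossprod(A, A %*% w - b))
  res <- cg_minimize(rep(0, 3), fn, gr, maxit = 200)
  exact <- solve(crossprod(A), crossprod(A, b))
  expect_equal(res$par, as.vector(exact), tolerance = 1e-6)
})

test_that("classification thresholds outputs with an inclusive boundary", {
  m <- mlp_model(2, 2, rng_seed = 5)
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2 <- 0  # output exactly 0.5
  expect_identical(classify(m, matrix(rnorm(6), 3, 2)), c(1L, 1L, 1L))
  m$b2 <- 5
  expect_identical(classify(m, matrix(0, 1, 2)), 1L)
  m$b2 <- -5
  expect_identical(classify(m, matrix(0, 1, 2)), 0L)
})

test_that("percent correct equals a confusion-count oracle on scored grains", {
  set.seed(99)
  m <- mlp_model(3, 6, rng_seed = 12)
  X <- matrix(rnorm(3000), 1000, 3)
  y <- sample(0:1, 1000, replace = TRUE)
  pred <- as.integer(mlp_forward(m, X) >= 0.5)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  expect_equal(grainscan:::percent_correct(m, X, y), 100 * (tp + tn) / 1000)
})

test_that("stratified splitting keeps both classes in every file", {
  set.seed(10)
  y <- rep(c(0, 1), c(30, 70))
  sp <- stratified_split(y, rng_seed = 4)
  expect_identical(sort(unname(unlist(sp))), seq_along(y))
  for (s in sp) expect_setequal(unique(y[s]), c(0, 1))
  expect_equal(length(sp$train), 50)
  expect_error(stratified_split(rep(c(0, 1), c(1, 99)), rng_seed = 1),
               "stratification error")
})

test_that("topology search finds a separable problem and reports 30 rows", {
  set.seed(7)
  n <- 120
  X <- rbind(matrix(rnorm(n, mean = -2), n / 2, 2),
             matrix(rnorm(n, mean = 2), n / 2, 2))
  y <- rep(c(0, 1), each = n / 2)
  cfg <- train_config(bp_cycles = 2, bp_epochs_per_cycle = 100,
                      cg_epochs = 60, rng_seed = 11)
  res <- topology_search(X, y, hidden_sizes = 2:31, cfg = cfg)
  expect_identical(nrow(res$leaderboard), 30L)
  expect_gte(res$leaderboard$pct_valid[which.max(res$leaderboard$pct_valid)],
             95)
  expect_gte(res$report$value[6], 90)  # test-file quality
  res2 <- topology_search(X, y, hidden_sizes = 2:31, cfg = cfg)
  expect_identical(res$leaderboard, res2$leaderboard)
})

test_that("an MLP model survives a JSON round trip", {
  m <- mlp_model(8, 14, rng_seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  mlp_write_json(m, path)
  m2 <- mlp_read_json(path)
  X <- matrix(rnorm(80), 10, 8)
  expect_equal(mlp_forward(m2, X), mlp_forward(m, X), tolerance = 1e-12)
  expect_identical(topology_string(m2), "MLP: 8-14-1")
})
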