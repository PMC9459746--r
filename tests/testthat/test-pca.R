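test_that("covariance matches the explicit double-loop oracle", {
  set.seed(12)
  X <- matrix(rnorm(300), 50, 6)
  expect_equal(unname(covariance_matrix(X, standardize = FALSE)),
               oracle_covariance(X), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("duplicated columns show perfect covariance and correlations of 1", {
  set.seed(3)
  x <- rnorm(30)
  X <- cbind(a = x, b = x)
  C <- covariance_matrix(X, standardize = FALSE)
  expect_equal(C[1, 2], C[1, 1])
  R <- covariance_matrix(cbind(X, c = rnorm(30)), standardize = TRUE)
  expect_equal(unname(diag(R)), rep(1, 3))
})

test_that("zero-variance columns are dropped with a warning when standardizing", {
  set.seed(5)
  X <- cbind(a = rnorm(20), b = rep(2, 20), c = rnorm(20))
  expect_warning(C <- covariance_matrix(X, standardize = TRUE),
                 "zero-variance")
  expect_identical(attr(C, "dropped"), "b")
  expect_identical(colnames(C), c("a", "c"))
})

test_that("diagonal and isotropic matrices decompose exactly", {
  d <- spectral_decomposition(diag(c(4, 1)))
  expect_equal(d$values, c(4, 1))
  expect_equal(abs(d$vectors), diag(2))
  i5 <- spectral_decomposition(diag(5))
  expect_equal(i5$values, rep(1, 5))
  rec <- i5$vectors %*% diag(i5$values) %*% t(i5$vectors)
  expect_equal(rec, diag(5), tolerance = 1e-8)
  expect_error(spectral_decomposition(matrix(c(1, 2, 0, 1), 2)),
               "not symmetric")
})

test_that("spectral identities hold on random symmetric matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    A <- matrix(rnorm(100), 10)
    S <- (A + t(A)) / 2
    d <- spectral_decomposition(S)
    expect_lt(abs(sum(d$values) - sum(diag(S))) / max(abs(sum(diag(S))), 1),
              1e-10)
    rec <- d$vectors %*% diag(d$values) %*% t(d$vectors)
    expect_lt(max(abs(rec - S)), 1e-8)
    expect_equal(crossprod(d$vectors), diag(10), tolerance = 1e-8)
    expect_true(all(diff(d$values) <= 1e-12))
  }
})

test_that("component selection follows the Kaiser and fixed-k rules", {
  expect_identical(select_components(c(3.2, 1.5, 1.01, 0.9, 0.4), "kaiser"), 3L)
  expect_identical(select_components(rep(1.5, 64)[1:64], "fixed_k", k = 8), 8L)
  expect_identical(select_components(c(2, 1), "fixed_k", k = 5), 2L)
  expect_error(select_components(c(3, 1), "kaiser", standardized = FALSE),
               "correlation")
})

test_that("Kaiser recovers a planted rank-3 factor model", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    n <- 200; p <- 20
    block <- rep(1:3, length.out = p)
    f <- matrix(rnorm(n * 3, sd = 2), n, 3)
    X <- f[, block] + matrix(rnorm(n * p), n, p)
    m <- fit_pca(X, standardize = TRUE, rule = "kaiser")
    if (m$k_retained == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("eigenvalues match an independent SVD route and scores obey the model", {
  for (seed in 1:100) {
    set.seed(seed)
    X <- matrix(rnorm(500), 50, 10)
    m <- fit_pca(X, standardize = FALSE, rule = "fixed_k", k = 10)
    # SVD of the centred data as the independent decomposition
    Xc <- scale(X, scale = FALSE)
    sv <- svd(Xc)
    ev_svd <- sv$d^2 / (nrow(X) - 1)
    expect_equal(m$eigenvalues, ev_svd, tolerance = 1e-8)
    # principal angles between the leading 3-dim subspaces
    Q1 <- m$vectors[, 1:3]; Q2 <- sv$v[, 1:3]
    cosines <- svd(crossprod(Q1, Q2))$d
    expect_lt(max(acos(pmin(cosines, 1))), 1e-6)
    S <- predict(m, X)
    SC <- cov(S)
    expect_lt(max(abs(SC - diag(diag(SC)))), 1e-6)
    expect_equal(unname(diag(SC)), m$eigenvalues[1:10], tolerance = 1e-6)
    expect_lt(abs(sum(m$eigenvalues) - sum(diag(cov(X)))) /
                abs(sum(diag(cov(X)))), 1e-10)
  }
})

test_that("explained variance percentages are non-increasing and sum to 100", {
  set.seed(8)
  X <- matrix(rnorm(800), 80, 10)
  m <- fit_pca(X, rule = "fixed_k", k = 10)
  expect_true(all(diff(m$explained_pct) <= 1e-12))
  expect_equal(sum(m$explained_pct), 100, tolerance = 1e-6)
  tab <- explained_variance_table(m, k = 10)
  expect_equal(tab$cumulative_pct[10], 100, tolerance = 1e-6)
})

test_that("projection centres the training mean and inverts at full rank", {
  set.seed(23)
  X <- matrix(rnorm(240), 40, 6)
  colnames(X) <- paste0("d", 1:6)
  m <- fit_pca(X, standardize = TRUE, rule = "fixed_k", k = 6)
  mean_row <- matrix(colMeans(X), 1, dimnames = list(NULL, colnames(X)))
  expect_equal(as.vector(predict(m, mean_row)), rep(0, 6), tolerance = 1e-10)
  S <- predict(m, X)
  back <- sweep(sweep(S %*% t(m$vectors), 2, m$scale, `*`), 2, m$center, `+`)
  expect_equal(unname(back), unname(X), tolerance = 1e-8)
  expect_error(predict(m, X[, 1:3]), "schema")
})

test_that("a dominant-variance column ranks first on PC1", {
  set.seed(31)
  X <- cbind(X1 = rnorm(60, sd = 10), X2 = rnorm(60, sd = 1))
  m <- fit_pca(X, standardize = FALSE, rule = "fixed_k", k = 2)
  rk <- rank_descriptors(m, component = 1)
  expect_identical(rk$descriptor[1], "X1")
  expect_identical(nrow(rank_descriptors(m, 1, top_m = 1)), 1L)
  expect_error(rank_descriptors(m, component = 5), "index error")
})

test_that("a PCA model survives a JSON round trip", {
  set.seed(14)
  X <- matrix(rnorm(200), 20, 10)
  colnames(X) <- paste0("v", 1:10)
  m <- fit_pca(X, rule = "fixed_k", k = 4)
  path <- withr::local_tempfile(fileext = ".json")
  pca_write_json(m, path)
  m2 <- pca_read_json(path)
  expect_equal(m2$eigenvalues, m$eigenvalues)
  expect_equal(unname(m2$vectors), unname(m$vectors))
  expect_equal(unname(predict(m2, X)), unname(predict(m, X)))
})
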