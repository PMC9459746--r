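strip_region <- function(lums, pad_rows = 0) {
  # 1 x n foreground strip with prescribed luminance (achromatic colours)
  n <- length(lums)
  mask <- matrix(TRUE, 1, n)
  crop <- array(rep(lums, each = 1), dim = c(1, n, 3))
  grain_region(mask, crop)
}

test_that("quantization handles degenerate, endpoint and random cases", {
  const <- strip_region(rep(120, 6))
  expect_true(all(quantize_gray(const)[const$mask] == 0L))

  two <- strip_region(c(10, 250))
  expect_identical(as.vector(quantize_gray(two, levels = 8)), c(0L, 7L))

  set.seed(77)
  reg <- random_region(77, size = 14)
  q <- quantize_gray(reg, levels = 8)
  lum <- 0.299 * reg$crop[, , 1] + 0.587 * reg$crop[, , 2] +
    0.114 * reg$crop[, , 3]
  v <- lum[reg$mask]
  hand <- pmin(floor((v - min(v)) / (max(v) - min(v)) * 8), 7)
  expect_identical(tabulate(q[reg$mask] + 1L, 8), tabulate(hand + 1L, 8))
  expect_true(all(is.na(q[!reg$mask])))
})

test_that("a constant patch gives the single-cell co-occurrence matrix", {
  q <- matrix(0L, 6, 6)
  f <- compute_glcm_features(q)
  expect_equal(f[["GLCMEnergy"]], 1)
  expect_equal(f[["GLCMContrast"]], 0)
  expect_equal(f[["GLCMHomogeneity"]], 1)
  expect_equal(f[["GLCMCorrelation"]], 1)  # degenerate field convention
})

test_that("hand-enumerated alternating strip co-occurrence is reproduced", {
  q <- matrix(c(0L, 1L, 0L, 1L), 1, 4)
  f <- compute_glcm_features(q, levels = 2, directions = "0")
  # 3 ordered pairs, symmetrized: P(0,1) = P(1,0) = 1/2
  expect_equal(f[["GLCMContrast"]], 1)
  expect_equal(f[["GLCMEnergy"]], 0.5)
  expect_equal(f[["GLCMHomogeneity"]], 0.5)
})

test_that("co-occurrence features equal the brute-force pair counter", {
  for (seed in c(2, 9, 31, 64, 105)) {
    q <- random_patch(seed)
    got <- compute_glcm_features(q, levels = 8)
    want <- oracle_glcm(q, levels = 8)
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("single-run and all-unit-run strips give closed-form run features", {
  one_run <- matrix(0L, 1, 8)
  f <- compute_runlength_features(one_run, directions = "0")
  expect_equal(f[["rSRE"]], 1 / 64)
  expect_equal(f[["rLRE"]], 64)
  expect_equal(f[["rFIR"]], 1 / 8)

  alt <- matrix(rep(c(0L, 1L), 4), 1, 8)
  f2 <- compute_runlength_features(alt, directions = "0")
  expect_equal(f2[["rSRE"]], 1)
  expect_equal(f2[["rLRE"]], 1)
  expect_equal(f2[["rFIR"]], 1)
})

test_that("run-length features equal the brute-force run enumerator", {
  for (seed in c(4, 17, 52, 88, 131)) {
    q <- random_patch(seed)
    got <- compute_runlength_features(q)
    want <- oracle_runlength(q)
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("a flat field has zero gradient everywhere", {
  reg <- render_analytic_shape("disk", r = 10)
  f <- compute_gradient_features(reg)
  expect_equal(f[["MGmean"]], 0)
  expect_equal(f[["ZeroPercent"]], 100)
  expect_equal(f[["MGskew"]], 0)
  expect_equal(f[["MGkurto"]], 0)
})

test_that("a linear luminance ramp recovers its slope", {
  n <- 15
  mask <- matrix(TRUE, n, n)
  crop <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) crop[, , ch] <- matrix(rep(3 * (1:n), each = n), n, n)
  reg <- grain_region(mask, crop)  # luminance = 3 * column index
  f <- compute_gradient_features(reg)
  expect_equal(f[["MGmean"]], 3, tolerance = 1e-12)
  expect_equal(f[["MGvar"]], 0, tolerance = 1e-12)
  expect_equal(f[["ZeroPercent"]], 0)
})

test_that("gradient statistics equal the explicit convolution oracle", {
  for (seed in c(6, 44, 120)) {
    reg <- random_region(seed, size = 18)
    got <- compute_gradient_features(reg)
    want <- oracle_gradient(reg)
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("degenerate textures raise errors", {
  q <- matrix(NA_integer_, 4, 4)
  expect_error(compute_glcm_features(q), "degenerate-texture")
  expect_error(compute_runlength_features(q), "degenerate-texture")
  tiny <- render_analytic_shape("square", side = 2)
  expect_error(compute_gradient_features(tiny), "degenerate-region")
})

test_that("the assembled record is complete, canonical and deterministic", {
  disk <- render_analytic_shape("disk", r = 25)
  v <- extract_all(disk)
  expect_length(v, 64)
  expect_identical(names(v), canonical_descriptors())
  expect_true(all(is.finite(v)))
  expect_gt(v[["GLCMEnergy"]], 0); expect_lte(v[["GLCMEnergy"]], 1)
  expect_gt(v[["GLCMHomogeneity"]], 0); expect_lte(v[["GLCMHomogeneity"]], 1)
  expect_identical(v, extract_all(disk))
})

test_that("descriptor tables are order-invariant and round-trip via CSV", {
  regs <- lapply(c(5, 6, 7), random_region)
  for (i in seq_along(regs)) regs[[i]]$grain_id <- paste0("g", i)
  tab <- descriptor_table(regs, labels = c(1, 0, 1), fraction = "F25")
  tab_rev <- descriptor_table(rev(regs), labels = c(1, 0, 1),
                              fraction = "F25")
  expect_equal(tab[tab$grain_id == "g2", canonical_descriptors()],
               tab_rev[tab_rev$grain_id == "g2", canonical_descriptors()],
               ignore_attr = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptors(tab, path)
  back <- read_descriptors(path)
  for (d in canonical_descriptors())
    expect_equal(back[[d]], tab[[d]], tolerance = 1e-12)
  expect_identical(back$label, tab$label)
})
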