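test_that("the variability filter drops degenerate categorical columns", {
  d <- data.frame(num = rnorm(8),
                  const = rep("x", 8),
                  rare = c("y", rep("n", 7)),
                  ok = rep(c("a", "b"), 4))
  f <- filter_variables(d)
  expect_setequal(names(f), c("num", "ok"))
  expect_error(filter_variables(d[, "const", drop = FALSE]), "no variables")
})

test_that("total inertia decomposes as p_cont + sum(levels - 1)", {
  set.seed(10)
  d <- data.frame(a = rnorm(12), b = runif(12),
                  g = sample(c("x", "y", "z"), 12, TRUE),
                  h = sample(c("u", "v"), 12, TRUE))
  fit <- fit_famd(d, n_axes = 10)
  expect_equal(fit$inertia_total, 2 + (3 - 1) + (2 - 1))
  expect_equal(sum(fit$eigenvalues), fit$inertia_total, tolerance = 1e-8)
  expect_true(all(diff(fit$eigenvalues) < 1e-10))
  expect_true(all(fit$eigenvalues >= -1e-12))
  expect_equal(sum(fit$pct_variance), 100, tolerance = 1e-8)
})

test_that("the all-continuous limit equals standardized principal components", {
  set.seed(11)
  d <- data.frame(a = rnorm(15), b = rnorm(15), c = runif(15))
  fit <- fit_famd(d, n_axes = 3)
  expect_equal(fit$eigenvalues, sort(eigen(cor(d))$values, decreasing = TRUE),
               tolerance = 1e-9)

  # two perfectly correlated columns: one axis carries everything
  d2 <- data.frame(x = 1:10, y = 2 * (1:10) + 3)
  fit2 <- fit_famd(d2)
  expect_equal(fit2$pct_variance[1], 100, tolerance = 1e-8)
})

test_that("the all-categorical limit matches a correspondence-analysis oracle", {
  d <- data.frame(g = c("a", "a", "b", "b", "c", "c"),
                  h = c("u", "v", "u", "v", "v", "u"),
                  k = c("p", "p", "q", "q", "p", "q"))
  fit <- fit_famd(d, n_axes = 10)
  mca <- oracle_mca_eigen(d)
  # with inertia scaled to sum(levels - 1), eigenvalues are Q times the
  # indicator-matrix correspondence-analysis eigenvalues
  expect_equal(fit$eigenvalues, ncol(d) * mca, tolerance = 1e-8)
})

test_that("row geometry is invariant to relabeling and affine rescaling", {
  set.seed(12)
  d <- data.frame(a = rnorm(10), g = sample(c("x", "y"), 10, TRUE),
                  h = sample(c("p", "q", "r"), 10, TRUE))
  fit <- fit_famd(d, n_axes = 3)

  d2 <- d
  d2$g <- chartr("xy", "mn", d2$g)      # relabel levels
  d2$a <- 5 * d2$a - 2                  # affine rescale continuous
  fit2 <- fit_famd(d2, n_axes = 3)
  expect_equal(abs(fit2$row_coords), abs(fit$row_coords), tolerance = 1e-7)
  expect_equal(fit2$eigenvalues, fit$eigenvalues, tolerance = 1e-9)

  # axis orthogonality of row coordinates
  G <- crossprod(fit$row_coords)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("zero-variance continuous columns fail naming the column", {
  d <- data.frame(a = rnorm(6), dead = rep(2, 6),
                  g = rep(c("x", "y"), 3))
  expect_error(fit_famd(d), "dead")
})

test_that("iterative imputation honours its contracts", {
  d0 <- data.frame(x = rnorm(8), g = rep(c("a", "b"), 4))
  expect_identical(impute_missing(d0), d0)

  # rank-1 completion is recovered exactly
  d1 <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 4, NA, 8, 10))
  done <- impute_missing(d1, n_components = 1, tol = 1e-10)
  expect_equal(done$y[3], 6, tolerance = 1e-4)

  # categorical cells are imputed with an observed level, coherently
  # with the correlated continuous column
  set.seed(13)
  g <- rep(c("lo", "hi"), each = 10)
  d2 <- data.frame(x = ifelse(g == "hi", 5, -5) + rnorm(20, sd = 0.3),
                   g = g, stringsAsFactors = FALSE)
  d2$g[4] <- NA                         # a 'lo' row
  done2 <- impute_missing(d2, n_components = 1)
  expect_true(done2$g[4] %in% c("lo", "hi"))
  expect_equal(done2$g[4], "lo")

  expect_error(impute_missing(data.frame(x = c(NA, NA, 1))), "30%")
})
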