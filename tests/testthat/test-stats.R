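test_that("log10 transform is strict about positivity", {
  expect_equal(log10_transform(c(100, 1)), c(2, 0))
  expect_error(log10_transform(c(1, 0, 10)), "2")
})

test_that("normality check wraps Shapiro-Wilk with sane errors", {
  set.seed(1)
  r <- normality_check(rnorm(200))
  expect_gt(r$p, 0.001)
  expect_true(r$W > 0 && r$W <= 1)
  # lognormal fails raw, passes after log10 (typical draw)
  x <- exp(rnorm(200, sd = 1.5))
  expect_lt(normality_check(x)$p, 0.05)
  expect_gt(normality_check(log10_transform(x))$p, 0.001)
  expect_error(normality_check(rep(1, 10)), "constant")
})

rand_dist <- function(n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

test_that("mantel_test detects perfect association and respects relabeling", {
  set.seed(5)
  X <- rand_dist(10)
  m <- mantel_test(X, 2 * X, n_perm = 99, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 100)          # minimum attainable
  # relabeling both matrices identically leaves r unchanged
  Y <- rand_dist(10)
  p <- sample(10)
  m1 <- mantel_test(X, Y, n_perm = 49, seed = 2)
  m2 <- mantel_test(X[p, p], Y[p, p], n_perm = 49, seed = 2)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
  expect_error(mantel_test(X, matrix(0, 10, 10)), "zero variance")
  expect_error(mantel_test(X[1:3, 1:3], X[1:3, 1:3]), "n >= 4")
})

test_that("partial_mantel matches the closed-form partial correlation", {
  set.seed(6)
  for (k in 1:20) {
    n <- sample(8:16, 1)
    X <- rand_dist(n); Y <- rand_dist(n); Z <- rand_dist(n)
    lt <- lower.tri(X)
    rxy <- cor(X[lt], Y[lt]); rxz <- cor(X[lt], Z[lt])
    rzy <- cor(Z[lt], Y[lt])
    closed <- (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
    pm <- partial_mantel(X, Y, list(Z), n_perm = 19, seed = 1)
    expect_equal(pm$r, closed, tolerance = 1e-12)
  }
  # conditioning on a copy of X leaves nothing to correlate
  X <- rand_dist(12)
  expect_error(partial_mantel(X, rand_dist(12), list(X)), "collinear")
  # a conditioner uncorrelated with both barely moves r (large n)
  set.seed(7)
  n <- 40
  X <- rand_dist(n); Y <- rand_dist(n); Z <- rand_dist(n)
  lt <- lower.tri(X)
  pm <- partial_mantel(X, Y, list(Z), n_perm = 19, seed = 1)
  expect_lt(abs(pm$r - cor(X[lt], Y[lt])), 0.1)
})

test_that("one-way ANOVA reproduces the hand-computed F and letters", {
  a <- anova_oneway(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  expect_equal(a$F, 1.5)
  expect_equal(a$df[1:2], c(1, 4))
  # identical groups: F = 0, all letters shared
  a0 <- anova_oneway(rep(c(2, 3), 4), rep(c("g1", "g2"), each = 4))
  expect_equal(a0$F, 0)
  expect_equal(unname(a0$letters["g1"]), unname(a0$letters["g2"]))
  expect_error(anova_oneway(1:5, rep("g1", 5)), "two groups")
  # well-separated groups get distinct letters; overlapping share one
  set.seed(8)
  v <- c(rnorm(10, 0, .1), rnorm(10, 5, .1), rnorm(10, 5.02, .1))
  g <- rep(c("lo", "hi1", "hi2"), each = 10)
  a3 <- anova_oneway(v, g)
  lset <- function(nm) strsplit(a3$letters[nm], "")[[1]]
  expect_length(intersect(lset("lo"), lset("hi1")), 0)
  expect_gt(length(intersect(lset("hi1"), lset("hi2"))), 0)
  # singleton groups enter the table but receive no letter
  a1 <- anova_oneway(c(v, 99), c(g, "single"))
  expect_true(is.na(a1$letters["single"]))
})

test_that("fit_glm recovers exact fits and flags collinearity", {
  x <- 1:20
  y <- 3 + 2 * x
  f <- fit_glm(y, data.frame(x = x))
  expect_equal(unname(f$coefficients), c(3, 2), tolerance = 1e-9)
  expect_equal(sum(residuals(f$model)^2), 0, tolerance = 1e-9)
  expect_equal(f$k, 3L)
  f0 <- fit_glm(y)
  expect_equal(unname(f0$coefficients[1]), mean(y))
  expect_error(fit_glm(y, data.frame(x = x, x2 = 2 * x)), "collinear")
})

test_that("aicc follows the formula and its monotonicities", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_error(aicc(0, 2, 3), "n must exceed")
  # converges to AIC for large n
  expect_lt(abs(aicc(-12, 3, 1e9) - (24 + 6)), 1e-6)
  # decreasing in loglik, increasing in k at fixed n
  expect_gt(aicc(-10, 3, 50), aicc(-9, 3, 50))
  expect_gt(aicc(-10, 4, 50), aicc(-10, 3, 50))
})

test_that("dredge_glm enumerates all subsets with coherent weights", {
  set.seed(9)
  x1 <- rnorm(60); x2 <- rnorm(60)
  y <- 2 * x1 + rnorm(60)
  tab <- dredge_glm(y, data.frame(x1 = x1, x2 = x2))
  expect_equal(nrow(tab), 4L)
  expect_equal(sum(tab$weight), 1, tolerance = 1e-9)
  expect_equal(tab$delta[1], 0)
  expect_false(is.unsorted(tab$aicc))
  expect_true("(null)" %in% tab$predictors)
  # rows reproduce fit_glm values
  row <- tab[tab$predictors == "x1", ]
  f <- fit_glm(y, data.frame(x1 = x1))
  expect_equal(row$loglik, f$loglik, tolerance = 1e-9)
  expect_equal(row$aicc, aicc(f$loglik, f$k, 60), tolerance = 1e-9)
  # identical after re-enumeration in a different column order
  tab2 <- dredge_glm(y, data.frame(x2 = x2, x1 = x1))
  expect_equal(tab2$aicc, tab$aicc, tolerance = 1e-9)
})

test_that("concordance returns OLS slope and squared correlation", {
  expect_equal(concordance(1:10, 1:10)$slope, 1)
  expect_equal(concordance(1:10, 2 * (1:10))$slope, 2)
  expect_equal(concordance(1:10, 2 * (1:10))$r_squared, 1)
  set.seed(10)
  r <- concordance(rnorm(1000), rnorm(1000))
  expect_lt(r$r_squared, 0.05)
  expect_error(concordance(rep(1, 5), 1:5), "zero variance")
})
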