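# Distance-matrix inference (Mantel, partial Mantel), transforms,
# one-way ANOVA with compact letter display, Gaussian GLM with AICc
# all-subsets selection, and slope/r-squared concordance checks.

#' Common-logarithm transform with strict positivity check
#'
#' @param x numeric vector; all values must be strictly positive.
#' @return `log10(x)`.
#' @export
log10_transform <- function(x) {
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop("log10 transform requires positive values; offending rows: ",
         paste(head(bad), collapse = ", "))
  log10(x)
}

#' Shapiro-Wilk normality check
#'
#' @param x numeric vector, 3 to 5000 values with nonzero variance.
#' @return a list with `W` and `p`.
#' @export
normality_check <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 to 5000 values")
  if (sd(x) == 0) stop("constant vector: normality check undefined")
  sw <- shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

check_distance_matrix <- function(X, name = "matrix") {
  if (!is.matrix(X) || nrow(X) != ncol(X))
    stop(name, " must be a square matrix")
  if (max(abs(X - t(X))) > 1e-8 * max(1, max(abs(X))))
    stop(name, " must be symmetric")
  if (any(abs(diag(X)) > 1e-12)) stop(name, " must have a zero diagonal")
  invisible(X)
}

#' Simple Mantel test
#'
#' Pearson correlation of the lower-triangle vectors of two distance
#' matrices; significance by simultaneous row/column permutation of one
#' matrix. The p-value is two-sided:
#' `(1 + #{|r*| >= |r|}) / (1 + n_perm)`.
#'
#' @param X,Y square symmetric distance matrices with zero diagonals,
#'   same dimension `n >= 4`.
#' @param n_perm number of permutations.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `"mantel_result"` with `r`, `p`,
#'   `n_perm`, `conditioners` (empty).
#' @export
mantel_test <- function(X, Y, n_perm = 9999, seed = NULL) {
  check_distance_matrix(X, "X")
  check_distance_matrix(Y, "Y")
  n <- nrow(X)
  if (n < 4L || nrow(Y) != n) stop("matrices must agree and have n >= 4")
  lt <- lower.tri(X)
  x <- X[lt]
  y <- Y[lt]
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in a distance triangle")
  r <- cor(x, y)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- cor(x, Y[p, p][lt])
    if (abs(rp) >= abs(r)) hits <- hits + 1L
  }
  structure(list(r = r, p = (1 + hits) / (1 + n_perm), n_perm = n_perm,
                 conditioners = character(0)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  kind <- if (length(x$conditioners)) "Partial Mantel" else "Mantel"
  cat(kind, " test: r = ", format(x$r, digits = 4),
      ", p = ", format(x$p, digits = 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  if (length(x$conditioners))
    cat("Conditioned on:", paste(x$conditioners, collapse = ", "), "\n")
  invisible(x)
}

triangle_residuals <- function(v, Z) {
  fit <- lm.fit(cbind(1, Z), v)
  res <- fit$residuals
  if (sd(res) < 1e-12 * max(1, sd(v)))
    stop("conditioner collinear with a distance matrix (zero residual variance)")
  res
}

#' Partial Mantel test
#'
#' Correlation between two distance matrices after removing the linear
#' effect of one or more conditioning matrices from both triangle
#' vectors. Significance follows the residual-permutation scheme: the
#' residuals of `X` are folded back into matrix form, rows and columns
#' are permuted simultaneously, re-residualized on the conditioners,
#' and correlated with the residuals of `Y`. With a single conditioner
#' the statistic equals the closed-form first-order partial
#' correlation.
#'
#' @inheritParams mantel_test
#' @param conditioners a list of conforming distance matrices (>= 1).
#' @return an object of class `"mantel_result"`.
#' @export
partial_mantel <- function(X, Y, conditioners, n_perm = 9999,
                           seed = NULL) {
  if (is.matrix(conditioners)) conditioners <- list(conditioners)
  if (!length(conditioners)) stop("need at least one conditioner")
  check_distance_matrix(X, "X")
  check_distance_matrix(Y, "Y")
  n <- nrow(X)
  for (Z in conditioners) {
    check_distance_matrix(Z, "conditioner")
    if (nrow(Z) != n) stop("conditioner dimension mismatch")
  }
  lt <- lower.tri(X)
  Zv <- vapply(conditioners, function(Z) Z[lt], numeric(sum(lt)))
  rx <- triangle_residuals(X[lt], Zv)
  ry <- triangle_residuals(Y[lt], Zv)
  r <- cor(rx, ry)
  RX <- matrix(0, n, n)
  RX[lt] <- rx
  RX <- RX + t(RX)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    rxp <- RX[p, p][lt]
    rxp <- rxp - cbind(1, Zv) %*% qr.coef(qr(cbind(1, Zv)), rxp)
    rp <- cor(rxp, ry)
    if (abs(rp) >= abs(r)) hits <- hits + 1L
  }
  structure(list(r = r, p = (1 + hits) / (1 + n_perm), n_perm = n_perm,
                 conditioners = paste0("Z", seq_along(conditioners))),
            class = "mantel_result")
}

#' One-way ANOVA across groups with compact letter display
#'
#' Classical one-way ANOVA F test, followed by all pairwise Welch
#' t-tests with Holm correction; groups that are not significantly
#' different share a letter (letters are maximal cliques of the
#' not-different graph, ordered by group mean). Groups with a single
#' observation enter the F test but receive no letter.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @param alpha significance level for the pairwise letters.
#' @return a list of class `"anova_result"`: `F`, `df`, `p`, `means`,
#'   `letters`.
#' @export
anova_oneway <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  tabn <- table(groups)
  if (length(tabn) < 2L) stop("need at least two groups")
  fit <- lm(values ~ factor(groups))
  an <- suppressWarnings(anova(fit))   # constant data warns; F is set to 0
  Fv <- an$`F value`[1]
  if (sd(values) == 0) Fv <- 0
  means <- tapply(values, groups, mean)
  glab <- names(tabn)[tabn >= 2L]
  letters_out <- setNames(rep(NA_character_, length(tabn)), names(tabn))
  if (length(glab) >= 2L) {
    pr <- combn(glab, 2)
    pv <- apply(pr, 2, function(gp) {
      x <- values[groups == gp[1]]
      y <- values[groups == gp[2]]
      if (sd(x) == 0 && sd(y) == 0)
        return(if (mean(x) == mean(y)) 1 else 0)
      stats::t.test(x, y)$p.value
    })
    pv <- stats::p.adjust(pv, "holm")
    differ <- pv < alpha
    # letters = maximal cliques of the "not significantly different" graph
    g <- igraph::make_empty_graph(n = length(glab), directed = FALSE)
    igraph::V(g)$name <- glab
    same <- pr[, !differ, drop = FALSE]
    if (ncol(same))
      g <- igraph::add_edges(g, as.vector(same))
    cl <- igraph::max_cliques(g)
    cl_names <- lapply(cl, function(v) igraph::V(g)$name[v])
    ord <- order(vapply(cl_names, function(v) max(means[v]), 0),
                 decreasing = TRUE)
    cl_names <- cl_names[ord]
    for (i in seq_along(cl_names)) {
      li <- letters[(i - 1) %% 26 + 1]
      for (gname in cl_names[[i]])
        letters_out[gname] <- paste0(
          ifelse(is.na(letters_out[gname]), "", letters_out[gname]), li)
    }
  }
  structure(list(F = unname(Fv), df = an$Df, p = an$`Pr(>F)`[1],
                 means = means, n = as.integer(tabn),
                 letters = letters_out, alpha = alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df[1], ", ", x$df[2], ") = ",
      format(x$F, digits = 4), ", p = ", format(x$p, digits = 4),
      "\n", sep = "")
  df <- data.frame(mean = as.numeric(x$means), n = x$n,
                   letter = x$letters[names(x$means)])
  rownames(df) <- names(x$means)
  print(df)
  invisible(x)
}

#' Gaussian identity-link GLM by least squares
#'
#' @param y response vector.
#' @param X data frame or matrix of predictor columns, or `NULL` for an
#'   intercept-only model.
#' @return a list with `loglik`, `coefficients`, `k` (number of
#'   estimated parameters: intercept, slopes and the error variance),
#'   `n` and the fitted `model`.
#' @export
fit_glm <- function(y, X = NULL) {
  if (is.null(X) || (!is.null(ncol(X)) && ncol(X) == 0)) {
    df <- data.frame(y = y)
    fit <- lm(y ~ 1, data = df)
  } else {
    X <- as.data.frame(X)
    if (nrow(X) != length(y)) stop("X and y lengths differ")
    df <- cbind(data.frame(y = y), X)
    fit <- lm(y ~ ., data = df)
  }
  cf <- coef(fit)
  if (anyNA(cf))
    stop("collinear predictor columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  k <- length(cf) + 1L   # + error variance
  if (length(y) <= k) stop("n must exceed k + 1")
  list(loglik = as.numeric(logLik(fit)), coefficients = cf, k = k,
       n = length(y), model = fit)
}

#' Second-order Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`; converges to AIC as `n`
#' grows.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters (including the error
#'   variance).
#' @param n sample size; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets Gaussian GLM selection by AICc
#'
#' Fits every subset of the candidate predictors, including the null
#' (intercept-only) model, and ranks them by AICc with differences and
#' Akaike weights.
#'
#' @param y response vector.
#' @param X data frame of candidate predictors (at most 12 columns).
#' @return a data frame of class `"model_selection"`, one row per
#'   subset, sorted by AICc: `predictors`, `k`, `loglik`, `aicc`,
#'   `delta`, `weight`. Weights sum to 1 and the top row has
#'   `delta = 0`.
#' @export
dredge_glm <- function(y, X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p < 1L) stop("need at least one candidate predictor")
  if (p > 12L) stop("at most 12 candidate predictors supported")
  n <- length(y)
  rows <- vector("list", 2^p)
  for (mask in 0:(2^p - 1)) {
    inc <- bitwAnd(mask, 2^(seq_len(p) - 1)) > 0
    fit <- fit_glm(y, if (any(inc)) X[, inc, drop = FALSE] else NULL)
    rows[[mask + 1]] <- data.frame(
      predictors = if (any(inc)) paste(names(X)[inc], collapse = "+")
                   else "(null)",
      k = fit$k, loglik = fit$loglik,
      aicc = aicc(fit$loglik, fit$k, n),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aicc), ]
  tab$delta <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  class(tab) <- c("model_selection", "data.frame")
  tab
}

#' Slope and squared correlation between paired outcomes
#'
#' Concordance check used for sensitivity analyses: outcomes computed
#' two ways (e.g. small vs large dataset, resolved vs unresolved tree)
#' leave conclusions unchanged when the OLS slope and the squared
#' Pearson correlation are both close to 1.
#'
#' @param x,y paired numeric vectors (`n >= 3`, `var(x) > 0`).
#' @return a list with `slope` (OLS slope of `y` on `x`), `intercept`
#'   and `r_squared`.
#' @export
concordance <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (sd(x) == 0) stop("zero variance in x")
  cf <- coef(lm(y ~ x))
  r2 <- if (sd(y) == 0) 0 else cor(x, y)^2
  list(slope = unname(cf[2]), intercept = unname(cf[1]), r_squared = r2)
}
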