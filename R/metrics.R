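# Alpha and beta phylogenetic metrics, Jaccard similarity, and
# permutation-null standardized effect sizes (betaNRI / betaNTI).

check_taxa_in_D <- function(taxa, D, what = "taxon set") {
  if (length(taxa) == 0L) stop(what, " is empty")
  idx <- match(taxa, rownames(D))
  if (anyNA(idx))
    stop("taxa missing from distance matrix: ",
         paste(taxa[is.na(idx)], collapse = ", "))
  idx
}

#' Mean pairwise phylogenetic distance of a community
#'
#' Mean cophenetic distance over all unordered pairs of distinct taxa.
#' Sensitive to tree-wide structure including deep splits.
#'
#' @param taxa character vector of taxon labels (>= 2 distinct taxa).
#' @param D cophenetic distance matrix from [cophenetic_matrix()].
#' @return MPD in the units of `D` (Myr for calibrated trees).
#' @export
mpd <- function(taxa, D) {
  taxa <- unique(taxa)
  if (length(taxa) < 2L)
    stop("MPD is undefined for fewer than 2 taxa")
  idx <- check_taxa_in_D(taxa, D)
  sub <- D[idx, idx, drop = FALSE]
  mean(sub[lower.tri(sub)])
}

#' Mean nearest taxon distance of a community
#'
#' Mean over member taxa of the distance to the nearest other member;
#' emphasizes structure near the tips of the phylogeny (recent
#' evolutionary events).
#'
#' @inheritParams mpd
#' @return MNTD in the units of `D`.
#' @export
mntd <- function(taxa, D) {
  taxa <- unique(taxa)
  if (length(taxa) < 2L)
    stop("MNTD is undefined for fewer than 2 taxa")
  idx <- check_taxa_in_D(taxa, D)
  sub <- D[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

#' Jaccard similarity between two taxon sets
#'
#' Shared taxa divided by the size of the union; 1 for identical sets,
#' 0 for disjoint sets.
#'
#' @param a,b character vectors of taxon labels (non-empty).
#' @return similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("taxon sets must be non-empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Between-community mean pairwise phylogenetic distance (betaMPD)
#'
#' Mean cophenetic distance over all ordered cross pairs of taxa, one
#' from each community. Taxa shared by both communities contribute zero
#' self-distances (the comdist convention), which lowers betaMPD for
#' overlapping communities.
#'
#' @param a,b character vectors of taxon labels (non-empty).
#' @param D cophenetic distance matrix.
#' @return betaMPD in the units of `D`.
#' @export
beta_mpd <- function(a, b, D) {
  ia <- check_taxa_in_D(unique(a), D)
  ib <- check_taxa_in_D(unique(b), D)
  cpp_beta_mpd(D, ia, ib)
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' Mean over the taxa of both communities of the distance to the
#' nearest taxon in the opposite community (zero for shared taxa); the
#' two directions are averaged, so the metric is symmetric.
#'
#' @inheritParams beta_mpd
#' @return betaMNTD in the units of `D`.
#' @export
beta_mntd <- function(a, b, D) {
  ia <- check_taxa_in_D(unique(a), D)
  ib <- check_taxa_in_D(unique(b), D)
  cpp_beta_mntd(D, ia, ib)
}

ses_from_null <- function(observed, null_values, n_rand, metric,
                          threshold = 1.96) {
  mu <- mean(null_values)
  sdv <- sd(null_values)
  degenerate <- !is.finite(sdv) || sdv <= 0
  ses <- if (degenerate) NA_real_ else (observed - mu) / sdv
  neg <- -ses
  structure(list(observed = observed,
                 null_mean = mu,
                 null_sd = sdv,
                 n_rand = n_rand,
                 ses = ses,
                 negated_ses = neg,
                 metric = metric,
                 threshold = threshold,
                 degenerate = degenerate,
                 significant = !degenerate && abs(neg) > threshold,
                 significant_low = !degenerate && neg > threshold,
                 significant_high = !degenerate && neg < -threshold),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  lab <- if (x$metric == "beta_mpd") "betaNRI" else "betaNTI"
  cat("Observed ", x$metric, " = ", format(x$observed),
      "; null mean ", format(x$null_mean), " sd ", format(x$null_sd),
      " (", x$n_rand, " randomizations)\n", sep = "")
  if (x$degenerate) {
    cat("Degenerate null (zero variance): SES undefined\n")
  } else {
    cat(lab, " = ", format(x$negated_ses),
        if (x$significant_low) "  [significantly LOW turnover]"
        else if (x$significant_high) "  [significantly HIGH turnover]"
        else "", "\n", sep = "")
  }
  invisible(x)
}

#' Permutation-null standardized effect size for beta metrics
#'
#' Builds the null distribution of betaMPD or betaMNTD under the
#' unconstrained null model: each randomization shuffles taxon
#' identities across the supplied pool (a bijection of pool labels),
#' preserving the sizes of both communities and the number of taxa they
#' share. The negated standardized effect size is betaNRI (for betaMPD)
#' or betaNTI (for betaMNTD); values above the threshold flag
#' significantly low turnover, values below its negative significantly
#' high turnover.
#'
#' @inheritParams beta_mpd
#' @param metric `"beta_mpd"` or `"beta_mntd"`.
#' @param pool character vector of taxon labels to shuffle over; must
#'   contain the union of `a` and `b`. Defaults to all labels of `D`.
#' @param n_rand number of randomizations (>= 100).
#' @param seed integer seed; results are reproducible for equal seeds.
#' @param threshold two-sided significance threshold on the negated SES
#'   (default 1.96).
#' @return an object of class `"ses_result"`; `degenerate` is `TRUE`
#'   (and no significance call is made) when the null has zero
#'   variance, e.g. on a star phylogeny.
#' @export
null_ses <- function(a, b, D, metric = c("beta_mntd", "beta_mpd"),
                     pool = rownames(D), n_rand = 999, seed = NULL,
                     threshold = 1.96) {
  metric <- match.arg(metric)
  if (n_rand < 100) stop("n_rand must be at least 100")
  a <- unique(a); b <- unique(b)
  ia <- check_taxa_in_D(a, D)
  ib <- check_taxa_in_D(b, D)
  ipool <- check_taxa_in_D(unique(pool), D, "pool")
  if (!all(c(ia, ib) %in% ipool))
    stop("pool must contain the union of both communities")
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- length(intersect(a, b))
  nulls <- cpp_null_beta(D, ipool, length(a), length(b), s, as.integer(n_rand))
  obs <- if (metric == "beta_mpd") cpp_beta_mpd(D, ia, ib)
         else cpp_beta_mntd(D, ia, ib)
  col <- if (metric == "beta_mpd") 1L else 2L
  ses_from_null(obs, nulls[, col], n_rand, metric, threshold)
}

# Stable per-pair RNG stream: polynomial hash of the sorted community
# ids folded with the run seed, so results do not depend on community
# input order and pairs can be processed in any order or in parallel.
pair_seed <- function(seed, id1, id2) {
  key <- paste(sort(c(as.character(id1), as.character(id2))),
               collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Alpha and beta metrics for every community and community pair
#'
#' Driver for the full analysis table: per-community MPD and MNTD (with
#' common logarithms), and per-pair Jaccard similarity, betaMPD,
#' betaMNTD plus their permutation-null standardized effect sizes
#' betaNRI and betaNTI. Each pair draws its randomizations from an
#' independent RNG stream derived from the run seed and the pair's
#' community ids, so results are invariant to community input order.
#'
#' @param cm a `"community_matrix"` from [pool_taxa()], or an abundance
#'   matrix with community rows and taxon columns.
#' @param D cophenetic distance matrix covering all community taxa.
#' @param n_rand randomizations per pair for the null model; 0 skips
#'   the SES columns.
#' @param seed integer run seed.
#' @param threshold significance threshold on |betaNRI| / |betaNTI|.
#' @return a list with `communities` (id, richness, mpd, mntd, log_mpd,
#'   log_mntd) and `pairs` (community1, community2, jaccard, beta_mpd,
#'   beta_mntd and, when `n_rand > 0`, beta_nri, beta_nti, degenerate,
#'   sig_low_nri, sig_low_nti).
#' @export
all_pair_metrics <- function(cm, D, n_rand = 999, seed = 1,
                             threshold = 1.96) {
  m <- if (inherits(cm, "community_matrix")) cm$abund else cm
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  comms <- rownames(m)
  sets <- lapply(seq_len(nrow(m)), function(i) colnames(m)[m[i, ] > 0])
  names(sets) <- comms
  if (any(lengths(sets) == 0L))
    stop("communities without taxa: ",
         paste(comms[lengths(sets) == 0L], collapse = ", "))
  pool <- colnames(m)
  ipool <- check_taxa_in_D(pool, D, "community matrix taxa")

  cdf <- data.frame(community = comms, richness = lengths(sets),
                    mpd = NA_real_, mntd = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(sets)) {
    if (lengths(sets)[i] >= 2L) {
      cdf$mpd[i] <- mpd(sets[[i]], D)
      cdf$mntd[i] <- mntd(sets[[i]], D)
    }
  }
  cdf$log_mpd <- ifelse(cdf$mpd > 0, log10(cdf$mpd), NA_real_)
  cdf$log_mntd <- ifelse(cdf$mntd > 0, log10(cdf$mntd), NA_real_)

  n <- length(sets)
  if (n < 2L) stop("need at least two communities")
  idx <- combn(n, 2)
  np <- ncol(idx)
  pdf <- data.frame(community1 = comms[idx[1, ]],
                    community2 = comms[idx[2, ]],
                    jaccard = NA_real_, beta_mpd = NA_real_,
                    beta_mntd = NA_real_, stringsAsFactors = FALSE)
  if (n_rand > 0) {
    pdf$beta_nri <- NA_real_
    pdf$beta_nti <- NA_real_
    pdf$degenerate <- FALSE
    pdf$sig_low_nri <- NA
    pdf$sig_low_nti <- NA
  }
  for (k in seq_len(np)) {
    a <- sets[[idx[1, k]]]
    b <- sets[[idx[2, k]]]
    pdf$jaccard[k] <- jaccard(a, b)
    pdf$beta_mpd[k] <- beta_mpd(a, b, D)
    pdf$beta_mntd[k] <- beta_mntd(a, b, D)
    if (n_rand > 0) {
      set.seed(pair_seed(seed, pdf$community1[k], pdf$community2[k]))
      s <- length(intersect(a, b))
      nulls <- cpp_null_beta(D, ipool, length(a), length(b), s,
                             as.integer(n_rand))
      r1 <- ses_from_null(pdf$beta_mpd[k], nulls[, 1], n_rand,
                          "beta_mpd", threshold)
      r2 <- ses_from_null(pdf$beta_mntd[k], nulls[, 2], n_rand,
                          "beta_mntd", threshold)
      pdf$beta_nri[k] <- r1$negated_ses
      pdf$beta_nti[k] <- r2$negated_ses
      pdf$degenerate[k] <- r1$degenerate || r2$degenerate
      pdf$sig_low_nri[k] <- r1$significant_low
      pdf$sig_low_nti[k] <- r2$significant_low
    }
  }
  list(communities = cdf, pairs = pdf)
}
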