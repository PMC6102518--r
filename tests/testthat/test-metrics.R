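test_that("alpha and beta metrics reproduce the worked 4-tip examples", {
  D <- four_tip_D()
  expect_equal(mpd(c("A", "B", "C", "D"), D), 28 / 6)
  expect_equal(mpd(c("A", "B"), D), 2)
  expect_error(mpd("A", D), "fewer than 2")
  expect_equal(mntd(c("A", "B", "C", "D"), D), 2)
  expect_equal(mntd(c("A", "C"), D), 6)
  expect_error(mntd("A", D), "fewer than 2")
  expect_equal(jaccard(c("A", "B"), c("A", "C")), 1 / 3)
  expect_equal(jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard(c("A", "B"), c("C", "D")), 0)
  expect_error(jaccard(character(0), "A"), "non-empty")
  expect_equal(beta_mpd(c("A", "B"), c("C", "D"), D), 6)
  expect_equal(beta_mpd(c("A", "B"), c("A", "B"), D), 1)  # shared zeros
  expect_equal(beta_mpd("A", "A", D), 0)
  expect_equal(beta_mntd(c("A", "B"), c("A", "C"), D), 2)
  expect_equal(beta_mntd(c("A", "B"), c("C", "D"), D), 6)
  expect_equal(beta_mntd("A", "A", D), 0)
  expect_error(beta_mpd(c("A", "Z"), "B", D), "missing")
})

test_that("metrics agree exactly with independent brute-force oracles", {
  for (seed in 1:50) {
    inst <- rand_instance(seed)
    expect_equal(mpd(inst$a, inst$D), oracle_mpd(inst$a, inst$D),
                 tolerance = 1e-12)
    expect_equal(mntd(inst$a, inst$D), oracle_mntd(inst$a, inst$D),
                 tolerance = 1e-12)
    expect_equal(jaccard(inst$a, inst$b), oracle_jaccard(inst$a, inst$b),
                 tolerance = 1e-12)
    expect_equal(beta_mpd(inst$a, inst$b, inst$D),
                 oracle_beta_mpd(inst$a, inst$b, inst$D),
                 tolerance = 1e-12)
    expect_equal(beta_mntd(inst$a, inst$b, inst$D),
                 oracle_beta_mntd(inst$a, inst$b, inst$D),
                 tolerance = 1e-12)
  }
})

test_that("beta metrics are symmetric and betaMNTD bounds betaMPD on disjoint sets", {
  for (seed in 1:25) {
    inst <- rand_instance(seed + 900)
    expect_equal(beta_mpd(inst$a, inst$b, inst$D),
                 beta_mpd(inst$b, inst$a, inst$D), tolerance = 1e-12)
    expect_equal(beta_mntd(inst$a, inst$b, inst$D),
                 beta_mntd(inst$b, inst$a, inst$D), tolerance = 1e-12)
    a <- setdiff(inst$a, inst$b)
    b <- setdiff(inst$b, inst$a)
    if (length(a) && length(b)) {
      expect_lte(beta_mntd(a, b, inst$D),
                 beta_mpd(a, b, inst$D) + 1e-12)
    }
  }
})

test_that("null SES has the stated arithmetic, flags, and degeneracy", {
  # arithmetic: observed 2, null mean 4, null sd ~1 -> SES ~ -2,
  # negated ~ +2, significant low turnover
  nulls <- 4 + scale(rnorm(200))[, 1]          # exact mean 4, sd 1
  r <- phyloturn:::ses_from_null(2, nulls, 200, "beta_mntd")
  expect_equal(r$ses, -2, tolerance = 1e-9)
  expect_equal(r$negated_ses, 2, tolerance = 1e-9)
  expect_true(r$significant_low)
  expect_false(r$significant_high)
  # observed equal to the null mean -> SES 0, not significant
  r0 <- phyloturn:::ses_from_null(4, nulls, 200, "beta_mntd")
  expect_equal(r0$ses, 0, tolerance = 1e-9)
  expect_false(r0$significant)

  # star phylogeny: every shuffle identical -> degenerate
  star <- as_calibrated(parse_newick(
    paste0("(", paste(paste0("t", 1:8, ":1"), collapse = ","), ");")))
  Ds <- cophenetic_matrix(star)
  rs <- null_ses(c("t1", "t2"), c("t3", "t4"), Ds, "beta_mpd",
                 n_rand = 200, seed = 1)
  expect_true(rs$degenerate)
  expect_true(is.na(rs$ses))
  expect_false(isTRUE(rs$significant))

  # determinism under seed
  ct <- rand_ct(16, 5)
  D <- cophenetic_matrix(ct)
  labs <- rownames(D)
  r1 <- null_ses(labs[1:5], labs[4:9], D, "beta_mntd", n_rand = 300,
                 seed = 42)
  r2 <- null_ses(labs[1:5], labs[4:9], D, "beta_mntd", n_rand = 300,
                 seed = 42)
  expect_identical(r1$ses, r2$ses)
  expect_error(null_ses(labs[1:5], labs[4:9], D, n_rand = 50), "at least 100")
})

test_that("the null shuffle preserves community sizes and overlap", {
  ct <- rand_ct(20, 8)
  D <- cophenetic_matrix(ct)
  pool <- match(rownames(D), rownames(D))
  set.seed(1)
  nulls <- phyloturn:::cpp_null_beta(D, pool, 6L, 5L, 2L, 50L)
  expect_equal(dim(nulls), c(50L, 2L))
  # null betaMNTD of overlapping communities includes shared zeros, so
  # it is bounded by the all-distinct case: all values finite, >= 0
  expect_true(all(is.finite(nulls)))
  expect_true(all(nulls >= 0))
})

test_that("all_pair_metrics fills every pair and is order invariant", {
  ct <- rand_ct(24, 31)
  D <- cophenetic_matrix(ct)
  labs <- rownames(D)
  set.seed(2)
  m <- matrix(0L, 4, length(labs), dimnames = list(paste0("c", 1:4), labs))
  for (i in 1:4) m[i, sample(labs, 8)] <- 1L
  res <- all_pair_metrics(m, D, n_rand = 200, seed = 9)
  expect_equal(nrow(res$pairs), 6L)
  expect_equal(nrow(res$communities), 4L)
  expect_true(all(is.finite(res$pairs$beta_nti)))
  expect_equal(res$communities$log_mpd, log10(res$communities$mpd))

  # permuting community rows leaves all per-pair values unchanged
  m2 <- m[c(3, 1, 4, 2), ]
  res2 <- all_pair_metrics(m2, D, n_rand = 200, seed = 9)
  key <- function(p) {
    k <- ifelse(p$community1 < p$community2,
                paste(p$community1, p$community2),
                paste(p$community2, p$community1))
    p[order(k), c("jaccard", "beta_mpd", "beta_mntd", "beta_nri",
                  "beta_nti")]
  }
  expect_equal(unname(as.matrix(key(res$pairs))),
               unname(as.matrix(key(res2$pairs))), tolerance = 1e-12)

  # duplicated community: the twin pair has Jaccard 1, no self pairs
  m3 <- rbind(m, c5 = m[1, ])
  res3 <- all_pair_metrics(m3, D, n_rand = 0)
  expect_equal(nrow(res3$pairs), 10L)
  twin <- res3$pairs[res3$pairs$community1 == "c1" &
                     res3$pairs$community2 == "c5", ]
  expect_equal(twin$jaccard, 1)
})
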