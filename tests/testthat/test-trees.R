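test_that("parse_newick handles the basic grammar and degenerate trees", {
  phy <- parse_newick("((A:1,B:1):2,(C:1,D:1):2);")
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, c("A", "B", "C", "D"))
  expect_equal(length(phy$tip.label), 4L)
  # root has two children
  root <- length(phy$tip.label) + 1L
  expect_equal(sum(phy$edge[, 1] == root), 2L)

  single <- parse_newick("(A);")
  expect_equal(single$tip.label, "A")

  expect_error(parse_newick("((A,B)"), "malformed Newick")
  expect_error(parse_newick("((A,B);"), "malformed Newick")
  expect_error(parse_newick("(A,A);"), "duplicate tip")
})

test_that("write_newick round-trips trees, names and branch lengths", {
  for (seed in 1:20) {
    set.seed(seed)
    phy <- ape::rtree(sample(3:20, 1))
    txt <- write_newick(phy)
    back <- parse_newick(txt)
    d1 <- cophenetic_matrix(phy)
    d2 <- cophenetic_matrix(back)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-12)
  }
  # singleton interior nodes survive the round trip
  txt <- "(((T:1)u2:2)u1:3)r;"
  expect_equal(write_newick(parse_newick(txt)), txt)
  # no lengths -> no ':' tokens; interior names after ')'
  phy <- parse_newick("((A,B)x,C)r;")
  out <- write_newick(phy)
  expect_false(grepl(":", out))
  expect_match(out, "\\)x")
  # cross-check against ape on a singleton-free tree
  set.seed(99)
  phy <- ape::rtree(10)
  ours <- parse_newick(write_newick(phy))
  theirs <- ape::read.tree(text = ape::write.tree(phy))
  expect_equal(cophenetic_matrix(ours)[phy$tip.label, phy$tip.label],
               cophenetic_matrix(theirs)[phy$tip.label, phy$tip.label],
               tolerance = 1e-10)
})

test_that("graft_taxa applies the genus/family attachment and pruning rules", {
  bb <- parse_newick("((Ocotea,Persea)Lauraceae,(Myrcia)Myrtaceae)root;")
  taxa <- data.frame(
    family = c("Lauraceae", "Lauraceae", "Lauraceae", "Fabaceae"),
    genus = c("Ocotea", "Ocotea", "Nectandra", "Inga"),
    label = c("Ocotea_odorifera", "Ocotea_sp1", "Nectandra_sp1",
              "Inga_sp1"),
    stringsAsFactors = FALSE)
  g <- graft_taxa(bb, taxa)
  # exactly one tip per grafted taxon, backbone tips pruned
  expect_setequal(g$tree$tip.label,
                  c("Ocotea_odorifera", "Ocotea_sp1", "Nectandra_sp1"))
  expect_equal(g$skipped$label, "Inga_sp1")
  tab <- phyloturn:::phylo_to_table(g$tree)
  # congeners form a polytomy (cherry) under the genus node
  oc <- tab$id[tab$name == "Ocotea"]
  expect_equal(sum(tab$parent == oc, na.rm = TRUE), 2L)
  # new genus node created under the family
  ne <- tab$id[tab$name == "Nectandra"]
  expect_equal(tab$name[tab$parent[ne]], "Lauraceae")
  # unused Myrtaceae clade pruned entirely
  expect_false("Myrtaceae" %in% tab$name)

  expect_error(graft_taxa(bb, taxa[0, ]), "empty")
  # case-insensitive, separator-insensitive matching
  g2 <- graft_taxa(bb, data.frame(family = "LAURACEAE", genus = "ocotea",
                                  label = "Ocotea_x"))
  expect_equal(g2$tree$tip.label, "Ocotea_x")
})

test_that("calibrate_bladj spaces undated nodes evenly and errors on conflicts", {
  # chain root(10) -> u1 -> u2 -> tip: u1 = 20/3, u2 = 10/3
  ct <- calibrate_bladj(chain_tree(2), c(r = 10))
  ages <- setNames(ct$ages,
                   c(ct$phy$tip.label,
                     ct$phy$node.label))
  expect_equal(unname(ages["u1"]), 20 / 3)
  expect_equal(unname(ages["u2"]), 10 / 3)
  expect_equal(unname(ages["T"]), 0)

  # all interior nodes dated -> ages unchanged
  phy <- parse_newick("((A,B)x,(C,D)y)r;")
  ct2 <- calibrate_bladj(phy, c(r = 10, x = 4, y = 7))
  nm <- c(ct2$phy$tip.label, ct2$phy$node.label)
  expect_equal(unname(ct2$ages[match(c("x", "y", "r"), nm)]),
               c(4, 7, 10))

  # dated child older than dated ancestor
  expect_error(calibrate_bladj(phy, c(r = 10, x = 12)),
               "calibration conflict")
  # missing root age
  expect_error(calibrate_bladj(phy, c(x = 4)), "root")
})

test_that("bladj even spacing matches the closed formula on random chains", {
  for (seed in 1:30) {
    set.seed(seed)
    k <- sample(1:6, 1)
    root_age <- runif(1, 5, 50)
    ct <- calibrate_bladj(chain_tree(k), setNames(root_age, "r"))
    nm <- c(ct$phy$tip.label, ct$phy$node.label)
    for (i in seq_len(k)) {
      expect_equal(unname(ct$ages[match(paste0("u", i), nm)]),
                   root_age - i * root_age / (k + 1), tolerance = 1e-12)
    }
  }
})

test_that("bladj preserves dated ages bit-exactly with non-negative branches", {
  for (seed in 1:25) {
    ct0 <- rand_ct(sample(6:24, 1), seed + 500)
    phy <- ct0$phy
    ntip <- length(phy$tip.label)
    # name and date a random subset of interior nodes
    n_int <- phy$Nnode
    lab <- rep("", n_int)
    pickn <- sample(seq_len(n_int - 1) + 1, max(1, n_int %/% 3))
    lab[pickn] <- paste0("n", pickn)
    lab[1] <- "r"                       # root is node ntip+1 = index 1
    phy$node.label <- lab
    ages <- ct0$ages[ntip + which(nzchar(lab))]
    names(ages) <- lab[nzchar(lab)]
    ct <- calibrate_bladj(phy, ages)
    nm <- c(ct$phy$tip.label, ct$phy$node.label)
    expect_identical(unname(ct$ages[match(names(ages), nm)]),
                     unname(ages))
    expect_true(all(ct$phy$edge.length >= 0))
    expect_true(all(ct$ages[seq_len(ntip)] == 0))
  }
})

test_that("resolve_polytomies is deterministic, binary, and local", {
  ct <- calibrate_bladj(parse_newick("((A,B,C,D)x,(E,F)y)r;"),
                        c(r = 10, x = 5, y = 5))
  r1 <- resolve_polytomies(ct, seed = 7)
  r2 <- resolve_polytomies(ct, seed = 7)
  expect_identical(write_newick(r1), write_newick(r2))
  expect_equal(r1$phy$Nnode, length(r1$phy$tip.label) - 1L)
  # new node ages strictly between parent and children
  expect_true(all(r1$phy$edge.length > 0))
  # distances unchanged for pairs whose MRCA is outside the polytomy
  d0 <- cophenetic_matrix(ct)
  d1 <- cophenetic_matrix(r1)[rownames(d0), colnames(d0)]
  outside <- rbind(c("E", "F"), c("A", "E"), c("B", "F"), c("D", "E"))
  for (k in seq_len(nrow(outside)))
    expect_equal(d1[outside[k, 1], outside[k, 2]],
                 d0[outside[k, 1], outside[k, 2]])
  # already-binary tree: topology and distances unchanged
  ctb <- rand_ct(8, 1234)
  rb <- resolve_polytomies(ctb, seed = 3)
  expect_equal(cophenetic_matrix(rb)[rownames(cophenetic_matrix(ctb)),
                                     colnames(cophenetic_matrix(ctb))],
               cophenetic_matrix(ctb), tolerance = 1e-12)

  # 4-child polytomy gains two interior nodes
  ct4 <- calibrate_bladj(parse_newick("((A,B,C,D)x)r;"), c(r = 10, x = 5))
  r4 <- resolve_polytomies(ct4, seed = 1)
  expect_equal(r4$phy$Nnode, 3L)

  expect_error(resolve_polytomies(ct), "seed")
})

test_that("trifurcation resolutions occur with equal frequency", {
  ct <- calibrate_bladj(parse_newick("((A,B,C)x,D)r;"), c(r = 10, x = 5))
  sister_of <- function(res) {
    d <- cophenetic_matrix(res)
    pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
    which.min(vapply(pairs, function(p) d[p[1], p[2]], 0))
  }
  counts <- tabulate(vapply(1:1200, function(s)
    sister_of(resolve_polytomies(ct, seed = s)), 0L), nbins = 3)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("cophenetic distances equal the brute-force path-sum oracle", {
  # worked example: cherries at 2, cross pairs at 6
  D <- four_tip_D()
  expect_equal(D["A", "B"], 2)
  expect_equal(D["C", "D"], 2)
  expect_equal(D["A", "C"], 6)
  expect_equal(unname(diag(D)), rep(0, 4))
  for (seed in 1:20) {
    set.seed(seed)
    phy <- ape::rtree(sample(4:32, 1))
    expect_equal(cophenetic_matrix(phy), oracle_cophenetic(phy),
                 tolerance = 1e-12)
  }
  # ultrametric three-point condition over all triples
  ct <- rand_ct(12, 77)
  D <- cophenetic_matrix(ct)
  for (tri in utils::combn(rownames(D), 3, simplify = FALSE)) {
    d3 <- sort(c(D[tri[1], tri[2]], D[tri[1], tri[3]],
                 D[tri[2], tri[3]]))
    expect_equal(d3[2], d3[3], tolerance = 1e-9)
  }
})

test_that("read_ages parses a Phylocom-style ages file", {
  f <- tempfile()
  writeLines(c("rosids 110", "asterids 95.5"), f)
  ages <- read_ages(f)
  expect_equal(ages, c(rosids = 110, asterids = 95.5))
  writeLines(c("a 5", "a 6"), f)
  expect_error(read_ages(f), "duplicate")
  writeLines(c("a -5"), f)
  expect_error(read_ages(f), "positive")
})
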