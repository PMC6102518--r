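# Independent brute-force oracles and fixture generators. These stay
# deliberately naive (explicit loops over every pair/path) so they share
# no code path with the package implementations they check.

oracle_mpd <- function(taxa, D) {
  s <- 0; n <- 0
  for (i in seq_along(taxa)) for (j in seq_along(taxa)) {
    if (i < j) { s <- s + D[taxa[i], taxa[j]]; n <- n + 1 }
  }
  s / n
}

oracle_mntd <- function(taxa, D) {
  mins <- numeric(length(taxa))
  for (i in seq_along(taxa)) {
    best <- Inf
    for (j in seq_along(taxa)) {
      if (i != j) best <- min(best, D[taxa[i], taxa[j]])
    }
    mins[i] <- best
  }
  mean(mins)
}

oracle_jaccard <- function(a, b) {
  length(intersect(a, b)) / length(unique(c(a, b)))
}

oracle_beta_mpd <- function(a, b, D) {
  s <- 0
  for (i in a) for (j in b) s <- s + D[i, j]
  s / (length(a) * length(b))
}

oracle_beta_mntd <- function(a, b, D) {
  s <- 0
  for (i in a) s <- s + min(D[i, b])
  for (j in b) s <- s + min(D[j, a])
  s / (length(a) + length(b))
}

# path-sum cophenetic distance by explicit root-path traversal
oracle_cophenetic <- function(phy) {
  ntip <- length(phy$tip.label)
  nv <- ntip + phy$Nnode
  parent <- rep(NA_integer_, nv)
  plen <- rep(0, nv)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  plen[phy$edge[, 2]] <- phy$edge.length
  path_to_root <- function(i) {
    nodes <- i; lens <- numeric(0)
    while (!is.na(parent[i])) {
      lens <- c(lens, plen[i])
      i <- parent[i]
      nodes <- c(nodes, i)
    }
    list(nodes = nodes, cum = c(0, cumsum(lens)))
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  D <- matrix(0, ntip, ntip,
              dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    if (i >= j) next
    pi <- paths[[i]]; pj <- paths[[j]]
    shared <- intersect(pi$nodes, pj$nodes)
    di <- min(pi$cum[match(shared, pi$nodes)])
    dj <- min(pj$cum[match(shared, pj$nodes)])
    D[i, j] <- D[j, i] <- di + dj
  }
  D
}

# random ultrametric calibrated tree
rand_ct <- function(ntip, seed) {
  set.seed(seed)
  as_calibrated(ape::rcoal(ntip))
}

# random (tree, two communities) instance for metric checks
rand_instance <- function(seed, max_tips = 12) {
  set.seed(seed)
  ntip <- sample(4:max_tips, 1)
  ct <- as_calibrated(ape::rcoal(ntip))
  D <- cophenetic_matrix(ct)
  labs <- rownames(D)
  na <- sample(2:(ntip - 1), 1)
  nb <- sample(2:(ntip - 1), 1)
  list(D = D,
       a = sample(labs, na),
       b = sample(labs, nb))
}

# the worked 4-tip tree: cherries at age 1, root at age 3
four_tip_D <- function() {
  ct <- as_calibrated(parse_newick("((A:1,B:1):2,(C:1,D:1):2);"))
  cophenetic_matrix(ct)
}

# random rooted chain tree r -> u1 -> ... -> uk -> tip
chain_tree <- function(k) {
  inner <- "T"
  for (i in rev(seq_len(k))) inner <- paste0("(", inner, ")u", i)
  parse_newick(paste0("(", inner, ")r;"))
}

# small survey-record fixture with known pooling collisions
pooling_fixture <- function() {
  data.frame(
    survey = c("s1", "s1", "s1", "s1", "s2", "s2", "s2", "s3", "s3"),
    family = c("Lauraceae", "Lauraceae", "Lauraceae", "Myrtaceae",
               "Lauraceae", "Lauraceae", "Myrtaceae",
               "Lauraceae", "Annonaceae"),
    genus = c("Ocotea", "Ocotea", "Ocotea", "Myrcia",
              "Ocotea", "Nectandra", "Myrcia",
              "Ocotea", ""),
    label = c("odorifera", "sp.1", "sp.2", "glabra",
              "sp.1", "sp.", "glabra",
              "odorifera", "sp."),
    level = c("species", "genus", "genus", "species",
              "genus", "genus", "species",
              "species", "family"),
    abundance = c(5L, 2L, 1L, 4L, 3L, 2L, 6L, 1L, 2L),
    stringsAsFactors = FALSE)
}
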