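# Ground-truth simulator: pure-birth phylogenies whose lineages occupy
# communities on a latitudinal landscape, diversifying under sympatric
# or allopatric speciation with distance-decaying dispersal, plus
# spatially structured climate. The defaults echo the study geometry
# this pipeline was designed around: ~50 tree communities in 5 regions
# along a ~3000 km arc with ~300 species.

#' Scenario configuration for the speciation simulator
#'
#' @param mode `"sympatric"` (daughter species inherit the parent's
#'   community set, so sisters co-occur), `"allopatric"` (daughters
#'   receive disjoint community sets, so sisters never co-occur before
#'   dispersal) or `"mixed"`.
#' @param seed integer seed (mandatory); the full dataset is
#'   deterministic given the configuration.
#' @param n_regions number of regions along the latitudinal arc.
#' @param communities_per_region communities per region.
#' @param n_founders founding lineages (>= 2), seeded one per region in
#'   round-robin order; each founder occupies a random subset of its
#'   region's communities (see `founder_occupancy`), so communities of
#'   one region differ in composition as real surveys do.
#' @param n_speciation number of speciation events; the final tree has
#'   `n_founders + n_speciation` tips.
#' @param founder_occupancy probability that a founder occupies each
#'   community of its natal region (at least one is guaranteed). If
#'   chance leaves a community with no species the dataset is redrawn,
#'   with a message, from a seed derived from `seed`.
#' @param dispersal_scale kernel scale lambda in km: after the tree
#'   completes, each species colonizes each unoccupied community with
#'   probability `dispersal_prob * exp(-d / lambda)` where `d` is the
#'   distance to its nearest occupied community. `0` disables
#'   dispersal; `Inf` makes the kernel distance-independent, which with
#'   `dispersal_prob < 1` models near-complete secondary contact
#'   (ranges overlap with no spatial structure).
#' @param dispersal_prob ceiling colonization probability of the
#'   kernel.
#' @param range_loss per-split probability that a daughter species
#'   sheds each inherited community at a sympatric split (range
#'   evolution under niche conservatism); sisters always retain one
#'   shared anchor community. `0` reproduces exact inheritance, under
#'   which entire clades occupy identical community sets.
#' @param prop_sympatric fraction of sympatric splits in `"mixed"`
#'   mode.
#' @param lat_range,lon_range landscape extent in decimal degrees
#'   (defaults span ~27 degrees of latitude, ~3000 km).
#' @param comm_jitter_sd community scatter around its region center
#'   (degrees).
#' @param mat_center,mat_slope,mat_noise_sd mean annual temperature
#'   (deg C) at the arc center, change per degree latitude, and
#'   site-level noise.
#' @param map_center,map_slope,map_noise_sd mean annual precipitation
#'   (mm) at the arc center, change per degree longitude, and noise.
#' @param root_age crown age in Myr used to scale the tree.
#' @param dated_fraction fraction of the shallow interior nodes
#'   carrying a named age anchor, emulating partially dated megatrees.
#' @param dated_above_frac every interior node older than this fraction
#'   of the root age is dated (and the root always is): deep backbone
#'   relationships are the fossil-calibrated, resolved part of real
#'   megatrees, while lack of resolution sits near the tips.
#' @param collapse_fraction fraction of the undated interior nodes
#'   collapsed into their parent, creating polytomies like those a
#'   genus-level backbone produces.
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(mode = c("sympatric", "allopatric", "mixed"),
                            seed,
                            n_regions = 5,
                            communities_per_region = 10,
                            n_founders = 3 * n_regions,
                            n_speciation = 300 - n_founders,
                            dispersal_scale = 50,
                            dispersal_prob = 1,
                            range_loss = 0.1,
                            founder_occupancy = 0.8,
                            prop_sympatric = 0.5,
                            lat_range = c(-3, -30),
                            lon_range = c(-36, -50),
                            comm_jitter_sd = 0.6,
                            mat_center = 18.5, mat_slope = 0.45,
                            mat_noise_sd = 0.5,
                            map_center = 1450, map_slope = -45,
                            map_noise_sd = 80,
                            root_age = 60,
                            dated_fraction = 0.6,
                            dated_above_frac = 0.4,
                            collapse_fraction = 0.25) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_regions >= 1, communities_per_region >= 1,
            n_founders >= 2, n_speciation >= 1,
            dispersal_scale >= 0,
            dispersal_prob >= 0, dispersal_prob <= 1,
            range_loss >= 0, range_loss < 1,
            founder_occupancy > 0, founder_occupancy <= 1,
            prop_sympatric >= 0, prop_sympatric <= 1,
            dated_fraction >= 0, dated_fraction <= 1,
            dated_above_frac >= 0, dated_above_frac <= 1,
            collapse_fraction >= 0, collapse_fraction <= 1,
            root_age > 0)
  structure(list(mode = mode, seed = as.integer(seed),
                 n_regions = n_regions,
                 communities_per_region = communities_per_region,
                 n_founders = n_founders, n_speciation = n_speciation,
                 dispersal_scale = dispersal_scale,
                 dispersal_prob = dispersal_prob,
                 range_loss = range_loss,
                 founder_occupancy = founder_occupancy,
                 prop_sympatric = prop_sympatric,
                 lat_range = lat_range, lon_range = lon_range,
                 comm_jitter_sd = comm_jitter_sd,
                 mat_center = mat_center, mat_slope = mat_slope,
                 mat_noise_sd = mat_noise_sd,
                 map_center = map_center, map_slope = map_slope,
                 map_noise_sd = map_noise_sd,
                 root_age = root_age,
                 dated_fraction = dated_fraction,
                 dated_above_frac = dated_above_frac,
                 collapse_fraction = collapse_fraction),
            class = "scenario_config")
}

#' Add spatially structured climate to a site table
#'
#' MAT is linear in latitude and MAP linear in longitude, each plus
#' independent Gaussian noise, so climate differences grow with
#' distance by construction. Habitat classes are assigned by
#' temperature terciles (EMF coolest, SSF intermediate, EDF warmest).
#'
#' @param sites data frame with `community`, `lat`, `lon`.
#' @param config a `"scenario_config"`.
#' @return `sites` with `MAT`, `MAP` and `habitat` columns added.
#' @export
climate_field <- function(sites, config) {
  check_sites(sites)
  lat0 <- mean(config$lat_range)
  lon0 <- mean(config$lon_range)
  sites$MAT <- config$mat_center +
    config$mat_slope * (sites$lat - lat0) +
    rnorm(nrow(sites), 0, config$mat_noise_sd)
  sites$MAP <- config$map_center +
    config$map_slope * (sites$lon - lon0) +
    rnorm(nrow(sites), 0, config$map_noise_sd)
  q <- stats::quantile(sites$MAT, c(1 / 3, 2 / 3))
  sites$habitat <- cut(sites$MAT, c(-Inf, q, Inf),
                       labels = c("EMF", "SSF", "EDF"))
  sites$habitat <- as.character(sites$habitat)
  sites
}

# sample() without the length-1 surprise
resample <- function(x, size) x[sample.int(length(x), size)]

# random bipartition of a set into two non-empty halves
split_two <- function(x) {
  if (length(x) < 2L) stop("cannot bipartition fewer than 2 elements")
  repeat {
    side <- runif(length(x)) < 0.5
    if (any(side) && any(!side)) return(list(x[side], x[!side]))
  }
}

#' Simulate a speciation scenario: tree, ranges, communities, climate
#'
#' Grows a pure-birth tree from the founding lineages by repeatedly
#' splitting a uniformly chosen extant lineage at exponential waiting
#' times. At a sympatric split both daughters inherit the parent's
#' community set; at an allopatric split the parent's communities are
#' divided into two disjoint sets (by region when the parent spans
#' several, otherwise by random bipartition; a single-community parent
#' keeps its community and the other daughter jumps to a community of
#' another region). After the tree completes, every species disperses
#' independently to each unoccupied community with probability
#' `exp(-d / dispersal_scale)`. Node ages are scaled so the root sits
#' at `root_age`; a configurable fraction of interior nodes is dated
#' (named anchors) and a fraction of the undated ones collapsed into
#' polytomies, after which the delivered tree is recalibrated with
#' [calibrate_bladj()] exactly as a field dataset would be.
#'
#' @param config a `"scenario_config"` from [scenario_config()].
#' @return a list of class `"speciation_sim"`: `tree`
#'   (`"calibrated_phylo"`), `ages` (anchor table), `comm`
#'   (`"community_matrix"`), `sites` (with climate and habitat),
#'   `regions` (named region label per community), `mode`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  for (attempt in 0:49) {
    out <- simulate_dataset_once(config,
                                 (config$seed + attempt * 1000003) %%
                                   .Machine$integer.max)
    if (!is.null(out)) {
      if (attempt > 0)
        message("redrew dataset ", attempt,
                " time(s) to avoid an empty community")
      return(out)
    }
  }
  stop("could not assemble a dataset without empty communities; ",
       "raise founder_occupancy or n_founders")
}

simulate_dataset_once <- function(config, seed) {
  set.seed(seed)
  nr <- config$n_regions
  cpr <- config$communities_per_region
  ncomm <- nr * cpr

  lat_c <- seq(config$lat_range[1], config$lat_range[2], length.out = nr)
  lon_c <- seq(config$lon_range[1], config$lon_range[2], length.out = nr)
  region <- rep(seq_len(nr), each = cpr)
  sites <- data.frame(
    community = sprintf("c%02d", seq_len(ncomm)),
    lat = lat_c[region] + rnorm(ncomm, 0, config$comm_jitter_sd),
    lon = lon_c[region] + rnorm(ncomm, 0, config$comm_jitter_sd),
    stringsAsFactors = FALSE)
  sites$lat <- pmax(pmin(sites$lat, 90), -90)
  sites <- climate_field(sites, config)
  km <- geo_distance_matrix(sites)

  f <- config$n_founders
  ne <- config$n_speciation
  n_nodes_max <- 1L + f + 2L * ne
  parent <- rep(NA_integer_, n_nodes_max)
  t_node <- rep(NA_real_, n_nodes_max)
  range_of <- vector("list", n_nodes_max)
  parent[1 + seq_len(f)] <- 1L
  t_node[1] <- 0
  for (i in seq_len(f)) {
    r <- (i - 1L) %% nr + 1L
    natal <- which(region == r)
    occ <- natal[runif(length(natal)) < config$founder_occupancy]
    if (!length(occ)) occ <- resample(natal, 1L)
    range_of[[1 + i]] <- occ
  }
  active <- 1L + seq_len(f)
  used <- 1L + f
  tnow <- 0
  for (e in seq_len(ne)) {
    tnow <- tnow + rexp(1, rate = length(active))
    pick <- active[sample.int(length(active), 1L)]
    t_node[pick] <- tnow
    d1 <- used + 1L; d2 <- used + 2L; used <- used + 2L
    parent[c(d1, d2)] <- pick
    sympatric <- switch(config$mode,
                        sympatric = TRUE,
                        allopatric = FALSE,
                        mixed = runif(1) < config$prop_sympatric)
    pr <- range_of[[pick]]
    if (sympatric) {
      # daughters inherit the parent's communities; with range_loss > 0
      # each independently sheds a fraction of them (range evolution),
      # but both always retain a common anchor community so sister
      # species co-occur by construction
      anchor <- resample(pr, 1L)
      thin <- function() {
        keep <- pr[runif(length(pr)) >= config$range_loss]
        sort(unique(c(anchor, keep)))
      }
      range_of[[d1]] <- thin()
      range_of[[d2]] <- thin()
    } else {
      regs <- unique(region[pr])
      if (length(regs) > 1L) {
        # vicariance: the parent's regions are split between daughters
        halves <- split_two(regs)
        range_of[[d1]] <- pr[region[pr] %in% halves[[1]]]
        range_of[[d2]] <- pr[region[pr] %in% halves[[2]]]
      } else if (nr > 1L) {
        # peripatric jump: one daughter keeps the natal region, the
        # other colonizes a different region (sisters end up apart)
        range_of[[d1]] <- pr
        newreg <- resample(setdiff(seq_len(nr), regs), 1L)
        natal <- which(region == newreg)
        occ <- natal[runif(length(natal)) < config$founder_occupancy]
        if (!length(occ)) occ <- resample(natal, 1L)
        range_of[[d2]] <- occ
      } else {
        # single-region landscape: split the communities instead
        if (length(pr) > 1L) {
          halves <- split_two(pr)
          range_of[[d1]] <- halves[[1]]
          range_of[[d2]] <- halves[[2]]
        } else {
          range_of[[d1]] <- pr
          other <- setdiff(seq_len(ncomm), pr)
          range_of[[d2]] <- if (length(other)) resample(other, 1L) else pr
        }
      }
    }
    active <- c(setdiff(active, pick), d1, d2)
  }
  t_end <- tnow + rexp(1, rate = length(active))
  t_node[active] <- t_end
  age <- config$root_age * (t_end - t_node) / t_end

  # dispersal phase
  lam <- config$dispersal_scale
  for (tip in active) {
    occ <- range_of[[tip]]
    if (lam > 0 && config$dispersal_prob > 0 && length(occ) < ncomm) {
      free <- setdiff(seq_len(ncomm), occ)
      dmin <- apply(km[free, occ, drop = FALSE], 1, min)
      p_col <- config$dispersal_prob *
        if (is.finite(lam)) exp(-dmin / lam) else 1
      gain <- free[runif(length(free)) < p_col]
      range_of[[tip]] <- c(occ, gain)
    }
  }

  tips <- active[order(active)]
  tip_name <- sprintf("sp%04d", seq_along(tips))
  m <- matrix(0L, ncomm, length(tips),
              dimnames = list(sites$community, tip_name))
  for (i in seq_along(tips)) m[range_of[[tips[i]]], i] <- 1L
  if (any(rowSums(m) == 0)) return(NULL)   # caller redraws

  # assemble the tree table in true node ages
  ids <- sort(unique(c(1L, which(!is.na(t_node)))))
  nv <- length(ids)
  remap <- integer(n_nodes_max)
  remap[ids] <- seq_len(nv)
  nm <- rep("", nv)
  nm[remap[tips]] <- tip_name
  tab <- data.frame(id = seq_len(nv),
                    parent = ifelse(is.na(parent[ids]), NA_integer_,
                                    remap[parent[ids]]),
                    name = nm, length = NA_real_,
                    stringsAsFactors = FALSE)
  node_age <- age[ids]

  # date the deep backbone plus a fraction of shallow interior nodes;
  # the root is always dated
  kids <- tab_children(tab)
  interior <- which(vapply(kids, length, 1L) > 0L)
  root <- tab_root(tab)
  deep <- interior[node_age[interior] >=
                     config$dated_above_frac * config$root_age]
  shallow <- setdiff(interior, deep)
  n_dated <- round(config$dated_fraction * length(shallow))
  dated_ids <- unique(c(root, deep,
                        if (n_dated > 0) resample(shallow, n_dated)))
  tab$name[dated_ids] <- ifelse(dated_ids == root, "root",
                                sprintf("n%04d", dated_ids))
  ages_tab <- setNames(node_age[dated_ids], tab$name[dated_ids])

  # collapse a fraction of undated interior nodes into polytomies
  undated <- setdiff(interior, c(dated_ids, root))
  n_coll <- round(config$collapse_fraction * length(undated))
  if (n_coll > 0) {
    drop <- resample(undated, n_coll)
    for (u in drop) {
      ch <- which(tab$parent == u)
      tab$parent[ch] <- tab$parent[u]
    }
    keep <- setdiff(seq_len(nv), drop)
    new_of <- integer(nv)
    new_of[keep] <- seq_along(keep)
    tab <- tab[keep, , drop = FALSE]
    tab$parent <- ifelse(is.na(tab$parent), NA_integer_,
                         new_of[tab$parent])
    tab$id <- seq_along(keep)
  }
  phy <- table_to_phylo(tab)
  tree <- calibrate_bladj(phy, ages_tab[names(ages_tab) != "root"],
                          root_age = unname(ages_tab["root"]))

  cm <- structure(list(abund = m,
                       taxa = data.frame(label = tip_name,
                                         family = NA_character_,
                                         genus = NA_character_,
                                         level = "species",
                                         stringsAsFactors = FALSE)),
                  class = "community_matrix")
  structure(list(tree = tree, ages = ages_tab, comm = cm,
                 sites = sites,
                 regions = setNames(paste0("R", region), sites$community),
                 mode = config$mode, config = config),
            class = "speciation_sim")
}

#' @export
print.speciation_sim <- function(x, ...) {
  cat("Simulated", x$mode, "speciation scenario:",
      ncol(x$comm$abund), "species,", nrow(x$comm$abund),
      "communities in", x$config$n_regions, "regions\n")
  invisible(x)
}

#' Check pipeline results against the scenario's predicted signature
#'
#' Runs the turnover diagnostics that distinguish the speciation
#' scenarios: Mantel correlation of betaMNTD with geographic distance,
#' Mantel correlation of Jaccard similarity with distance, and the
#' within-region versus between-region contrast of betaMNTD. A
#' sympatric scenario predicts a significantly positive
#' betaMNTD-distance correlation with lower turnover within regions;
#' an allopatric scenario with broad dispersal predicts an attenuated
#' or absent signal. A single-region landscape carries no spatial
#' signal and is flagged inconclusive.
#'
#' @param ds a `"speciation_sim"` from [simulate_dataset()].
#' @param n_perm Mantel permutations.
#' @param seed integer seed for the permutation tests.
#' @param alpha significance level.
#' @return a list of class `"signature_report"`: the measured
#'   quantities, the mode's predicted signature and whether it
#'   matched.
#' @export
expected_signature_check <- function(ds, n_perm = 999, seed = 1,
                                     alpha = 0.05) {
  stopifnot(inherits(ds, "speciation_sim"))
  D <- cophenetic_matrix(ds$tree)
  res <- all_pair_metrics(ds$comm, D, n_rand = 0)
  pairs <- res$pairs
  comms <- ds$sites$community
  km <- geo_distance_matrix(ds$sites)
  Bm <- pairs_to_matrix(pairs, "beta_mntd", comms)
  Jm <- pairs_to_matrix(pairs, "jaccard", comms)
  single_region <- ds$config$n_regions < 2

  mt_b <- mantel_test(Bm, km, n_perm = n_perm, seed = seed)
  mt_j <- mantel_test(Jm, km, n_perm = n_perm, seed = seed + 1)
  same_region <- ds$regions[pairs$community1] ==
    ds$regions[pairs$community2]
  within <- mean(pairs$beta_mntd[same_region])
  between <- mean(pairs$beta_mntd[!same_region])

  mntd_dist_positive <- mt_b$r > 0 && mt_b$p < alpha
  jaccard_decay <- mt_j$r < 0 && mt_j$p < alpha
  within_lower <- is.finite(within) && is.finite(between) &&
    within < between
  predicted <- switch(ds$mode,
    sympatric = "positive significant betaMNTD-distance Mantel; within-region betaMNTD below between-region",
    allopatric = "attenuated or absent betaMNTD-distance signal",
    mixed = "intermediate betaMNTD-distance signal")
  match <- if (single_region) NA else switch(ds$mode,
    sympatric = mntd_dist_positive && within_lower,
    allopatric = !mntd_dist_positive,
    mixed = NA)
  structure(list(mode = ds$mode,
                 mantel_betamntd_km = mt_b,
                 mantel_jaccard_km = mt_j,
                 within_region_betamntd = within,
                 between_region_betamntd = between,
                 mntd_dist_positive = mntd_dist_positive,
                 within_lower = within_lower,
                 jaccard_decay = jaccard_decay,
                 predicted = predicted,
                 inconclusive = single_region,
                 matches_prediction = match),
            class = "signature_report")
}

#' @export
print.signature_report <- function(x, ...) {
  cat("Scenario:", x$mode, "\n")
  cat("betaMNTD ~ km:  r =", format(x$mantel_betamntd_km$r, digits = 3),
      " p =", format(x$mantel_betamntd_km$p, digits = 3), "\n")
  cat("Jaccard ~ km:   r =", format(x$mantel_jaccard_km$r, digits = 3),
      " p =", format(x$mantel_jaccard_km$p, digits = 3), "\n")
  cat("betaMNTD within regions", format(x$within_region_betamntd, digits = 4),
      "vs between", format(x$between_region_betamntd, digits = 4), "\n")
  if (x$inconclusive) {
    cat("Single-region landscape: no spatial signal possible (inconclusive)\n")
  } else {
    cat("Predicted:", x$predicted, "\n")
    cat("Matches prediction:", x$matches_prediction, "\n")
  }
  invisible(x)
}
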