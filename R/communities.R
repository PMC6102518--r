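# Survey ingestion, taxon pooling and pairwise geographic/environmental
# distance structures.

MORPHO_RE <- "^(sp|indet|cf|aff)[._ ]*([0-9]*)[._ ]*([a-z]*)$"

# Canonicalize a morphotype tag: "sp.", "sp. 1", "sp_1" -> "sp"/"sp1";
# "cf. glabra" -> "cf_glabra". Returns NA for fully identified epithets.
normalize_morphotag <- function(x) {
  y <- tolower(trimws(x))
  mm <- regmatches(y, regexec(MORPHO_RE, y))
  out <- rep(NA_character_, length(y))
  for (i in seq_along(y)) {
    g <- mm[[i]]
    if (length(g)) {
      out[i] <- paste0(g[2], g[3],
                       if (nzchar(g[4])) paste0("_", g[4]) else "")
    }
  }
  out
}

cap_first <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Pool survey records into a community-by-taxon abundance matrix
#'
#' Implements the two taxon-pooling conventions for literature surveys
#' with inconsistent open nomenclature. Fully identified species merge
#' across surveys on their binomial in both modes. Records identified
#' only to genus (or family) level are keyed by genus (or family) plus
#' the normalized morphotype tag: in `"small"` mode the same key merges
#' across surveys; in `"large"` mode each survey's morphotype stays a
#' separate taxon (the label is suffixed with the survey id). Distinct
#' tags within one survey never merge in either mode, so the large-mode
#' taxon count is always at least the small-mode count.
#'
#' @param records data frame with columns `survey`, `family`, `genus`,
#'   `label` (species epithet or morphotype tag such as `"sp.1"`),
#'   `level` (one of `"species"`, `"genus"`, `"family"`) and `abundance`
#'   (positive integer counts).
#' @param mode `"small"` (pool morphotypes across surveys) or `"large"`
#'   (keep them survey-specific).
#' @return a list of class `"community_matrix"`: `abund` (integer
#'   matrix, communities x taxa, ordered by first appearance), and
#'   `taxa` (data frame mapping taxon labels to family/genus, usable as
#'   [graft_taxa()] input).
#' @export
pool_taxa <- function(records, mode = c("small", "large")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records))
  need <- c("survey", "family", "genus", "label", "level", "abundance")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0L) stop("records is empty")
  if (any(records$abundance < 1 | records$abundance != round(records$abundance)))
    stop("abundances must be positive integers; offending rows: ",
         paste(head(which(records$abundance < 1 |
                          records$abundance != round(records$abundance))),
               collapse = ", "))
  no_id <- !nzchar(trimws(records$family)) & !nzchar(trimws(records$genus))
  if (any(no_id))
    stop("records with neither family nor genus: rows ",
         paste(which(no_id), collapse = ", "))
  if (!all(records$level %in% c("species", "genus", "family")))
    stop("level must be species, genus or family")

  gen <- cap_first(norm_name(records$genus))
  fam <- cap_first(norm_name(records$family))
  lab <- norm_name(records$label)
  tag <- normalize_morphotag(records$label)
  tag[is.na(tag)] <- paste0("sp_", lab[is.na(tag)])  # fallback: keep raw tag

  taxon <- character(nrow(records))
  sp <- records$level == "species"
  taxon[sp] <- paste0(gen[sp], "_", lab[sp])
  gl <- records$level == "genus"
  fl <- records$level == "family"
  if (any(gl & !nzchar(gen))) stop("genus-level records need a genus name")
  if (any(fl & !nzchar(fam))) stop("family-level records need a family name")
  base_g <- paste0(gen, "_", tag)
  base_f <- paste0(fam, "_", sub("^sp", "indet", tag))
  if (mode == "small") {
    taxon[gl] <- base_g[gl]
    taxon[fl] <- base_f[fl]
  } else {
    taxon[gl] <- paste0(base_g[gl], "_", records$survey[gl])
    taxon[fl] <- paste0(base_f[fl], "_", records$survey[fl])
  }

  comms <- unique(as.character(records$survey))
  taxa <- unique(taxon)
  m <- matrix(0L, length(comms), length(taxa),
              dimnames = list(comms, taxa))
  for (i in seq_len(nrow(records))) {
    ci <- as.character(records$survey[i])
    m[ci, taxon[i]] <- m[ci, taxon[i]] + as.integer(records$abundance[i])
  }
  info <- data.frame(label = taxa,
                     family = fam[match(taxa, taxon)],
                     genus = gen[match(taxa, taxon)],
                     level = records$level[match(taxa, taxon)],
                     stringsAsFactors = FALSE)
  structure(list(abund = m, taxa = info), class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("Community matrix:", nrow(x$abund), "communities x",
      ncol(x$abund), "taxa\n")
  invisible(x)
}

#' Read a Phylocom-style three-column sample file
#'
#' Columns: plot id, abundance, taxon label (tab- or space-delimited).
#'
#' @param path file path.
#' @return a `"community_matrix"` (with a minimal `taxa` table; genus is
#'   taken as the part of the label before the first underscore).
#' @export
read_sample_file <- function(path) {
  tab <- read.table(path, header = FALSE,
                    col.names = c("survey", "abundance", "taxon"),
                    stringsAsFactors = FALSE)
  comms <- unique(as.character(tab$survey))
  taxa <- unique(tab$taxon)
  m <- matrix(0L, length(comms), length(taxa),
              dimnames = list(comms, taxa))
  for (i in seq_len(nrow(tab)))
    m[as.character(tab$survey[i]), tab$taxon[i]] <-
      m[as.character(tab$survey[i]), tab$taxon[i]] + as.integer(tab$abundance[i])
  genus <- sub("_.*$", "", taxa)
  structure(list(abund = m,
                 taxa = data.frame(label = taxa, family = NA_character_,
                                   genus = genus, level = NA_character_,
                                   stringsAsFactors = FALSE)),
            class = "community_matrix")
}

check_sites <- function(sites) {
  need <- c("community", "lat", "lon")
  if (!all(need %in% names(sites)))
    stop("sites must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sites$community)) stop("duplicate community ids")
  miss <- !is.finite(sites$lat) | !is.finite(sites$lon)
  if (any(miss))
    stop("missing coordinates for community: ",
         paste(sites$community[miss], collapse = ", "))
  if (any(abs(sites$lat) > 90) || any(abs(sites$lon) > 180))
    stop("coordinates out of range")
  invisible(sites)
}

EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance matrix between survey sites
#'
#' Haversine distances in kilometers (Earth radius 6371 km).
#'
#' @param sites data frame with columns `community`, `lat`, `lon`
#'   (decimal degrees).
#' @return symmetric matrix of distances (km) with community ids as
#'   dimnames.
#' @export
geo_distance_matrix <- function(sites) {
  check_sites(sites)
  p <- cbind(sites$lon, sites$lat)
  d <- geosphere::distm(p, fun = function(a, b)
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM * 1000)) / 1000
  dimnames(d) <- list(sites$community, sites$community)
  d
}

#' Absolute pairwise difference matrix for a site climate variable
#'
#' @param sites data frame with columns `community` and the requested
#'   variable (`MAT` in degrees C or `MAP` in mm).
#' @param variable `"MAT"` or `"MAP"`.
#' @return symmetric matrix of absolute differences in the variable's
#'   native units.
#' @export
env_difference_matrix <- function(sites, variable = c("MAT", "MAP")) {
  variable <- match.arg(variable)
  if (!variable %in% names(sites))
    stop("sites has no column ", variable)
  x <- sites[[variable]]
  miss <- !is.finite(x)
  if (any(miss))
    stop("missing ", variable, " for community: ",
         paste(sites$community[miss], collapse = ", "))
  d <- abs(outer(x, x, "-"))
  dimnames(d) <- list(sites$community, sites$community)
  d
}

#' Long-format table of pairwise distances between communities
#'
#' One row per unordered community pair with great-circle distance and
#' absolute climate differences; the substrate that beta-diversity
#' metrics are later joined onto.
#'
#' @param sites data frame with columns `community`, `lat`, `lon` and
#'   optionally `MAT`, `MAP`.
#' @return data frame with `n (n - 1) / 2` rows: `community1`,
#'   `community2`, `km`, and `dMAT`/`dMAP` when available.
#' @export
build_pairwise_table <- function(sites) {
  check_sites(sites)
  n <- nrow(sites)
  if (n < 2L) stop("need at least two communities")
  idx <- combn(n, 2)
  out <- data.frame(community1 = sites$community[idx[1, ]],
                    community2 = sites$community[idx[2, ]],
                    stringsAsFactors = FALSE)
  gd <- geo_distance_matrix(sites)
  out$km <- gd[cbind(idx[1, ], idx[2, ])]
  for (v in c("MAT", "MAP")) {
    if (v %in% names(sites)) {
      ed <- env_difference_matrix(sites, v)
      out[[paste0("d", v)]] <- ed[cbind(idx[1, ], idx[2, ])]
    }
  }
  out
}

#' Rebuild a symmetric matrix from a long pair table
#'
#' @param pairs data frame with `community1`, `community2` and the value
#'   column.
#' @param value name of the value column.
#' @param communities optional character vector fixing row/column order.
#' @return a symmetric matrix with zero diagonal.
#' @export
pairs_to_matrix <- function(pairs, value, communities = NULL) {
  if (!value %in% names(pairs)) stop("no column ", value, " in pairs")
  if (is.null(communities))
    communities <- unique(c(pairs$community1, pairs$community2))
  n <- length(communities)
  m <- matrix(0, n, n, dimnames = list(communities, communities))
  i <- match(pairs$community1, communities)
  j <- match(pairs$community2, communities)
  if (anyNA(i) || anyNA(j)) stop("pair table names a community not in list")
  m[cbind(i, j)] <- pairs[[value]]
  m[cbind(j, i)] <- pairs[[value]]
  m
}
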