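# Spatial aggregations: communities linked by significantly low
# phylogenetic turnover, formalized as connected components of the
# significant-pair graph, plus within/between summary tables.

#' Community pairs with significantly low phylogenetic turnover
#'
#' Selects the pairs whose betaNTI (or betaNRI) exceeds the threshold,
#' i.e. turnover lower than expected under the null; pairs flagged as
#' degenerate-null are excluded.
#'
#' @param pairs pair table from [all_pair_metrics()] (needs columns
#'   `community1`, `community2` and the chosen index).
#' @param index `"beta_nti"` (default; recent turnover) or
#'   `"beta_nri"`.
#' @param threshold significance threshold (default 1.96).
#' @return an edge-list data frame (subset of `pairs`).
#' @export
significant_low_pairs <- function(pairs, index = c("beta_nti", "beta_nri"),
                                  threshold = 1.96) {
  index <- match.arg(index)
  if (!index %in% names(pairs)) stop("pairs has no column ", index)
  v <- pairs[[index]]
  keep <- !is.na(v) & v > threshold
  if ("degenerate" %in% names(pairs))
    keep <- keep & !pairs$degenerate
  pairs[keep, , drop = FALSE]
}

#' Connected components of the low-turnover graph
#'
#' Undirected connected components over the community set; each
#' component is a spatial aggregation, labeled by its smallest member
#' id. Communities in no edge remain singleton aggregations.
#'
#' @param nodes character vector of all community ids.
#' @param edges data frame with columns `community1`, `community2`
#'   (may have zero rows).
#' @return a data frame of class `"aggregation_partition"`:
#'   `community`, `aggregation`.
#' @export
connected_components <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate community ids in nodes")
  enames <- unique(c(as.character(edges$community1),
                     as.character(edges$community2)))
  unknown <- setdiff(enames, nodes)
  if (length(unknown))
    stop("edges name unknown communities: ",
         paste(unknown, collapse = ", "))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(as.character(edges$community1),
                                    as.character(edges$community2)))
  comp <- igraph::components(g)
  lab <- vapply(seq_len(comp$no), function(k)
    min(nodes[comp$membership == k]), "")
  out <- data.frame(community = nodes,
                    aggregation = lab[comp$membership],
                    stringsAsFactors = FALSE)
  out <- out[order(out$community), ]
  rownames(out) <- NULL
  class(out) <- c("aggregation_partition", "data.frame")
  out
}

#' Within- and between-aggregation summary of pair metrics
#'
#' Groups community pairs by the (unordered) pair of aggregation labels
#' of their members and reports mean and standard deviation of each
#' requested field, with compact significance letters from
#' [anova_oneway()] where enough groups have two or more pairs.
#'
#' @param pairs pair table (e.g. from [all_pair_metrics()], possibly
#'   merged with [build_pairwise_table()]).
#' @param partition an `"aggregation_partition"` (or any data frame
#'   with `community`, `aggregation`).
#' @param fields character vector of numeric columns to summarize.
#' @param alpha significance level for the letters.
#' @return a data frame: `group`, `n_pairs`, then `<field>_mean`,
#'   `<field>_sd`, `<field>_letter` per field.
#' @export
within_between_summary <- function(pairs, partition,
                                   fields = c("jaccard", "beta_mntd",
                                              "beta_mpd"),
                                   alpha = 0.05) {
  lab <- setNames(partition$aggregation, partition$community)
  l1 <- lab[as.character(pairs$community1)]
  l2 <- lab[as.character(pairs$community2)]
  if (anyNA(l1) || anyNA(l2))
    stop("pair table names communities missing from the partition")
  group <- ifelse(l1 <= l2, paste(l1, l2, sep = "-"),
                  paste(l2, l1, sep = "-"))
  fields <- fields[fields %in% names(pairs)]
  if (!length(fields)) stop("no requested field present in pairs")
  glev <- sort(unique(group))
  out <- data.frame(group = glev,
                    n_pairs = as.integer(table(group)[glev]),
                    stringsAsFactors = FALSE)
  for (f in fields) {
    v <- pairs[[f]]
    out[[paste0(f, "_mean")]] <- as.numeric(tapply(v, group, mean)[glev])
    out[[paste0(f, "_sd")]] <- as.numeric(tapply(v, group, sd)[glev])
    lt <- rep(NA_character_, length(glev))
    enough <- names(which(table(group) >= 2))
    if (length(enough) >= 2) {
      keep <- group %in% enough
      an <- anova_oneway(v[keep], group[keep], alpha = alpha)
      lt[match(names(an$letters), glev)] <- an$letters
    }
    out[[paste0(f, "_letter")]] <- lt
  }
  out
}
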