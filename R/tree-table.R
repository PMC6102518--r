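# Internal flat representation of a rooted tree used by the grafting,
# calibration and polytomy-resolution machinery. One row per node:
#   id     integer, 1..n_nodes (arbitrary but stable)
#   parent integer, NA for the root
#   name   character, "" where absent
#   length numeric branch length to parent, NA where absent
# Tips are the nodes with no children; singleton (one-child) interior
# nodes are permitted, which is why we do not lean on the "phylo" edge
# matrix for editing operations.

phylo_to_table <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  nv <- ntip + nnode
  parent <- rep(NA_integer_, nv)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  len <- rep(NA_real_, nv)
  if (!is.null(phy$edge.length)) len[phy$edge[, 2]] <- phy$edge.length
  nm <- c(phy$tip.label,
          if (is.null(phy$node.label)) rep("", nnode) else phy$node.label)
  nm[is.na(nm)] <- ""
  data.frame(id = seq_len(nv), parent = parent, name = nm, length = len,
             stringsAsFactors = FALSE)
}

tab_children <- function(tab) {
  has_par <- !is.na(tab$parent)
  kids <- vector("list", nrow(tab))
  for (i in which(has_par)) {
    p <- tab$parent[i]
    kids[[p]] <- c(kids[[p]], tab$id[i])
  }
  kids
}

tab_root <- function(tab) {
  r <- tab$id[is.na(tab$parent)]
  if (length(r) != 1L) stop("tree must have exactly one root, found ", length(r))
  r
}

tab_validate <- function(tab) {
  root <- tab_root(tab)
  # reachability / acyclicity: walk up from every node, bounded by n
  n <- nrow(tab)
  for (i in tab$id) {
    cur <- i
    steps <- 0L
    while (!is.na(tab$parent[cur])) {
      cur <- tab$parent[cur]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in tree structure")
    }
    if (cur != root) stop("node ", i, " not connected to the root")
  }
  kids <- tab_children(tab)
  tips <- tab$id[vapply(kids, length, 1L) == 0L]
  tipnames <- tab$name[tips]
  if (anyDuplicated(tipnames[tipnames != ""]))
    stop("duplicate tip names: ",
         paste(unique(tipnames[duplicated(tipnames)]), collapse = ", "))
  invisible(tab)
}

# Convert the flat table back to an ape "phylo", renumbering nodes to the
# ape convention (tips 1..n, then interior nodes in preorder from the root).
table_to_phylo <- function(tab) {
  kids <- tab_children(tab)
  root <- tab_root(tab)
  nk <- vapply(kids, length, 1L)
  tips <- tab$id[nk == 0L]
  ntip <- length(tips)
  if (ntip < 1L) stop("tree has no tips")
  # preorder over interior nodes
  interior <- integer(0)
  stack <- root
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (nk[cur] > 0L) {
      interior <- c(interior, cur)
      stack <- c(stack, rev(kids[[cur]]))
    }
  }
  new_id <- integer(nrow(tab))
  new_id[tips] <- seq_len(ntip)
  new_id[interior] <- ntip + seq_along(interior)
  # depth-first (cladewise) edge emission
  n_edge <- sum(!is.na(tab$parent))
  ep <- integer(n_edge)
  ec <- integer(n_edge)
  k <- 0L
  stack <- rev(kids[[root]])
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ep[k] <- tab$parent[v]
    ec[k] <- v
    if (nk[v] > 0L) stack <- c(stack, rev(kids[[v]]))
  }
  edge <- cbind(new_id[ep], new_id[ec])
  nonroot <- ec
  phy <- list(edge = edge,
              tip.label = tab$name[tips],
              Nnode = length(interior))
  node_lab <- tab$name[interior]
  if (any(node_lab != "")) phy$node.label <- node_lab
  if (any(!is.na(tab$length))) {
    el <- tab$length[nonroot]
    if (anyNA(el)) stop("branch lengths present for some but not all edges")
    phy$edge.length <- el
  }
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

# Normalize a taxon/node name for matching: case-insensitive,
# punctuation and whitespace collapsed to single underscores.
norm_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}
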