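#' Parse a Newick string into a tree
#'
#' Recursive-descent parser accepting interior node names, branch
#' lengths, quoted labels, and singleton (one-child) interior nodes
#' such as the family-genus-species chains a backbone megatree
#' produces. Errors report the character offset of the problem.
#'
#' @param text a single Newick string.
#' @return an object of class `"phylo"`.
#' @examples
#' parse_newick("((A:1,B:1):2,(C:1,D:1):2);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- text
  n <- nchar(s)
  pos <- 1L
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  skip_ws <- function() {
    while (pos <= n && substr(s, pos, pos) %in% c(" ", "\t", "\r", "\n"))
      pos <<- pos + 1L
  }
  perr <- function(msg)
    stop("malformed Newick: ", msg, " at character ", pos)

  parent <- integer(0)
  nm <- character(0)
  len <- numeric(0)
  add_node <- function(p) {
    parent[length(parent) + 1L] <<- p
    nm[length(nm) + 1L] <<- ""
    len[length(len) + 1L] <<- NA_real_
    length(parent)
  }
  read_label <- function() {
    skip_ws()
    if (peek() == "'") {
      pos <<- pos + 1L
      st <- pos
      while (pos <= n && substr(s, pos, pos) != "'") pos <<- pos + 1L
      if (pos > n) perr("unterminated quoted label")
      out <- substr(s, st, pos - 1L)
      pos <<- pos + 1L
      return(out)
    }
    st <- pos
    while (pos <= n &&
           !(substr(s, pos, pos) %in%
             c("(", ")", ",", ":", ";", " ", "\t", "\r", "\n")))
      pos <<- pos + 1L
    substr(s, st, pos - 1L)
  }
  read_length <- function() {
    skip_ws()
    st <- pos
    while (pos <= n &&
           grepl("[-+0-9.eE]", substr(s, pos, pos))) pos <<- pos + 1L
    v <- suppressWarnings(as.numeric(substr(s, st, pos - 1L)))
    if (is.na(v)) perr("invalid branch length")
    v
  }
  parse_clade <- function(p) {
    skip_ws()
    id <- add_node(p)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        parse_clade(id)
        skip_ws()
        ch <- peek()
        if (ch == ",") {
          pos <<- pos + 1L
        } else if (ch == ")") {
          pos <<- pos + 1L
          break
        } else perr("expected ',' or ')'")
      }
    }
    lab <- read_label()
    if (nzchar(lab)) nm[id] <<- lab
    skip_ws()
    if (peek() == ":") {
      pos <<- pos + 1L
      len[id] <<- read_length()
    }
    id
  }
  root <- parse_clade(NA_integer_)
  skip_ws()
  if (peek() != ";") perr("expected terminating ';'")
  tab <- data.frame(id = seq_along(parent), parent = parent,
                    name = nm, length = len, stringsAsFactors = FALSE)
  if (all(is.na(tab$length[-root]))) tab$length <- NA_real_
  else if (anyNA(tab$length[tab$id != root]))
    perr("branch lengths present for some but not all edges")
  tab_validate(tab)
  table_to_phylo(tab)
}

#' Serialize a tree to a Newick string
#'
#' Inverse of [parse_newick()]: the result re-parses to an isomorphic
#' tree with identical names and branch lengths. Handles singleton
#' interior nodes.
#'
#' @param tree a `"phylo"` object or a [calibrate_bladj()] result.
#' @return a single Newick string.
#' @export
write_newick <- function(tree) {
  if (inherits(tree, "calibrated_phylo")) tree <- tree$phy
  stopifnot(inherits(tree, "phylo"))
  tab <- phylo_to_table(tree)
  kids <- tab_children(tab)
  fmt <- function(id) {
    ch <- kids[[id]]
    core <- if (length(ch))
      paste0("(", paste(vapply(ch, fmt, ""), collapse = ","), ")",
             tab$name[id])
    else tab$name[id]
    if (!is.na(tab$length[id]))
      core <- paste0(core, ":", sprintf("%.15g", tab$length[id]))
    core
  }
  paste0(fmt(tab_root(tab)), ";")
}

#' Read a Phylocom-style node ages file
#'
#' Two whitespace-delimited columns, node name then age in Myr.
#'
#' @param path file path.
#' @return a named numeric vector of ages.
#' @export
read_ages <- function(path) {
  tab <- read.table(path, header = FALSE, col.names = c("name", "age"),
                    stringsAsFactors = FALSE)
  ages <- as.numeric(tab$age)
  names(ages) <- tab$name
  validate_age_table(ages)
  ages
}

validate_age_table <- function(ages) {
  if (length(ages) == 0L) return(invisible(ages))
  if (is.null(names(ages)) || any(names(ages) == ""))
    stop("age table entries must all be named")
  if (anyDuplicated(norm_name(names(ages))))
    stop("duplicate node names in age table")
  if (any(!is.finite(ages)) || any(ages <= 0))
    stop("ages must all be positive and finite")
  invisible(ages)
}

#' Graft a family/genus/species taxon list onto a backbone megatree
#'
#' Phylomatic-style pruning and grafting: each taxon is attached to the
#' backbone interior node matching its genus; if the genus is absent but
#' the family is present, a new genus node is created under the family
#' node; taxa whose family is also absent are skipped and reported. All
#' backbone tips, and any backbone node left without a grafted
#' descendant, are pruned, so the output contains exactly one tip per
#' retained input taxon. Congeners grafted to the same genus form a
#' polytomy. Name matching is case-insensitive with whitespace and
#' punctuation normalized to underscores.
#'
#' @param backbone a `"phylo"` backbone whose interior nodes carry family
#'   and genus names.
#' @param taxa a data frame with columns `family`, `genus`, `label`
#'   (terminal label: species binomial or morphotype tag).
#' @return a list with `tree` (the grafted `"phylo"`, without branch
#'   lengths; calibrate with [calibrate_bladj()]) and `skipped` (data
#'   frame of taxa whose family was not found).
#' @export
graft_taxa <- function(backbone, taxa) {
  stopifnot(inherits(backbone, "phylo"), is.data.frame(taxa))
  need <- c("family", "genus", "label")
  if (!all(need %in% names(taxa)))
    stop("taxa must have columns: ", paste(need, collapse = ", "))
  if (nrow(taxa) == 0L) stop("empty taxon list")
  bad <- !nzchar(trimws(taxa$family)) | !nzchar(trimws(taxa$genus)) |
    !nzchar(trimws(taxa$label))
  if (any(bad))
    stop("taxon rows with empty components: ",
         paste(which(bad), collapse = ", "))
  if (anyDuplicated(norm_name(taxa$label)))
    stop("duplicate terminal labels in taxon list")

  tab <- phylo_to_table(backbone)
  tab$length <- NA_real_                      # calibration happens later
  kids_n <- tabulate(tab$parent[!is.na(tab$parent)], nbins = nrow(tab))
  backbone_tip <- kids_n == 0L
  node_key <- norm_name(tab$name)
  lookup <- function(key) {
    hit <- which(node_key == key & nzchar(key))
    if (length(hit)) hit[1L] else NA_integer_
  }

  next_id <- nrow(tab)
  add_node <- function(parent, name) {
    next_id <<- next_id + 1L
    tab[next_id, ] <<- list(next_id, parent, name, NA_real_)
    next_id
  }

  grafted <- integer(0)
  skipped <- integer(0)
  for (i in seq_len(nrow(taxa))) {
    gnode <- lookup(norm_name(taxa$genus[i]))
    if (is.na(gnode)) {
      fnode <- lookup(norm_name(taxa$family[i]))
      if (is.na(fnode)) {
        skipped <- c(skipped, i)
        next
      }
      gnode <- add_node(fnode, taxa$genus[i])
      node_key <- c(node_key, norm_name(taxa$genus[i]))
    }
    tip <- add_node(gnode, taxa$label[i])
    node_key <- c(node_key, "")               # tips never match as graft points
    grafted <- c(grafted, tip)
  }
  if (!length(grafted))
    stop("no taxon could be grafted: no family or genus matched the backbone")

  # keep grafted tips and their ancestors only: backbone tips that were not
  # grafted onto are never ancestors of a grafted tip and so are pruned,
  # along with every interior node left without grafted descendants
  keep <- rep(FALSE, nrow(tab))
  for (g in grafted) {
    cur <- g
    while (!is.na(cur) && !keep[cur]) {
      keep[cur] <- TRUE
      cur <- tab$parent[cur]
    }
  }
  sub <- tab[keep, , drop = FALSE]
  new_of <- integer(nrow(tab))
  new_of[sub$id] <- seq_len(nrow(sub))
  sub$parent <- ifelse(is.na(sub$parent), NA_integer_, new_of[sub$parent])
  sub$id <- seq_len(nrow(sub))
  # singleton chains (family -> sole genus -> sole tip) are retained: the
  # named interior nodes are calibration anchors for calibrate_bladj
  tab_validate(sub)
  out <- table_to_phylo(sub)
  skip_df <- taxa[skipped, , drop = FALSE]
  if (nrow(skip_df)) skip_df$reason <- "family not found in backbone"
  list(tree = out, skipped = skip_df)
}

new_calibrated_phylo <- function(phy, ages, dated) {
  structure(list(phy = phy, ages = ages, dated = dated),
            class = "calibrated_phylo")
}

#' @export
print.calibrated_phylo <- function(x, ...) {
  ntip <- length(x$phy$tip.label)
  cat("Calibrated phylogeny:", ntip, "tips,", x$phy$Nnode,
      "interior nodes\n")
  cat("Root age:", format(max(x$ages)), "Myr;", sum(x$dated),
      "dated (anchored) nodes\n")
  invisible(x)
}

#' Age-calibrate a tree by even spacing between dated nodes (bladj)
#'
#' Named interior nodes present in `ages` are fixed at their table age,
#' tips at age 0, and every undated interior node on a path between two
#' fixed-age nodes is placed so that successive ages along the path are
#' equally spaced: with `k` undated nodes between ages `a > b`, node `i`
#' (counting from the older end) receives `a - i * (a - b) / (k + 1)`.
#' Where an undated node has several nearest dated descendants, the
#' oldest resulting candidate age is used, which keeps every child
#' strictly younger than its parent. Branch lengths are set to the age
#' difference between parent and child.
#'
#' @param tree a `"phylo"` object (branch lengths, if any, are ignored).
#' @param ages named numeric vector of node ages in Myr (Phylocom ages
#'   file semantics, see [read_ages()]). Every name must occur in the
#'   tree.
#' @param root_age age of the root in Myr; required if the root is not
#'   named in `ages`.
#' @return a `"calibrated_phylo"` object: the tree with branch lengths,
#'   a numeric `ages` vector over all nodes (ape numbering), and a
#'   logical `dated` vector marking anchored nodes.
#' @export
calibrate_bladj <- function(tree, ages, root_age = NULL) {
  stopifnot(inherits(tree, "phylo"))
  validate_age_table(ages)
  tab <- phylo_to_table(tree)
  tab_validate(tab)
  n <- nrow(tab)
  kids <- tab_children(tab)
  is_tip <- vapply(kids, length, 1L) == 0L
  root <- tab_root(tab)

  key <- norm_name(tab$name)
  akey <- norm_name(names(ages))
  hit <- match(akey, key)
  if (anyNA(hit))
    stop("age table names not found in tree: ",
         paste(names(ages)[is.na(hit)], collapse = ", "))
  if (any(is_tip[hit]))
    stop("age table names must refer to interior nodes, not tips: ",
         paste(names(ages)[is_tip[hit]], collapse = ", "))

  fixed_age <- rep(NA_real_, n)
  fixed_age[is_tip] <- 0
  fixed_age[hit] <- unname(ages)
  if (is.na(fixed_age[root])) {
    if (is.null(root_age))
      stop("root is not named in the age table; supply root_age")
    if (root_age <= 0) stop("root_age must be positive")
    fixed_age[root] <- root_age
  }
  fixed <- !is.na(fixed_age)
  age <- bladj_ages(tab, fixed_age)

  nonroot <- which(!is.na(tab$parent))
  blen <- age[tab$parent[nonroot]] - age[nonroot]
  if (any(blen < 0))
    stop("internal error: negative branch length after calibration")
  tab$length[nonroot] <- blen
  phy <- table_to_phylo(tab)
  # table_to_phylo renumbers; recompute age/dated in the new numbering
  reorder_map <- match_node_identity(tab, phy)
  dated <- fixed
  dated[is_tip] <- FALSE            # tips are trivially at age 0, not anchors
  new_calibrated_phylo(phy, age[reorder_map], dated[reorder_map])
}

# Core bladj even-spacing: `fixed_age` is a numeric vector over tab ids
# (NA = free node). Every free node on a path between two fixed-age
# nodes is spaced evenly; a node with several nearest fixed descendants
# takes the oldest candidate, which keeps children strictly younger than
# parents. Errors on any fixed node at or above the age of its nearest
# fixed ancestor.
bladj_ages <- function(tab, fixed_age) {
  n <- nrow(tab)
  kids <- tab_children(tab)
  root <- tab_root(tab)
  fixed <- !is.na(fixed_age)
  if (!fixed[root]) stop("root must have a fixed age")
  age <- fixed_age

  for (i in which(fixed)) {
    if (i == root) next
    cur <- tab$parent[i]
    while (!is.na(cur) && !fixed[cur]) cur <- tab$parent[cur]
    if (!is.na(cur) && age[i] >= age[cur])
      stop("calibration conflict: node '",
           ifelse(nzchar(tab$name[i]), tab$name[i], i),
           "' (age ", age[i], ") is not younger than its dated ancestor '",
           ifelse(nzchar(tab$name[cur]), tab$name[cur], cur),
           "' (age ", age[cur], ")")
  }

  # nearest fixed ancestor and its distance in edges, per free node
  up_anc <- rep(NA_integer_, n)
  up_steps <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (fixed[i]) next
    cur <- tab$parent[i]
    steps <- 1L
    while (!fixed[cur]) {
      cur <- tab$parent[cur]
      steps <- steps + 1L
    }
    up_anc[i] <- cur
    up_steps[i] <- steps
  }

  # nearest fixed descendants (no fixed node strictly between), by DFS
  nearest_fixed_below <- function(u) {
    out_age <- numeric(0)
    out_steps <- integer(0)
    stack_id <- kids[[u]]
    stack_st <- rep(1L, length(stack_id))
    while (length(stack_id)) {
      k <- length(stack_id)
      v <- stack_id[k]; s <- stack_st[k]
      stack_id <- stack_id[-k]; stack_st <- stack_st[-k]
      if (fixed[v]) {
        out_age <- c(out_age, age[v])
        out_steps <- c(out_steps, s)
      } else {
        ch <- kids[[v]]
        stack_id <- c(stack_id, ch)
        stack_st <- c(stack_st, rep(s + 1L, length(ch)))
      }
    }
    list(age = out_age, steps = out_steps)
  }

  for (u in which(!fixed)) {
    a <- age[up_anc[u]]
    n1 <- up_steps[u]
    below <- nearest_fixed_below(u)
    cand <- below$age + (a - below$age) *
      (below$steps / (n1 + below$steps))
    age[u] <- max(cand)
  }
  age
}

# Map ape node numbers of `phy` (built from `tab`) back to table ids.
# table_to_phylo assigns tips 1..n in table order and interior nodes in
# preorder; reproduce that mapping here.
match_node_identity <- function(tab, phy) {
  kids <- tab_children(tab)
  nk <- vapply(kids, length, 1L)
  tips <- tab$id[nk == 0L]
  root <- tab_root(tab)
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
  c(tips, interior)
}

#' Treat an ultrametric phylogram as a calibrated tree
#'
#' Derives node ages from root-to-node path lengths of an ultrametric
#' tree (all tips equidistant from the root), e.g. a coalescent tree from
#' [ape::rcoal()]. Named interior nodes are marked as dated anchors.
#'
#' @param phy an ultrametric `"phylo"` with branch lengths.
#' @param tol tolerance for the ultrametricity check (relative).
#' @return a `"calibrated_phylo"` object.
#' @export
as_calibrated <- function(phy, tol = 1e-8) {
  stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  depth <- ape::node.depth.edgelength(phy)
  ntip <- length(phy$tip.label)
  tip_depth <- depth[seq_len(ntip)]
  h <- max(tip_depth)
  if (h <= 0) stop("tree has zero height")
  if (max(abs(tip_depth - h)) > tol * h)
    stop("tree is not ultrametric")
  age <- h - depth
  age[seq_len(ntip)] <- 0
  dated <- rep(FALSE, length(age))
  if (!is.null(phy$node.label))
    dated[ntip + which(nzchar(phy$node.label))] <- TRUE
  new_calibrated_phylo(phy, age, dated)
}

#' Randomly resolve polytomies and recalibrate
#'
#' Every multifurcation is resolved into a series of dichotomies by
#' sequential random pairing: while a node has more than two children,
#' two are chosen uniformly at random and joined under a new unnamed
#' node. For a trifurcation each of the three rooted resolutions occurs
#' with probability 1/3. Newly created nodes are undated and receive
#' ages by the bladj even-spacing rule with every pre-existing node
#' anchored at its current age, so tip-to-tip distances change only for
#' pairs whose most recent common ancestor lay inside a former
#' polytomy. Singleton (one-child) interior nodes are collapsed, which
#' leaves path distances unchanged, so the result is strictly
#' bifurcating.
#'
#' @param tree a `"calibrated_phylo"` from [calibrate_bladj()] or
#'   [as_calibrated()].
#' @param seed integer seed; mandatory for reproducibility of replicated
#'   sensitivity analyses. Equal seeds give identical output.
#' @return a strictly bifurcating `"calibrated_phylo"`.
#' @export
resolve_polytomies <- function(tree, seed) {
  stopifnot(inherits(tree, "calibrated_phylo"))
  if (missing(seed)) stop("seed is mandatory")
  tab <- phylo_to_table(tree$phy)
  ntab <- nrow(tab)
  fixed_age <- tree$ages             # anchor every original node

  set.seed(as.integer(seed) %% .Machine$integer.max)
  kids <- tab_children(tab)
  next_id <- ntab
  for (u in seq_len(ntab)) {
    ch <- kids[[u]]
    while (length(ch) > 2L) {
      pick <- sample(seq_along(ch), 2L)
      next_id <- next_id + 1L
      tab[next_id, ] <- list(next_id, u, "", NA_real_)
      fixed_age[next_id] <- NA_real_
      tab$parent[ch[pick]] <- next_id
      ch <- c(ch[-pick], next_id)
    }
  }
  age <- bladj_ages(tab, fixed_age)
  nonroot <- which(!is.na(tab$parent))
  tab$length[nonroot] <- age[tab$parent[nonroot]] - age[nonroot]
  phy <- table_to_phylo(tab)
  remap <- match_node_identity(tab, phy)
  dated <- c(tree$dated, rep(FALSE, nrow(tab) - ntab))
  out <- new_calibrated_phylo(phy, age[remap], dated[remap])
  collapse_singletons(out)
}

# Remove single-child interior nodes from a calibrated tree (path
# distances are unchanged; ages of remaining nodes are preserved), so
# that a fully resolved tree has exactly n_tips - 1 interior nodes.
collapse_singletons <- function(ct) {
  tab <- phylo_to_table(ct$phy)
  age <- ct$ages
  dated <- ct$dated
  repeat {
    kids <- tab_children(tab)
    nk <- vapply(kids, length, 1L)
    present <- !is.na(tab$parent) | tab$id == tab_root(tab)
    single <- which(nk == 1L)
    single <- single[single %in% tab$id[present]]
    if (!length(single)) break
    for (u in single) {
      ch <- tab_children(tab)[[u]]
      if (length(ch) != 1L) next
      if (is.na(tab$parent[u])) {
        tab$parent[ch] <- NA_integer_    # singleton root: child becomes root
      } else {
        tab$parent[ch] <- tab$parent[u]
      }
      tab <- tab[tab$id != u, , drop = FALSE]
      # renumber
      new_of <- integer(max(tab$id, u))
      new_of[tab$id] <- seq_len(nrow(tab))
      tab$parent <- ifelse(is.na(tab$parent), NA_integer_,
                           new_of[tab$parent])
      age <- age[-u]
      dated <- dated[-u]
      tab$id <- seq_len(nrow(tab))
      break                              # recompute children lists
    }
  }
  nonroot <- which(!is.na(tab$parent))
  tab$length[nonroot] <- age[tab$parent[nonroot]] - age[nonroot]
  phy <- table_to_phylo(tab)
  remap <- match_node_identity(tab, phy)
  new_calibrated_phylo(phy, age[remap], dated[remap])
}

#' Tip-to-tip cophenetic distance matrix
#'
#' Path distances (sums of branch lengths) between all tip pairs. For a
#' calibrated ultrametric tree each entry equals twice the age of the
#' pair's most recent common ancestor.
#'
#' @param tree a `"calibrated_phylo"` or a `"phylo"` with branch lengths.
#' @return a symmetric numeric matrix with tip labels as dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  if (inherits(tree, "calibrated_phylo")) tree <- tree$phy
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ntip <- length(tree$tip.label)
  d <- ape::dist.nodes(tree)[seq_len(ntip), seq_len(ntip), drop = FALSE]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}
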