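#' Read a taxon list
#'
#' CSV with columns `family,genus,species,site`, one row per species-site
#' pair.  Tip labels are formed as `Genus_species@site` and must be unique.
#'
#' @param file path to the CSV.
#' @return a data frame with the four columns plus `label`.
#' @export
read_taxa <- function(file) {
  tx <- read.csv(file, stringsAsFactors = FALSE)
  validate_taxa(tx)
}

#' @keywords internal
validate_taxa <- function(taxa) {
  need <- c("family", "genus", "species", "site")
  miss <- setdiff(need, names(taxa))
  if (length(miss)) stopf("taxon table lacks columns: %s", paste(miss, collapse = ", "))
  taxa[need] <- lapply(taxa[need], function(v) trimws(as.character(v)))
  if (any(!nzchar(taxa$family))) stopf("empty family names in taxon table")
  taxa$label <- paste0(taxa$genus, "_", taxa$species, "@", taxa$site)
  if (anyDuplicated(taxa$label))
    stopf("duplicate species-site records: %s",
          paste(unique(taxa$label[duplicated(taxa$label)]), collapse = ", "))
  taxa
}

#' Read a node-age table
#'
#' Whitespace-delimited two-column file, `name age`, ages in Myr
#' (the format used by even-spacing dating tools).
#'
#' @param file path.
#' @return named numeric vector of ages.
#' @export
read_ages <- function(file) {
  tab <- read.table(file, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("name", "age"))
  ages <- setNames(as.numeric(tab$age), tab$name)
  if (anyNA(ages) || any(ages <= 0)) stopf("node ages must be positive numbers")
  if (anyDuplicated(names(ages))) stopf("duplicate node names in age table")
  ages
}

escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

#' Graft a species-site taxon list onto a family-level backbone
#'
#' Emulates taxonomy-based supertree grafting: each sampled family on the
#' backbone is expanded into a polytomy of its genera, each genus into a
#' polytomy of its species, and each species found at several sites into a
#' polytomy of `Genus_species@site` tips.  Backbone families with no
#' sampled taxa are pruned, and unary nodes left by pruning or by
#' single-member clades are suppressed.  The result is topology-only
#' (branch lengths are assigned afterwards by [smooth_ages()]).
#'
#' @param backbone a `"phylo"` object whose tips (or named internal nodes)
#'   are family names.
#' @param taxa a taxon table as returned by [read_taxa()], or any data
#'   frame with columns `family,genus,species,site`.
#' @return a `"phylo"` object without branch lengths whose tips are the
#'   taxon labels; the names of multi-site species nodes are recorded in
#'   `attr(, "species_nodes")` for the epsilon-branch policy of
#'   [smooth_ages()].
#' @export
graft_taxa <- function(backbone, taxa) {
  if (!inherits(backbone, "phylo")) stopf("backbone must be a \"phylo\" object")
  taxa <- validate_taxa(taxa)
  fams <- unique(taxa$family)
  known <- c(backbone$tip.label, backbone$node.label %||% character())
  missing <- setdiff(fams, known)
  if (length(missing))
    stopf("unplaced taxa: families absent from backbone: %s",
          paste(missing, collapse = ", "))

  bb <- backbone
  bb$edge.length <- NULL
  drop <- setdiff(bb$tip.label, fams)
  if (length(drop)) {
    keep <- setdiff(bb$tip.label, drop)
    if (length(keep) >= 2L) {
      bb <- ape::drop.tip(bb, drop, collapse.singles = FALSE)
    } else if (length(keep) == 1L && all(fams %in% keep)) {
      # whole analysis collapses into one family: synthesize from scratch
      s <- family_subtree(keep, taxa[taxa$family == keep, , drop = FALSE])
      return(finish_graft(paste0(s, ";"), taxa))
    } else {
      stopf("pruning backbone would lose grafting points for: %s",
            paste(setdiff(fams, keep), collapse = ", "))
    }
    lost <- setdiff(fams, c(bb$tip.label, bb$node.label %||% character()))
    if (length(lost))
      stopf("families lost while pruning backbone (internal family nodes need a sampled descendant): %s",
            paste(lost, collapse = ", "))
  }

  nwk <- ape::write.tree(bb)
  for (f in fams) {
    rows <- taxa[taxa$family == f, , drop = FALSE]
    s <- family_subtree(f, rows)
    esc <- escape_regex(f)
    tip_pat <- paste0("(?<=[(,])", esc, "(?=[,)])")
    int_pat <- paste0("\\)", esc, "(?=[,);])")
    if (grepl(tip_pat, nwk, perl = TRUE)) {
      nwk <- sub(tip_pat, s, nwk, perl = TRUE)
    } else if (grepl(int_pat, nwk, perl = TRUE)) {
      # family is an internal node: add sampled members as extra children
      children <- if (startsWith(s, "(") && endsWith(s, f))
        substr(s, 2L, nchar(s) - nchar(f) - 1L) else s
      nwk <- sub(int_pat, paste0(",", children, ")", f), nwk, perl = TRUE)
    } else {
      stopf("could not locate family '%s' in backbone Newick", f)
    }
  }
  finish_graft(nwk, taxa)
}

#' @keywords internal
family_subtree <- function(fam, rows) {
  species_sub <- function(g, s) {
    sites <- rows$site[rows$genus == g & rows$species == s]
    labs <- paste0(g, "_", s, "@", sites)
    if (length(labs) == 1L) labs
    else paste0("(", paste(labs, collapse = ","), ")", g, "_", s)
  }
  genus_sub <- function(g) {
    sps <- unique(rows$species[rows$genus == g])
    subs <- vapply(sps, function(s) species_sub(g, s), character(1))
    if (length(subs) == 1L) subs
    else paste0("(", paste(subs, collapse = ","), ")", g)
  }
  gens <- unique(rows$genus)
  subs <- vapply(gens, genus_sub, character(1))
  if (length(subs) == 1L) subs
  else paste0("(", paste(subs, collapse = ","), ")", fam)
}

#' @keywords internal
finish_graft <- function(nwk, taxa) {
  tr <- ape::read.tree(text = nwk)
  if (is.null(tr)) stopf("internal error: grafted Newick failed to parse")
  tr <- ape::collapse.singles(tr)
  stopifnot(setequal(tr$tip.label, taxa$label),
            ape::Ntip(tr) == nrow(taxa))
  multi <- taxa[duplicated(paste(taxa$genus, taxa$species)), ]
  sp_nodes <- unique(paste0(multi$genus, "_", multi$species))
  attr(tr, "species_nodes") <- intersect(sp_nodes, tr$node.label %||% character())
  tr
}

#' Date a tree by spacing undated nodes evenly between dated ones
#'
#' Assigns every internal node an age: nodes named in `ages` get exactly
#' their table age, tips sit at age 0, and each undated node is placed by
#' even spacing along the chains connecting its nearest dated ancestor to
#' its nearest dated (or tip) descendants.  When several such chains give
#' different candidate ages the maximum is taken, which keeps branches
#' toward older dated descendants non-negative; strict parent-older-than-
#' child monotonicity is verified afterwards.  Branch lengths are then
#' parent age minus child age, yielding an ultrametric tree.
#'
#' Multi-site species nodes (from [graft_taxa()], or passed via
#' `pin_nodes`) are pinned at a small positive age
#' `epsilon_frac * root age` so that duplicate species-site tips get short
#' but non-zero terminal branches and the phylogenetic covariance matrix
#' stays non-singular at lambda = 1.
#'
#' @param tree a `"phylo"` object (branch lengths, if any, are ignored).
#' @param ages named numeric vector of node ages (Myr); must include the
#'   root's name.
#' @param epsilon_frac fraction of the root age used for pinned species
#'   nodes (default `1e-6`).
#' @param pin_nodes node names to pin at the epsilon age; defaults to
#'   `attr(tree, "species_nodes")`.
#' @return an ultrametric `"phylo"` object with branch lengths in Myr.
#' @export
smooth_ages <- function(tree, ages, epsilon_frac = 1e-6, pin_nodes = NULL) {
  if (!inherits(tree, "phylo")) stopf("not a \"phylo\" object")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  nlab <- tree$node.label %||% rep("", nnode)
  root <- ntip + 1L
  root_name <- nlab[1L]
  if (!nzchar(root_name) || !(root_name %in% names(ages)))
    stopf("root age missing: the root node must be named and present in the age table")

  ntot <- ntip + nnode
  age <- rep(NA_real_, ntot)
  dated <- logical(ntot)
  age[seq_len(ntip)] <- 0
  dated[seq_len(ntip)] <- TRUE
  idx <- match(nlab, names(ages))
  has <- !is.na(idx)
  age[ntip + which(has)] <- ages[idx[has]]
  dated[ntip + which(has)] <- TRUE

  root_age <- age[root]
  pin <- pin_nodes %||% attr(tree, "species_nodes") %||% character()
  if (length(pin)) {
    pi <- ntip + which(nlab %in% pin & !has)
    age[pi] <- epsilon_frac * root_age
    dated[pi] <- TRUE
  }

  parent <- integer(ntot)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  node_name <- function(v) {
    ifelse(v <= ntip, tree$tip.label[v],
           ifelse(nzchar(nlab[v - ntip]), nlab[v - ntip], paste0("#", v)))
  }

  # preorder so a parent's nearest dated ancestor is known before its kids
  preord <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    preord <- c(preord, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  nda <- integer(ntot)  # nearest dated strict ancestor
  nda[root] <- root
  for (v in preord[-1L]) nda[v] <- if (dated[parent[v]]) parent[v] else nda[parent[v]]

  # dated-node consistency: a dated node must be younger than its nearest
  # dated ancestor
  for (v in which(dated & seq_len(ntot) != root)) {
    a <- nda[v]
    if (age[a] <= age[v])
      stopf("age inversion among dated nodes: '%s' (%.6g) is not older than descendant '%s' (%.6g)",
            node_name(a), age[a], node_name(v), age[v])
  }

  for (u in which(!dated)) {
    a <- nda[u]
    # dated boundary descendants reachable from u without crossing a dated node
    bnd <- integer(0)
    stack <- kids[[as.character(u)]]
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (dated[v]) bnd <- c(bnd, v)
      else stack <- c(stack, kids[[as.character(v)]])
    }
    cand <- vapply(bnd, function(d) {
      path <- integer(0)  # undated nodes strictly between a and d
      v <- parent[d]
      while (v != a) { path <- c(path, v); v <- parent[v] }
      m <- length(path)
      i <- m + 1L - which(path == u)  # position counting down from the ancestor
      age[a] - i * (age[a] - age[d]) / (m + 1)
    }, numeric(1))
    age[u] <- max(cand)
  }

  bad <- which(age[parent[-root]] <= age[-root])
  if (length(bad)) {
    v <- (seq_len(ntot)[-root])[bad[1L]]
    stopf("internal consistency error: node '%s' not strictly older than '%s' after dating",
          node_name(parent[v]), node_name(v))
  }

  out <- tree
  out$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  attr(out, "species_nodes") <- attr(tree, "species_nodes")
  attr(out, "node_ages") <- age
  out
}
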