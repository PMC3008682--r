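#' Read a phylogeny from a Newick string or file
#'
#' Thin, validating wrapper around [ape::read.tree()].  Square-bracket
#' comments are stripped, quoted labels are supported, and internal-node
#' labels (including bare support-like numbers) are preserved verbatim so
#' that node-age tables can key on them.  Edges without a stated branch
#' length receive length 1 with a warning.
#'
#' @param text a Newick string (must end in `;`), or `NULL` if `file` given.
#' @param file path to a Newick file (`.nwk`/`.tre`).
#' @return an object of class `"phylo"` (rooted, lengths in Myr by
#'   convention).
#' @examples
#' tr <- read_newick("((A:1,B:1)n1:1,C:2)root;")
#' tr$node.label
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stopf("one of 'text' or 'file' is required")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- gsub("\\[[^][]*\\]", "", text)  # strip [...] comments
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    chars <- strsplit(text, "", fixed = TRUE)[[1L]]
    depth <- cumsum((chars == "(") - (chars == ")"))
    off <- if (any(depth < 0)) which(depth < 0)[1L] else nchar(text)
    stopf("unbalanced parentheses in Newick string (near character %d)", off)
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stopf("could not parse Newick string")
  if (inherits(tr, "multiPhylo")) stopf("expected a single tree, got %d", length(tr))
  unquote <- function(l) sub("^'(.*)'$", "\\1", l)
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate tip labels: %s",
          paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) {
    warnf("tree has no branch lengths; defaulting all to 1")
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warnf("%d edges lack branch lengths; defaulting them to 1",
          sum(is.na(tr$edge.length)))
    tr$edge.length[is.na(tr$edge.length)] <- 1
  }
  validate_phylo(tr)
  tr
}

#' Write a phylogeny as a Newick string
#'
#' Inverse of [read_newick()]: `read_newick(write_newick(tr))` is
#' isomorphic to `tr` with branch lengths preserved to at least 6 decimals.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; when given the string is also written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylo(tree)
  s <- ape::write.tree(tree, digits = 10)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks: class, at least 2 tips, unique tip labels, finite non-negative
#' branch lengths, and a single root (as guaranteed by the `phylo` edge
#' matrix for rooted trees).
#'
#' @param tree a `"phylo"` object.
#' @return `tree`, invisibly.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a \"phylo\" object")
  if (ape::Ntip(tree) < 2L) stopf("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!is.null(tree$edge.length)) {
    if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
      stopf("non-finite branch lengths")
    if (any(tree$edge.length < 0)) stopf("negative branch lengths")
  }
  # one root, every other node exactly one parent (polytomies are fine,
  # including a basal one, which ape::is.rooted would reject)
  ntot <- ape::Ntip(tree) + tree$Nnode
  n_par <- tabulate(tree$edge[, 2L], ntot)
  root <- which(n_par == 0L)
  if (length(root) != 1L || any(n_par > 1L))
    stopf("tree must have exactly one root and a single parent per node")
  invisible(tree)
}

#' Phylogenetic variance-covariance matrix
#'
#' Tip-to-tip covariance expected under Brownian motion: entry (i, j) is
#' the shared root-to-MRCA path length, the diagonal the root-to-tip
#' distance.  This is the GLS covariance structure V (also written C).
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param tip_order optional character vector of tip labels giving the row
#'   and column order; defaults to `tree$tip.label`.
#' @return a symmetric numeric matrix with dimnames `tip_order`.
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree, tip_order = NULL) {
  validate_phylo(tree)
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  V <- ape::vcv.phylo(tree)
  if (!is.null(tip_order)) {
    missing <- setdiff(tip_order, rownames(V))
    if (length(missing))
      stopf("labels not in tree: %s", paste(missing, collapse = ", "))
    V <- V[tip_order, tip_order, drop = FALSE]
  }
  V
}

#' Root-to-tip distances
#' @keywords internal
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Test whether a tree is ultrametric
#'
#' True when the spread of root-to-tip distances is at most
#' `rel_tol` times the maximum depth (all extant tips contemporaneous).
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param rel_tol relative tolerance (default `1e-6`).
#' @return logical scalar.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_phylo(tree)
  d <- tip_depths(tree)
  (max(d) - min(d)) <= rel_tol * max(d)
}
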