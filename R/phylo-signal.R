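#' Resolve polytomies to a seeded arbitrary bifurcation
#'
#' Contrast computation needs a binary tree; polytomies are resolved in a
#' random but seeded order with zero-length internal branches, which
#' leaves the implied covariance structure unchanged.
#'
#' @keywords internal
resolve_polytomies <- function(tree, seed = NULL) {
  if (ape::is.binary(tree)) return(tree)
  with_seed(seed, ape::multi2di(tree, random = TRUE))
}

#' Precompile a pruning schedule for repeated contrast evaluation
#'
#' Returns the postorder node traversal of a binary tree so that contrasts
#' for many trait vectors (e.g. permutations) reuse one schedule.
#' @keywords internal
pic_schedule <- function(tree) {
  stopifnot(ape::is.binary(tree))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  e <- tr$edge
  len <- tr$edge.length
  # postorder edges come in sibling pairs per internal node
  parents <- e[seq(1L, nrow(e), by = 2L), 1L]
  left <- e[seq(1L, nrow(e), by = 2L), 2L]
  right <- e[seq(2L, nrow(e), by = 2L), 2L]
  stopifnot(all(parents == e[seq(2L, nrow(e), by = 2L), 1L]))
  list(ntip = ntip, n_int = tr$Nnode, parents = parents,
       left = left, right = right,
       bl_left = len[seq(1L, nrow(e), by = 2L)],
       bl_right = len[seq(2L, nrow(e), by = 2L)],
       tip_label = tr$tip.label)
}

#' @keywords internal
pic_engine <- function(sched, x) {
  ntot <- sched$ntip + sched$n_int
  val <- numeric(ntot)
  bl <- numeric(ntot)
  val[seq_len(sched$ntip)] <- x
  contrasts <- numeric(sched$n_int)
  for (k in seq_len(sched$n_int)) {
    l <- sched$left[k]; r <- sched$right[k]
    bl_l <- sched$bl_left[k] + bl[l]
    bl_r <- sched$bl_right[k] + bl[r]
    s <- bl_l + bl_r
    if (s <= 0)
      stopf("zero summed branch length at an internal node: contrasts cannot be standardized (apply the epsilon terminal-branch policy)")
    contrasts[k] <- (val[l] - val[r]) / sqrt(s)
    p <- sched$parents[k]
    val[p] <- (bl_r * val[l] + bl_l * val[r]) / s
    bl[p] <- bl_l * bl_r / s
  }
  contrasts
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning recursion: at each internal node of a binary tree
#' the contrast is the difference between daughter values divided by the
#' square root of the summed (extended) daughter branch lengths; the
#' node's value is the branch-length-weighted average of its daughters and
#' its own stem branch is lengthened by the product-over-sum of the
#' daughter branches.  Polytomies are first resolved to a seeded arbitrary
#' bifurcation with zero-length branches.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param x named numeric vector of tip values (names must match the
#'   tree's tips; the tree is pruned to `names(x)`).
#' @param seed seed for the polytomy resolution (only used when the tree
#'   is not binary).
#' @return numeric vector of `n - 1` standardized contrasts.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' independent_contrasts(tr, c(A = 1, B = 3, C = 0))
#' @export
independent_contrasts <- function(tree, x, seed = NULL) {
  prep <- align_trait(tree, x)
  if (prep$n < 2L) stopf("need at least 2 tips with trait values")
  tr <- resolve_polytomies(prep$tree, seed)
  sched <- pic_schedule(tr)
  pic_engine(sched, prep$x[sched$tip_label])
}

#' Match a trait vector to a tree, pruning missing tips
#' @keywords internal
align_trait <- function(tree, x) {
  validate_phylo(tree)
  if (is.null(names(x))) {
    if (length(x) != ape::Ntip(tree))
      stopf("unnamed trait vector must have one value per tip")
    names(x) <- tree$tip.label
  }
  x <- x[!is.na(x)]
  unknown <- setdiff(names(x), tree$tip.label)
  if (length(unknown))
    stopf("trait labels not in tree: %s", paste(head(unknown, 5L), collapse = ", "))
  keep <- intersect(tree$tip.label, names(x))
  tr <- if (length(keep) < ape::Ntip(tree)) ape::keep.tip(tree, keep) else tree
  list(tree = tr, x = x[tr$tip.label], n = length(keep))
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' Compares the observed ratio of the trait's cross-species mean squared
#' error to its phylogenetically corrected mean squared error against the
#' ratio expected under Brownian motion on the same tree.  With
#' phylogenetic covariance matrix `V`, phylogenetic mean
#' `a = (1'V^-1 x)/(1'V^-1 1)`, `MSE0 = (x-a)'(x-a)/(n-1)` and
#' `MSE = (x-a)'V^-1(x-a)/(n-1)`, the statistic is
#' `K = (MSE0/MSE) / [(tr(V) - n/(1'V^-1 1))/(n-1)]`.
#' `K = 1` is expected under Brownian motion; larger values mean more
#' similarity among relatives than Brownian motion predicts.
#'
#' @inheritParams independent_contrasts
#' @return the K statistic (non-negative scalar).
#' @export
blomberg_k <- function(tree, x) {
  prep <- align_trait(tree, x)
  if (prep$n < 3L) stopf("need at least 3 tips with trait values")
  x <- prep$x
  if (var(x) == 0) stopf("trait has zero variance: K undefined")
  V <- phylo_vcv(prep$tree)
  n <- length(x)
  U <- tryCatch(chol(V), error = function(e)
    stopf("phylogenetic covariance matrix is singular: %s", conditionMessage(e)))
  Vi <- chol2inv(U)
  one <- rep(1, n)
  s_vi <- sum(Vi)
  a_hat <- sum(Vi %*% x) / s_vi
  d <- x - a_hat
  mse0 <- sum(d^2) / (n - 1)
  mse <- drop(crossprod(d, Vi %*% d)) / (n - 1)
  expected <- (sum(diag(V)) - n / s_vi) / (n - 1)
  (mse0 / mse) / expected
}

#' Tip-shuffling permutation test of phylogenetic signal
#'
#' The observed statistic is the variance of the standardized independent
#' contrasts; low variance means relatives have similar values, i.e.
#' signal.  The null distribution comes from `n_perm` random shuffles of
#' the trait values across the tips (the tree is held fixed), and the
#' one-tailed P-value uses the add-one convention
#' `P = (1 + #(null <= observed)) / (1 + n_perm)`, so the attainable floor
#' with 999 shuffles is 0.001.  Blomberg's K is reported alongside as the
#' effect-size measure.
#'
#' @inheritParams independent_contrasts
#' @param n_perm number of tip shuffles (default 999).
#' @param seed integer seed (mandatory for reproducibility).
#' @param trait_name optional label carried into the result.
#' @return an object of class `"signal_test"`: list with `trait`, `K`,
#'   `P`, `obs_variance`, `n`, `n_perm`, `seed`.
#' @export
signal_test <- function(tree, x, n_perm = 999L, seed, trait_name = NULL) {
  if (missing(seed)) stopf("'seed' is required")
  if (!is.numeric(n_perm) || n_perm < 1L) stopf("'n_perm' must be >= 1")
  n_perm <- as.integer(n_perm)
  prep <- align_trait(tree, x)
  if (prep$n < 3L) stopf("need at least 3 tips with trait values")
  K <- blomberg_k(prep$tree, prep$x)
  res <- with_seed(seed, {
    tr <- resolve_polytomies(prep$tree, seed = NULL)  # inside seeded stream
    sched <- pic_schedule(tr)
    xv <- prep$x[sched$tip_label]
    obs <- var(pic_engine(sched, xv))
    null <- vapply(seq_len(n_perm),
                   function(i) var(pic_engine(sched, sample(xv))),
                   numeric(1))
    list(obs = obs, p = (1 + sum(null <= obs)) / (1 + n_perm))
  })
  structure(list(trait = trait_name %||% deparse(substitute(x)),
                 K = K, P = res$p, obs_variance = res$obs,
                 n = prep$n, n_perm = n_perm, seed = seed),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat("Phylogenetic signal (tip-shuffling permutation test)\n")
  cat(sprintf("  trait: %s   n = %d tips\n", x$trait, x$n))
  cat(sprintf("  Blomberg's K = %.4g\n", x$K))
  cat(sprintf("  contrast variance = %.4g\n", x$obs_variance))
  cat(sprintf("  P = %.4g  (%d shuffles, add-one rule; floor %.4g)\n",
              x$P, x$n_perm, 1 / (x$n_perm + 1)))
  invisible(x)
}
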