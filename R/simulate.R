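#' Simulate a pure-birth ultrametric tree
#'
#' Seeded pure-birth (Yule) tree rescaled so the root sits at the
#' requested age; a simple stand-in for a dated supertree when testing the
#' pipeline.
#'
#' @param n_tips number of tips (>= 2).
#' @param age root age in Myr (default 100).
#' @param seed integer seed (mandatory: generators have no implicit
#'   entropy).
#' @param labels optional tip labels (length `n_tips`).
#' @return an ultrametric `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, age = 100, seed, labels = NULL) {
  if (missing(seed)) stopf("'seed' is required")
  if (n_tips < 2L) stopf("need at least 2 tips")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(tip_depths(tr))
  tr$edge.length <- tr$edge.length * (age / depth)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n_tips)
    tr$tip.label <- labels
  }
  tr
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Realized by branch-wise independent Gaussian increments with variance
#' `sigma2 * branch length`, walking from the root to the tips, so tip
#' values are multivariate normal with mean `root_state` and covariance
#' `sigma2 * phylo_vcv(tree)`.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param sigma2 Brownian rate (variance per Myr).
#' @param root_state trait value at the root.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, root_state = 0, seed) {
  if (missing(seed)) stopf("'seed' is required")
  if (sigma2 < 0) stopf("'sigma2' must be >= 0")
  validate_phylo(tree)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  with_seed(seed, {
    val <- numeric(ntot)
    val[ntip + 1L] <- root_state
    # cladewise order guarantees parents are visited before children
    tr <- ape::reorder.phylo(tree, "cladewise")
    inc <- rnorm(nrow(tr$edge), 0, sqrt(sigma2 * tr$edge.length))
    for (k in seq_len(nrow(tr$edge)))
      val[tr$edge[k, 2L]] <- val[tr$edge[k, 1L]] + inc[k]
    setNames(val[seq_len(ntip)], tree$tip.label)
  })
}

#' Simulate a lambda-structured trait on a tree
#'
#' Multivariate normal draw with covariance
#' `sigma2 * lambda_transform(phylo_vcv(tree), lambda)`: `lambda = 1` is
#' distributionally identical to Brownian motion, `lambda = 0` gives
#' independent tips with their Brownian variances.
#'
#' @inheritParams simulate_bm_trait
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @return named numeric vector of tip values.
#' @export
simulate_lambda_trait <- function(tree, lambda, sigma2 = 1, root_state = 0, seed) {
  if (missing(seed)) stopf("'seed' is required")
  validate_phylo(tree)
  Cl <- lambda_transform(phylo_vcv(tree), lambda)
  L <- t(chol(Cl))
  with_seed(seed, {
    z <- rnorm(nrow(Cl))
    setNames(root_state + sqrt(sigma2) * drop(L %*% z), rownames(Cl))
  })
}

#' Default generative settings for the 20 continuous leaf traits
#'
#' Per-trait intercept `a` and slope `b` (on the log10 trait vs log10 MAT
#' scale), residual Pagel's lambda, residual standard deviation, and
#' whether the trait is a tooth measurement (defined only on rows with
#' toothed specimens).  Values chosen to resemble published
#' leaf-physiognomy calibration data for eastern North America plus one
#' tropical site.
#'
#' @return data frame with columns `name`, `a`, `b`, `lambda`, `sigma`,
#'   `tooth`.
#' @export
default_trait_specs <- function() {
  d <- data.frame(
    name = c("Blade area", "Perimeter", "Internal perimeter",
             "Perimeter ratio", "Compactness", "Shape factor",
             "Major axis length", "Minor axis length", "Feret diameter",
             "Feret diameter ratio", "Tooth area", "Tooth area : blade area",
             "Tooth area : perimeter", "Tooth area : internal perimeter",
             "Number of primary teeth", "Number of secondary teeth",
             "Number of teeth", "Average tooth area",
             "Number of teeth : perimeter",
             "Number of teeth : internal perimeter"),
    a = c(2.11, 1.84, 1.78, 0.12, 1.61, -0.51, 1.27, 1.10, 1.10, -0.18,
          0.66, -1.59, -1.31, -1.19, 1.59, 1.14, 1.65, -1.00, -0.22, -0.11),
    b = c(-0.38, -0.27, -0.25, -0.06, -0.19, 0.18, -0.17, -0.26, -0.19,
          -0.01, -0.54, -0.02, -0.18, -0.24, -0.39, -0.56, -0.43, -0.09,
          -0.15, -0.21),
    lambda = c(0.94, 0.91, 0.85, 0.89, 0.77, 0.77, 0.93, 0.97, 0.94, 0.99,
               0.97, 1.00, 1.00, 1.00, 1.00, 0.94, 1.00, 1.00, 1.00, 1.00),
    sigma = 0.3,
    tooth = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
              FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
              TRUE),
    stringsAsFactors = FALSE)
  d
}

#' Build a community-simulation specification
#'
#' Defaults emulate the structure of the empirical calibration dataset the
#' package is designed for: 17 sites spanning mean annual temperatures of
#' 5.6-25.8 degrees C, a species-rich tropical site at the warm end, and
#' 569 species-site pairs in total (413 after removing the tropical site).
#' Species are drawn from a seeded pure-birth species pool; site
#' membership follows a Brownian "temperature preference" trait so that
#' MAT, viewed as a species trait, carries phylogenetic signal; continuous
#' traits are linear in log10 MAT with lambda-structured residuals; margin
#' state comes from a Brownian liability thresholded at a quantile, with a
#' configurable (default zero) direct MAT effect.
#'
#' @param seed integer seed (mandatory).
#' @param n_species size of the species pool.
#' @param n_sites number of sites.
#' @param mat_range increasing length-2 vector of site MAT limits (deg C).
#' @param site_quotas species-site pairs per site, coolest to warmest
#'   (must have length `n_sites`).
#' @param site_fidelity per-site expected number of sites shared by that
#'   site's typical species (length `n_sites`): 1 means an essentially
#'   endemic flora (the default for the warmest, tropical site, whose
#'   lineages are largely absent elsewhere), larger values mean species
#'   recur across that many adjacent sites.  Controls how much of the
#'   species pool concentrates at each point of the temperature gradient.
#' @param tree_age root age of the species tree (Myr).
#' @param pref_sigma2 Brownian rate of the site-preference trait.
#' @param traits trait definition table (see [default_trait_specs()]).
#' @param liability_sigma2 Brownian rate of the margin liability.
#' @param margin_mat_effect effect of standardized log10 MAT on the
#'   liability (0 = margin state independent of temperature).
#' @param untoothed_frac target fraction of untoothed species-site pairs.
#' @param margin_scale width (in liability SDs) of the mixed-margin zone.
#' @param n_specimens specimens scored per species-site pair.
#' @param epsilon_frac terminal-branch fraction for duplicate species-site
#'   tips.
#' @return list of class `"community_spec"`.
#' @export
community_spec <- function(seed,
                           n_species = 300L,
                           n_sites = 17L,
                           mat_range = c(5.6, 25.8),
                           site_quotas = c(rep(25L, 3L), rep(26L, 13L), 156L),
                           site_fidelity = c(rep(3, n_sites - 1L), 1),
                           tree_age = 100,
                           pref_sigma2 = 1,
                           traits = default_trait_specs(),
                           liability_sigma2 = 1,
                           margin_mat_effect = 0,
                           untoothed_frac = 0.43,
                           margin_scale = 0.1,
                           n_specimens = 5L,
                           epsilon_frac = 0.02) {
  if (missing(seed)) stopf("'seed' is required")
  if (length(mat_range) != 2L || diff(mat_range) <= 0)
    stopf("'mat_range' must be increasing")
  if (length(site_quotas) != n_sites)
    stopf("'site_quotas' must have one entry per site")
  if (length(site_fidelity) != n_sites || any(site_fidelity < 1))
    stopf("'site_fidelity' must have one entry >= 1 per site")
  if (any(site_quotas > n_species))
    stopf("infeasible sizes: a site quota (%d) exceeds the species pool (%d)",
          max(site_quotas), n_species)
  if (sum(site_quotas / site_fidelity) > n_species)
    stopf("infeasible sizes: quotas/fidelity imply %.0f species but the pool has %d",
          sum(site_quotas / site_fidelity), n_species)
  if (any(site_quotas < 1L)) stopf("site quotas must be >= 1")
  structure(list(seed = seed, n_species = as.integer(n_species),
                 n_sites = as.integer(n_sites), mat_range = mat_range,
                 site_quotas = as.integer(site_quotas),
                 site_fidelity = site_fidelity, tree_age = tree_age,
                 pref_sigma2 = pref_sigma2, traits = traits,
                 liability_sigma2 = liability_sigma2,
                 margin_mat_effect = margin_mat_effect,
                 untoothed_frac = untoothed_frac,
                 margin_scale = margin_scale,
                 n_specimens = as.integer(n_specimens),
                 epsilon_frac = epsilon_frac),
            class = "community_spec")
}

#' Assign tips to clade groups by an age cut
#' @keywords internal
clade_groups <- function(tree, cut_age) {
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_len(ntip)]) - depth
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  vapply(seq_len(ntip), function(v) {
    while (parent[v] != 0L && age[parent[v]] <= cut_age) v <- parent[v]
    v
  }, integer(1))
}

#' Expand species tips into species-site polytomies
#'
#' Each species occurring at k >= 2 sites is replaced by a k-tip polytomy
#' whose terminal branches have length `eps`, keeping the tree ultrametric
#' and its covariance matrix non-singular.
#' @keywords internal
expand_species_tips <- function(tree, site_map, eps) {
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  rec <- function(v) {
    if (v <= ntip) {
      lab <- tree$tip.label[v]
      sites <- site_map[[lab]]
      stem <- elen[v]
      if (length(sites) == 1L)
        return(paste0(lab, "@", sites, ":", format(stem, digits = 12)))
      e <- min(eps, stem / 2)
      inner <- paste0(lab, "@", sites, ":", format(e, digits = 12),
                      collapse = ",")
      return(paste0("(", inner, ")", lab, ":",
                    format(stem - e, digits = 12)))
    }
    inner <- paste(vapply(kids[[as.character(v)]], rec, character(1)),
                   collapse = ",")
    if (v == ntip + 1L) paste0("(", inner, ")")
    else paste0("(", inner, "):", format(elen[v], digits = 12))
  }
  ape::read.tree(text = paste0(rec(ntip + 1L), ";"))
}

#' Simulate a species-site community with traits and temperatures
#'
#' Realizes the full data-generating structure described in
#' [community_spec()]: a species pool on a pure-birth tree, a
#' phylogenetically conserved temperature preference governing which
#' species occur at which sites, per-pair continuous traits linear in
#' log10 MAT with lambda-structured residuals, and a thresholded Brownian
#' liability for margin state scored over several specimens.
#'
#' @param spec a [community_spec()].
#' @return list of class `"leaf_community"` with elements `tree` (the
#'   species-site phylogeny, ultrametric, one tip per species-site pair),
#'   `table` (trait table; one row per pair), `sites` (site MATs), and
#'   `spec`.
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  n_sp <- spec$n_species
  sp_labels <- sprintf("s%03d", seq_len(n_sp))
  sp_tree <- simulate_tree(n_sp, spec$tree_age, derive_seed(spec$seed, 1L),
                           labels = sp_labels)

  # phylogenetically conserved temperature preference -> site occupancy.
  # A Brownian "preference" trait fixes the phylogenetic ordering of
  # species along the gradient; its ranks are then mapped through the
  # quota/fidelity-weighted site-MAT distribution so the pool's density
  # matches demand (e.g. a species-rich, largely endemic tropical flora).
  site_mat <- seq(spec$mat_range[1], spec$mat_range[2], length.out = spec$n_sites)
  u <- simulate_bm_trait(sp_tree, spec$pref_sigma2, 0, derive_seed(spec$seed, 2L))
  w <- spec$site_quotas / spec$site_fidelity
  cw <- cumsum(w) / sum(w)
  p <- (rank(u, ties.method = "first") - 0.5) / n_sp
  pref <- stats::approx(x = c(0, cw), y = c(site_mat[1L], site_mat),
                        xout = p, rule = 2)$y
  site_ids <- sprintf("S%02d", seq_len(spec$n_sites))
  occupancy <- lapply(seq_len(spec$n_sites), function(j) {
    sp_labels[order(abs(pref - site_mat[j]))[seq_len(spec$site_quotas[j])]]
  })
  site_map <- lapply(sp_labels, function(sp)
    site_ids[vapply(occupancy, function(o) sp %in% o, logical(1))])
  names(site_map) <- sp_labels
  used <- lengths(site_map) > 0L
  if (any(!used)) {
    site_map <- site_map[used]
    sp_tree_used <- ape::keep.tip(sp_tree, sp_labels[used])
  } else sp_tree_used <- sp_tree

  # taxonomy from clades of the species tree
  fam_grp <- clade_groups(sp_tree, 0.55 * spec$tree_age)
  gen_grp <- clade_groups(sp_tree, 0.25 * spec$tree_age)
  fam_id <- match(fam_grp, unique(fam_grp))
  gen_id <- match(gen_grp, unique(gen_grp))
  taxonomy <- data.frame(species = sp_labels,
                         genus = sprintf("Gen%03d", gen_id),
                         family = sprintf("Fam%02d", fam_id),
                         stringsAsFactors = FALSE)

  eps <- spec$epsilon_frac * spec$tree_age
  comm <- expand_species_tips(sp_tree_used, site_map, eps)
  n_pairs <- ape::Ntip(comm)
  stopifnot(n_pairs == sum(spec$site_quotas))

  labs <- comm$tip.label
  sp_of <- sub("@.*$", "", labs)
  site_of <- sub("^.*@", "", labs)
  mat <- site_mat[match(site_of, site_ids)]
  tax <- taxonomy[match(sp_of, taxonomy$species), ]
  full_label <- paste0(tax$genus, "_", tax$species, "@", site_of)
  comm$tip.label <- full_label

  tab <- data.frame(label = full_label, family = tax$family,
                    genus = tax$genus, species = tax$species,
                    site = site_of, mat = mat,
                    stringsAsFactors = FALSE, check.names = FALSE)

  # margin: thresholded Brownian liability (+ optional direct MAT effect)
  liab <- simulate_bm_trait(comm, spec$liability_sigma2, 0,
                            derive_seed(spec$seed, 50L))
  lm10 <- log10(mat)
  liab <- liab + spec$margin_mat_effect * (lm10 - mean(lm10)) / sd(lm10) * sd(liab)
  thr <- quantile(liab, 1 - spec$untoothed_frac, names = FALSE)
  p_untoothed <- plogis((liab - thr) / (spec$margin_scale * sd(liab)))
  codes <- with_seed(derive_seed(spec$seed, 51L), {
    t(vapply(seq_len(n_pairs), function(i) {
      states <- ifelse(runif(spec$n_specimens) < p_untoothed[i],
                       "untoothed", "toothed")
      code_margin(states)
    }, c(ternary = 0, binomial = 0)))
  })
  tab$margin_ternary <- codes[, "ternary"]
  tab$margin_binomial <- codes[, "binomial"]

  # continuous traits: a + b * log10(MAT) + lambda-structured residual
  C <- phylo_vcv(comm)
  C <- C / max(diag(C))
  for (k in seq_len(nrow(spec$traits))) {
    tr <- spec$traits[k, ]
    Cl <- lambda_transform(C, tr$lambda)
    L <- t(chol(Cl))
    resid <- with_seed(derive_seed(spec$seed, 100L + k),
                       tr$sigma * drop(L %*% rnorm(n_pairs)))
    val <- tr$a + tr$b * lm10 + resid
    raw <- 10^val
    if (tr$tooth) raw[tab$margin_binomial == 1] <- NA_real_
    tab[[tr$name]] <- raw
  }

  rownames(tab) <- tab$label
  structure(list(tree = comm,
                 table = tab,
                 sites = data.frame(site = site_ids, mat = site_mat,
                                    quota = spec$site_quotas),
                 spec = spec),
            class = "leaf_community")
}

#' @export
print.leaf_community <- function(x, ...) {
  cat(sprintf("Synthetic leaf-trait community: %d species-site pairs at %d sites\n",
              nrow(x$table), nrow(x$sites)))
  cat(sprintf("  MAT range %.1f-%.1f C; %d trait columns; seed %s\n",
              min(x$sites$mat), max(x$sites$mat),
              nrow(x$spec$traits) + 1L, format(x$spec$seed)))
  invisible(x)
}
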