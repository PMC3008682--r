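test_that("pure-birth tree simulation is seeded, scaled, and bifurcating", {
  t2 <- simulate_tree(2, age = 40, seed = 1)
  expect_equal(ape::Ntip(t2), 2L)
  expect_equal(unname(leafphylo:::tip_depths(t2)), c(40, 40), tolerance = 1e-9)

  a <- simulate_tree(64, 100, seed = 7)
  b <- simulate_tree(64, 100, seed = 7)
  expect_identical(write_newick(a), write_newick(b))
  expect_equal(a$Nnode, 63L)
  expect_true(is_ultrametric(a, 1e-8))
  expect_false(identical(write_newick(simulate_tree(64, 100, seed = 8)),
                         write_newick(a)))
  expect_error(simulate_tree(1, seed = 1), "at least 2")
  expect_error(simulate_tree(5, 100), "seed")
})

test_that("Brownian tip moments match the covariance matrix", {
  tr <- simulate_tree(8, 10, seed = 2)
  V <- phylo_vcv(tr)
  X <- vapply(1:2000, function(i)
    simulate_bm_trait(tr, sigma2 = 2, root_state = 5, seed = 10000 + i),
    numeric(8))
  emp <- cov(t(X))
  expect_equal(rowMeans(X), rep(5, 8), tolerance = 0.3,
               ignore_attr = TRUE)
  # diagonal: tip variance ~ sigma2 * depth within 10%
  expect_equal(unname(diag(emp)), unname(2 * diag(V)), tolerance = 0.1)
  # deepest off-diagonal: sister covariance ~ sigma2 * shared depth
  od <- which(V == max(V[upper.tri(V)]), arr.ind = TRUE)[1, ]
  expect_equal(emp[od[1], od[2]], 2 * V[od[1], od[2]], tolerance = 0.1)
  expect_equal(simulate_bm_trait(tr, 0, 3, seed = 1),
               setNames(rep(3, 8), tr$tip.label))
})

test_that("lambda-structured traits have the lambda-scaled covariance", {
  tr <- simulate_tree(8, 10, seed = 3)
  Cl <- lambda_transform(phylo_vcv(tr), 0.5)
  X <- vapply(1:5000, function(i)
    simulate_lambda_trait(tr, lambda = 0.5, sigma2 = 1, seed = 20000 + i),
    numeric(8))
  emp <- cov(t(X))
  expect_equal(unname(emp), unname(Cl), tolerance = 0.06)
  # lambda = 0: tips independent with Brownian variances
  X0 <- vapply(1:3000, function(i)
    simulate_lambda_trait(tr, lambda = 0, sigma2 = 1, seed = 30000 + i),
    numeric(8))
  emp0 <- cov(t(X0))
  expect_equal(unname(diag(emp0)), unname(diag(Cl)), tolerance = 0.1)
  expect_lt(max(abs(emp0[upper.tri(emp0)])) / max(diag(Cl)), 0.08)
})

test_that("community defaults reproduce the target species-site structure", {
  comm <- simulate_community(community_spec(seed = 99))
  tab <- comm$table
  expect_equal(nrow(tab), 569L)
  expect_equal(length(unique(tab$site)), 17L)
  expect_equal(range(tab$mat), c(5.6, 25.8), tolerance = 1e-9)
  hottest <- tab$site[which.max(tab$mat)]
  expect_equal(nrow(exclude_site(tab, hottest)), 413L)
  # tree and table describe exactly the same species-site pairs
  expect_setequal(comm$tree$tip.label, tab$label)
  expect_true(is_ultrametric(comm$tree, 1e-6))
  expect_false(anyDuplicated(tab$label) > 0)
  expect_true(all(is.finite(tab$mat)))
  # margin codes and tooth-trait missingness are consistent
  expect_true(all(tab$margin_ternary %in% c(0, 0.5, 1)))
  expect_true(all(tab$margin_binomial %in% c(0, 1)))
  expect_identical(tab$margin_binomial == 1, tab$margin_ternary == 1)
  expect_identical(is.na(tab[["Number of teeth"]]), tab$margin_binomial == 1)
  expect_true(all(is.finite(tab[["Blade area"]])))
})

test_that("community generation is bit-reproducible for a given seed", {
  a <- simulate_community(community_spec(seed = 123))
  b <- simulate_community(community_spec(seed = 123))
  expect_identical(a$table, b$table)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  c2 <- simulate_community(community_spec(seed = 124))
  expect_false(identical(a$table, c2$table))
})

test_that("MAT viewed as a species trait carries phylogenetic signal", {
  # single-community K is long-tailed (a few deep contrasts dominate), so
  # the level check averages over communities; the permutation test is the
  # sharper per-community check
  ks <- vapply(c(31, 42, 77, 123, 200), function(s) {
    comm <- simulate_community(community_spec(seed = s))
    blomberg_k(comm$tree, prepare_trait(comm$table, "mat", "log10")$values)
  }, numeric(1))
  expect_gt(mean(ks), 0.1)
  comm <- simulate_community(community_spec(seed = 31))
  v <- prepare_trait(comm$table, "mat", "log10")$values
  st <- signal_test(comm$tree, v, n_perm = 199, seed = 32)
  expect_equal(st$P, 1 / 200)  # conserved occupancy reaches the floor
})

test_that("infeasible community sizes are rejected up front", {
  expect_error(community_spec(seed = 1, n_species = 10,
                              n_sites = 3, site_quotas = c(5, 5, 50),
                              site_fidelity = c(1, 1, 1)),
               "infeasible")
  expect_error(community_spec(seed = 1, n_sites = 3, site_quotas = c(1, 1)),
               "one entry per site")
  expect_error(community_spec(seed = 1, mat_range = c(10, 5)), "increasing")
})

test_that("a null trait (b = 0, lambda = 0) yields a slope centered on zero", {
  specs <- default_trait_specs()[1, ]
  specs$b <- 0
  specs$lambda <- 0
  slopes <- vapply(1:50, function(i) {
    comm <- simulate_community(community_spec(
      seed = 4000 + i, n_species = 60, n_sites = 5,
      site_quotas = c(10, 10, 10, 10, 20), site_fidelity = c(3, 3, 3, 3, 1),
      traits = specs))
    p <- prepare_trait(comm$table, specs$name, "log10")
    d <- data.frame(y = unname(p$values),
                    x = log10(comm$table[p$labels, "mat"]),
                    row.names = p$labels)
    unname(coef(fit_gls(y ~ x, d))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})
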