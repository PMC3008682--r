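test_that("lambda_transform scales off-diagonals only and validates lambda", {
  C <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3)
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)))
  expect_equal(lambda_transform(C, 0.5),
               matrix(c(2, 0.5, 0, 0.5, 2, 0, 0, 0, 2), 3))
  expect_error(lambda_transform(C, 1.2), "lambda")
  expect_error(lambda_transform(C, -0.1), "lambda")
})

test_that("fit_gls recovers exact lines and matches the normal equations", {
  d <- data.frame(x = c(0, 1, 2), y = c(1, 3, 5))
  f <- fit_gls(y ~ x, d)
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-12)

  dc <- data.frame(x = c(0, 1, 2, 4), y = rep(3, 4))
  fc <- fit_gls(y ~ x, dc)
  expect_equal(unname(coef(fc)), c(3, 0), tolerance = 1e-12)

  set.seed(11)
  dr <- data.frame(x = rnorm(50), y = rnorm(50))
  fr <- fit_gls(y ~ x, dr)
  X <- cbind(1, dr$x)
  beta <- solve(t(X) %*% X, t(X) %*% dr$y)
  expect_equal(unname(coef(fr)), drop(beta), tolerance = 1e-10)
  # ML parameterization: sigma2 = RSS/n, AIC = 2k - 2logL with k = 3
  rss <- sum((dr$y - X %*% beta)^2)
  expect_equal(fr$sigma2, rss / 50, tolerance = 1e-12)
  expect_equal(fr$aic, 2 * 3 - 2 * fr$logL, tolerance = 1e-9)
  expect_error(fit_gls(y ~ x, data.frame(x = rep(1, 5), y = rnorm(5))),
               "singular")
})

test_that("gls_loglik: identity, scaling identity, and dense MVN oracle", {
  set.seed(21)
  n <- 12
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  expect_equal(gls_loglik(y, X, diag(n)), gls_loglik(y, X, NULL),
               tolerance = 1e-12)
  # V = 4I: likelihood equals the OLS likelihood of y/2 shifted by the
  # log-Jacobian n*log(2) of the rescaling
  expect_equal(gls_loglik(y, X, 4 * diag(n)),
               gls_loglik(y / 2, X, NULL) - n * log(2),
               tolerance = 1e-10)
  # dense brute-force MVN evaluation on small random trees
  for (s in 1:15) {
    tr <- random_tree(sample(3:8, 1), seed = 600 + s)
    ntip <- ape::Ntip(tr)
    V <- phylo_vcv(tr)
    set.seed(s)
    yy <- rnorm(ntip)
    XX <- cbind(1, rnorm(ntip))
    expect_equal(gls_loglik(yy, XX, V), mvn_loglik_oracle(yy, XX, V),
                 tolerance = 1e-9)
  }
  expect_error(gls_loglik(y, X, diag(n) - 2), "positive definite")
})

test_that("pGLS at lambda = 0 reproduces OLS on an ultrametric tree", {
  tr <- simulate_tree(40, 100, seed = 31)
  x <- simulate_bm_trait(tr, 1, 0, seed = 32)
  set.seed(33)
  d <- data.frame(x = unname(x), y = 1 + 0.5 * unname(x) + rnorm(40),
                  row.names = names(x))
  g <- fit_gls(y ~ x, d)
  p <- fit_pgls(y ~ x, d, tr, lambda = 0)
  expect_equal(coef(p), coef(g), tolerance = 1e-8)
  expect_equal(p$se, g$se, tolerance = 1e-8)
  expect_equal(p$logL, g$logL, tolerance = 1e-8)
  expect_equal(p$k, g$k)  # fixed lambda is not an estimated parameter
})

test_that("lambda is flagged unidentifiable on a star tree", {
  star <- read_newick(paste0("(", paste0("t", 1:24, ":1", collapse = ","), ");"))
  set.seed(41)
  d <- data.frame(x = rnorm(24), y = rnorm(24),
                  row.names = paste0("t", 1:24))
  p <- fit_pgls(y ~ x, d, star)
  expect_false(p$lambda_identifiable)
  expect_true(p$lambda %in% c(0, 1))
})

test_that("ML-lambda pGLS agrees with nlme::gls + corPagel", {
  skip_if_no("nlme")
  tr <- simulate_tree(64, 1, seed = 51)
  x <- simulate_bm_trait(tr, 1, 0, seed = 52)
  resid <- simulate_lambda_trait(tr, lambda = 0.7, sigma2 = 0.5, seed = 53)
  d <- data.frame(x = unname(x), y = unname(2 - 0.4 * x + resid),
                  row.names = names(x))
  mine <- fit_pgls(y ~ x, d, tr)
  ref <- suppressWarnings(
    nlme::gls(y ~ x, data = d, method = "ML",
              correlation = ape::corPagel(0.5, tr, form = ~ 1)))
  expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(mine$lambda,
               as.numeric(ref$modelStruct$corStruct), tolerance = 1e-3)
  expect_equal(mine$logL, as.numeric(logLik(ref)), tolerance = 1e-5)
})

test_that("model comparison reports signed delta-AIC and ties", {
  mk <- function(aic, n) structure(list(aic = aic, n = n), class = "pgls_fit")
  cmp <- compare_models(mk(100, 10), mk(110, 10))
  expect_equal(cmp$delta_aic, -10)
  expect_equal(cmp$preferred, "a")
  expect_equal(compare_models(mk(50, 9), mk(50, 9))$preferred, "tie")
  expect_error(compare_models(mk(1, 5), mk(1, 6)), "different numbers")
  expect_error(compare_models(mk(NA_real_, 5), mk(1, 5)), "PQL")
  # AIC arithmetic by definition
  expect_equal(2 * 2 - 2 * 0, 4)
  f <- fit_gls(y ~ x, data.frame(x = rnorm(10), y = rnorm(10)))
  expect_equal(AIC(f), f$aic, tolerance = 1e-12)
})

test_that("PQL with tau2 = 0 on a star tree equals logistic IRLS", {
  star <- read_newick(paste0("(", paste0("t", 1:60, ":1", collapse = ","), ");"))
  set.seed(61)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(-0.3 + 1.2 * x))
  d <- data.frame(x = x, y = y, row.names = paste0("t", 1:60))
  f <- fit_binomial_pql(y ~ x, d, star, tau2 = 0)
  ref <- logistic_irls_oracle(cbind(1, x), y)
  expect_equal(unname(coef(f)), ref, tolerance = 1e-6)
  expect_true(is.na(f$aic))  # PQL working likelihood is not AIC-comparable
})

test_that("PQL slope CI covers zero when response is independent of x", {
  tr <- simulate_tree(80, 100, seed = 71)
  set.seed(72)
  d <- data.frame(x = rnorm(80), y = rep(c(0, 1), 40),
                  row.names = tr$tip.label)
  f <- fit_binomial_pql(y ~ x, d, tr)
  ci <- confint(f)["x", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("PQL rejects degenerate responses and reports separation", {
  tr <- simulate_tree(20, 100, seed = 81)
  d0 <- data.frame(x = rnorm(20), y = rep(0, 20), row.names = tr$tip.label)
  expect_error(fit_binomial_pql(y ~ x, d0, tr), "classes")
  x <- sort(rnorm(20))
  d1 <- data.frame(x = x, y = as.numeric(x > 0), row.names = tr$tip.label)
  expect_error(fit_binomial_pql(y ~ x, d1, tr, tau2 = 0), "separation")
})
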