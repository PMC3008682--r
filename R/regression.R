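#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of `C` by `lambda`, leaving the
#' diagonal untouched.  `lambda = 1` returns the full Brownian covariance,
#' `lambda = 0` the star-phylogeny (independence) covariance.
#'
#' @param C phylogenetic covariance matrix (see [phylo_vcv()]).
#' @param lambda scalar in `[0, 1]`.
#' @return transformed covariance matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stopf("'lambda' must be a single value in [0, 1]")
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

#' Core GLS solver with profiled ML variance
#'
#' Whitens through the Cholesky factor of V (no explicit inverse), solves
#' the least-squares problem by QR, and profiles out the residual variance
#' at its ML value RSS/n.
#' @keywords internal
gls_engine <- function(y, X, V = NULL) {
  n <- length(y)
  if (is.null(V)) {
    ty <- y
    tX <- X
    logdet <- 0
  } else {
    U <- tryCatch(chol(V), error = function(e) {
      ev <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
      stopf("covariance matrix is not positive definite (smallest eigenvalue %.3e)%s",
            ev,
            if (ev > -1e-8) "; duplicate tips need the epsilon terminal-branch policy of smooth_ages()" else "")
    })
    ty <- backsolve(U, y, transpose = TRUE)
    tX <- backsolve(U, X, transpose = TRUE)
    logdet <- 2 * sum(log(diag(U)))
  }
  qx <- qr(tX)
  if (qx$rank < ncol(X)) stopf("singular design matrix (constant predictor?)")
  beta <- setNames(drop(qr.coef(qx, ty)), colnames(X))
  r <- drop(ty - tX %*% beta)
  rss <- sum(r^2)
  sigma2 <- rss / n
  logL <- if (sigma2 > 0)
    -0.5 * (n * log(2 * pi * sigma2) + n + logdet)
  else Inf  # perfect fit: degenerate likelihood
  covb_unscaled <- chol2inv(qr.R(qx))
  dimnames(covb_unscaled) <- list(colnames(X), colnames(X))
  fitted <- drop(X %*% beta)
  list(beta = beta, sigma2 = sigma2, logL = logL,
       covb = sigma2 * covb_unscaled,
       se = sqrt(pmax(sigma2 * diag(covb_unscaled), 0)),
       fitted = fitted, residuals = drop(y - fitted))
}

#' Gaussian GLS log-likelihood
#'
#' Multivariate-normal log-likelihood of `y` given design `X` and
#' covariance proportional to `V`, with GLS coefficients and the ML
#' residual variance profiled in; computed through the Cholesky factor of
#' `V`.
#'
#' @param y response vector.
#' @param X design matrix (same number of rows as `y`).
#' @param V positive-definite covariance matrix, or `NULL` for identity.
#' @return the log-likelihood (scalar).
#' @export
gls_loglik <- function(y, X, V = NULL) {
  gls_engine(y, as.matrix(X), V)$logL
}

new_pgls_fit <- function(kind, eng, k, n, extra = list()) {
  obj <- c(list(kind = kind,
                coefficients = eng$beta, se = eng$se,
                sigma2 = eng$sigma2, logL = eng$logL,
                k = k, aic = 2 * k - 2 * eng$logL, n = n,
                fitted.values = eng$fitted, residuals = eng$residuals,
                vcov = eng$covb),
           extra)
  class(obj) <- "pgls_fit"
  obj
}

#' Ordinary (non-phylogenetic) GLS regression
#'
#' Ordinary least squares with the Gaussian ML parameterization used for
#' AIC comparison against phylogenetic models: residual variance estimated
#' as RSS/n, parameter count k = 3 (intercept, slope, variance) for a
#' simple regression, and AIC = 2k - 2 logL.  Coefficient standard errors
#' use the ML variance for comparability with [fit_pgls()].
#'
#' @param formula model formula, e.g. `log_trait ~ log_mat`.
#' @param data data frame containing the variables.
#' @return an object of class `"pgls_fit"` with `kind = "gls"`.
#' @examples
#' d <- data.frame(x = 0:2, y = c(1, 3, 5))
#' coef(fit_gls(y ~ x, d))
#' @export
fit_gls <- function(formula, data) {
  mf <- model.frame(formula, data, na.action = na.omit)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (length(y) < 3L) stopf("need at least 3 observations")
  eng <- gls_engine(y, X, NULL)
  out <- new_pgls_fit("gls", eng, k = ncol(X) + 1L, n = length(y),
                      extra = list(lambda = NA_real_, formula = formula,
                                   terms = attr(mf, "terms"),
                                   call = match.call(), V = NULL,
                                   labels = rownames(mf)))
  out
}

#' @keywords internal
align_model_data <- function(formula, data, tree) {
  labels <- if ("label" %in% names(data)) as.character(data$label) else rownames(data)
  if (is.null(labels)) stopf("'data' needs row names or a 'label' column matching tree tips")
  mf <- model.frame(formula, data, na.action = stats::na.pass)
  ok <- stats::complete.cases(mf)
  mf <- mf[ok, , drop = FALSE]
  labels <- labels[ok]
  if (anyDuplicated(labels)) stopf("duplicate observation labels")
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown))
    stopf("observation labels not in tree: %s%s",
          paste(head(unknown, 5L), collapse = ", "),
          if (length(unknown) > 5L) sprintf(" (+%d more)", length(unknown) - 5L) else "")
  tr <- if (length(labels) < ape::Ntip(tree)) ape::keep.tip(tree, labels) else tree
  ord <- match(tr$tip.label, labels)
  mf <- mf[ord, , drop = FALSE]
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  list(tree = tr, y = y, X = X, labels = labels[ord], terms = attr(mf, "terms"))
}

#' Phylogenetic GLS with Pagel's lambda branch-length scaling
#'
#' Generalized least squares whose error covariance is the phylogenetic
#' covariance matrix of `tree` with off-diagonals scaled by Pagel's
#' lambda.  With `lambda = "ML"` the scaling is estimated by maximizing
#' the profile log-likelihood over `[0, 1]` (bounded search, tolerance
#' 1e-6, boundary values allowed; a flat profile, e.g. on a star tree, is
#' flagged via `lambda_identifiable`).  Coefficients, their ML standard
#' errors, log-likelihood and AIC (k = 4: intercept, slope, variance,
#' lambda) are returned for comparison with [fit_gls()].
#'
#' Observations are matched to tips by the data's row names (or a
#' `label` column); the tree is pruned to the observations with complete
#' data.
#'
#' @inheritParams fit_gls
#' @param tree a `"phylo"` object covering all observation labels.
#' @param lambda `"ML"` to optimize, or a fixed value in `[0, 1]`.
#' @return an object of class `"pgls_fit"` with `kind = "pgls"`.
#' @export
fit_pgls <- function(formula, data, tree, lambda = "ML") {
  al <- align_model_data(formula, data, tree)
  n <- length(al$y)
  estimate <- identical(lambda, "ML") || identical(lambda, "optimize")
  if (estimate && n < 4L) stopf("need at least 4 observations to estimate lambda")
  if (!estimate && n < 3L) stopf("need at least 3 observations")
  C <- phylo_vcv(al$tree)
  prof <- function(l) gls_engine(al$y, al$X, lambda_transform(C, l))$logL
  identifiable <- TRUE
  if (estimate) {
    opt <- optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, 1, opt$maximum)
    ll <- c(prof(0), prof(1), opt$objective)
    # ties within 1e-8 resolved toward a boundary value
    best <- max(ll)
    at_best <- which(ll >= best - 1e-8)
    lam <- cand[at_best[1L]]
    grid <- vapply(c(0, 0.25, 0.5, 0.75, 1), prof, numeric(1))
    if (max(grid) - min(grid) < 1e-8) identifiable <- FALSE
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stopf("'lambda' must be \"ML\" or a value in [0, 1]")
    lam <- lambda
  }
  Vl <- lambda_transform(C, lam)
  eng <- gls_engine(al$y, al$X, Vl)
  k <- ncol(al$X) + 1L + as.integer(estimate)
  new_pgls_fit("pgls", eng, k = k, n = n,
               extra = list(lambda = lam, lambda_estimated = estimate,
                            lambda_identifiable = identifiable,
                            formula = formula, terms = al$terms,
                            call = match.call(), V = Vl,
                            labels = al$labels, tree = al$tree))
}

#' Compare two fitted models by AIC
#'
#' @param a,b `"pgls_fit"` objects fitted to the same response data.
#' @return list with `delta_aic` (= `AIC(a) - AIC(b)`), `preferred`
#'   (`"a"`, `"b"` or `"tie"`), and the two AIC values.
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "pgls_fit"), inherits(b, "pgls_fit"))
  if (a$n != b$n) stopf("models fitted to different numbers of observations (%d vs %d)", a$n, b$n)
  if (is.na(a$aic) || is.na(b$aic))
    stopf("AIC not defined for a PQL fit; comparison unavailable")
  d <- a$aic - b$aic
  list(delta_aic = d,
       preferred = if (d < 0) "a" else if (d > 0) "b" else "tie",
       aic_a = a$aic, aic_b = b$aic)
}

#' Phylogenetic binomial regression by penalized quasi-likelihood
#'
#' Logit-link binomial model whose residual structure includes a
#' phylogenetic random component: at each cycle the usual IRLS working
#' response `z = eta + (y - mu)/(mu(1-mu))` is regressed on the design
#' under total covariance `W^-1 + tau2 * C`, where `W` are the binomial
#' working weights and `C` the tip covariance scaled to unit height; the
#' variance component `tau2` is re-estimated each cycle by a
#' one-dimensional profile search.  Starting values come from an ordinary
#' logistic fit.  As with any PQL scheme the working likelihood is not a
#' true marginal likelihood, so `logL` and `AIC` are reported as `NA`.
#'
#' @inheritParams fit_pgls
#' @param tau2 `"ML"` to profile each cycle, or a fixed value >= 0
#'   (0 recovers ordinary logistic regression).
#' @param max_iter,tol iteration control: stop when the largest
#'   coefficient change drops below `tol` (default 1e-6) or after
#'   `max_iter` cycles.
#' @return an object of class `"pgls_fit"` with `kind = "binomial-pql"`,
#'   carrying `tau2` and NA `logL`/`aic`.
#' @export
fit_binomial_pql <- function(formula, data, tree, tau2 = "ML",
                             max_iter = 100L, tol = 1e-6) {
  al <- align_model_data(formula, data, tree)
  y <- al$y
  X <- al$X
  if (!all(y %in% c(0, 1))) stopf("response must be coded 0/1")
  if (length(unique(y)) < 2L) stopf("both response classes must be present")
  n <- length(y)
  C <- phylo_vcv(al$tree)
  C <- C / max(diag(C))
  estimate_tau <- identical(tau2, "ML") || identical(tau2, "optimize")
  if (!estimate_tau && (!is.numeric(tau2) || tau2 < 0))
    stopf("'tau2' must be \"ML\" or a non-negative value")

  gauss_fit <- function(z, S) {
    U <- chol(S)
    tz <- backsolve(U, z, transpose = TRUE)
    tX <- backsolve(U, X, transpose = TRUE)
    qx <- qr(tX)
    if (qx$rank < ncol(X)) stopf("singular design matrix")
    beta <- setNames(drop(qr.coef(qx, tz)), colnames(X))
    r <- drop(tz - tX %*% beta)
    covb <- chol2inv(qr.R(qx))
    dimnames(covb) <- list(colnames(X), colnames(X))
    list(beta = beta,
         logL = -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(U))) + sum(r^2)),
         covb = covb)
  }

  beta <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients)
  t2 <- if (estimate_tau) 0 else tau2
  fit <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    if (max(abs(eta)) > 30) {
      slope <- beta[length(beta)]
      stopf("non-convergence: complete or quasi-complete separation (diverging %s slope on '%s')",
            if (slope > 0) "positive" else "negative",
            colnames(X)[ncol(X)])
    }
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    Wi <- diag(1 / w, n)
    if (estimate_tau) {
      g <- function(t) gauss_fit(z, Wi + t * C)$logL
      op <- optimize(g, c(0, 10), maximum = TRUE, tol = 1e-4)
      t2 <- if (g(0) >= op$objective) 0 else op$maximum
    }
    fit <- gauss_fit(z, Wi + t2 * C)
    if (max(abs(fit$beta - beta)) < tol) {
      beta <- fit$beta
      converged <- TRUE
      break
    }
    beta <- fit$beta
  }
  if (!converged) warnf("PQL did not converge in %d iterations", max_iter)
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  eng <- list(beta = beta, sigma2 = NA_real_, logL = NA_real_,
              covb = fit$covb, se = sqrt(diag(fit$covb)),
              fitted = mu, residuals = y - mu)
  out <- new_pgls_fit("binomial-pql", eng, k = ncol(X) + 1L, n = n,
                      extra = list(lambda = NA_real_, tau2 = t2,
                                   formula = al$terms, terms = al$terms,
                                   call = match.call(), V = NULL,
                                   labels = al$labels, converged = converged,
                                   iterations = it))
  out$aic <- NA_real_  # PQL working likelihood is not AIC-comparable
  out
}
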