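#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  kind <- switch(x$kind,
                 gls = "Ordinary GLS (non-phylogenetic)",
                 pgls = "Phylogenetic GLS (Pagel's lambda)",
                 `binomial-pql` = "Phylogenetic binomial regression (PQL)")
  cat(kind, "\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  if (x$kind == "pgls")
    cat(sprintf("lambda = %.4g%s\n", x$lambda,
                if (isFALSE(x$lambda_identifiable)) " (not identifiable: flat profile)" else ""))
  if (x$kind == "binomial-pql")
    cat(sprintf("tau2 = %.4g  (%s after %d PQL cycles)\n", x$tau2,
                if (isTRUE(x$converged)) "converged" else "NOT converged",
                x$iterations))
  if (!is.na(x$aic))
    cat(sprintf("n = %d   logLik = %.4f   AIC = %.4f\n", x$n, x$logL, x$aic))
  else
    cat(sprintf("n = %d   (logLik/AIC not defined under PQL)\n", x$n))
  invisible(x)
}

#' @export
summary.pgls_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab), class = "summary.pgls_fit")
}

#' @export
print.summary.pgls_fit <- function(x, ...) {
  print(x$fit)
  cat("\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (!is.na(x$fit$sigma2))
    cat(sprintf("\nResidual variance (ML): %.6g\n", x$fit$sigma2))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
vcov.pgls_fit <- function(object, ...) object$vcov

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
nobs.pgls_fit <- function(object, ...) object$n

#' @export
fitted.pgls_fit <- function(object, ...) object$fitted.values

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals

#' @export
confint.pgls_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients
  se <- object$se
  if (missing(parm)) parm <- names(est)
  zq <- qnorm(1 - (1 - level) / 2)
  out <- cbind(est - zq * se, est + zq * se)
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out[parm, , drop = FALSE]
}

#' @export
predict.pgls_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(object$terms)
  X <- model.matrix(tt, model.frame(tt, newdata, na.action = na.omit))
  eta <- drop(X %*% object$coefficients)
  if (object$kind == "binomial-pql") plogis(eta) else eta
}

#' Simulate responses from a fitted Gaussian (p)GLS model
#'
#' Draws from the fitted multivariate normal
#' `N(X beta, sigma2 * V_lambda)` (identity covariance for ordinary GLS).
#' Not available for PQL fits.
#'
#' @param object a `"pgls_fit"` of kind `"gls"` or `"pgls"`.
#' @param nsim number of replicate response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns, rows in fitting order.
#' @export
simulate.pgls_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$kind == "binomial-pql")
    stopf("simulate() is not available for PQL fits")
  n <- object$n
  mu <- object$fitted.values
  L <- if (is.null(object$V)) NULL else t(chol(object$V))
  with_seed(seed, {
    out <- replicate(nsim, {
      z <- rnorm(n, 0, sqrt(object$sigma2))
      mu + if (is.null(L)) z else drop(L %*% z)
    })
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}
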