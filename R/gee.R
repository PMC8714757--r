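#' Gaussian GEE with exchangeable working correlation
#'
#' Fits a marginal linear model by generalized estimating equations with an
#' identity link, Gaussian working variance and an exchangeable working
#' correlation within clusters, the standard model for paired-eye ophthalmic
#' data (cluster = subject, two correlated eyes). Inference uses the robust
#' sandwich (Huber-White) covariance, so standard errors are valid even when
#' the working correlation is misspecified.
#'
#' The exchangeable correlation parameter `alpha` is estimated by the moment
#' estimator on standardized residuals; coefficient updates solve the
#' generalized least squares equations with the closed-form inverse
#' `R^-1 = 1/(1-alpha) * (I - alpha/(1+(n_i-1)alpha) * J)` per cluster, and
#' the two steps alternate until the coefficients change by less than `tol`.
#'
#' @param formula model formula, e.g. `Df_whole ~ sex + age_years`.
#' @param data data frame containing the model variables and the cluster id.
#' @param id cluster identifier: a column name (character) or a vector of
#'   length `nrow(data)`.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change (default `1e-8`).
#' @param maxit maximum number of iterations (default 100).
#' @return An object of class `gee_exch` with components `coefficients`,
#'   `vcov` (robust), `alpha` (working correlation), `dispersion`,
#'   `residuals`, `fitted.values`, `n_clusters`, `converged`, `n_iter` and
#'   the usual model metadata. Methods: `print`, `summary`, `coef`, `vcov`,
#'   `confint`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' tab <- generate_cohort(cohort_params(n_subjects = 50), seed = 1)
#' fit <- gee_exch(Df_whole ~ sex + age_years, tab, id = "subject_id")
#' summary(fit)
#' @export
gee_exch <- function(formula, data, id, tol = 1e-8, maxit = 100) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  tt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop_validation("response must be numeric")
  X <- stats::model.matrix(tt, mf)
  if (is.character(id) && length(id) == 1) {
    if (!id %in% names(data)) stop_validation("id column '", id, "' not in data")
    id <- data[[id]]
  }
  if (length(id) != nrow(data)) stop_validation("id must match nrow(data)")
  id <- factor(id)
  n <- length(y); p <- ncol(X)
  if (nlevels(id) < 2) stop_validation("need at least 2 clusters")
  if (qr(X)$rank < p) stop_validation("singular design matrix")

  ni <- as.vector(table(id))
  max_ni <- max(ni)
  beta <- qr.coef(qr(X), y)

  alpha <- 0
  iter <- 0; converged <- FALSE
  repeat {
    iter <- iter + 1
    e <- as.vector(y - X %*% beta)
    sigma2 <- sum(e^2) / (n - p)
    if (max_ni > 1) {
      Se <- rowsum(e, id); Se2 <- rowsum(e^2, id)
      num <- sum((Se^2 - Se2) / 2)
      den <- (sum(ni * (ni - 1)) / 2 - p) * sigma2
      alpha <- if (den > 0) num / den else 0
      lower <- -1 / (max_ni - 1) + 1e-6
      alpha <- min(max(alpha, lower), 0.999)
    }
    ci <- alpha / (1 + (ni - 1) * alpha)           # per cluster
    cobs <- ci[as.integer(id)]
    SX <- rowsum(X, id); Sy <- rowsum(y, id)
    A <- crossprod(X) - crossprod(SX, SX * ci)
    b <- crossprod(X, y) - crossprod(SX, Sy * ci)
    beta_new <- solve(A, b)[, 1]
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= maxit) break
  }
  if (!converged)
    warning("gee_exch did not converge in ", maxit, " iterations")

  e <- as.vector(y - X %*% beta)
  sigma2 <- sum(e^2) / (n - p)
  Se <- rowsum(e, id)
  u0 <- e - (ci[as.integer(id)]) * Se[as.integer(id)]
  U <- rowsum(X * u0, id)
  Ainv <- solve(A)
  V <- Ainv %*% crossprod(U) %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(coefficients = beta, vcov = V, alpha = alpha,
                 dispersion = sigma2,
                 residuals = e, fitted.values = as.vector(X %*% beta),
                 n = n, n_clusters = nlevels(id), cluster_sizes = ni,
                 converged = converged, n_iter = iter,
                 terms = tt, xlevels = stats::.getXlevels(tt, mf),
                 formula = formula, call = cl),
            class = "gee_exch")
}

#' @export
print.gee_exch <- function(x, ...) {
  cat("Gaussian GEE, exchangeable working correlation\n")
  cat("  ", x$n, "observations in", x$n_clusters, "clusters; alpha =",
      signif(x$alpha, 4), "\n")
  cat("Coefficients:\n")
  print(signif(x$coefficients, 6))
  invisible(x)
}

#' @export
summary.gee_exch <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients,
               `Robust SE` = se,
               `CI lower` = object$coefficients - 1.96 * se,
               `CI upper` = object$coefficients + 1.96 * se,
               z = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(call = object$call, coefficients = tab, alpha = object$alpha,
              dispersion = object$dispersion, n = object$n,
              n_clusters = object$n_clusters, converged = object$converged)
  class(out) <- "summary.gee_exch"
  out
}

#' @export
print.summary.gee_exch <- function(x, ...) {
  cat("Gaussian GEE (identity link, exchangeable working correlation)\n")
  cat("Call: "); print(x$call)
  cat("\n", x$n, " eyes / observations in ", x$n_clusters,
      " clusters; working correlation alpha = ", signif(x$alpha, 4),
      "; dispersion = ", signif(x$dispersion, 4), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients, has.Pvalue = TRUE, P.values = TRUE,
                      cs.ind = 1:4, tst.ind = 5)
  if (!x$converged) cat("\nWARNING: fit did not converge\n")
  invisible(x)
}

#' @export
coef.gee_exch <- function(object, ...) object$coefficients

#' @export
vcov.gee_exch <- function(object, ...) object$vcov

#' @export
confint.gee_exch <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$coefficients - zq * se, object$coefficients + zq * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
fitted.gee_exch <- function(object, ...) object$fitted.values

#' @export
residuals.gee_exch <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "pearson") r <- r / sqrt(object$dispersion)
  r
}

#' @export
predict.gee_exch <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  as.vector(X %*% object$coefficients)
}

#' @export
plot.gee_exch <- function(x, ...) {
  graphics::plot(x$fitted.values, x$residuals,
                 xlab = "Fitted values", ylab = "Residuals",
                 main = "GEE residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

# Wald test of L %*% beta = 0 for a single contrast row L.
gee_contrast <- function(fit, L) {
  est <- sum(L * fit$coefficients)
  se <- sqrt(max(as.vector(t(L) %*% fit$vcov %*% L), 0))
  z <- est / se
  c(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}
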