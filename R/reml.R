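#' REML variance components for a single-GRM mixed model
#'
#' Fits \eqn{y = W\alpha + u + e} with \eqn{u \sim N(0, A\sigma_g^2)} and
#' \eqn{e \sim N(0, I\sigma_e^2)} by restricted maximum likelihood.  After
#' one eigendecomposition \eqn{A = U D U'}, the model is rotated so the
#' covariance is diagonal, \eqn{\sigma_g^2} is profiled out, and the
#' restricted likelihood is maximized exactly over the single variance
#' ratio \eqn{\delta = \sigma_e^2/\sigma_g^2} by Brent search on the log
#' scale.  Boundary fits (\eqn{\sigma_g^2 \to 0} or
#' \eqn{\sigma_e^2 \to 0}) correspond to the edges of the search interval
#' and cannot diverge.
#'
#' @param y numeric trait vector.
#' @param W fixed-effect design matrix (full column rank, includes the
#'   intercept).
#' @param grm a [compute_grm()] object (an existing eigendecomposition in
#'   `grm$eig` is reused).
#' @param tol relative tolerance of the likelihood search.
#' @param max_iter maximum likelihood evaluations before the fit is flagged
#'   unconverged.
#' @return object of class `variance_components`: list with `sigma_g2`,
#'   `sigma_e2`, `h2`, `log_likelihood` (restricted, up to a constant),
#'   `converged`, `n_iterations`.
#' @export
fit_reml <- function(y, W, grm, tol = 1e-6, max_iter = 200L) {
  n <- length(y)
  W <- as.matrix(W)
  stopifnot(nrow(W) == n, nrow(grm$A) == n)
  if (qr(W)$rank < ncol(W)) stop("fixed-effect design is rank deficient")
  c_ <- ncol(W)
  eig <- grm_eigen(grm)
  yt <- drop(crossprod(eig$vectors, y))
  Wt <- crossprod(eig$vectors, W)
  d <- eig$values

  evals <- 0L
  # -2 * restricted log-likelihood profile in log(delta)
  negll <- function(logdelta) {
    evals <<- evals + 1L
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    WtWW <- crossprod(Wt, Wt * w)
    b <- solve(WtWW, crossprod(Wt, yt * w))
    r <- yt - drop(Wt %*% b)
    rss <- sum(w * r^2)
    s2 <- rss / (n - c_)
    (n - c_) * log(s2) + sum(log(d + delta)) +
      as.numeric(determinant(WtWW, logarithm = TRUE)$modulus) + (n - c_)
  }
  lo <- log(1e-6); hi <- log(1e8)
  opt <- stats::optimize(negll, c(lo, hi), tol = tol)
  # compare against the boundaries (sigma_g2 ~ 0 is delta -> infinity)
  cand <- rbind(c(opt$minimum, opt$objective),
                c(lo, negll(lo)), c(hi, negll(hi)))
  best <- cand[which.min(cand[, 2]), ]
  delta <- exp(best[1])
  w <- 1 / (d + delta)
  WtWW <- crossprod(Wt, Wt * w)
  b <- solve(WtWW, crossprod(Wt, yt * w))
  r <- yt - drop(Wt %*% b)
  sigma_g2 <- sum(w * r^2) / (n - c_)
  sigma_e2 <- delta * sigma_g2
  floor_ <- 1e-10 * stats::var(y)
  out <- list(sigma_g2 = max(sigma_g2, 0),
              sigma_e2 = max(sigma_e2, floor_),
              h2 = max(sigma_g2, 0) /
                (max(sigma_g2, 0) + max(sigma_e2, floor_)),
              log_likelihood = -0.5 * best[2],
              converged = evals <= max_iter,
              n_iterations = evals)
  class(out) <- "variance_components"
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("REML: sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f (%s, %d evals)\n",
              x$sigma_g2, x$sigma_e2, x$h2,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}
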