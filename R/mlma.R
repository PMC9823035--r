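#' Mixed-linear-model association with leave-one-chromosome-out GRMs
#'
#' For each chromosome `c`, variance components are estimated once by
#' [fit_reml()] under the GRM that excludes `c` (so the tested variant is
#' never part of its own relationship matrix), giving
#' \eqn{V = A_{loco}\sigma_g^2 + I\sigma_e^2}.  Each variant on `c` with
#' minor allele frequency at least `maf_min` is then tested by generalized
#' least squares: with \eqn{\tilde x, \tilde y} the genotype and trait
#' projected orthogonally to the fixed effects under the \eqn{V^{-1}}
#' metric,
#' \deqn{\hat\beta = \frac{\tilde x' V^{-1} \tilde y}{\tilde x' V^{-1} \tilde x},
#'   \quad se^2 = \frac{1}{\tilde x' V^{-1}\tilde x},}
#' and the p-value comes from \eqn{(\hat\beta/se)^2 \sim \chi^2_1}.
#' Missing dosages are mean-imputed; variants with a call rate below
#' `callrate_min` are skipped.
#'
#' @param gt a [simulate_genotypes()]-style genotype matrix.
#' @param pheno a data frame holding the trait and fixed-effect columns,
#'   sample-aligned with `gt` (or pass a bare numeric trait via `trait_values`).
#' @param covariates character vector of `pheno` columns used as fixed
#'   effects (factors become full-rank indicator contrasts with intercept);
#'   `character(0)` for intercept only.
#' @param trait name of the trait column in `pheno`.
#' @param trait_values optional numeric vector overriding `pheno[[trait]]`.
#' @param maf_min minor-allele-frequency threshold (default 0.01).
#' @param callrate_min minimum variant call rate.
#' @param loco_cache optional [make_loco_cache()] result to reuse
#'   eigendecompositions.
#' @param var_components optional list(sigma_g2, sigma_e2) to fix the
#'   variance components instead of estimating them (used for degenerate
#'   checks, e.g. `sigma_g2 = 0` reduces the scan to least squares).
#' @return a `gwas_result` data frame: `id`, `chrom`, `pos`, `maf`, `n`,
#'   `beta`, `se`, `p`, ordered by genome position, with attribute `vc`
#'   (per-chromosome variance components).
#' @export
mlma_loco <- function(gt, pheno, covariates = c("hatch"),
                      trait = "fpd_bc", trait_values = NULL,
                      maf_min = 0.01, callrate_min = 0.5,
                      loco_cache = NULL, var_components = NULL) {
  y <- if (!is.null(trait_values)) trait_values else pheno[[trait]]
  stopifnot(length(y) == nrow(gt$dosage))
  W <- build_design(pheno, covariates)
  chroms <- unique(gt$map$chrom)
  if (is.null(loco_cache) && is.null(var_components))
    loco_cache <- make_loco_cache(gt, chroms)
  res <- vector("list", length(chroms))
  vcs <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    on_ch <- which(gt$map$chrom == ch)
    X <- gt$dosage[, on_ch, drop = FALSE]
    cr <- colMeans(!is.na(X))
    p <- colMeans(X, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    keep <- which(cr >= callrate_min & maf >= maf_min)
    if (!length(keep)) {
      message("no variants pass the MAF/call-rate filters on ", ch)
      next
    }
    nobs <- round(cr[keep] * nrow(X))
    X <- impute_dosage(X[, keep, drop = FALSE])

    if (is.null(var_components)) {
      grm <- loco_cache[[ch]]
      vc <- fit_reml(y, W, grm)
      eig <- grm_eigen(grm)
      Uy <- drop(crossprod(eig$vectors, y))
      UW <- crossprod(eig$vectors, W)
      UX <- crossprod(eig$vectors, X)
      w <- 1 / (eig$values * vc$sigma_g2 + vc$sigma_e2)
    } else {
      vc <- var_components
      Uy <- y; UW <- W; UX <- X
      w <- rep(1 / (vc$sigma_g2 + vc$sigma_e2), length(y))
    }
    vcs[[ch]] <- vc
    sw <- sqrt(w)
    qW <- qr(UW * sw)
    yr <- qr.resid(qW, Uy * sw)
    xr <- qr.resid(qW, UX * sw)
    xtx <- colSums(xr^2)
    beta <- colSums(xr * yr) / xtx
    se <- sqrt(1 / xtx)
    pval <- stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
    res[[ci]] <- data.frame(id = gt$map$id[on_ch][keep], chrom = ch,
                            pos = gt$map$pos[on_ch][keep],
                            maf = unname(maf[keep]), n = unname(nobs),
                            beta = unname(beta), se = unname(se),
                            p = unname(pval), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(id = character(0), chrom = character(0),
                                      pos = integer(0), maf = numeric(0),
                                      n = integer(0), beta = numeric(0),
                                      se = numeric(0), p = numeric(0))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gwas_result", "data.frame")
  attr(out, "vc") <- vcs
  out
}

# fixed-effect design: intercept + full-rank contrasts for each covariate
build_design <- function(pheno, covariates) {
  n <- nrow(pheno)
  if (length(covariates) == 0)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  covariates <- covariates[vapply(covariates, function(cv) {
    v <- pheno[[cv]]
    if (is.null(v)) stop("covariate column not found: ", cv)
    length(unique(v[!is.na(v)])) > 1          # drop constant columns
  }, logical(1))]
  if (length(covariates) == 0)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(stats::reformulate(covariates), data = pheno)
}

#' Proportion of phenotypic variance explained by one variant
#'
#' \eqn{PVE = \beta^2 Var(X) / Var(Y)} with
#' \eqn{Var(Y) = \beta^2 Var(X) + \sigma^2}; supply either `var_y` or the
#' remaining variance `sigma2`.  The estimate is clipped to \[0, 1\].
#'
#' @param beta estimated allele-substitution effect.
#' @param var_x genotype variance of the variant.
#' @param var_y phenotypic variance (if known directly).
#' @param sigma2 remaining variance (used when `var_y` is `NULL`).
#' @return PVE as a fraction in \[0, 1\].
#' @export
estimate_pve <- function(beta, var_x, var_y = NULL, sigma2 = NULL) {
  stopifnot(var_x >= 0)
  if (is.null(var_y)) {
    if (is.null(sigma2)) stop("supply var_y or sigma2")
    var_y <- beta^2 * var_x + sigma2
  }
  if (any(var_y <= 0)) stop("var_y must be positive")
  pmin(pmax(beta^2 * var_x / var_y, 0), 1)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param m number of tests (variants screened).
#' @param alpha family-wise error rate.
#' @return per-test p-value threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1 || !is.finite(m) || m < 1) stop("m must be >= 1")
  alpha / m
}
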