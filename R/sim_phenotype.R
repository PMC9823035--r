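#' Simulate the behavioural phenotype
#'
#' Builds a Gaussian trait on the scale of an already Box-Cox-transformed
#' count (the feather-pecks-delivered phenotype):
#' \deqn{y = \mathrm{hatch} + \mathrm{line} + \sum_j \beta_j x_j + g + e}
#' where the QTL effects \eqn{\beta_j} are solved from their target PVE via
#' \eqn{PVE = \beta^2 Var(x) / Var(y)}, the polygenic term \eqn{g} is an
#' infinitesimal sum of per-marker effects rescaled so that its realized
#' variance fraction equals `h2_polygenic` exactly, and the residual makes
#' the non-fixed-effect variance 1.  QTL markers are excluded from the
#' polygenic sum so the decomposition is clean.
#'
#' @param gt a [simulate_genotypes()] object.
#' @param cfg the matching [new_sim_config()].
#' @param truth the matching [simulate_truth()] set (QTL assignments).
#' @return a `pheno_table` data frame with columns `sample_id`, `fpd_bc`,
#'   `hatch`, `line`, carrying an attribute `realized` (realized variance
#'   fractions and solved QTL betas).
#' @export
simulate_phenotype <- function(gt, cfg, truth) {
  stopifnot(inherits(gt, "genotype_matrix"))
  qtl <- truth$qtl
  if (!is.null(qtl) && any(qtl$variant > ncol(gt$dosage)))
    stop("truth QTL index outside the genotype matrix")
  if (cfg$h2_polygenic + total_qtl_pve(cfg) >= 1)
    stop("requested variance fractions total >= 1")
  with_seed(child_seed(cfg, "phenotype"), {
    n <- nrow(gt$dosage)
    X <- impute_dosage(gt$dosage)

    hatch <- factor(sample.int(cfg$n_hatches, n, replace = TRUE),
                    labels = paste0("H", seq_len(cfg$n_hatches)))
    hatch_eff <- rnorm(cfg$n_hatches, 0, cfg$hatch_sd)
    line <- if (cfg$two_lines) {
      factor(sample(c("HFP", "LFP"), n, replace = TRUE), c("HFP", "LFP"))
    } else factor(rep("F2", n))
    line_eff <- if (cfg$two_lines) {
      ifelse(line == "HFP", cfg$line_diff / 2, -cfg$line_diff / 2)
    } else rep(0, n)

    y <- hatch_eff[as.integer(hatch)] + line_eff

    betas <- numeric(0)
    qtl_part <- rep(0, n)
    if (!is.null(qtl) && nrow(qtl)) {
      betas <- vapply(seq_len(nrow(qtl)), function(i) {
        x <- X[, qtl$variant[i]]
        vx <- stats::var(x)
        if (vx <= 0) stop("QTL marker is monomorphic in this draw")
        sqrt(qtl$pve[i] / vx)
      }, numeric(1))
      for (i in seq_len(nrow(qtl)))
        qtl_part <- qtl_part + betas[i] * X[, qtl$variant[i]]
      qtl$beta <- betas
    }

    g <- rep(0, n)
    if (cfg$h2_polygenic > 0) {
      keep <- setdiff(seq_len(ncol(X)), if (is.null(qtl)) integer(0)
                      else qtl$variant)
      Z <- scale(X[, keep, drop = FALSE])
      Z[, attr(Z, "scaled:scale") == 0] <- 0
      g <- drop(Z %*% rnorm(ncol(Z)))
      g <- g / stats::sd(g) * sqrt(cfg$h2_polygenic)
    }

    sigma2_e <- 1 - cfg$h2_polygenic - total_qtl_pve(cfg)
    e <- rnorm(n, 0, sqrt(sigma2_e))
    y <- y + qtl_part + g + e

    vy <- stats::var(y)
    realized <- list(
      h2 = stats::var(g) / vy,
      sigma_g2 = stats::var(g), sigma_e2 = sigma2_e,
      qtl = if (is.null(qtl)) NULL else
        transform(qtl, realized_pve = betas^2 *
                    apply(X[, qtl$variant, drop = FALSE], 2, stats::var) / vy),
      var_y = vy)

    out <- data.frame(sample_id = rownames(gt$dosage), fpd_bc = y,
                      hatch = hatch, line = line, stringsAsFactors = FALSE)
    class(out) <- c("pheno_table", "data.frame")
    attr(out, "realized") <- realized
    out
  })
}
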