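#' Compute a genomic relationship matrix (optionally leave-one-chromosome-out)
#'
#' VanRaden-style standardized cross-product:
#' \deqn{A_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}{2p_i(1-p_i)}}
#' over the markers `i` not on `exclude_chrom`, with `p_i` the sample allele
#' frequency.  Missing dosages are mean-imputed (to `2 p_i`) and monomorphic
#' markers are skipped.
#'
#' @param gt a [simulate_genotypes()] object, or any list with `dosage`
#'   (samples x markers) and `map` (with a `chrom` column).
#' @param exclude_chrom chromosome label to leave out, or `NULL` for all
#'   markers.
#' @return an object of class `grm`: list with `A` (n x n), `samples`,
#'   `m_markers`, `exclude_chrom`.
#' @export
compute_grm <- function(gt, exclude_chrom = NULL) {
  X <- gt$dosage
  if (!is.null(exclude_chrom)) {
    keep <- gt$map$chrom != exclude_chrom
    X <- X[, keep, drop = FALSE]
  }
  X <- impute_dosage(X)
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(X)
  if (m < 2) stop("fewer than 2 polymorphic markers available for the GRM")
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(Z) / m
  structure(list(A = A, samples = rownames(gt$dosage), m_markers = m,
                 exclude_chrom = exclude_chrom),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$A), "samples from", x$m_markers, "markers",
      if (!is.null(x$exclude_chrom))
        paste0("(excluding ", x$exclude_chrom, ")"), "\n")
  invisible(x)
}

# eigendecomposition cache for a GRM; reused across REML fits and scans
grm_eigen <- function(grm) {
  if (!is.null(grm$eig)) return(grm$eig)
  e <- eigen(grm$A, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  e
}

#' Precompute leave-one-chromosome-out GRM eigendecompositions
#'
#' One `compute_grm()` + eigendecomposition per chromosome, reusable across
#' traits (the main phenotype scan and all eGWAS scans share them).
#'
#' @param gt a genotype matrix object.
#' @param chroms chromosomes to cover (default: all in the map).
#' @return named list of `grm` objects with an `eig` element.
#' @export
make_loco_cache <- function(gt, chroms = NULL) {
  if (is.null(chroms)) chroms <- unique(gt$map$chrom)
  out <- lapply(chroms, function(ch) {
    g <- compute_grm(gt, exclude_chrom = ch)
    g$eig <- grm_eigen(g)
    g
  })
  names(out) <- chroms
  out
}
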