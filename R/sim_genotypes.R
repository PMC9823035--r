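#' Simulate a genotype matrix with tunable local LD
#'
#' Generates diploid dosages (0/1/2) for `n_samples` individuals at
#' `n_chromosomes * n_variants_per_chrom` markers.  Haplotypes follow a
#' first-order copying process: each marker either reuses the previous
#' marker's latent uniform (probability `ld_decay`) or draws a fresh one, and
#' the allele is the indicator that the uniform falls below the marker's
#' allele frequency.  When adjacent allele frequencies match, the adjacent
#' haplotype (and dosage) correlation equals `ld_decay`; `ld_decay = 0`
#' gives independent markers.  Two haplotypes are summed into a dosage.
#'
#' @param cfg a [new_sim_config()] object.
#' @return an object of class `genotype_matrix`: a list with `dosage`
#'   (samples x markers integer matrix, `NA` for missing) and `map`
#'   (data frame: `id`, `chrom`, `pos`, `type`).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(child_seed(cfg, "genotypes"), {
    n <- cfg$n_samples
    mper <- cfg$n_variants_per_chrom
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    dose <- vector("list", cfg$n_chromosomes)
    maps <- vector("list", cfg$n_chromosomes)
    for (ci in seq_along(chroms)) {
      p <- runif(mper, cfg$maf_range[1], cfg$maf_range[2])
      pos <- sort(sample.int(cfg$chrom_length, mper))
      U <- matrix(runif(2L * n * mper), nrow = 2L * n, ncol = mper)
      if (cfg$ld_decay > 0 && mper > 1L) {
        for (j in 2:mper) {
          copy <- runif(2L * n) < cfg$ld_decay
          U[copy, j] <- U[copy, j - 1L]
        }
      }
      hap <- U < matrix(p, nrow = 2L * n, ncol = mper, byrow = TRUE)
      X <- hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
        hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
      storage.mode(X) <- "integer"
      dose[[ci]] <- X
      maps[[ci]] <- data.frame(id = paste0(chroms[ci], "_", pos),
                               chrom = chroms[ci], pos = pos,
                               type = "SNP", stringsAsFactors = FALSE)
    }
    dosage <- do.call(cbind, dose)
    map <- do.call(rbind, maps)
    rownames(map) <- NULL
    dimnames(dosage) <- list(sprintf("S%04d", seq_len(n)), map$id)
    if (cfg$missing_rate > 0) {
      miss <- which(runif(length(dosage)) < cfg$missing_rate)
      dosage[miss] <- NA_integer_
    }
    structure(list(dosage = dosage, map = map), class = "genotype_matrix")
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "markers on", length(unique(x$map$chrom)), "chromosomes\n")
  invisible(x)
}

# mean-impute missing dosages column-wise (used in GRM and association math)
impute_dosage <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}
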