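#' Simulate normalized gene expression with a TF hub
#'
#' Expression of each gene is its cis-eQTL effect (from the truth set's
#' gene-to-variant map) plus Gaussian noise; target genes of the
#' transcription-factor hub additionally receive `effect * hub expression`,
#' so their expression scans (eGWAS) pick up the hub gene's eQTL variant.
#' Expression is emitted on an already-normalized (Gaussian) scale.
#'
#' @param gt a [simulate_genotypes()] object.
#' @param cfg the matching [new_sim_config()].
#' @param truth the matching [simulate_truth()] set.
#' @return an `expression_table`: `n_expr_samples` x `n_genes` numeric
#'   matrix with sample/gene dimnames.
#' @export
simulate_expression <- function(gt, cfg, truth) {
  stopifnot(inherits(gt, "genotype_matrix"))
  if (cfg$n_expr_samples > nrow(gt$dosage))
    stop("n_expr_samples exceeds the number of genotyped samples")
  hub <- cfg$tf_hub
  if (!is.null(hub) && any(c(hub$hub, hub$targets) > cfg$n_genes))
    stop("tf_hub gene indices out of range")
  with_seed(child_seed(cfg, "expression"), {
    ns <- cfg$n_expr_samples
    X <- impute_dosage(gt$dosage)[seq_len(ns), , drop = FALSE]
    genes <- truth$eqtl$gene
    E <- matrix(0, nrow = ns, ncol = cfg$n_genes,
                dimnames = list(rownames(X), genes))
    cis <- X[, truth$eqtl$variant, drop = FALSE] *
      matrix(truth$eqtl$effect, ns, cfg$n_genes, byrow = TRUE)
    noise <- matrix(rnorm(ns * cfg$n_genes, 0, cfg$expr_noise_sd),
                    ns, cfg$n_genes)
    E[] <- cis + noise
    if (!is.null(hub) && length(hub$targets) && hub$effect != 0) {
      E[, hub$targets] <- E[, hub$targets] + hub$effect * E[, hub$hub]
    }
    structure(E, class = c("expression_table", class(E)))
  })
}
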