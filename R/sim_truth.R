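#' Generate the ground-truth set for a simulation
#'
#' Draws everything downstream stages are checked against: QTL assignments,
#' the gene annotation (TSS per gene), the cis-eQTL map with the
#' transcription-factor hub, the true structural-variant (SV) records with
#' per-sample genotypes, and the foreground set of genes that will carry
#' planted promoter motifs.
#'
#' True SV start positions on a chromosome are kept at least 3,001 bp apart
#' so that distinct true events can never fall within the default 1,000-bp
#' merging distance of each other; merged counts are then identifiable
#' against the truth.
#'
#' @param cfg a [new_sim_config()] object.
#' @param n_motif_genes number of foreground (motif-planted) genes.
#' @return an object of class `truth_set`: a list with elements `qtl`,
#'   `genes`, `eqtl`, `sv`, `sv_gt`, and `motif_genes`.
#' @export
simulate_truth <- function(cfg, n_motif_genes = 23L) {
  validate_sim_config(cfg)
  with_seed(child_seed(cfg, "truth"), {
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    m <- cfg$n_chromosomes * cfg$n_variants_per_chrom

    qtl <- cfg$qtl_spec
    if (!is.null(qtl)) {
      qtl <- data.frame(variant = as.integer(qtl$variant), pve = qtl$pve,
                        beta = NA_real_)
    }

    gene_names <- sprintf("gene_%03d", seq_len(cfg$n_genes))
    genes <- data.frame(
      gene = gene_names,
      chrom = sample(chroms, cfg$n_genes, replace = TRUE),
      tss = sample.int(cfg$chrom_length, cfg$n_genes, replace = TRUE),
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      stringsAsFactors = FALSE)

    # each gene gets a distinct cis-eQTL marker; the hub gene's eQTL is the
    # variant whose eGWAS signal should surface in every target gene scan
    eqtl <- data.frame(
      gene = gene_names,
      variant = sample.int(m, cfg$n_genes, replace = FALSE),
      effect = rep(cfg$eqtl_effect, cfg$n_genes),
      stringsAsFactors = FALSE)

    sv <- simulate_sv_records(cfg, chroms)
    sv_maf <- runif(cfg$n_sv, 0.05, 0.5)
    sv_gt <- matrix(rbinom(cfg$n_sv * cfg$n_samples, 2L,
                           rep(sv_maf, cfg$n_samples)),
                    nrow = cfg$n_sv, ncol = cfg$n_samples)
    rownames(sv_gt) <- sv$truth_id
    colnames(sv_gt) <- sprintf("S%04d", seq_len(cfg$n_samples))

    n_motif_genes <- min(as.integer(n_motif_genes), cfg$n_genes)
    motif_genes <- sort(sample(gene_names, n_motif_genes))

    structure(list(qtl = qtl, genes = genes, eqtl = eqtl, sv = sv,
                   sv_maf = sv_maf, sv_gt = sv_gt,
                   motif_genes = motif_genes),
              class = "truth_set")
  })
}

# true SV records; start positions >= 3001 bp apart within a chromosome
simulate_sv_records <- function(cfg, chroms) {
  min_gap <- 3001
  chrom <- sort(sample(chroms, cfg$n_sv, replace = TRUE))
  per <- table(chrom)
  starts <- unlist(lapply(names(per), function(ch) {
    k <- per[[ch]]
    avail <- cfg$chrom_length - (k - 1) * min_gap
    if (avail < k) stop("chromosome too short for requested SV count")
    sort(sample.int(avail, k)) + (seq_len(k) - 1L) * min_gap
  }), use.names = FALSE)
  type <- sample(c("DEL", "DUP", "INV", "TRA"), cfg$n_sv, replace = TRUE,
                 prob = c(0.54, 0.25, 0.12, 0.09))
  size <- round(runif(cfg$n_sv, cfg$sv_size_range[1], cfg$sv_size_range[2]))
  strands <- t(vapply(type, sv_type_strands, character(2)))
  data.frame(truth_id = sprintf("sv_%04d", seq_len(cfg$n_sv)),
             chrom = chrom, start = starts,
             end = starts + size - 1L, sv_type = type,
             strand1 = strands[, 1], strand2 = strands[, 2],
             stringsAsFactors = FALSE)
}

# conventional strand pairs per SV type (inversions pick one orientation)
sv_type_strands <- function(type) {
  switch(type,
         DEL = c("+", "-"),
         DUP = c("-", "+"),
         INV = if (runif(1) < 0.5) c("+", "+") else c("-", "-"),
         TRA = sample(c("+", "-"), 2, replace = TRUE),
         stop("unknown SV type: ", type))
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$sv), "true SVs,", nrow(x$eqtl), "eQTL genes,",
      length(x$motif_genes), "motif-planted genes\n")
  if (!is.null(x$qtl)) cat("  QTL at marker(s)",
                           paste(x$qtl$variant, collapse = ", "),
                           "with PVE", paste(x$qtl$pve, collapse = ", "), "\n")
  invisible(x)
}
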