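#' Expression GWAS: one mixed-model scan per gene
#'
#' Runs [mlma_loco()] once per expression trait over the same variant panel,
#' with hatch (by default) as the fixed-effect covariate.  Genes with zero
#' expression variance are skipped with a message.  The leave-one-
#' chromosome-out GRM eigendecompositions are computed once on the
#' expression subset of samples and shared by all scans.
#'
#' @param gt genotype matrix covering at least the expression samples.
#' @param expr an [simulate_expression()] matrix (samples x genes).
#' @param pheno phenotype/covariate table for the genotyped samples.
#' @param covariates fixed-effect columns of `pheno` (default hatch).
#' @param maf_min minor-allele-frequency threshold.
#' @param loco_cache optional precomputed [make_loco_cache()] for the
#'   expression subset.
#' @return an `egwas_set`: named list of `gwas_result` data frames, one per
#'   gene, all over the same variant key space.
#' @export
run_egwas <- function(gt, expr, pheno, covariates = c("hatch"),
                      maf_min = 0.01, loco_cache = NULL) {
  samples <- rownames(expr)
  idx <- match(samples, rownames(gt$dosage))
  if (anyNA(idx)) stop("expression samples missing from the genotype matrix")
  gt_sub <- structure(list(dosage = gt$dosage[idx, , drop = FALSE],
                           map = gt$map), class = "genotype_matrix")
  ph <- pheno[match(samples, pheno$sample_id), , drop = FALSE]
  if (is.null(loco_cache)) loco_cache <- make_loco_cache(gt_sub)
  out <- list()
  for (g in colnames(expr)) {
    yg <- expr[, g]
    if (stats::var(yg) <= 0) {
      message("skipping constant-expression gene ", g)
      next
    }
    out[[g]] <- mlma_loco(gt_sub, ph, covariates = covariates,
                          trait_values = yg, maf_min = maf_min,
                          loco_cache = loco_cache)
  }
  structure(out, class = "egwas_set")
}

#' Select variants for the association weight matrix
#'
#' A variant enters the AWM when its main-trait p-value is below `p_thresh`
#' OR it reaches `p < p_thresh` in at least `min_egwas_hits` of the
#' expression scans.  (Defaults: `1e-4` and 10, the study's rules.)
#' Selection order is deterministic (genome position).
#'
#' @param main `gwas_result` for the main phenotype.
#' @param egwas an [run_egwas()] set.
#' @param p_thresh selection p-value threshold.
#' @param min_egwas_hits minimum number of expression scans below threshold.
#' @return character vector of selected variant IDs, with attribute
#'   `egwas_hits` (named hit counts for all variants).
#' @export
select_awm_variants <- function(main, egwas, p_thresh = 1e-4,
                                min_egwas_hits = 10L) {
  ids <- main$id
  hits <- integer(length(ids))
  names(hits) <- ids
  for (r in egwas) {
    i <- match(r$id, ids)
    ok <- !is.na(i)
    hits[i[ok]] <- hits[i[ok]] + as.integer(r$p[ok] < p_thresh)
  }
  sel <- main$p < p_thresh | hits >= min_egwas_hits
  ord <- order(main$chrom, main$pos)
  out <- main$id[ord][sel[ord]]
  attr(out, "egwas_hits") <- hits
  out
}

#' Build the association weight matrix
#'
#' Rows are the selected variants, columns the traits (main trait first,
#' then every expression trait); entries are signed association z-scores
#' \eqn{z = \beta / se}.  A cell whose underlying scan did not test the
#' variant (e.g. MAF-filtered in that scan) is filled with 0.  Columns can
#' optionally be standardized.
#'
#' @param selected variant IDs from [select_awm_variants()].
#' @param main main-trait `gwas_result`.
#' @param egwas an [run_egwas()] set.
#' @param main_name column label for the main trait.
#' @param standardize standardize columns to unit variance.
#' @param gene_annotation optional data frame (`gene`, `chrom`, `tss`) used
#'   to annotate each variant with its nearest gene.
#' @return an `awm` matrix (variants x traits) with attribute
#'   `variant_gene` (nearest assigned gene per row, if annotated).
#' @export
build_awm <- function(selected, main, egwas, main_name = "fpd_bc",
                      standardize = FALSE, gene_annotation = NULL) {
  if (length(selected) == 0) stop("empty variant selection for the AWM")
  traits <- c(main_name, names(egwas))
  Z <- matrix(0, length(selected), length(traits),
              dimnames = list(selected, traits))
  fill <- function(col, r) {
    i <- match(selected, r$id)
    ok <- !is.na(i)
    Z[ok, col] <<- r$beta[i[ok]] / r$se[i[ok]]
  }
  fill(main_name, main)
  for (g in names(egwas)) fill(g, egwas[[g]])
  if (standardize) {
    s <- apply(Z, 2, stats::sd)
    s[s == 0] <- 1
    Z <- sweep(Z, 2, s, "/")
  }
  if (!is.null(gene_annotation)) {
    m <- main[match(selected, main$id), c("chrom", "pos")]
    attr(Z, "variant_gene") <- assign_nearest_gene(m, gene_annotation)
  }
  class(Z) <- c("awm", class(Z))
  Z
}

# nearest annotated gene (by |pos - tss| on the same chromosome) per variant
assign_nearest_gene <- function(variants, genes) {
  vapply(seq_len(nrow(variants)), function(i) {
    g <- genes[genes$chrom == variants$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(NA_character_)
    g$gene[which.min(abs(g$tss - variants$pos[i]))]
  }, character(1))
}
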