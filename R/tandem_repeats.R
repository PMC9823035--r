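#' Construct a tandem-repeat call set
#'
#' Models the genotyped output of a TR caller: per-variant motif and
#' position plus per-sample copy-number genotypes with sequencing depth
#' (DP) and a quality score (Q in \[0, 1\]).
#'
#' @param records data frame with columns `id`, `chrom`, `pos`, `motif`.
#' @param gt variants x samples copy-number genotype matrix (`NA` missing).
#' @param dp,q matrices of the same shape: read depth and quality.
#' @return an object of class `tr_callset`.
#' @export
tr_callset <- function(records, gt, dp, q) {
  stopifnot(nrow(records) == nrow(gt), all(dim(gt) == dim(dp)),
            all(dim(gt) == dim(q)))
  if (any(dp < 0, na.rm = TRUE)) stop("DP must be non-negative")
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("Q must lie in [0, 1]")
  structure(list(records = records, gt = gt, dp = dp, q = q),
            class = "tr_callset")
}

#' Filter tandem-repeat genotypes and variants
#'
#' Per-sample genotypes with depth `DP < min_dp` or quality `Q <= min_q`
#' (the quality cut is strict: "higher than" the threshold) are set
#' missing; variants whose resulting call rate falls below `min_callrate`
#' are removed.  Defaults are the study's TR filters (DP 10, Q 0.8, call
#' rate 0.8).  Idempotent.
#'
#' @param calls a [tr_callset()].
#' @param min_dp minimum per-sample depth (inclusive).
#' @param min_q per-sample quality threshold (exclusive).
#' @param min_callrate minimum variant call rate after masking.
#' @return a filtered `tr_callset`.
#' @export
filter_tr <- function(calls, min_dp = 10, min_q = 0.8, min_callrate = 0.8) {
  stopifnot(inherits(calls, "tr_callset"))
  gt <- calls$gt
  mask <- (calls$dp < min_dp) | (calls$q <= min_q)
  mask[is.na(mask)] <- TRUE
  gt[mask] <- NA
  cr <- rowMeans(!is.na(gt))
  keep <- cr >= min_callrate
  tr_callset(calls$records[keep, , drop = FALSE],
             gt[keep, , drop = FALSE],
             calls$dp[keep, , drop = FALSE],
             calls$q[keep, , drop = FALSE])
}

#' Split multiallelic variants into biallelic records
#'
#' A variant with `k` alternate alleles becomes `k` biallelic records (the
#' reference versus each alternate); each sample's dosage in a split record
#' is its copy count of that alternate allele.  Split record IDs are
#' suffixed `_a1 ... _ak`; biallelic inputs pass through with their IDs
#' unchanged.  Allele counts are conserved: the per-sample sum of alternate
#' dosages over the split records equals the sample's total alternate
#' allele count at the original variant.
#'
#' @param variants list of variants, each a list with `id`, `alleles`
#'   (character vector of alternate allele labels) and `genotypes`
#'   (samples x 2 matrix of allele codes: 0 = reference, `i` = i-th
#'   alternate, `NA` = missing).
#' @return list with `records` (data frame: `id`, `source_id`, `allele`)
#'   and `dosage` (split records x samples matrix, `NA` where the source
#'   genotype was missing).
#' @export
split_multiallelic <- function(variants) {
  stopifnot(is.list(variants))
  recs <- list()
  rows <- list()
  for (v in variants) {
    k <- length(v$alleles)
    stopifnot(k >= 1, ncol(v$genotypes) == 2)
    g <- v$genotypes
    miss <- is.na(g[, 1]) | is.na(g[, 2])
    for (a in seq_len(k)) {
      dose <- rowSums(g == a)
      dose[miss] <- NA
      id <- if (k == 1) v$id else paste0(v$id, "_a", a)
      recs[[length(recs) + 1L]] <- data.frame(
        id = id, source_id = v$id, allele = v$alleles[a],
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- dose
    }
  }
  records <- do.call(rbind, recs)
  dosage <- do.call(rbind, rows)
  rownames(dosage) <- records$id
  list(records = records, dosage = dosage)
}
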