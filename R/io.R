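# TSV/FASTA writers and readers for the pipeline's fixed file contracts.

#' Write / read a dosage matrix as TSV (samples x variants)
#' @param gt a `genotype_matrix`.
#' @param path output path (two files: `<path>` and `<path>.map`).
#' @return the path, invisibly.
#' @export
write_dosage_tsv <- function(gt, path) {
  d <- as.data.frame(gt$dosage)
  d <- cbind(sample_id = rownames(gt$dosage), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gt$map, paste0(path, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  map <- utils::read.table(paste0(path, ".map"), sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  X <- as.matrix(d[, -1, drop = FALSE])
  rownames(X) <- d$sample_id
  structure(list(dosage = X, map = map), class = "genotype_matrix")
}

#' Write an SV call set (merged or per-caller) as a VCF-like TSV
#'
#' One row per record: coordinates, type, strands, QUAL, then per-sample
#' genotype columns (`.` for missing).
#' @param callset an `sv_callset` or `merged_callset`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_callset_tsv <- function(callset, path) {
  rec <- callset$records
  gt <- callset$gt
  gtc <- matrix(as.character(gt), nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
  gtc[is.na(gtc)] <- "."
  out <- cbind(rec, as.data.frame(gtc, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association result table
#' @param res a `gwas_result` (or meta-analysis) data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_assoc_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Write the AWM as a TSV (variants x traits)
#' @param awm a [build_awm()] matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_awm_tsv <- function(awm, path) {
  d <- cbind(variant = rownames(awm), as.data.frame(unclass(awm)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
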