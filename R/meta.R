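#' Sample-size-weighted GWAS meta-analysis (Stouffer/METAL scheme)
#'
#' Per shared variant, each study's two-sided p-value is converted to a
#' signed Z score, \eqn{Z_i = \Phi^{-1}(1 - p_i/2)\,\mathrm{sign}(\beta_i)},
#' and combined with square-root-sample-size weights
#' \eqn{w_i = \sqrt{n_i}}:
#' \deqn{Z = \frac{\sum_i w_i Z_i}{\sqrt{\sum_i w_i^2}}, \qquad
#'       p = 2(1 - \Phi(|Z|)).}
#' Variants present in only one study carry that study's Z through.
#' Zero p-values are clamped to the smallest representable positive double
#' (with a message); a zero effect sign contributes Z = 0.
#'
#' @param results named list (>= 2 entries unless `allow_single`) of
#'   `gwas_result` data frames sharing variant IDs.
#' @param allow_single permit a single study (identity pass-through).
#' @return data frame: `id`, `chrom`, `pos`, `n_studies`, `n_total`, `z`,
#'   `p`, ordered by genome position.
#' @export
meta_sample_size <- function(results, allow_single = FALSE) {
  stopifnot(is.list(results), length(results) >= if (allow_single) 1L else 2L)
  for (r in results) stopifnot(all(c("id", "beta", "p", "n") %in% names(r)),
                               all(r$n > 0))
  ids <- unique(unlist(lapply(results, `[[`, "id")))
  zmat <- matrix(NA_real_, length(ids), length(results),
                 dimnames = list(ids, NULL))
  wmat <- matrix(NA_real_, length(ids), length(results))
  nmat <- matrix(0, length(ids), length(results))
  clamped <- 0L
  for (si in seq_along(results)) {
    r <- results[[si]]
    p <- r$p
    zero <- p <= 0
    if (any(zero)) { p[zero] <- .Machine$double.xmin; clamped <- clamped + sum(zero) }
    z <- stats::qnorm(p / 2, lower.tail = FALSE) * sign(r$beta)
    i <- match(r$id, ids)
    zmat[i, si] <- z
    wmat[i, si] <- sqrt(r$n)
    nmat[i, si] <- r$n
  }
  if (clamped > 0) message(clamped, " zero p-value(s) clamped before Z conversion")
  num <- rowSums(wmat * zmat, na.rm = TRUE)
  den <- sqrt(rowSums(wmat^2, na.rm = TRUE))
  zc <- num / den
  pc <- 2 * stats::pnorm(abs(zc), lower.tail = FALSE)
  ann <- do.call(rbind, lapply(results, function(r)
    r[, intersect(c("id", "chrom", "pos"), names(r)), drop = FALSE]))
  ann <- ann[!duplicated(ann$id), , drop = FALSE]
  out <- data.frame(id = ids,
                    n_studies = rowSums(!is.na(zmat)),
                    n_total = rowSums(nmat),
                    z = unname(zc), p = unname(pc),
                    stringsAsFactors = FALSE)
  out <- merge(out, ann, by = "id", all.x = TRUE, sort = FALSE)
  cols <- intersect(c("id", "chrom", "pos", "n_studies", "n_total", "z", "p"),
                    names(out))
  out <- out[, cols]
  if (all(c("chrom", "pos") %in% names(out)))
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
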