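#' Scan a promoter window for motif hits
#'
#' Scores every start position on both strands of the window
#' `[TSS - upstream, TSS + downstream)` with the PWM's log-odds matrix
#' (reverse strand = the reverse-complemented matrix at the same forward
#' coordinates) and reports the positions whose score reaches
#' \deqn{min + threshold\_frac \cdot (max - min)}
#' where min/max are the matrix's attainable score bounds.  A window
#' extending past the sequence is truncated with a warning.  Offsets are
#' reported relative to the TSS.
#'
#' @param sequence a character string or [Biostrings::DNAString].
#' @param pwm a [load_jaspar()] model.
#' @param tss_offset 1-based position of the TSS within `sequence`.
#' @param upstream,downstream scan limits in bp (defaults 1500/500, the
#'   study's window).
#' @param threshold_frac fraction of the attainable score range, in (0, 1].
#' @return data frame of hits: `offset` (bp relative to TSS), `strand`,
#'   `score`.
#' @export
scan_gene_window <- function(sequence, pwm, tss_offset,
                             upstream = 1500, downstream = 500,
                             threshold_frac = 0.85) {
  stopifnot(threshold_frac > 0, threshold_frac <= 1)
  seq_chr <- toupper(as.character(sequence))
  len <- nchar(seq_chr)
  stopifnot(tss_offset >= 1, tss_offset <= len)
  L <- ncol(pwm$log_odds)
  wstart <- tss_offset - upstream
  wend <- tss_offset + downstream - 1
  if (wstart < 1 || wend > len) {
    warning("scan window extends past the sequence; truncated")
    wstart <- max(wstart, 1)
    wend <- min(wend, len)
  }
  last <- wend - L + 1
  if (last < wstart)
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  code <- match(strsplit(substr(seq_chr, wstart, wend), "")[[1]],
                c("A", "C", "G", "T"))
  npos <- length(code) - L + 1
  rng <- pwm_score_range(pwm)
  thr <- rng["min"] + threshold_frac * (rng["max"] - rng["min"])
  lo_f <- pwm$log_odds
  lo_r <- revcomp_matrix(lo_f)
  score_with <- function(lo) {
    s <- numeric(npos)
    for (j in seq_len(L)) {
      b <- code[j:(j + npos - 1)]
      v <- lo[cbind(b, j)]
      v[is.na(b)] <- -Inf           # ambiguous base never matches
      s <- s + v
    }
    s
  }
  sf <- score_with(lo_f)
  sr <- score_with(lo_r)
  hit_f <- which(sf >= thr - 1e-9)
  hit_r <- which(sr >= thr - 1e-9)
  out <- data.frame(
    offset = c(hit_f, hit_r) + (wstart - 1) - tss_offset,
    strand = c(rep("+", length(hit_f)), rep("-", length(hit_r))),
    score = c(sf[hit_f], sr[hit_r]), stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# reverse-complement a 4 x L log-odds (or count) matrix:
# out[b, j] = m[complement(b), L + 1 - j]
revcomp_matrix <- function(m) {
  out <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Scan a set of promoters and count hits per gene
#'
#' Equal-length promoters sharing one TSS position are scored in a single
#' vectorized pass (all genes at once); mixed-length inputs fall back to a
#' per-gene [scan_gene_window()] loop.  Both paths apply the same window
#' and threshold rule.
#'
#' @param seqs named character vector or [Biostrings::DNAStringSet] of
#'   promoter sequences.
#' @param pwm a `pwm_model`.
#' @param tss_offset TSS position within each promoter (scalar).
#' @param upstream,downstream,threshold_frac as in [scan_gene_window()].
#' @return list with `counts` (named per-gene hit counts) and `hits`
#'   (data frame: gene, offset, strand, score).
#' @export
scan_promoters <- function(seqs, pwm, tss_offset, upstream = 1500,
                           downstream = 500, threshold_frac = 0.85) {
  genes <- names(seqs)
  stopifnot(!is.null(genes))
  schr <- toupper(as.character(seqs))
  lens <- nchar(schr)
  L <- ncol(pwm$log_odds)
  if (length(unique(lens)) == 1 && tss_offset - upstream >= 1 &&
      tss_offset + downstream - 1 <= lens[1]) {
    n <- length(schr)
    lut <- rep(NA_integer_, 128)
    lut[utf8ToInt("ACGT")] <- 1:4
    wstart <- tss_offset - upstream
    wend <- tss_offset + downstream - 1
    # one flattened vector over all windows; window positions that would
    # run into the next gene's sequence are masked out afterwards
    x <- lut[utf8ToInt(paste(substr(schr, wstart, wend), collapse = ""))]
    x[is.na(x)] <- 5L                      # ambiguous base: never matches
    W <- wend - wstart + 1
    npos <- W - L + 1
    total <- n * W
    rng <- pwm_score_range(pwm)
    thr <- rng["min"] + threshold_frac * (rng["max"] - rng["min"])
    score_flat <- function(lo) {
      s <- numeric(total - L + 1)
      for (j in seq_len(L)) {
        col <- c(lo[, j], -Inf)
        s <- s + col[x[j:(total - L + j)]]
      }
      s
    }
    sf <- score_flat(pwm$log_odds)
    sr <- score_flat(revcomp_matrix(pwm$log_odds))
    collect <- function(s, strand) {
      p <- which(s >= thr - 1e-9)
      within <- ((p - 1L) %% W) + 1L       # offset inside the window
      keep <- within <= npos
      p <- p[keep]; within <- within[keep]
      data.frame(gene = genes[((p - 1L) %/% W) + 1L],
                 offset = within + (wstart - 1L) - tss_offset,
                 strand = rep(strand, length(p)), score = s[p],
                 stringsAsFactors = FALSE)
    }
    hits <- rbind(collect(sf, "+"), collect(sr, "-"))
    counts <- table(factor(hits$gene, levels = genes))
    counts <- stats::setNames(as.integer(counts), genes)
    hits <- hits[order(match(hits$gene, genes), hits$offset, hits$strand), ,
                 drop = FALSE]
    rownames(hits) <- NULL
    return(list(counts = counts, hits = hits))
  }
  per <- lapply(genes, function(g) {
    h <- scan_gene_window(schr[[g]], pwm, tss_offset, upstream = upstream,
                          downstream = downstream,
                          threshold_frac = threshold_frac)
    if (nrow(h)) cbind(gene = g, h, stringsAsFactors = FALSE) else NULL
  })
  hits <- do.call(rbind, per)
  if (is.null(hits))
    hits <- data.frame(gene = character(0), offset = integer(0),
                       strand = character(0), score = numeric(0))
  counts <- table(factor(hits$gene, levels = genes))
  list(counts = stats::setNames(as.integer(counts), genes), hits = hits)
}
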