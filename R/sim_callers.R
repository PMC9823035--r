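#' Simulate noisy per-caller SV call sets over a shared truth
#'
#' Each caller reports each true SV with probability `1 - fn_rate`, with both
#' breakpoints perturbed by rounded Gaussian jitter and SV type and strands
#' preserved.  False positives are added at `fp_rate` per true record
#' (Poisson count) with random type and position.  Per-record QUAL scores are
#' drawn from caller-realistic distributions (true events score higher than
#' false positives) and per-sample genotypes are carried over from the truth
#' with caller-specific missingness.
#'
#' @param truth a [simulate_truth()] set.
#' @param n_callers number of callers (>= 1).
#' @param jitter_sd breakpoint jitter standard deviation in bp.
#' @param fn_rate_per_caller false-negative rate, scalar or one per caller.
#' @param fp_rate expected false positives per true record.
#' @param gt_missing_rate per-caller genotype missingness.
#' @param chrom_length chromosome length used for false-positive positions.
#' @param seed integer seed.
#' @return a list of `sv_callset` objects, each with `caller_id`,
#'   `records` (data frame: `id`, `chrom`, `start`, `end`, `sv_type`,
#'   `strand1`, `strand2`, `qual`, `truth_id`) and `gt` (records x samples
#'   dosage matrix with `NA` for missing).
#' @export
simulate_caller_outputs <- function(truth, n_callers = 3L, jitter_sd = 100,
                                    fn_rate_per_caller = 0.1, fp_rate = 0.05,
                                    gt_missing_rate = 0.05,
                                    chrom_length = 1e6, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"), n_callers >= 1L)
  fn <- rep_len(fn_rate_per_caller, n_callers)
  with_seed(seed, {
    lapply(seq_len(n_callers), function(i) {
      caller <- paste0("caller", LETTERS[i])
      sv <- truth$sv
      keep <- runif(nrow(sv)) >= fn[i]
      rec <- sv[keep, , drop = FALSE]
      gt <- truth$sv_gt[keep, , drop = FALSE]
      if (nrow(rec)) {
        rec$start <- rec$start + round(rnorm(nrow(rec), 0, jitter_sd))
        rec$end <- rec$end + round(rnorm(nrow(rec), 0, jitter_sd))
        rec$start <- pmax(rec$start, 1)
        rec$end <- pmax(rec$end, rec$start)
        rec$qual <- 800 + rgamma(nrow(rec), shape = 2, scale = 600)
      } else rec$qual <- numeric(0)
      n_fp <- rpois(1, fp_rate * nrow(sv))
      if (n_fp > 0) {
        fp_type <- sample(c("DEL", "DUP", "INV", "TRA"), n_fp, replace = TRUE)
        fp_start <- sample.int(chrom_length, n_fp, replace = TRUE)
        fp_size <- round(runif(n_fp, 40, 2000))
        fp_str <- t(vapply(fp_type, sv_type_strands, character(2)))
        fp <- data.frame(truth_id = NA_character_,
                         chrom = sample(unique(sv$chrom), n_fp, replace = TRUE),
                         start = fp_start, end = fp_start + fp_size - 1L,
                         sv_type = fp_type, strand1 = fp_str[, 1],
                         strand2 = fp_str[, 2],
                         qual = rgamma(n_fp, shape = 2, scale = 300),
                         stringsAsFactors = FALSE)
        fp_gt <- matrix(rbinom(n_fp * ncol(truth$sv_gt), 2L,
                               rep(runif(n_fp, 0.02, 0.2), ncol(truth$sv_gt))),
                        nrow = n_fp, dimnames = list(NULL, colnames(truth$sv_gt)))
        rec <- rbind(rec, fp)
        gt <- rbind(gt, fp_gt)
      }
      if (nrow(rec)) {
        if (gt_missing_rate > 0) {
          miss <- which(runif(length(gt)) < gt_missing_rate)
          gt[miss] <- NA_integer_
        }
        rec$id <- sprintf("%s_%04d", caller, seq_len(nrow(rec)))
        rownames(rec) <- NULL
        rownames(gt) <- rec$id
      } else rec$id <- character(0)
      rec$caller_id <- rep(caller, nrow(rec))
      structure(list(caller_id = caller,
                     records = rec[, c("id", "caller_id", "chrom", "start",
                                       "end", "sv_type", "strand1", "strand2",
                                       "qual", "truth_id")],
                     gt = gt),
                class = "sv_callset")
    })
  })
}

#' @export
print.sv_callset <- function(x, ...) {
  cat("sv_callset", x$caller_id, ":", nrow(x$records), "records,",
      ncol(x$gt), "samples\n")
  invisible(x)
}
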