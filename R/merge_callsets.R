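#' Merge multi-caller SV call sets into a high-confidence set
#'
#' SURVIVOR-style breakpoint clustering: records from all callers are pooled
#' and sorted by coordinate, then greedily clustered by single linkage
#' against each cluster's seed record.  A record joins a cluster when both
#' breakpoints lie within `max_dist` of the seed's and, if the flags are
#' set, SV type and strand pair match.  Clusters supported by at least
#' `min_callers` distinct callers emit one merged record whose breakpoints
#' are those of the representative (the member from the highest-priority
#' caller); clusters with fewer supporters, or whose representative spans
#' fewer than `min_size` bp (translocations exempt, they carry no length),
#' are dropped.
#'
#' The defaults are the merging settings of the chicken feather-pecking SV
#' study: 1,000 bp, 2 callers, type- and strand-aware, 30 bp minimum size.
#'
#' @param callsets list of `sv_callset` objects
#'   (see [simulate_caller_outputs()]).
#' @param max_dist maximum breakpoint distance in bp.
#' @param min_callers minimum number of distinct supporting callers.
#' @param type_aware,strand_aware require matching SV type / strand pair.
#' @param min_size minimum SV length in bp (non-translocation types).
#' @param caller_priority character vector ordering callers for the
#'   representative choice; default: sorted caller ids (stable under
#'   permutation of the input list).
#' @return a `merged_callset`: list with `records` (data frame: `id`,
#'   `chrom`, `start`, `end`, `sv_type`, `strand1`, `strand2`, `qual`,
#'   `size`, `n_callers`, `supporting`, `truth_id`) and `gt` (consensus
#'   dosage matrix, representative's genotypes with missing entries filled
#'   from other members in priority order).
#' @export
merge_callsets <- function(callsets, max_dist = 1000, min_callers = 2L,
                           type_aware = TRUE, strand_aware = TRUE,
                           min_size = 30, caller_priority = NULL) {
  stopifnot(length(callsets) >= 1, max_dist > 0, min_callers >= 1,
            min_size >= 0)
  known_types <- c("DEL", "DUP", "INV", "TRA", "INS")
  recs <- do.call(rbind, lapply(callsets, function(cs) cs$records))
  gt <- do.call(rbind, lapply(callsets, function(cs) cs$gt))
  if (is.null(recs) || nrow(recs) == 0)
    return(empty_merged(callsets))
  bad <- !(recs$sv_type %in% known_types)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unknown sv_type skipped")
    recs <- recs[!bad, , drop = FALSE]
    gt <- gt[!bad, , drop = FALSE]
  }
  if (nrow(recs) == 0) return(empty_merged(callsets))
  if (is.null(caller_priority)) caller_priority <- sort(unique(recs$caller_id))
  # deterministic pool order, independent of the order of the input list
  o <- order(recs$chrom, recs$start, recs$end, recs$sv_type, recs$strand1,
             recs$strand2, -recs$qual, recs$caller_id)
  recs <- recs[o, , drop = FALSE]
  gt <- gt[o, , drop = FALSE]

  k <- nrow(recs)
  cluster <- integer(k)
  seed_idx <- integer(0)          # pool index of each cluster's seed
  for (i in seq_len(k)) {
    assigned <- 0L
    for (ci in rev(seq_along(seed_idx))) {
      s <- seed_idx[ci]
      if (recs$chrom[s] != recs$chrom[i]) break
      if (recs$start[i] - recs$start[s] > max_dist) break
      if (abs(recs$end[i] - recs$end[s]) > max_dist) next
      if (type_aware && recs$sv_type[i] != recs$sv_type[s]) next
      if (strand_aware && (recs$strand1[i] != recs$strand1[s] ||
                           recs$strand2[i] != recs$strand2[s])) next
      assigned <- ci
      break
    }
    if (assigned == 0L) {
      seed_idx <- c(seed_idx, i)
      assigned <- length(seed_idx)
    }
    cluster[i] <- assigned
  }

  prio <- match(recs$caller_id, caller_priority)
  out <- vector("list", length(seed_idx))
  gt_rows <- vector("list", length(seed_idx))
  for (ci in seq_along(seed_idx)) {
    members <- which(cluster == ci)
    callers <- unique(recs$caller_id[members])
    if (length(callers) < min_callers) next
    rep_i <- members[order(prio[members], members)][1]
    size <- if (recs$sv_type[rep_i] == "TRA") NA_integer_ else
      recs$end[rep_i] - recs$start[rep_i] + 1L
    if (!is.na(size) && size < min_size) next
    g <- gt[rep_i, ]
    for (mi in members[order(prio[members], members)]) {
      if (!anyNA(g)) break
      g[is.na(g)] <- gt[mi, ][is.na(g)]
    }
    out[[ci]] <- data.frame(
      chrom = recs$chrom[rep_i], start = recs$start[rep_i],
      end = recs$end[rep_i], sv_type = recs$sv_type[rep_i],
      strand1 = recs$strand1[rep_i], strand2 = recs$strand2[rep_i],
      qual = max(recs$qual[members]), size = size,
      n_callers = length(callers),
      supporting = paste(sort(callers), collapse = ","),
      truth_id = recs$truth_id[rep_i], stringsAsFactors = FALSE)
    gt_rows[[ci]] <- g
  }
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) return(empty_merged(callsets))
  records <- do.call(rbind, out[keep])
  records <- records[order(records$chrom, records$start, records$end), ,
                     drop = FALSE]
  records$id <- sprintf("merged_%04d", seq_len(nrow(records)))
  records <- records[, c("id", "chrom", "start", "end", "sv_type", "strand1",
                         "strand2", "qual", "size", "n_callers", "supporting",
                         "truth_id")]
  rownames(records) <- NULL
  gtm <- do.call(rbind, gt_rows[keep])
  gtm <- gtm[order(do.call(rbind, out[keep])$chrom,
                   do.call(rbind, out[keep])$start,
                   do.call(rbind, out[keep])$end), , drop = FALSE]
  rownames(gtm) <- records$id
  structure(list(records = records, gt = gtm), class = "merged_callset")
}

empty_merged <- function(callsets) {
  samples <- if (length(callsets) && !is.null(callsets[[1]]$gt))
    colnames(callsets[[1]]$gt) else character(0)
  records <- data.frame(id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        sv_type = character(0), strand1 = character(0),
                        strand2 = character(0), qual = numeric(0),
                        size = integer(0), n_callers = integer(0),
                        supporting = character(0), truth_id = character(0),
                        stringsAsFactors = FALSE)
  structure(list(records = records,
                 gt = matrix(integer(0), 0, length(samples),
                             dimnames = list(NULL, samples))),
            class = "merged_callset")
}

#' @export
print.merged_callset <- function(x, ...) {
  cat("merged_callset:", nrow(x$records), "merged variants\n")
  invisible(x)
}

#' Filter a merged SV call set on quality and call rate
#'
#' Retains exactly the records with `qual >= min_qual` and a genotype call
#' rate (fraction of non-missing genotypes) `>= min_callrate`; input order
#' is preserved.  Defaults are the study's filters (QUAL 1000, call rate
#' 0.8).  The function is idempotent.
#'
#' @param merged a [merge_callsets()] result.
#' @param min_qual minimum QUAL score.
#' @param min_callrate minimum call rate.
#' @return a filtered `merged_callset`.
#' @export
filter_merged <- function(merged, min_qual = 1000, min_callrate = 0.8) {
  stopifnot(inherits(merged, "merged_callset"))
  if (nrow(merged$records) == 0) return(merged)
  cr <- rowMeans(!is.na(merged$gt))
  keep <- merged$records$qual >= min_qual & cr >= min_callrate
  structure(list(records = merged$records[keep, , drop = FALSE],
                 gt = merged$gt[keep, , drop = FALSE]),
            class = "merged_callset")
}
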