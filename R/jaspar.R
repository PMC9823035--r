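#' Load a JASPAR-format frequency matrix
#'
#' Parses the 4-row JASPAR text format (`>motif_id name` header followed by
#' `A [ ... ]` ... `T [ ... ]` rows; bare unbracketed rows are accepted
#' too).  Log-odds scores are
#' \deqn{lo_{b,j} = \log_2\frac{(f_{b,j} + pc) / (\Sigma_j + 4\,pc)}{bg_b}}
#' with pseudocount `pc` and background base probabilities `bg`.
#'
#' @param path path to the matrix file.
#' @param pseudocount added to every count cell (default 0.25).
#' @param background base probabilities (A, C, G, T), summing to 1.
#' @return a `pwm_model`: list with `motif_id`, `name`, `counts` (4 x L),
#'   `pseudocount`, `background`, `log_odds`, `consensus`.
#' @export
load_jaspar <- function(path, pseudocount = 0.25,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines))])
  hdr <- grepl("^>", lines)
  motif_id <- "motif"
  name <- ""
  if (any(hdr)) {
    h <- sub("^>", "", lines[which(hdr)[1]])
    parts <- strsplit(h, "[ \t]+")[[1]]
    motif_id <- parts[1]
    if (length(parts) > 1) name <- paste(parts[-1], collapse = " ")
    lines <- lines[!hdr]
  }
  if (length(lines) != 4)
    stop("malformed JASPAR matrix: expected 4 base rows, got ", length(lines))
  parse_row <- function(ln) {
    ln <- sub("^[ACGTacgt][ \t]*", "", ln)
    ln <- gsub("[][]", " ", ln)
    as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
  }
  rows <- lapply(lines, parse_row)
  L <- unique(lengths(rows))
  if (length(L) != 1)
    stop("malformed JASPAR matrix: rows have unequal lengths")
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  new_pwm_model(counts, pseudocount, background, motif_id, name)
}

new_pwm_model <- function(counts, pseudocount = 0.25,
                          background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          motif_id = "motif", name = "") {
  stopifnot(nrow(counts) == 4, all(counts >= 0))
  if (any(colSums(counts) <= 0))
    stop("every matrix column must have a positive total")
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-8)
  rownames(counts) <- c("A", "C", "G", "T")
  freq <- sweep(counts + pseudocount, 2,
                colSums(counts) + 4 * pseudocount, "/")
  lo <- log2(sweep(freq, 1, background, "/"))
  if (any(!is.finite(lo))) stop("log-odds not finite; increase pseudocount")
  consensus <- paste(rownames(counts)[apply(counts, 2, which.max)],
                     collapse = "")
  structure(list(motif_id = motif_id, name = name, counts = counts,
                 pseudocount = pseudocount, background = background,
                 log_odds = lo, consensus = consensus),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat("pwm_model", x$motif_id, if (nzchar(x$name)) paste0("(", x$name, ")"),
      ": width", ncol(x$counts), ", consensus", x$consensus, "\n")
  invisible(x)
}

#' Write a PWM back to JASPAR format
#' @param pwm a `pwm_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_jaspar <- function(pwm, path) {
  hdr <- paste0(">", pwm$motif_id,
                if (nzchar(pwm$name)) paste0(" ", pwm$name))
  rows <- vapply(rownames(pwm$counts), function(b)
    paste0(b, " [ ", paste(format(pwm$counts[b, ], trim = TRUE),
                           collapse = " "), " ]"), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# attainable score bounds of the log-odds matrix
pwm_score_range <- function(pwm) {
  c(min = sum(apply(pwm$log_odds, 2, min)),
    max = sum(apply(pwm$log_odds, 2, max)))
}

# exact distribution of the per-position score under an i.i.d. base model:
# column-wise convolution on a discretized score grid.  `probs` defaults to
# the scan background; pass the motif's own frequencies to get the score
# distribution of sampled motif instances.
pwm_score_distribution <- function(pwm, probs = NULL, resolution = 1e-3) {
  lo <- pwm$log_odds
  if (is.null(probs)) probs <- matrix(pwm$background, 4, ncol(lo))
  if (is.vector(probs)) probs <- matrix(probs, 4, ncol(lo))
  grid <- round(lo / resolution)
  offset <- sum(apply(grid, 2, min))
  width <- sum(apply(grid, 2, max)) - offset + 1
  dist <- numeric(width)
  dist[1] <- 1
  base <- offset
  for (j in seq_len(ncol(lo))) {
    nd <- numeric(width)
    cmin <- min(grid[, j])
    for (b in 1:4) {
      shift <- grid[b, j] - cmin
      if (probs[b, j] > 0)
        nd[(1 + shift):width] <- nd[(1 + shift):width] +
          probs[b, j] * dist[1:(width - shift)]
    }
    dist <- nd
  }
  list(score = (seq_len(width) - 1 + offset) * resolution, prob = dist)
}

# P(score >= threshold) for one scanned position under i.i.d. background
pwm_tail_prob <- function(pwm, threshold, probs = NULL, resolution = 1e-3) {
  d <- pwm_score_distribution(pwm, probs, resolution)
  sum(d$prob[d$score >= threshold - resolution / 2])
}
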