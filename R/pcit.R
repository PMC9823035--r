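#' PCIT: partial-correlation network pruning
#'
#' Implements the partial-correlation-and-information-theory algorithm on a
#' trait-by-trait correlation matrix (typically correlations between the
#' columns of an association weight matrix).  For every trio (x, y, z) the
#' three first-order partial correlations are computed, e.g.
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}},}
#' and the trio's local tolerance is the mean of the three
#' partial-to-direct ratios.  The edge (x, y) is flagged non-significant if
#' some third node z satisfies
#' \eqn{|r_{xy}| < \varepsilon |r_{xz}|} and
#' \eqn{|r_{xy}| < \varepsilon |r_{yz}|}.  Pruning only removes edges.
#' Near-zero direct correlations (|r| below `zero_tol`) are pruned
#' outright; unit correlations make a trio's denominators vanish and the
#' dominated edge is pruned via a perfect proxy (with a message).
#' Trio enumeration is exhaustive.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param zero_tol direct correlations below this magnitude are dropped.
#' @return a `gene_network`: list with `nodes` and `edges` (data frame
#'   `node_a`, `node_b`, `weight`, `significant`; canonical a < b order).
#' @export
pcit <- function(corr, zero_tol = 1e-12) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  stopifnot(n == ncol(corr), max(abs(corr - t(corr))) < 1e-8,
            all(abs(corr) <= 1 + 1e-8))
  nodes <- colnames(corr)
  if (is.null(nodes)) nodes <- paste0("T", seq_len(n))
  sig <- matrix(TRUE, n, n)
  perfect <- 0L
  if (n >= 3) {
    idx <- seq_len(n)
    for (x in 1:(n - 1)) {
      for (y in (x + 1):n) {
        rxy <- corr[x, y]
        if (abs(rxy) < zero_tol) { sig[x, y] <- FALSE; next }
        z <- idx[-c(x, y)]
        rxz <- corr[x, z]
        ryz <- corr[y, z]
        den_xy <- (1 - rxz^2) * (1 - ryz^2)
        den_xz <- (1 - rxy^2) * (1 - ryz^2)
        den_yz <- (1 - rxy^2) * (1 - rxz^2)
        degen <- den_xy <= 0 | den_xz <= 0 | den_yz <= 0
        pxy <- (rxy - rxz * ryz) / sqrt(pmax(den_xy, .Machine$double.eps))
        pxz <- (rxz - rxy * ryz) / sqrt(pmax(den_xz, .Machine$double.eps))
        pyz <- (ryz - rxy * rxz) / sqrt(pmax(den_yz, .Machine$double.eps))
        eps <- (abs(pxy / rxy) + abs(pxz / rxz) + abs(pyz / ryz)) / 3
        dominated <- abs(rxy) < eps * abs(rxz) & abs(rxy) < eps * abs(ryz)
        dominated[degen] <- FALSE   # undefined ratios never prune by formula
        # a perfect proxy (|r| = 1 in the trio) dominates the edge
        if (any(degen)) {
          prox <- degen & abs(rxz) >= abs(rxy) & abs(ryz) >= abs(rxy) &
            (abs(rxz) >= 1 - 1e-12 | abs(ryz) >= 1 - 1e-12)
          if (any(prox)) { dominated[prox] <- TRUE; perfect <- perfect + 1L }
        }
        if (any(dominated, na.rm = TRUE)) sig[x, y] <- FALSE
      }
    }
  }
  if (perfect > 0)
    message(perfect, " edge check(s) involved a perfect-correlation proxy")
  pairs <- which(upper.tri(corr), arr.ind = TRUE)
  edges <- data.frame(node_a = nodes[pairs[, 1]], node_b = nodes[pairs[, 2]],
                      weight = corr[pairs],
                      significant = sig[pairs] & abs(corr[pairs]) >= zero_tol,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,",
      sum(x$edges$significant), "significant /", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Export a gene network as an edge list
#'
#' Writes a tab-separated file (`node_a`, `interaction`, `node_b`,
#' `weight`) loadable by standard network viewers; rows are sorted
#' deterministically.  By default only significant edges are written.
#'
#' @param net a [pcit()] network.
#' @param path output file path.
#' @param significant_only write only significant edges.
#' @return the path, invisibly.
#' @export
export_network <- function(net, path, significant_only = TRUE) {
  stopifnot(inherits(net, "gene_network"))
  e <- net$edges
  if (significant_only) e <- e[e$significant, , drop = FALSE]
  out <- data.frame(node_a = e$node_a,
                    interaction = rep("corr", nrow(e)),
                    node_b = e$node_b, weight = e$weight,
                    stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an exported edge list
#' @param path file written by [export_network()].
#' @return data frame with `node_a`, `interaction`, `node_b`, `weight`.
#' @export
read_network <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
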