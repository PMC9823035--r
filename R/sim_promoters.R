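#' Simulate promoter sequences with planted motifs
#'
#' Emits one i.i.d. background sequence per gene (composition
#' `cfg$base_probs`).  Genes in `motif_genes` receive a motif instance with
#' probability `plant_prob_fore`, all other genes with `plant_prob_back`.
#' Each planted instance is sampled column-wise from the frequency matrix
#' ("consensus-sampled"), inserted at a uniform random position on a random
#' strand.
#'
#' @param genes character vector of gene names (or a data frame with a
#'   `gene` column).
#' @param pwm a [load_jaspar()] model.
#' @param cfg a [new_sim_config()] object (promoter length, base
#'   composition, plant probabilities).
#' @param motif_genes character vector: the foreground gene set.
#' @param seed optional integer seed overriding the config's child seed.
#' @return a [Biostrings::DNAStringSet] named by gene, with attribute
#'   `planted` (data frame of gene, position, strand for every insertion).
#' @export
simulate_promoters <- function(genes, pwm, cfg, motif_genes = character(0),
                               seed = NULL) {
  if (is.data.frame(genes)) genes <- genes$gene
  L <- ncol(pwm$counts)
  if (L > cfg$promoter_length)
    stop("motif is longer than the promoter sequence")
  if (is.null(seed)) seed <- child_seed(cfg, "promoters")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    n <- length(genes)
    plen <- cfg$promoter_length
    draw <- sample.int(4L, n * plen, replace = TRUE, prob = cfg$base_probs)
    big <- paste(bases[draw], collapse = "")
    seqs <- substring(big, (seq_len(n) - 1L) * plen + 1L,
                      seq_len(n) * plen)
    p_plant <- ifelse(genes %in% motif_genes,
                      cfg$plant_prob_fore, cfg$plant_prob_back)
    plant <- runif(n) < p_plant
    planted <- data.frame(gene = character(0), position = integer(0),
                          strand = character(0), stringsAsFactors = FALSE)
    freqs <- sweep(pwm$counts, 2, colSums(pwm$counts), "/")
    for (i in which(plant)) {
      inst <- vapply(seq_len(L), function(j)
        sample(bases, 1, prob = freqs[, j]), character(1))
      strand <- sample(c("+", "-"), 1)
      if (strand == "-") inst <- rev(chartr("ACGT", "TGCA", inst))
      pos <- sample.int(plen - L + 1L, 1)
      substr(seqs[i], pos, pos + L - 1L) <- paste(inst, collapse = "")
      planted <- rbind(planted, data.frame(gene = genes[i], position = pos,
                                           strand = strand,
                                           stringsAsFactors = FALSE))
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- genes
    attr(out, "planted") <- planted
    out
  })
}
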