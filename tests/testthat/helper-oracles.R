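# Independent oracles and small scenario factories shared by the tests.
# Each oracle is deliberately written as plain brute force, independent of
# the package's implementation path.

# small, fast simulation configuration for unit tests (overridable)
tiny_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_samples = 120L, n_chromosomes = 3L,
               n_variants_per_chrom = 60L, n_genes = 12L,
               n_expr_samples = 60L,
               tf_hub = list(hub = 1L, targets = 2:6, effect = 0.8),
               n_sv = 40L)
  user <- list(...)
  args[names(user)] <- user
  do.call(new_sim_config, args)
}

# exhaustive triple-loop PCIT: prune edge (x,y) if some z dominates it
# under the trio tolerance (mean of the three partial-to-direct ratios)
pcit_oracle <- function(corr) {
  n <- nrow(corr)
  sig <- matrix(TRUE, n, n)
  pc <- function(rxy, rxz, ryz)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  for (x in seq_len(n - 1)) for (y in (x + 1):n) {
    if (abs(corr[x, y]) < 1e-12) { sig[x, y] <- FALSE; next }
    for (z in seq_len(n)) {
      if (z == x || z == y) next
      rxy <- corr[x, y]; rxz <- corr[x, z]; ryz <- corr[y, z]
      if (any(abs(c(rxy, rxz, ryz)) >= 1)) next
      eps <- mean(c(abs(pc(rxy, rxz, ryz) / rxy),
                    abs(pc(rxz, rxy, ryz) / rxz),
                    abs(pc(ryz, rxy, rxz) / ryz)))
      if (abs(rxy) < eps * abs(rxz) && abs(rxy) < eps * abs(ryz)) {
        sig[x, y] <- FALSE
        break
      }
    }
  }
  sig[upper.tri(sig)]
}

# one-sided hypergeometric tail p for a 2x2 coverage table
hypergeom_tail_p <- function(covered_fore, n_fore, covered_back, n_back) {
  k <- covered_fore + covered_back
  sum(stats::dhyper(covered_fore:min(n_fore, k), n_fore, n_back, k))
}

# connected-components clustering count over pooled caller records
# (adjacency: same chrom, both breakpoints within max_dist, matching type
# and strand pair); counts components supported by >= min_callers callers
merge_count_oracle <- function(callsets, max_dist = 1000, min_callers = 2) {
  rec <- do.call(rbind, lapply(callsets, function(cs) cs$records))
  k <- nrow(rec)
  if (k == 0) return(0L)
  comp <- rep(0L, k)
  nc <- 0L
  for (i in seq_len(k)) {
    if (comp[i] > 0L) next
    nc <- nc + 1L
    queue <- i
    comp[i] <- nc
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      for (b in seq_len(k)) {
        if (comp[b] > 0L) next
        if (rec$chrom[a] == rec$chrom[b] &&
            abs(rec$start[a] - rec$start[b]) <= max_dist &&
            abs(rec$end[a] - rec$end[b]) <= max_dist &&
            rec$sv_type[a] == rec$sv_type[b] &&
            rec$strand1[a] == rec$strand1[b] &&
            rec$strand2[a] == rec$strand2[b]) {
          comp[b] <- nc
          queue <- c(queue, b)
        }
      }
    }
  }
  sum(vapply(seq_len(nc), function(cc)
    length(unique(rec$caller_id[comp == cc])) >= min_callers, logical(1)))
}

# brute-force per-base PWM scoring of a full sequence, both strands
scan_oracle <- function(seq_chr, pwm) {
  bases <- strsplit(toupper(seq_chr), "")[[1]]
  L <- ncol(pwm$log_odds)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  npos <- length(bases) - L + 1
  fwd <- rev <- numeric(npos)
  for (p in seq_len(npos)) {
    sf <- sr <- 0
    for (j in seq_len(L)) {
      sf <- sf + pwm$log_odds[bases[p + j - 1], j]
      # minus-strand instance read 3'->5' on the forward coordinates
      sr <- sr + pwm$log_odds[comp[[bases[p + L - j]]], j]
    }
    fwd[p] <- sf; rev[p] <- sr
  }
  list(fwd = fwd, rev = rev)
}

# random positive-definite correlation matrix
random_corr <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm((n + 5) * n), n + 5, n)
  stats::cor(X)
}

# a sharp random PWM unrelated to the shipped ETS-like fixture
random_pwm <- function(seed, L = 12, id = paste0("RND", seed)) {
  set.seed(seed)
  counts <- matrix(2, 4, L)
  for (j in seq_len(L)) counts[sample.int(4, 1), j] <- 94
  pecknet:::new_pwm_model(counts, motif_id = id)
}

# shipped synthetic ETS-like motif
ets_pwm <- function() {
  load_jaspar(system.file("extdata", "synthetic_ets_motif.jaspar",
                          package = "pecknet"))
}
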