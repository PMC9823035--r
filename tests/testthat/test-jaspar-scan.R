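test_that("JASPAR parsing, log-odds arithmetic and round trip", {
  f <- tempfile(fileext = ".jaspar")
  writeLines(c(">TOY1 toy motif",
               "A [ 10 0 2 ]",
               "C [ 0 10 2 ]",
               "G [ 0 0 4 ]",
               "T [ 0 0 2 ]"), f)
  pwm <- load_jaspar(f)
  expect_equal(ncol(pwm$counts), 3)
  expect_equal(pwm$motif_id, "TOY1")
  # column (10,0,0,0), uniform background, pseudocount 0.25:
  # A log-odds = log2((10.25/11)/0.25)
  expect_equal(unname(pwm$log_odds["A", 1]), log2((10.25 / 11) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pwm$log_odds["A", 1]), 1.898, tolerance = 5e-4)
  f2 <- tempfile(fileext = ".jaspar")
  write_jaspar(pwm, f2)
  expect_equal(load_jaspar(f2)$counts, pwm$counts)
  # malformed inputs
  writeLines(c(">X", "A [ 1 2 ]", "C [ 1 2 ]", "G [ 1 2 ]"), f)
  expect_error(load_jaspar(f), "4 base rows")
  writeLines(c(">X", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"), f)
  expect_error(load_jaspar(f), "unequal")
})

test_that("the consensus is the only hit at the maximal threshold", {
  pwm <- ets_pwm()
  L <- ncol(pwm$counts)
  set.seed(101)
  bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  seq_chr <- paste0(substr(bg, 1, 100), pwm$consensus,
                    substr(bg, 101 + L, 300))
  hits <- scan_gene_window(seq_chr, pwm, tss_offset = 150, upstream = 149,
                           downstream = 141, threshold_frac = 1)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$offset, 101 - 150)
  expect_equal(fwd$score, unname(pecknet:::pwm_score_range(pwm)["max"]),
               tolerance = 1e-9)
})

test_that("reverse-complementing the sequence swaps strands, keeps hits", {
  pwm <- ets_pwm()
  set.seed(102)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                          prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq_chr), "")[[1]]),
              collapse = "")
  h1 <- scan_gene_window(seq_chr, pwm, tss_offset = 200, upstream = 199,
                         downstream = 201, threshold_frac = 0.75)
  h2 <- scan_gene_window(rc, pwm, tss_offset = 200, upstream = 199,
                         downstream = 201, threshold_frac = 0.75)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-9)
})

test_that("window scores equal the brute-force per-base oracle", {
  pwm <- ets_pwm()
  for (s in 1:20) {
    set.seed(7100 + s)
    seq_chr <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                    collapse = "")
    hits <- scan_gene_window(seq_chr, pwm, tss_offset = 60, upstream = 59,
                             downstream = 61, threshold_frac = 0.5)
    oracle <- scan_oracle(seq_chr, pwm)
    rng <- pecknet:::pwm_score_range(pwm)
    thr <- rng["min"] + 0.5 * (rng["max"] - rng["min"])
    exp_f <- which(oracle$fwd >= thr - 1e-9)
    exp_r <- which(oracle$rev >= thr - 1e-9)
    expect_equal(sort(hits$offset[hits$strand == "+"] + 60),
                 sort(exp_f), label = paste("fwd seed", s))
    expect_equal(sort(hits$offset[hits$strand == "-"] + 60),
                 sort(exp_r), label = paste("rev seed", s))
    got_f <- hits[hits$strand == "+", ]
    expect_equal(got_f$score, oracle$fwd[got_f$offset + 60],
                 tolerance = 1e-9)
  }
})

test_that("scores are invariant to padding outside the window", {
  pwm <- ets_pwm()
  set.seed(103)
  core <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  pad <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
  h1 <- scan_gene_window(core, pwm, tss_offset = 100, upstream = 50,
                         downstream = 50, threshold_frac = 0.6)
  h2 <- scan_gene_window(paste0(pad, core, pad), pwm, tss_offset = 150,
                         upstream = 50, downstream = 50,
                         threshold_frac = 0.6)
  expect_equal(h1, h2)
})

test_that("a window past the sequence end is truncated with a warning", {
  pwm <- ets_pwm()
  set.seed(104)
  seq_chr <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                   collapse = "")
  expect_warning(h <- scan_gene_window(seq_chr, pwm, tss_offset = 50),
                 "truncated")
  expect_true(all(h$offset >= -49))
})

test_that("vectorized promoter scanning equals the per-gene reference path", {
  pwm <- ets_pwm()
  cfg <- tiny_cfg(seed = 105, promoter_length = 400L, tss_position = 300L)
  truth <- simulate_truth(cfg)
  pr <- simulate_promoters(truth$genes, pwm, cfg,
                           motif_genes = truth$motif_genes)
  fast <- scan_promoters(pr, pwm, tss_offset = 300, upstream = 299,
                         downstream = 101, threshold_frac = 0.6)
  slow <- lapply(names(pr), function(g)
    scan_gene_window(as.character(pr[[g]]), pwm, tss_offset = 300,
                     upstream = 299, downstream = 101,
                     threshold_frac = 0.6))
  expect_equal(unname(fast$counts), vapply(slow, nrow, integer(1)))
  for (i in seq_along(slow)) {
    h <- fast$hits[fast$hits$gene == names(pr)[i], ]
    expect_equal(sort(h$offset), sort(slow[[i]]$offset))
    expect_equal(sum(h$score), sum(slow[[i]]$score), tolerance = 1e-9)
  }
})
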