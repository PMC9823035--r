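mk_merged <- function(qual, callrate, n_samples = 10) {
  k <- length(qual)
  rec <- data.frame(id = sprintf("m%02d", seq_len(k)), chrom = "chr1",
                    start = seq_len(k) * 10000L,
                    end = seq_len(k) * 10000L + 500L, sv_type = "DEL",
                    strand1 = "+", strand2 = "-", qual = qual,
                    size = 501L, n_callers = 2L,
                    supporting = "callerA,callerB",
                    truth_id = NA_character_, stringsAsFactors = FALSE)
  gt <- matrix(1L, k, n_samples)
  for (i in seq_len(k)) {
    n_miss <- round((1 - callrate[i]) * n_samples)
    if (n_miss > 0) gt[i, seq_len(n_miss)] <- NA_integer_
  }
  rownames(gt) <- rec$id
  structure(list(records = rec, gt = gt), class = "merged_callset")
}

test_that("quality and call-rate filters use the documented boundaries", {
  m <- mk_merged(qual = c(999.9, 1000), callrate = c(1, 0.8))
  f <- filter_merged(m)
  # qual 999.9 removed (below threshold); qual 1000 at call rate 0.8 kept
  expect_equal(f$records$id, "m02")
})

test_that("a mixed set filters to the enumerated survivor count", {
  qual <- c(500, 800, 999, rep(2000, 7))        # 3 fail the QUAL filter
  callrate <- c(1, 1, 1, 0.7, 0.5, rep(1, 5))   # 2 others fail call rate
  f <- filter_merged(mk_merged(qual, callrate))
  expect_equal(nrow(f$records), 5)
})

test_that("merged-set filtering is idempotent and order preserving", {
  m <- mk_merged(qual = c(2000, 500, 1500, 1200), callrate = c(1, 1, 0.5, 1))
  f1 <- filter_merged(m)
  expect_equal(filter_merged(f1), f1)
  expect_equal(f1$records$id, c("m01", "m04"))
})

mk_tr <- function(gt, dp, q) {
  k <- nrow(gt)
  rec <- data.frame(id = sprintf("tr%02d", seq_len(k)), chrom = "chr1",
                    pos = seq_len(k) * 1000L, motif = "CCCGGCCCG",
                    stringsAsFactors = FALSE)
  tr_callset(rec, gt, dp, q)
}

test_that("TR genotypes are masked on depth and strict quality", {
  gt <- matrix(5, 3, 10)
  dp <- matrix(20, 3, 10); q <- matrix(0.95, 3, 10)
  dp[1, ] <- 9                      # DP 9 < 10: all genotypes masked
  q[2, ] <- 0.8                     # Q exactly 0.8 is masked (strict >)
  f <- filter_tr(mk_tr(gt, dp, q))
  expect_equal(f$records$id, "tr03")
  # DP exactly 10 is kept (inclusive)
  dp2 <- matrix(10, 1, 10); q2 <- matrix(0.81, 1, 10)
  f2 <- filter_tr(mk_tr(matrix(5, 1, 10), dp2, q2))
  expect_equal(nrow(f2$records), 1)
})

test_that("TR call rate boundary retains exactly 0.8", {
  gt <- matrix(5, 1, 10)
  dp <- matrix(20, 1, 10); q <- matrix(0.95, 1, 10)
  dp[1, 1:2] <- 5                   # 8 of 10 pass -> call rate 0.8 retained
  f <- filter_tr(mk_tr(gt, dp, q))
  expect_equal(nrow(f$records), 1)
  dp[1, 3] <- 5                     # 7 of 10 -> removed
  expect_equal(nrow(filter_tr(mk_tr(gt, dp, q))$records), 0)
})

test_that("TR filtering is idempotent", {
  set.seed(9)
  gt <- matrix(rpois(50, 5), 5, 10)
  dp <- matrix(rpois(50, 12), 5, 10)
  q <- matrix(runif(50, 0.5, 1), 5, 10)
  f1 <- filter_tr(mk_tr(gt, dp, q))
  expect_equal(filter_tr(f1), f1)
})

test_that("multiallelic variants split into dosage-conserving biallelics", {
  v <- list(
    list(id = "tr1", alleles = c("cn5", "cn7"),
         genotypes = rbind(c(1, 2), c(0, 1), c(2, 2), c(NA, 1))),
    list(id = "del1", alleles = "ALT",
         genotypes = rbind(c(0, 1), c(1, 1), c(0, 0), c(0, 0))))
  s <- split_multiallelic(v)
  expect_equal(s$records$id, c("tr1_a1", "tr1_a2", "del1"))
  # sample with genotype (cn5, cn7) has dosage 1 in each split record
  expect_equal(unname(s$dosage["tr1_a1", 1]), 1)
  expect_equal(unname(s$dosage["tr1_a2", 1]), 1)
  # homozygous cn7 sample: dosage 2 in the cn7 record, 0 in the cn5 record
  expect_equal(unname(s$dosage["tr1_a2", 3]), 2)
  expect_equal(unname(s$dosage["tr1_a1", 3]), 0)
  # missing genotypes stay missing
  expect_true(is.na(s$dosage["tr1_a1", 4]))
  # biallelic input passes through unchanged
  expect_equal(unname(s$dosage["del1", ]), c(1, 2, 0, 0))
  # allele-count conservation over split records
  tot <- colSums(s$dosage[1:2, 1:3])
  expect_equal(unname(tot), c(2, 1, 2))
})
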