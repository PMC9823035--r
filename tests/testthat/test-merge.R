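# hand-built caller records for clustering unit tests
mk_callset <- function(caller, chrom, start, end, type = "DEL",
                       s1 = "+", s2 = "-", qual = 2000, n_samples = 4,
                       gt = NULL) {
  k <- length(start)
  rec <- data.frame(id = sprintf("%s_%02d", caller, seq_len(k)),
                    caller_id = caller, chrom = rep_len(chrom, k),
                    start = start, end = end,
                    sv_type = rep_len(type, k),
                    strand1 = rep_len(s1, k), strand2 = rep_len(s2, k),
                    qual = rep_len(qual, k), truth_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (is.null(gt)) gt <- matrix(1L, k, n_samples,
                                dimnames = list(rec$id,
                                                paste0("S", seq_len(n_samples))))
  structure(list(caller_id = caller, records = rec, gt = gt),
            class = "sv_callset")
}

test_that("breakpoint clustering follows the seed-distance rule", {
  # three callers: (1000,1500), (1200,1700), (1900,2400); all are within
  # 1000 bp of the seed record on both breakpoints, so one cluster of 3
  cs <- list(mk_callset("callerA", "chr1", 1000, 1500),
             mk_callset("callerB", "chr1", 1200, 1700),
             mk_callset("callerC", "chr1", 1900, 2400))
  m <- merge_callsets(cs)
  expect_equal(nrow(m$records), 1)
  expect_equal(m$records$n_callers, 3)
  expect_equal(m$records$supporting, "callerA,callerB,callerC")
  # representative comes from the highest-priority caller
  expect_equal(m$records$start, 1000)
  expect_equal(m$records$end, 1500)
})

test_that("type-aware merging never mixes SV types", {
  cs <- list(mk_callset("callerA", "chr1", 5000, 6000, type = "DEL"),
             mk_callset("callerB", "chr1", 5000, 6000, type = "INV",
                        s1 = "+", s2 = "+"))
  m <- merge_callsets(cs, min_callers = 2)
  expect_equal(nrow(m$records), 0)
  m1 <- merge_callsets(cs, min_callers = 1, strand_aware = FALSE)
  expect_equal(nrow(m1$records), 2)
})

test_that("the minimum SV size filter drops short variants", {
  cs <- list(mk_callset("callerA", "chr1", 1000, 1024),
             mk_callset("callerB", "chr1", 1000, 1024),
             mk_callset("callerC", "chr1", 1000, 1024))
  expect_equal(nrow(merge_callsets(cs)$records), 0)   # 25 bp < 30 bp
  cs30 <- list(mk_callset("callerA", "chr1", 1000, 1029),
               mk_callset("callerB", "chr1", 1000, 1029))
  expect_equal(nrow(merge_callsets(cs30)$records), 1) # exactly 30 bp
})

test_that("merging is invariant to the order of the caller sets", {
  cfg <- tiny_cfg(seed = 41)
  truth <- simulate_truth(cfg)
  cs <- simulate_caller_outputs(truth, jitter_sd = 150,
                                fn_rate_per_caller = 0.1, fp_rate = 0.1,
                                seed = 42)
  m1 <- merge_callsets(cs)
  m2 <- merge_callsets(rev(cs))
  expect_equal(m1$records, m2$records)
  expect_equal(m1$gt, m2$gt)
})

test_that("jitter-free error-free call sets recover the truth exactly", {
  cfg <- tiny_cfg(seed = 43)
  truth <- simulate_truth(cfg)
  cs <- simulate_caller_outputs(truth, jitter_sd = 0,
                                fn_rate_per_caller = 0, fp_rate = 0,
                                gt_missing_rate = 0, seed = 44)
  m <- merge_callsets(cs, min_size = 0)
  expect_equal(nrow(m$records), nrow(truth$sv))
  expect_setequal(m$records$truth_id, truth$sv$truth_id)
  expect_true(all(m$records$n_callers == 3))
})

test_that("a fully dropped caller leaves the two-caller merge intact", {
  cfg <- tiny_cfg(seed = 45)
  truth <- simulate_truth(cfg)
  cs <- simulate_caller_outputs(truth, jitter_sd = 0,
                                fn_rate_per_caller = c(1, 0, 0),
                                fp_rate = 0, gt_missing_rate = 0, seed = 46)
  expect_equal(nrow(cs[[1]]$records), 0)
  m <- merge_callsets(cs, min_size = 0)
  expect_equal(nrow(m$records), nrow(truth$sv))
  expect_true(all(m$records$n_callers == 2))
})

test_that("merged counts match the connected-components oracle under noise", {
  for (s in 1:5) {
    cfg <- tiny_cfg(seed = 50 + s)
    truth <- simulate_truth(cfg)
    cs <- simulate_caller_outputs(truth, jitter_sd = 200,
                                  fn_rate_per_caller = 0.1, fp_rate = 0.05,
                                  seed = 60 + s)
    m <- merge_callsets(cs, min_size = 0)
    expect_equal(nrow(m$records), merge_count_oracle(cs))
  }
})

test_that("unknown SV types are skipped with a warning", {
  cs <- list(mk_callset("callerA", "chr1", 1000, 2000),
             mk_callset("callerB", "chr1", 1000, 2000))
  cs[[2]]$records$sv_type <- "WEIRD"
  expect_warning(m <- merge_callsets(cs, min_callers = 1), "unknown sv_type")
  expect_equal(nrow(m$records), 1)
})
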