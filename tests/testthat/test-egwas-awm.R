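test_that("eGWAS produces one scan per gene over a shared variant panel", {
  cfg <- tiny_cfg(seed = 91)
  gt <- simulate_genotypes(cfg)
  truth <- simulate_truth(cfg)
  ph <- simulate_phenotype(gt, cfg, truth)
  expr <- simulate_expression(gt, cfg, truth)
  eg <- run_egwas(gt, expr, ph)
  expect_length(eg, ncol(expr))
  ids <- lapply(eg, `[[`, "id")
  expect_true(all(vapply(ids, identical, logical(1), ids[[1]])))
})

test_that("constant-expression genes are skipped with a message", {
  cfg <- tiny_cfg(seed = 92)
  gt <- simulate_genotypes(cfg)
  truth <- simulate_truth(cfg)
  ph <- simulate_phenotype(gt, cfg, truth)
  expr <- simulate_expression(gt, cfg, truth)
  expr[, 3] <- 1
  expect_message(eg <- run_egwas(gt, expr, ph), "constant-expression")
  expect_length(eg, ncol(expr) - 1)
  expect_false(colnames(expr)[3] %in% names(eg))
})

test_that("AWM selection applies the two-branch rule with its boundaries", {
  main <- data.frame(id = paste0("v", 1:4), chrom = "chr1",
                     pos = c(10, 20, 30, 40), maf = 0.2, n = 100,
                     beta = 1, se = 1,
                     p = c(5e-5, 0.5, 0.5, 0.5), stringsAsFactors = FALSE)
  mk_scan <- function(p) data.frame(id = main$id, chrom = "chr1",
                                    pos = main$pos, maf = 0.2, n = 100,
                                    beta = 1, se = 1, p = p,
                                    stringsAsFactors = FALSE)
  # v2 hits in exactly 10 scans, v3 in 9, v4 in none
  eg <- lapply(1:12, function(i)
    mk_scan(c(0.5, if (i <= 10) 1e-5 else 0.5,
              if (i <= 9) 1e-5 else 0.5, 0.5)))
  names(eg) <- paste0("g", 1:12)
  sel <- select_awm_variants(main, eg)
  expect_true("v1" %in% sel)    # main-trait branch
  expect_true("v2" %in% sel)    # exactly ten eGWAS hits
  expect_false("v3" %in% sel)   # nine is not "at least ten"
  expect_false("v4" %in% sel)
  hits <- attr(sel, "egwas_hits")
  expect_equal(unname(hits[c("v2", "v3")]), c(10, 9))
})

test_that("a selection rule satisfied by 57 of 35,571 variants is 0.16%", {
  m <- 35571
  p <- rep(0.5, m)
  p[seq_len(57)] <- 5e-5
  main <- data.frame(id = paste0("v", seq_len(m)), chrom = "chr1",
                     pos = seq_len(m), maf = 0.2, n = 100, beta = 1,
                     se = 1, p = p, stringsAsFactors = FALSE)
  sel <- select_awm_variants(main, list())
  expect_length(sel, 57)
  expect_equal(round(100 * length(sel) / m, 2), 0.16)
})

test_that("AWM entries are z-scores with a zero fill for missing scans", {
  main <- data.frame(id = c("v1", "v2"), chrom = "chr1", pos = c(1, 2),
                     maf = 0.2, n = 100, beta = c(0.5, 1),
                     se = c(0.25, 0.5), p = c(1e-5, 1e-5),
                     stringsAsFactors = FALSE)
  eg <- list(g1 = data.frame(id = "v1", chrom = "chr1", pos = 1, maf = 0.2,
                             n = 100, beta = -1, se = 0.5, p = 0.01,
                             stringsAsFactors = FALSE))
  awm <- build_awm(c("v1", "v2"), main, eg)
  expect_equal(dim(awm), c(2, 2))
  expect_equal(awm["v1", "fpd_bc"], 2)        # 0.5 / 0.25
  expect_equal(awm["v1", "g1"], -2)
  expect_equal(awm["v2", "g1"], 0)            # v2 absent from the g1 scan
  expect_error(build_awm(character(0), main, eg), "empty")
})

test_that("hub-target AWM columns are more correlated than unrelated pairs", {
  hit <- 0
  for (r in 1:5) {
    cfg <- new_sim_config(seed = 930 + r, n_samples = 200,
                          n_chromosomes = 2, n_variants_per_chrom = 120,
                          n_genes = 20, n_expr_samples = 200,
                          tf_hub = list(hub = 1L, targets = 2:9,
                                        effect = 0.8))
    gt <- simulate_genotypes(cfg)
    truth <- simulate_truth(cfg)
    ph <- simulate_phenotype(gt, cfg, truth)
    expr <- simulate_expression(gt, cfg, truth)
    eg <- run_egwas(gt, expr, ph)
    main <- mlma_loco(gt, ph, covariates = c("hatch", "line"))
    sel <- select_awm_variants(main, eg, min_egwas_hits = 1L)
    if (length(sel) < 3) next
    awm <- build_awm(sel, main, eg)
    cz <- cor(unclass(awm))
    tg <- colnames(expr)[2:9]
    other <- setdiff(colnames(expr)[10:20], tg)
    ct <- abs(cz[tg, tg][upper.tri(diag(length(tg)))])
    co <- abs(cz[other, other][upper.tri(diag(length(other)))])
    if (mean(ct) > mean(co)) hit <- hit + 1
  }
  expect_gte(hit, 4)
})

test_that("variants are annotated with their nearest gene", {
  genes <- data.frame(gene = c("gA", "gB"), chrom = c("chr1", "chr1"),
                      tss = c(100, 10000), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  v <- data.frame(chrom = c("chr1", "chr1", "chr2"), pos = c(150, 9000, 5))
  expect_equal(pecknet:::assign_nearest_gene(v, genes),
               c("gA", "gB", NA))
})
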