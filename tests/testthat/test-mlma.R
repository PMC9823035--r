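test_that("with sigma_g2 = 0 the scan reduces exactly to least squares", {
  cfg <- tiny_cfg(seed = 81)
  gt <- simulate_genotypes(cfg)
  truth <- simulate_truth(cfg)
  ph <- simulate_phenotype(gt, cfg, truth)
  res <- mlma_loco(gt, ph, covariates = c("hatch", "line"),
                   var_components = list(sigma_g2 = 0, sigma_e2 = 1))
  # independent OLS oracle with known unit residual variance
  W <- stats::model.matrix(~ hatch + line, ph)
  X <- pecknet:::impute_dosage(gt$dosage)
  for (i in seq(1, nrow(res), by = 17)) {
    x <- X[, res$id[i]]
    fit <- stats::lm(ph$fpd_bc ~ x + W - 1)
    expect_equal(res$beta[i], unname(coef(fit)["x"]), tolerance = 1e-8)
    xtx_inv <- chol2inv(chol(crossprod(cbind(x, W))))[1, 1]
    expect_equal(res$se[i], sqrt(xtx_inv), tolerance = 1e-8)
    z2 <- (res$beta[i] / res$se[i])^2
    expect_equal(res$p[i], pchisq(z2, 1, lower.tail = FALSE))
  }
})

test_that("the MAF threshold excludes rare variants from the result", {
  cfg <- tiny_cfg(seed = 82)
  gt <- simulate_genotypes(cfg)
  truth <- simulate_truth(cfg)
  ph <- simulate_phenotype(gt, cfg, truth)
  gt$dosage[, 5] <- 0L
  gt$dosage[1, 5] <- 1L                      # MAF 1/(2n) < 0.05
  res <- mlma_loco(gt, ph, maf_min = 0.05,
                   var_components = list(sigma_g2 = 0, sigma_e2 = 1))
  expect_false(gt$map$id[5] %in% res$id)
  expect_true(all(res$maf >= 0.05))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$se > 0))
})

test_that("a QTL on one chromosome leaves other LOCO fits variant-free", {
  # the tested variant is never part of its own GRM: perturbing markers on
  # the scanned chromosome does not change that chromosome's LOCO GRM
  cfg <- tiny_cfg(seed = 83)
  gt <- simulate_genotypes(cfg)
  cache <- make_loco_cache(gt)
  on1 <- gt$map$chrom == "chr1"
  gt2 <- gt
  gt2$dosage[, on1] <- sample(0:2, sum(on1) * nrow(gt$dosage), replace = TRUE)
  cache2 <- make_loco_cache(gt2)
  expect_equal(cache[["chr1"]]$A, cache2[["chr1"]]$A)
  expect_false(isTRUE(all.equal(cache[["chr2"]]$A, cache2[["chr2"]]$A)))
})

test_that("the QTL scenario detects the lead variant with the expected power", {
  ps <- vapply(1:8, function(r) {
    cfg <- new_sim_config(seed = 900 + r, n_samples = 500,
                          n_chromosomes = 2, n_variants_per_chrom = 150,
                          qtl_spec = data.frame(variant = 42, pve = 0.047))
    gt <- simulate_genotypes(cfg)
    truth <- simulate_truth(cfg)
    ph <- simulate_phenotype(gt, cfg, truth)
    res <- mlma_loco(gt, ph, covariates = c("hatch", "line"))
    res$p[match(gt$map$id[42], res$id)]
  }, numeric(1))
  expect_lt(median(ps), 1e-4)
})

test_that("PVE arithmetic follows the variance-decomposition formula", {
  expect_equal(estimate_pve(0, 1, var_y = 2), 0)
  expect_equal(estimate_pve(1, 1, sigma2 = 3), 0.25)
  expect_equal(estimate_pve(2, 0.5, var_y = 8), 0.25)
  expect_equal(estimate_pve(10, 10, var_y = 1), 1)   # clipped
  expect_error(estimate_pve(1, 1, var_y = 0), "positive")
  expect_error(estimate_pve(1, 1), "supply")
})

test_that("the Bonferroni threshold reproduces the genome-wide cut-off", {
  expect_equal(signif(bonferroni_threshold(35571), 3), 1.41e-6)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(50000), 1e-6)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("sample-size meta-analysis combines Z scores as documented", {
  mk <- function(p, beta, n, id = "v1")
    data.frame(id = id, chrom = "chr1", pos = 1, maf = 0.2, n = n,
               beta = beta, se = 1, p = p, stringsAsFactors = FALSE)
  z2 <- 2 * pnorm(2, lower.tail = FALSE)     # p for Z = 2
  # equal n, identical Z = 2 -> combined Z = 2 sqrt(2)
  m <- meta_sample_size(list(a = mk(z2, 1, 100), b = mk(z2, 1, 100)))
  expect_equal(m$z, 2 * sqrt(2), tolerance = 1e-10)
  # single study: identity
  m1 <- meta_sample_size(list(a = mk(z2, 1, 100)), allow_single = TRUE)
  expect_equal(m1$z, 2, tolerance = 1e-10)
  expect_equal(m1$p, z2, tolerance = 1e-10)
  # opposite signs, equal n: exact cancellation
  m0 <- meta_sample_size(list(a = mk(z2, 1, 100), b = mk(z2, -1, 100)))
  expect_equal(m0$z, 0)
  expect_equal(m0$p, 1)
  # k identical studies scale Z by sqrt(k)
  for (k in c(3, 5)) {
    mk_list <- replicate(k, mk(z2, 1, 64), simplify = FALSE)
    names(mk_list) <- paste0("s", seq_len(k))
    expect_equal(meta_sample_size(mk_list)$z, 2 * sqrt(k),
                 tolerance = 1e-10)
  }
  # a variant present in one study only carries its Z through
  two <- meta_sample_size(list(a = mk(z2, 1, 100),
                               b = mk(z2, 1, 400, id = "v2")))
  expect_equal(two$z[two$id == "v1"], 2, tolerance = 1e-10)
  expect_equal(two$n_studies, c(1, 1))
  # zero p-values are clamped, not fatal
  expect_message(mz <- meta_sample_size(list(a = mk(0, 1, 100),
                                             b = mk(z2, 1, 100))),
                 "clamped")
  expect_true(is.finite(mz$z))
})
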