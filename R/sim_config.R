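#' Simulation configuration for the synthetic study
#'
#' Bundles every tunable of the synthetic-data generators into a single
#' validated object.  The defaults describe a desk-scale half-sib-like (HS)
#' design: 500 phenotyped hens in two divergently selected lines and four
#' hatches, 2,000 biallelic markers on 5 chromosomes, polygenic heritability
#' 0.15, 86 expression traits measured on 167 of the birds, and a
#' transcription-factor hub gene regulating 20 of them.  A single QTL can be
#' requested through `qtl_spec`; the lead-variant scenario of the study it
#' emulates uses a target PVE (proportion of phenotypic variance explained)
#' of 0.047.
#'
#' One global `seed` is expanded into fixed per-component child seeds, so
#' each generator is a pure function of `(cfg, seed)` and stages can be
#' regenerated independently.
#'
#' @param seed integer master seed (keep it small; child seeds are offsets).
#' @param n_samples number of genotyped/phenotyped individuals.
#' @param n_chromosomes,n_variants_per_chrom marker panel dimensions.
#' @param chrom_length chromosome length in bp used for marker and SV
#'   positions.
#' @param maf_range allele-frequency range, both ends in (0, 0.5].
#' @param ld_decay probability that adjacent markers copy the same latent
#'   haplotype uniform; equals the adjacent-marker haplotype correlation when
#'   allele frequencies match.  Must lie in \[0, 1).
#' @param missing_rate genotype missingness rate (dosages set `NA`).
#' @param h2_polygenic narrow-sense heritability of the polygenic term.
#' @param qtl_spec data frame with columns `variant` (marker index) and
#'   `pve` (target variance fraction), or `NULL` for none.
#' @param n_hatches number of hatches (batch fixed effect).
#' @param two_lines if `TRUE`, samples split into high/low lines with a mean
#'   difference `line_diff`.
#' @param hatch_sd,line_diff fixed-effect magnitudes on the unit-variance
#'   trait scale.
#' @param n_genes,n_expr_samples expression panel dimensions
#'   (`n_expr_samples <= n_samples`).
#' @param eqtl_effect cis-eQTL allele substitution effect shared by genes.
#' @param expr_noise_sd residual standard deviation of expression.
#' @param tf_hub list with `hub` (gene index), `targets` (gene indices) and
#'   `effect` (regulatory effect of hub expression on each target).
#' @param n_sv number of true structural variants in the SV truth set.
#' @param sv_size_range true SV length range in bp.
#' @param promoter_length promoter sequence length in bp.
#' @param tss_position 1-based position of the TSS within each promoter.
#' @param plant_prob_fore,plant_prob_back probability that a
#'   foreground/background gene's promoter receives a planted motif.
#' @param base_probs background base composition (A, C, G, T; sums to 1).
#' @return an object of class `sim_config`.
#' @export
new_sim_config <- function(seed = 1L,
                           n_samples = 500L,
                           n_chromosomes = 5L,
                           n_variants_per_chrom = 400L,
                           chrom_length = 1e6,
                           maf_range = c(0.05, 0.5),
                           ld_decay = 0.3,
                           missing_rate = 0,
                           h2_polygenic = 0.15,
                           qtl_spec = NULL,
                           n_hatches = 4L,
                           two_lines = TRUE,
                           hatch_sd = 0.5,
                           line_diff = 0.5,
                           n_genes = 86L,
                           n_expr_samples = 167L,
                           eqtl_effect = 1,
                           expr_noise_sd = 1,
                           tf_hub = list(hub = 1L, targets = 2:21, effect = 0.8),
                           n_sv = 200L,
                           sv_size_range = c(50, 5000),
                           promoter_length = 2001L,
                           tss_position = 1501L,
                           plant_prob_fore = 0.6,
                           plant_prob_back = 0.2,
                           base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              n_variants_per_chrom = as.integer(n_variants_per_chrom),
              chrom_length = chrom_length, maf_range = maf_range,
              ld_decay = ld_decay, missing_rate = missing_rate,
              h2_polygenic = h2_polygenic, qtl_spec = qtl_spec,
              n_hatches = as.integer(n_hatches), two_lines = isTRUE(two_lines),
              hatch_sd = hatch_sd, line_diff = line_diff,
              n_genes = as.integer(n_genes),
              n_expr_samples = as.integer(n_expr_samples),
              eqtl_effect = eqtl_effect, expr_noise_sd = expr_noise_sd,
              tf_hub = tf_hub, n_sv = as.integer(n_sv),
              sv_size_range = sv_size_range,
              promoter_length = as.integer(promoter_length),
              tss_position = as.integer(tss_position),
              plant_prob_fore = plant_prob_fore,
              plant_prob_back = plant_prob_back,
              base_probs = base_probs)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  counts <- c(cfg$n_samples, cfg$n_chromosomes, cfg$n_variants_per_chrom,
              cfg$n_hatches, cfg$n_genes, cfg$n_expr_samples, cfg$n_sv)
  if (any(!is.finite(counts)) || any(counts < 1L))
    bad("all counts must be positive")
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    bad("maf_range must lie within (0, 0.5]")
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1)
    bad("ld_decay must lie in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    bad("missing_rate must lie in [0, 1)")
  if (cfg$h2_polygenic < 0 || cfg$h2_polygenic >= 1)
    bad("h2_polygenic must lie in [0, 1)")
  pve_total <- total_qtl_pve(cfg)
  if (cfg$h2_polygenic + pve_total >= 1)
    bad("h2_polygenic + total QTL PVE must be < 1")
  if (!is.null(cfg$qtl_spec)) {
    if (!all(c("variant", "pve") %in% names(cfg$qtl_spec)))
      bad("qtl_spec needs columns 'variant' and 'pve'")
    m <- cfg$n_chromosomes * cfg$n_variants_per_chrom
    if (any(cfg$qtl_spec$variant < 1 | cfg$qtl_spec$variant > m))
      bad("qtl_spec variant index out of range")
    if (any(cfg$qtl_spec$pve <= 0)) bad("qtl_spec PVE must be positive")
  }
  if (cfg$n_expr_samples > cfg$n_samples)
    bad("n_expr_samples must not exceed n_samples")
  hub <- cfg$tf_hub
  if (!is.null(hub)) {
    idx <- c(hub$hub, hub$targets)
    if (any(idx < 1 | idx > cfg$n_genes))
      bad("tf_hub gene indices out of range")
    if (hub$hub %in% hub$targets) bad("tf_hub hub cannot be its own target")
  }
  if (cfg$tss_position < 1 || cfg$tss_position > cfg$promoter_length)
    bad("tss_position must lie within the promoter")
  for (p in c(cfg$plant_prob_fore, cfg$plant_prob_back))
    if (p < 0 || p > 1) bad("plant probabilities must lie in [0, 1]")
  if (length(cfg$base_probs) != 4 || abs(sum(cfg$base_probs) - 1) > 1e-8 ||
      any(cfg$base_probs < 0))
    bad("base_probs must be 4 non-negative values summing to 1")
  invisible(cfg)
}

total_qtl_pve <- function(cfg) {
  if (is.null(cfg$qtl_spec)) 0 else sum(cfg$qtl_spec$pve)
}

# fixed offsets expand the master seed into per-component streams
child_seed <- function(cfg, component) {
  offsets <- c(truth = 101L, genotypes = 211L, phenotype = 307L,
               expression = 401L, callers = 503L, promoters = 601L,
               pipeline = 701L)
  if (!component %in% names(offsets))
    stop("unknown seed component: ", component)
  (cfg$seed + offsets[[component]]) %% .Machine$integer.max
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_samples, "samples,",
      x$n_chromosomes * x$n_variants_per_chrom, "markers on",
      x$n_chromosomes, "chromosomes\n")
  cat("  h2_polygenic =", x$h2_polygenic, "; total QTL PVE =",
      total_qtl_pve(x), "\n")
  cat("  expression:", x$n_genes, "genes x", x$n_expr_samples, "samples\n")
  invisible(x)
}
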