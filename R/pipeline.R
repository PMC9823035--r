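#' Run the full analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order:
#' `simulate` (two study designs: an F2-like cross and a half-sib-like
#' two-line population, plus expression, caller call sets and promoters),
#' `merge` (multi-caller merging and filtering), `gwas` (MLM-LOCO per
#' design), `meta` (sample-size-weighted combination), `egwas`, `awm`
#' (variant selection, AWM, PCIT network) and `tfbs` (promoter scan and
#' coverage enrichment).  Every stage writes its outputs under `outdir` and
#' appends to the returned manifest; a stage whose upstream outputs are
#' missing raises a dependency error naming the stage.
#'
#' @param cfg a `run_config` from [validate_config()] (or `NULL` for
#'   defaults).
#' @param outdir output directory (created if needed).
#' @param seed optional integer overriding the config seed.
#' @return data frame manifest: `stage`, `file`, `n_rows`, `params`.
#' @export
run_pipeline <- function(cfg = NULL, outdir = tempfile("pecknet_run_"),
                         seed = NULL) {
  if (is.null(cfg)) cfg <- validate_config(NULL)$config
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  manifest <- list()
  note <- function(stage, file, n_rows, params = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = file, n_rows = n_rows, params = params,
      stringsAsFactors = FALSE)
  }
  pth <- function(...) file.path(outdir, paste0(...))
  need <- function(stage, file) {
    if (!file.exists(file))
      stop("stage '", stage, "' is missing its upstream input: ", file,
           call. = FALSE)
    file
  }
  env <- new.env(parent = emptyenv())
  pwm_file <- system.file("extdata", "synthetic_ets_motif.jaspar",
                          package = "pecknet")

  if ("simulate" %in% stages) {
    qtl <- data.frame(variant = 42L, pve = cfg$sim.qtl_pve)
    hub <- list(hub = 1L,
                targets = 2:max(2L, min(21L, cfg$sim.n_genes)),
                effect = 0.8)
    env$cfg_hs <- new_sim_config(
      seed = cfg$seed, n_samples = cfg$sim.n_samples_hs,
      n_chromosomes = cfg$sim.n_chromosomes,
      n_variants_per_chrom = cfg$sim.n_variants_per_chrom,
      h2_polygenic = cfg$sim.h2_polygenic, qtl_spec = qtl,
      two_lines = TRUE, n_genes = cfg$sim.n_genes, tf_hub = hub,
      n_expr_samples = cfg$sim.n_expr_samples)
    env$cfg_f2 <- new_sim_config(
      seed = cfg$seed + 1L, n_samples = cfg$sim.n_samples_f2,
      n_chromosomes = cfg$sim.n_chromosomes,
      n_variants_per_chrom = cfg$sim.n_variants_per_chrom,
      h2_polygenic = cfg$sim.h2_polygenic, qtl_spec = qtl,
      two_lines = FALSE, n_genes = cfg$sim.n_genes, tf_hub = hub,
      n_expr_samples = min(cfg$sim.n_expr_samples, cfg$sim.n_samples_f2))
    for (design in c("hs", "f2")) {
      scfg <- env[[paste0("cfg_", design)]]
      # keep a non-empty promoter background even for small gene panels
      truth <- simulate_truth(scfg,
                              n_motif_genes = max(1L,
                                                  min(23L, scfg$n_genes - 5L)))
      gt <- simulate_genotypes(scfg)
      ph <- simulate_phenotype(gt, scfg, truth)
      env[[paste0("gt_", design)]] <- gt
      env[[paste0("ph_", design)]] <- ph
      env[[paste0("truth_", design)]] <- truth
      write_dosage_tsv(gt, pth("genotypes_", design, ".tsv"))
      utils::write.table(ph, pth("phenotypes_", design, ".tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      note("simulate", pth("genotypes_", design, ".tsv"), nrow(gt$dosage),
           paste0("design=", design))
      note("simulate", pth("phenotypes_", design, ".tsv"), nrow(ph))
    }
    env$expr <- simulate_expression(env$gt_hs, env$cfg_hs, env$truth_hs)
    utils::write.table(cbind(sample_id = rownames(env$expr),
                             as.data.frame(unclass(env$expr))),
                       pth("expression_hs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("simulate", pth("expression_hs.tsv"), nrow(env$expr))
    env$callsets <- simulate_caller_outputs(
      env$truth_hs, seed = child_seed(env$cfg_hs, "callers"))
    for (cs in env$callsets) {
      write_callset_tsv(cs, pth("callset_", cs$caller_id, ".tsv"))
      note("simulate", pth("callset_", cs$caller_id, ".tsv"),
           nrow(cs$records))
    }
    pwm <- load_jaspar(pwm_file)
    env$promoters <- simulate_promoters(env$truth_hs$genes, pwm, env$cfg_hs,
                                        motif_genes = env$truth_hs$motif_genes)
    Biostrings::writeXStringSet(env$promoters, pth("promoters.fa"))
    note("simulate", pth("promoters.fa"), length(env$promoters))
  }

  if ("merge" %in% stages) {
    if (is.null(env$callsets))
      stop("stage 'merge' requires the simulate stage outputs", call. = FALSE)
    merged <- merge_callsets(env$callsets, max_dist = cfg$merge.max_dist,
                             min_callers = cfg$merge.min_callers,
                             type_aware = cfg$merge.type_aware,
                             strand_aware = cfg$merge.strand_aware,
                             min_size = cfg$merge.min_size)
    filtered <- filter_merged(merged, min_qual = cfg$filter.min_qual,
                              min_callrate = cfg$filter.min_callrate)
    env$merged <- filtered
    write_callset_tsv(merged, pth("merged_raw.tsv"))
    write_callset_tsv(filtered, pth("merged_filtered.tsv"))
    note("merge", pth("merged_raw.tsv"), nrow(merged$records),
         sprintf("max_dist=%g,min_callers=%d", cfg$merge.max_dist,
                 cfg$merge.min_callers))
    note("merge", pth("merged_filtered.tsv"), nrow(filtered$records),
         sprintf("min_qual=%g,min_callrate=%g", cfg$filter.min_qual,
                 cfg$filter.min_callrate))
  }

  if ("gwas" %in% stages) {
    if (is.null(env$gt_hs))
      stop("stage 'gwas' requires the simulate stage outputs", call. = FALSE)
    env$assoc_hs <- mlma_loco(env$gt_hs, env$ph_hs,
                              covariates = c("hatch", "line"),
                              maf_min = cfg$gwas.maf_min)
    env$assoc_f2 <- mlma_loco(env$gt_f2, env$ph_f2, covariates = "hatch",
                              maf_min = cfg$gwas.maf_min)
    write_assoc_tsv(env$assoc_hs, pth("assoc_hs.tsv"))
    write_assoc_tsv(env$assoc_f2, pth("assoc_f2.tsv"))
    note("gwas", pth("assoc_hs.tsv"), nrow(env$assoc_hs),
         paste0("maf_min=", cfg$gwas.maf_min))
    note("gwas", pth("assoc_f2.tsv"), nrow(env$assoc_f2))
  }

  if ("meta" %in% stages) {
    f_hs <- need("meta", pth("assoc_hs.tsv"))
    f_f2 <- need("meta", pth("assoc_f2.tsv"))
    res <- list(hs = if (!is.null(env$assoc_hs)) env$assoc_hs
                     else read_assoc_tsv(f_hs),
                f2 = if (!is.null(env$assoc_f2)) env$assoc_f2
                     else read_assoc_tsv(f_f2))
    meta <- meta_sample_size(res)
    write_assoc_tsv(meta, pth("meta.tsv"))
    note("meta", pth("meta.tsv"), nrow(meta))
  }

  if ("egwas" %in% stages) {
    if (is.null(env$expr))
      stop("stage 'egwas' requires the simulate stage outputs", call. = FALSE)
    env$egwas <- run_egwas(env$gt_hs, env$expr, env$ph_hs,
                           maf_min = cfg$gwas.maf_min)
    dir.create(pth("egwas"), showWarnings = FALSE)
    for (g in names(env$egwas))
      write_assoc_tsv(env$egwas[[g]], file.path(pth("egwas"),
                                                paste0(g, ".tsv")))
    note("egwas", pth("egwas"), length(env$egwas))
  }

  if ("awm" %in% stages) {
    if (is.null(env$egwas) || is.null(env$assoc_hs))
      stop("stage 'awm' requires the gwas and egwas stage outputs",
           call. = FALSE)
    sel <- select_awm_variants(env$assoc_hs, env$egwas,
                               p_thresh = cfg$awm.p_thresh,
                               min_egwas_hits = cfg$awm.min_egwas_hits)
    if (length(sel) == 0) {
      note("awm", pth("awm.tsv"), 0, "no variants selected")
    } else {
      awm <- build_awm(sel, env$assoc_hs, env$egwas,
                       gene_annotation = env$truth_hs$genes)
      write_awm_tsv(awm, pth("awm.tsv"))
      note("awm", pth("awm.tsv"), nrow(awm),
           sprintf("p_thresh=%g,min_egwas_hits=%d", cfg$awm.p_thresh,
                   cfg$awm.min_egwas_hits))
      if (nrow(awm) >= 3) {
        Z <- unclass(awm)
        Z <- Z[, apply(Z, 2, stats::sd) > 0, drop = FALSE]
        net <- pcit(stats::cor(Z))
        export_network(net, pth("network.tsv"))
        note("awm", pth("network.tsv"), sum(net$edges$significant))
      } else {
        note("awm", pth("network.tsv"), 0,
             "too few selected variants for column correlations")
      }
    }
  }

  if ("tfbs" %in% stages) {
    if (is.null(env$promoters))
      stop("stage 'tfbs' requires the simulate stage outputs", call. = FALSE)
    pwm <- load_jaspar(pwm_file)
    fore <- env$promoters[names(env$promoters) %in% env$truth_hs$motif_genes]
    back <- env$promoters[!names(env$promoters) %in% env$truth_hs$motif_genes]
    enr <- multi_motif_panel(list(pwm), fore, back,
                             tss_offset = env$cfg_hs$tss_position,
                             upstream = cfg$tfbs.upstream,
                             downstream = cfg$tfbs.downstream,
                             threshold_frac = cfg$tfbs.threshold_frac)
    utils::write.table(enr, pth("tfbs_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("tfbs", pth("tfbs_enrichment.tsv"), nrow(enr),
         sprintf("window=-%g/+%g,threshold_frac=%g", cfg$tfbs.upstream,
                 cfg$tfbs.downstream, cfg$tfbs.threshold_frac))
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
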