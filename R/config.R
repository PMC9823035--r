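# Flat key-value run configuration: "stage.parameter = value" lines.
# Defaults are the study's printed settings.

run_config_defaults <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "merge", "gwas", "meta", "egwas", "awm", "tfbs"),
    merge.max_dist = 1000, merge.min_callers = 2L, merge.min_size = 30,
    merge.type_aware = TRUE, merge.strand_aware = TRUE,
    filter.min_qual = 1000, filter.min_callrate = 0.8,
    filter.tr_min_dp = 10, filter.tr_min_q = 0.8,
    gwas.maf_min = 0.01, gwas.alpha = 0.05,
    awm.p_thresh = 1e-4, awm.min_egwas_hits = 10L,
    tfbs.upstream = 1500, tfbs.downstream = 500,
    tfbs.threshold_frac = 0.85, tfbs.alpha = 0.05,
    sim.n_samples_hs = 500L, sim.n_samples_f2 = 817L,
    sim.n_chromosomes = 5L, sim.n_variants_per_chrom = 400L,
    sim.h2_polygenic = 0.15, sim.qtl_pve = 0.047,
    sim.n_genes = 86L, sim.n_expr_samples = 167L)
}

run_config_ranges <- function() {
  list(
    merge.max_dist = c(1, Inf), merge.min_callers = c(1, Inf),
    merge.min_size = c(0, Inf),
    filter.min_qual = c(0, Inf), filter.min_callrate = c(0, 1),
    filter.tr_min_dp = c(0, Inf), filter.tr_min_q = c(0, 1),
    gwas.maf_min = c(0, 0.5), gwas.alpha = c(0, 1),
    awm.p_thresh = c(0, 1), awm.min_egwas_hits = c(1, Inf),
    tfbs.upstream = c(0, Inf), tfbs.downstream = c(0, Inf),
    tfbs.threshold_frac = c(1e-6, 1), tfbs.alpha = c(0, 1),
    sim.n_samples_hs = c(10, Inf), sim.n_samples_f2 = c(10, Inf),
    sim.n_chromosomes = c(1, Inf), sim.n_variants_per_chrom = c(2, Inf),
    sim.h2_polygenic = c(0, 1), sim.qtl_pve = c(0, 1),
    sim.n_genes = c(1, Inf), sim.n_expr_samples = c(2, Inf))
}

#' Validate a flat key-value run configuration file
#'
#' The file holds `key = value` lines (`#` comments and blank lines
#' ignored); keys are stage-prefixed (`gwas.maf_min`, `merge.max_dist`,
#' ...).  Unknown keys, duplicate keys, unparsable values and out-of-range
#' values are all collected into the report; an empty (or missing `path`)
#' file yields the all-defaults configuration, whose defaults are the
#' study's printed settings.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return list with `config` (a `run_config`, or `NULL` if invalid) and
#'   `violations` (character vector enumerating every problem).
#' @export
validate_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  ranges <- run_config_ranges()
  violations <- character(0)
  if (!is.null(path)) {
    if (!file.exists(path)) return(list(config = NULL,
                                        violations = paste("file not found:", path)))
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    seen <- character(0)
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) {
        violations <- c(violations, paste("unparsable line:", ln))
        next
      }
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key %in% seen) {
        violations <- c(violations, paste("duplicate key:", key))
        next
      }
      seen <- c(seen, key)
      if (!key %in% names(cfg)) {
        violations <- c(violations, paste("unknown key:", key))
        next
      }
      old <- cfg[[key]]
      new <- if (key == "stages") strsplit(val, "[, ]+")[[1]]
        else if (is.logical(old)) as.logical(val)
        else suppressWarnings(as.numeric(val))
      if (length(new) == 0 || anyNA(new)) {
        violations <- c(violations, paste("unparsable value for", key, ":", val))
        next
      }
      if (is.integer(old) && !is.character(new)) new <- as.integer(new)
      cfg[[key]] <- new
    }
  }
  for (key in names(ranges)) {
    v <- cfg[[key]]
    r <- ranges[[key]]
    if (is.numeric(v) && (v < r[1] || v > r[2]))
      violations <- c(violations,
                      sprintf("%s = %s outside [%s, %s]", key, v, r[1], r[2]))
  }
  known_stages <- run_config_defaults()$stages
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad))
    violations <- c(violations, paste("unknown stage(s):",
                                      paste(bad, collapse = ", ")))
  if (length(violations)) return(list(config = NULL, violations = violations))
  class(cfg) <- "run_config"
  list(config = cfg, violations = character(0))
}
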