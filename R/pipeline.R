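# End-to-end pipeline driver.
#
# Stage order: preprocessing filters -> VMR detection -> methQTL scan with
# best-pair selection and skew diagnostics -> model competition ->
# genotype-segregated regressions -> island-context enrichment. Every stage
# writes a TSV intermediate into the run directory so stages are
# independently re-runnable, and a machine-readable JSON summary captures
# the counts and proportions the analysis reports.

#' Pipeline run configuration
#'
#' Collects all stage thresholds. Defaults mirror the package's standard
#' analysis settings: >5% beta-range variability filter, MAD threshold at
#' the 95th percentile, 1-kb VMR contiguity, 1000 skew-test bins, Akaike
#' delta > 2 and adjusted R-squared > 0.4 confidence filter.
#'
#' @param min_range variability filter threshold (beta units).
#' @param percentile MAD percentile for VMR calling.
#' @param max_gap_bp VMR contiguity distance.
#' @param n_bins skew-test bins.
#' @param delta_min,adjr2_min confidence-filter thresholds.
#' @param candidate_policy G-by-E SNP candidate policy (`"topk"` or
#'   `"same_chrom"`).
#' @param k_top K for the top-K candidate policy.
#' @param min_complete complete-case floor per scan regression.
#' @param min_group_n minimum genotype-class size for segregated analysis.
#' @param subset_ethnicity optional group label; when set, the whole
#'   pipeline runs on that subset of samples only (single-ethnicity re-run).
#' @param top_nonvmr how many top non-VMR CpGs to capture.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_range = 0.05, percentile = 95, max_gap_bp = 1000,
                       n_bins = 1000, delta_min = 2, adjr2_min = 0.4,
                       candidate_policy = "topk", k_top = 200,
                       min_complete = 10, min_group_n = 10,
                       subset_ethnicity = NULL, top_nonvmr = 1500) {
  stopifnot(min_range >= 0, percentile > 0, percentile < 100,
            max_gap_bp > 0, n_bins > 0)
  structure(list(min_range = min_range, percentile = percentile,
                 max_gap_bp = max_gap_bp, n_bins = n_bins,
                 delta_min = delta_min, adjr2_min = adjr2_min,
                 candidate_policy = candidate_policy, k_top = k_top,
                 min_complete = min_complete, min_group_n = min_group_n,
                 subset_ethnicity = subset_ethnicity,
                 top_nonvmr = top_nonvmr),
            class = "run_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()], or any list with
#'   the same elements (`meth`, `genotypes`, `snps`, `probes`, `islands`,
#'   `env`) built from files.
#' @param config a [run_config()].
#' @param outdir optional run directory; when given, stage intermediates
#'   (TSV/BED), a config echo and `summary.json` are written there.
#' @return list of class `vmrqtl_run` with elements `counts`, `vmrs`,
#'   `pairs`, `competition`, `segregation`, `enrichment`, `config`.
#' @export
run_pipeline <- function(cohort, config = run_config(), outdir = NULL) {
  if (!is.null(config$subset_ethnicity)) {
    keep <- cohort$env$ethnicity %in% config$subset_ethnicity
    if (!any(keep)) stop("subset_ethnicity matches no samples", call. = FALSE)
    cohort$env <- cohort$env[keep, , drop = FALSE]
    cohort$meth <- cohort$meth[, keep, drop = FALSE]
    cohort$genotypes <- cohort$genotypes[, keep, drop = FALSE]
  }
  al <- align_cohort(cohort$meth, cohort$genotypes, cohort$env)
  n_probes_in <- nrow(al$meth)
  n_snps_in <- nrow(al$genotypes)

  meth <- filter_variable_probes(al$meth, config$min_range)
  geno <- filter_heterologous_snps(al$genotypes)
  snp_map <- cohort$snps[cohort$snps$snp_id %in% rownames(geno), ,
                         drop = FALSE]
  manifest <- cohort$probes[cohort$probes$probe_id %in% rownames(meth), ,
                            drop = FALSE]

  scores <- compute_mad(meth)
  vmrs <- detect_vmrs(scores, manifest, config$percentile,
                      config$max_gap_bp)
  top_extra <- top_nonvmr_cpgs(scores, vmrs,
                               min(config$top_nonvmr, max(0, nrow(meth) -
                                 length(unlist(vmr_members(vmrs))))))

  pairs <- methqtl_pairs(meth, geno, snp_map, manifest, al$env$sex,
                         vmrs$rep_probe, config$n_bins,
                         config$min_complete)
  competition <- compete_all(meth, pairs, geno, snp_map, manifest, al$env,
                             candidate_policy = config$candidate_policy,
                             k_top = config$k_top,
                             min_complete = config$min_complete)
  segregation <- segregate(competition, meth, geno, al$env,
                           config$min_group_n)

  ann <- annotate_island_context(manifest$chrom, manifest$pos,
                                 cohort$islands)
  names(ann) <- manifest$probe_id
  enrichment <- enrichment_test(vmrs$rep_probe, manifest$probe_id, ann)

  cls_tab <- table(factor(pairs$class,
                          levels = c("disrupting", "cis", "trans")))
  win_tab <- table(factor(competition$winner, levels = c("G", "E", "GxE")))
  counts <- list(
    samples = length(al$samples),
    probes_in = n_probes_in, probes_variable = nrow(meth),
    snps_in = n_snps_in, snps_heterologous = nrow(geno),
    vmr_count = nrow(vmrs),
    vmr_probes = length(unlist(vmr_members(vmrs))),
    top_nonvmr_captured = length(top_extra),
    pair_classes = as.list(cls_tab),
    pair_class_prop = as.list(round(as.numeric(cls_tab) / nrow(pairs), 4)),
    skewed_count = sum(pairs$skewed),
    skewed_prop = round(mean(pairs$skewed), 4),
    winner_counts = as.list(win_tab),
    winner_prop = as.list(round(as.numeric(win_tab) /
                                  nrow(competition), 4)),
    confidence_subset = sum(competition$passes_confidence),
    segregated_regressions = attr(segregation, "m"),
    segregated_significant = if (nrow(segregation))
      sum(segregation$significant) else 0L)
  names(counts$pair_class_prop) <- names(cls_tab)
  names(counts$winner_prop) <- names(win_tab)

  run <- structure(list(counts = counts, vmrs = vmrs, pairs = pairs,
                        competition = competition,
                        segregation = segregation,
                        enrichment = enrichment,
                        top_nonvmr = top_extra, config = config),
                   class = "vmrqtl_run")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    jsonlite::write_json(unclass(config), p("config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_vmrs(vmrs, p("vmrs.bed"), p("vmrs.tsv"))
    utils::write.table(as.data.frame(pairs), p("pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(competition), p("competition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(segregation), p("segregation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enrichment, p("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(counts, p("summary.json"), auto_unbox = TRUE,
                         digits = 8)
  }
  run
}

#' @export
print.vmrqtl_run <- function(x, ...) {
  ct <- x$counts
  cat("vmrqtl pipeline run\n")
  cat(sprintf("  samples: %d | probes %d -> %d variable | SNPs %d -> %d heterologous\n",
              ct$samples, ct$probes_in, ct$probes_variable, ct$snps_in,
              ct$snps_heterologous))
  cat(sprintf("  VMRs: %d (%d member probes); top non-VMR CpGs captured: %d\n",
              ct$vmr_count, ct$vmr_probes, ct$top_nonvmr_captured))
  cat(sprintf("  best pairs: disrupting=%d cis=%d trans=%d | skewed: %d (%.0f%%)\n",
              ct$pair_classes$disrupting, ct$pair_classes$cis,
              ct$pair_classes$trans, ct$skewed_count,
              100 * ct$skewed_prop))
  cat(sprintf("  winners: G=%d E=%d GxE=%d | high-confidence: %d\n",
              ct$winner_counts$G, ct$winner_counts$E, ct$winner_counts$GxE,
              ct$confidence_subset))
  cat(sprintf("  segregated regressions: %d (%d significant after Bonferroni)\n",
              ct$segregated_regressions, ct$segregated_significant))
  invisible(x)
}
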