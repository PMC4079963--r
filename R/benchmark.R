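# Parameter-recovery experiment on the standard synthetic benchmark.
#
# One replicate = one simulated cohort at the default configuration (237
# samples in three ethnic groups, ~2,000 probes, ~5,000 SNPs, 19
# environments). Measurements condition on the planted truth, not on VMR
# detection, so each stage is scored against what was actually planted:
#  - cis recovery: fraction of planted genotype-effect cluster
#    representatives whose genome-wide best pair is the planted partner SNP;
#  - winner accuracy: AIC competition winner vs planted class, for planted
#    G and planted G-by-E representatives;
#  - cis fraction: share of planted representatives whose best pair is on
#    the probe's own chromosome (chance level 1/n_chromosomes);
#  - segregated-group recovery: for group-form interaction plants (effect
#    confined to genotype class 3), whether the per-genotype regressions
#    rank class 3 best;
#  - null calibration: Kolmogorov-Smirnov uniformity of the scan P-values
#    of a null probe against SNPs on other chromosomes.

#' Run the planted-effect recovery experiment
#'
#' @param seeds integer vector of simulation seeds (one cohort per seed).
#' @param config_fn function mapping a seed to a [sim_config()]; defaults
#'   to the standard benchmark configuration.
#' @param run_cfg a [run_config()] providing the analysis thresholds.
#' @return data frame with one row per seed: n_g, cis_recovered,
#'   winner_g_correct, n_gxe, winner_gxe_correct, n_reps, cis_pairs,
#'   n_group, seg_group_correct, null_ks_p.
#' @export
planted_recovery_experiment <- function(seeds,
                                        config_fn = function(s)
                                          sim_config(seed = s),
                                        run_cfg = run_config()) {
  rows <- lapply(seeds, function(s) {
    co <- simulate_cohort(config_fn(s))
    set.seed(stage_seed(s, 71L))
    tr <- co$truth
    scores <- compute_mad(co$meth)

    # one representative (max-MAD member) per planted cluster
    planted <- tr[tr$class != "null", , drop = FALSE]
    planted$cluster <- co$probes$cluster[match(planted$probe_id,
                                               co$probes$probe_id)]
    reps <- vapply(split(planted$probe_id, planted$cluster),
                   function(ids) ids[which.max(scores[ids])], character(1))
    rep_tr <- tr[match(reps, tr$probe_id), , drop = FALSE]

    pairs <- methqtl_pairs(co$meth, co$genotypes, co$snps, co$probes,
                           co$env$sex, reps, run_cfg$n_bins,
                           run_cfg$min_complete)
    is_g <- rep_tr$class == "G"
    is_gxe <- rep_tr$class == "GxE"
    cis_recovered <- sum(pairs$snp_id[is_g] == rep_tr$snp_id[is_g])

    cmp <- compete_all(co$meth, pairs[is_g | is_gxe, , drop = FALSE],
                       co$genotypes, co$snps, co$probes, co$env,
                       candidate_policy = run_cfg$candidate_policy,
                       k_top = run_cfg$k_top,
                       min_complete = run_cfg$min_complete)
    w_truth <- rep_tr$class[match(cmp$probe_id, rep_tr$probe_id)]
    winner_g_correct <- sum(cmp$winner == "G" & w_truth == "G")
    winner_gxe_correct <- sum(cmp$winner == "GxE" & w_truth == "GxE")

    # segregated analysis on the group-form plants, using the planted truth
    grp <- rep_tr[!is.na(rep_tr$gxe_form) & rep_tr$gxe_form == "group", ,
                  drop = FALSE]
    seg_ok <- 0L
    for (i in seq_len(nrow(grp))) {
      fake <- data.frame(probe_id = grp$probe_id[i], winner = "GxE",
                         snp_id = grp$snp_id[i], env = grp$env[i],
                         stringsAsFactors = FALSE)
      sg <- segregate(fake, co$meth, co$genotypes, co$env,
                      run_cfg$min_group_n)
      if (nrow(sg) && sg$genotype[sg$best_group] == grp$gxe_group[i])
        seg_ok <- seg_ok + 1L
    }

    # null calibration: permute the sample labels of a central null probe so
    # methylation is independent of genotype, then scan 1,000 SNPs from
    # other chromosomes and test the P-values for uniformity
    nulls <- tr[tr$class == "null", , drop = FALSE]
    np <- nulls$probe_id[which.min(abs(nulls$b0))]
    np_chrom <- co$probes$chrom[match(np, co$probes$probe_id)]
    trans_snps <- sample(co$snps$snp_id[co$snps$chrom != np_chrom], 1000L)
    sc <- scan_cpg(sample(co$meth[np, ]),
                   co$genotypes[trans_snps, , drop = FALSE],
                   co$env$sex, run_cfg$min_complete)
    pv <- sc$p_value[!is.na(sc$p_value)]
    ks <- suppressWarnings(stats::ks.test(pv, "punif"))

    data.frame(seed = s, n_g = sum(is_g), cis_recovered = cis_recovered,
               winner_g_correct = winner_g_correct,
               n_gxe = sum(is_gxe), winner_gxe_correct = winner_gxe_correct,
               n_reps = nrow(pairs),
               cis_pairs = sum(pairs$class %in% c("cis", "disrupting")),
               n_group = nrow(grp), seg_group_correct = seg_ok,
               null_ks_p = ks$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a recovery experiment
#'
#' @param x output of [planted_recovery_experiment()].
#' @return list of pooled rates: cis_recovery, winner_accuracy_g,
#'   winner_accuracy_gxe, winner_accuracy_pooled, cis_fraction,
#'   seg_group_recovery, null_calibration_pass (share of seeds with KS
#'   P > 0.01).
#' @export
summarise_recovery <- function(x) {
  list(cis_recovery = sum(x$cis_recovered) / sum(x$n_g),
       winner_accuracy_g = sum(x$winner_g_correct) / sum(x$n_g),
       winner_accuracy_gxe = sum(x$winner_gxe_correct) / sum(x$n_gxe),
       winner_accuracy_pooled = (sum(x$winner_g_correct) +
                                   sum(x$winner_gxe_correct)) /
         (sum(x$n_g) + sum(x$n_gxe)),
       cis_fraction = sum(x$cis_pairs) / sum(x$n_reps),
       seg_group_recovery = sum(x$seg_group_correct) / sum(x$n_group),
       null_calibration_pass = mean(x$null_ks_p > 0.01))
}
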