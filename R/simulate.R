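# Synthetic methylome-genotype-environment cohort generator.
#
# All effects are planted on the logit scale so beta values stay in (0,1) and
# effects are symmetric around the baseline. Genotype enters the generative
# model centred on {-1, 0, 1} (the 1/2/3 coding minus 2), so the intercept b0
# is the heterozygote baseline. Environmental variables are standardised to
# z-scores before effects are applied so effect sizes are comparable across
# variables measured in different units.

#' Simulation configuration
#'
#' Builds and validates the configuration that drives the synthetic cohort
#' generator. Defaults define the package's standard benchmark cohort:
#' 237 neonates from three ethnic groups (131/72/34), 22 autosomes, ~2,000
#' array probes in small genomic clusters, ~5,000 independent SNPs with
#' Balding-Nichols population structure, and 19 in-utero environment
#' variables.
#'
#' @param n_samples number of subjects.
#' @param n_chromosomes number of autosomes to simulate.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param n_probes total number of methylation probes.
#' @param n_snps total number of SNPs.
#' @param island_fraction proportion of probes placed inside CpG islands.
#' @param ethnic_groups named numeric vector of group proportions (sum to 1).
#' @param fst allele-frequency divergence parameter, in (0, 1).
#' @param env_specs list of environment variable specifications; see
#'   [default_env_specs()].
#' @param effect_plan data frame describing how many probe clusters receive
#'   each planted effect class; see [default_effect_plan()].
#' @param effect_table optional explicit per-probe effect table overriding
#'   `effect_plan` (columns `probe`, `class`, `snp`, `env`, `b0`, `b_g`,
#'   `b_e`, `b_gxe`, optionally `gxe_form`, `gxe_group`). SNP and probe are
#'   row indices into the generated maps.
#' @param noise_sd logit-scale residual standard deviation.
#' @param b_sex logit-scale sex effect applied to every probe (default 0; all
#'   downstream models adjust for sex regardless).
#' @param planted_maf_range ancestral allele-frequency range used for SNPs
#'   that partner a planted effect, so planted loci are common enough to be
#'   detectable at cohort scale.
#' @param seed integer random seed; the generator derives one sub-seed per
#'   stage from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 237L,
                       n_chromosomes = 22L,
                       chrom_length_bp = 5e6,
                       n_probes = 2000L,
                       n_snps = 5000L,
                       island_fraction = 0.3,
                       ethnic_groups = c(chinese = 131 / 237,
                                         malay = 72 / 237,
                                         indian = 34 / 237),
                       fst = 0.1,
                       env_specs = default_env_specs(),
                       effect_plan = default_effect_plan(),
                       effect_table = NULL,
                       noise_sd = 0.3,
                       b_sex = 0,
                       planted_maf_range = c(0.25, 0.75),
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_probes = as.integer(n_probes),
              n_snps = as.integer(n_snps),
              island_fraction = island_fraction,
              ethnic_groups = ethnic_groups,
              fst = fst,
              env_specs = env_specs,
              effect_plan = effect_plan,
              effect_table = effect_table,
              noise_sd = noise_sd,
              b_sex = b_sex,
              planted_maf_range = planted_maf_range,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_samples > 0, cfg$n_probes >= 0, cfg$n_snps >= 0,
            cfg$n_chromosomes > 0, cfg$chrom_length_bp > 0)
  if (!(cfg$fst > 0 && cfg$fst < 1))
    stop("fst must lie strictly in (0, 1)", call. = FALSE)
  if (abs(sum(cfg$ethnic_groups) - 1) > 1e-8)
    stop("ethnic group proportions must sum to 1", call. = FALSE)
  if (cfg$island_fraction < 0 || cfg$island_fraction > 1)
    stop("island_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  for (spec in cfg$env_specs) {
    if (!spec$type %in% c("continuous", "binary", "ordinal"))
      stop("unknown environment variable type: ", spec$type, call. = FALSE)
  }
  invisible(cfg)
}

# per-stage sub-seeds derived from the master seed; kept below 2^31
stage_seed <- function(seed, offset) (as.integer(seed) %% 900000000L) + offset

#' Default environment variable specifications
#'
#' Nineteen in-utero environment surrogates: a mix of continuous measures
#' (gestational age, birth weight, maternal BMI, depression score, ...),
#' ordinal covariates (birth order, income bracket) and binary exposures
#' (maternal smoking, gestational diabetes, ...). Distribution parameters are
#' field-plausible cohort values; they are placeholders a user studying a
#' specific cohort should replace.
#'
#' @return list of specs, each `list(name, type, ...)`.
#' @export
default_env_specs <- function() {
  cont <- function(name, mean, sd) list(name = name, type = "continuous",
                                        mean = mean, sd = sd)
  bin <- function(name, prevalence) list(name = name, type = "binary",
                                         prevalence = prevalence)
  ord <- function(name, levels, probs) list(name = name, type = "ordinal",
                                            levels = levels, probs = probs)
  list(
    cont("gestational_age_wk", 38.5, 1.4),
    cont("birth_weight_kg", 3.10, 0.42),
    cont("birth_length_cm", 49.0, 2.0),
    cont("head_circumference_cm", 33.5, 1.4),
    cont("maternal_age_yr", 30.5, 5.0),
    cont("maternal_bmi", 22.8, 3.9),
    cont("maternal_weight_gain_kg", 12.0, 4.5),
    cont("maternal_fasting_glucose", 4.4, 0.5),
    cont("maternal_depression_score", 7.0, 4.0),
    cont("maternal_anxiety_score", 35.0, 8.0),
    ord("household_income_bracket", 1:5, c(0.15, 0.25, 0.30, 0.20, 0.10)),
    ord("maternal_education_yr", c(8, 10, 12, 14, 16),
        c(0.10, 0.20, 0.30, 0.25, 0.15)),
    ord("birth_order", 1:4, c(0.45, 0.35, 0.15, 0.05)),
    bin("maternal_smoking", 0.06),
    bin("household_smoking", 0.25),
    bin("maternal_alcohol_use", 0.05),
    bin("gestational_diabetes", 0.15),
    bin("pregnancy_hypertension", 0.08),
    bin("supplement_use", 0.60)
  )
}

#' Default planted-effect plan
#'
#' Describes, per effect class, how many probe clusters are planted and with
#' what logit-scale effect sizes. The default plants 12 genotype-only
#' clusters (b_G = 0.8), 10 linear gene-by-environment clusters with main
#' effects (b_G = b_E = 0.4, b_GxE = 1.0), 6 group-form G-by-E clusters where
#' the environment slope exists only in genotype class 3 (b = 1.0), and 6
#' environment-only clusters (b_E = 0.8); everything else is null. Cis
#' partner SNPs are placed at distances drawn uniformly from
#' [`dist_lo`, `dist_hi`] bp.
#'
#' @return data frame with one row per planted class.
#' @export
default_effect_plan <- function() {
  data.frame(
    class = c("G", "GxE", "GxE", "E"),
    n_clusters = c(12L, 10L, 6L, 6L),
    b_g = c(0.8, 0.4, 0, 0),
    b_e = c(0, 0.4, 0, 0.8),
    b_gxe = c(0, 1.0, 1.0, 0),
    gxe_form = c("linear", "linear", "group", "linear"),
    gxe_group = c(NA, NA, 3L, NA),
    dist_lo = c(1e3, 1e3, 1e3, NA),
    dist_hi = c(5e4, 5e4, 5e4, NA),
    stringsAsFactors = FALSE
  )
}

#' Generate probe manifest, SNP map and CpG-island intervals
#'
#' Probes are laid out in clusters (1-4 probes, 100-450 bp apart, clusters
#' separated by at least 5 kb) so that regions of >= 2 probes within 1 kb
#' exist and variably methylated regions are callable. A fraction
#' `island_fraction` of probes is covered by non-overlapping CpG-island
#' intervals. SNP positions are uniform per chromosome.
#'
#' @param config a [sim_config()].
#' @return list with `probes` (probe_id, chrom, pos, cluster), `snps`
#'   (snp_id, chrom, pos), and `islands` (chrom, start, end; 1-based
#'   inclusive coordinates).
#' @export
generate_manifest <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 11L))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  if (config$n_probes == 0L) {
    return(list(
      probes = data.frame(probe_id = character(), chrom = character(),
                          pos = integer(), cluster = integer(),
                          stringsAsFactors = FALSE),
      snps = sim_snp_positions(config, chroms),
      islands = data.frame(chrom = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)))
  }

  # distribute probes over chromosomes as evenly as possible
  per_chrom <- rep(config$n_probes %/% config$n_chromosomes,
                   config$n_chromosomes)
  extra <- config$n_probes %% config$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  min_sep <- 5000
  probes <- vector("list", config$n_chromosomes)
  cluster_counter <- 0L
  for (ci in seq_len(config$n_chromosomes)) {
    n_chr <- per_chrom[ci]
    if (n_chr == 0L) next
    sizes <- integer(0)
    while (sum(sizes) < n_chr) {
      sizes <- c(sizes, sample(c(1L, 2L, 3L, 4L), 1L,
                               prob = c(0.50, 0.25, 0.15, 0.10)))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_chr)
    sizes <- sizes[sizes > 0L]
    n_cl <- length(sizes)
    span_budget <- n_cl * (min_sep + 4 * 450)
    if (span_budget >= config$chrom_length_bp)
      stop("chromosome too short (", config$chrom_length_bp,
           " bp) to place ", n_cl, " probe clusters", call. = FALSE)
    # anchors with guaranteed separation: sorted uniforms on the slack space
    slack <- config$chrom_length_bp - span_budget
    anchors <- sort(runif(n_cl, 0, slack)) +
      (seq_len(n_cl) - 1) * (min_sep + 4 * 450) + 1
    pos <- unlist(lapply(seq_len(n_cl), function(k) {
      gaps <- if (sizes[k] > 1) cumsum(c(0, sample(100:450, sizes[k] - 1,
                                                   replace = TRUE)))
              else 0
      round(anchors[k]) + gaps
    }))
    cl <- rep(cluster_counter + seq_len(n_cl), times = sizes)
    cluster_counter <- cluster_counter + n_cl
    probes[[ci]] <- data.frame(chrom = chroms[ci], pos = as.integer(pos),
                               cluster = as.integer(cl),
                               stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, probes)
  probes$probe_id <- sprintf("cg%06d", seq_len(nrow(probes)))
  probes <- probes[, c("probe_id", "chrom", "pos", "cluster")]

  islands <- sim_islands(probes, config$island_fraction)
  snps <- sim_snp_positions(config, chroms)
  list(probes = probes, snps = snps, islands = islands)
}

# islands cover whole (or leading parts of) probe clusters until the target
# probe count is reached; clusters are >=5 kb apart so islands never overlap
sim_islands <- function(probes, island_fraction) {
  target <- round(island_fraction * nrow(probes))
  if (target == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  cl_ids <- sample(unique(probes$cluster))
  out <- list()
  covered <- 0L
  for (cl in cl_ids) {
    if (covered >= target) break
    rows <- probes[probes$cluster == cl, , drop = FALSE]
    rows <- rows[order(rows$pos), , drop = FALSE]
    take <- min(nrow(rows), target - covered)
    sel <- rows[seq_len(take), , drop = FALSE]
    pad <- sample(100:400, 2L, replace = TRUE)
    end <- max(sel$pos) + if (take < nrow(rows)) 50L else pad[2]
    out[[length(out) + 1L]] <- data.frame(
      chrom = sel$chrom[1], start = max(1L, min(sel$pos) - pad[1]),
      end = as.integer(end), stringsAsFactors = FALSE)
    covered <- covered + take
  }
  isl <- do.call(rbind, out)
  isl <- isl[order(isl$chrom, isl$start), , drop = FALSE]
  rownames(isl) <- NULL
  isl
}

sim_snp_positions <- function(config, chroms) {
  if (config$n_snps == 0L)
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), planted = logical(),
                      stringsAsFactors = FALSE))
  per_chrom <- rep(config$n_snps %/% config$n_chromosomes,
                   config$n_chromosomes)
  extra <- config$n_snps %% config$n_chromosomes
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  snps <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    n <- per_chrom[ci]
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(config$chrom_length_bp, n))
    data.frame(chrom = chroms[ci], pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }))
  snps$planted <- FALSE
  snps$snp_id <- sprintf("snp%06d", seq_len(nrow(snps)))
  snps[, c("snp_id", "chrom", "pos", "planted")]
}

#' Plant genetic, environmental and interaction effects
#'
#' Assigns every probe a planted-effect record (most are null) following the
#' config's effect plan: each planted cluster of >= 2 probes receives the
#' same effect class, partner SNP and environment on all member probes, so a
#' called region carries a single recoverable truth. Cis partner SNPs are
#' relocated to the requested distance from the cluster's first probe (the
#' SNP map is re-sorted and re-labelled afterwards). Planted probes get a
#' near-central baseline (b0 ~ U(-0.5, 0.5)) so effects are visible on the
#' beta scale; null probes get b0 ~ U(-2.5, 2.5), emulating the genome-wide
#' spread of methylation levels.
#'
#' @param config a [sim_config()].
#' @param manifest output of [generate_manifest()].
#' @return list with `truth` (one row per probe) and the possibly updated
#'   `snps` map.
#' @export
plant_effects <- function(config, manifest) {
  set.seed(stage_seed(config$seed, 17L))
  probes <- manifest$probes
  snps <- manifest$snps
  n_probes <- nrow(probes)

  truth <- data.frame(
    probe_id = probes$probe_id, probe_idx = seq_len(n_probes),
    class = "null", snp_id = NA_character_, env = NA_character_,
    b0 = runif(n_probes, -2.5, 2.5), b_g = 0, b_e = 0, b_gxe = 0,
    gxe_form = NA_character_, gxe_group = NA_integer_,
    cis = NA, target_dist_bp = NA_real_, realized_dist_bp = NA_real_,
    stringsAsFactors = FALSE)

  if (!is.null(config$effect_table)) {
    et <- config$effect_table
    for (i in seq_len(nrow(et))) {
      j <- et$probe[i]
      truth$class[j] <- et$class[i]
      truth$b0[j] <- if ("b0" %in% names(et)) et$b0[i] else runif(1, -0.5, 0.5)
      truth$b_g[j] <- et$b_g[i]
      truth$b_e[j] <- et$b_e[i]
      truth$b_gxe[j] <- et$b_gxe[i]
      if (!is.null(et$snp) && !is.na(et$snp[i])) {
        truth$snp_id[j] <- snps$snp_id[et$snp[i]]
        snps$planted[et$snp[i]] <- TRUE
        same <- snps$chrom[et$snp[i]] == probes$chrom[j]
        truth$cis[j] <- same
        truth$realized_dist_bp[j] <-
          if (same) abs(snps$pos[et$snp[i]] - probes$pos[j]) else NA_real_
      }
      if (!is.null(et$env)) truth$env[j] <- et$env[i]
      if (!is.null(et$gxe_form)) truth$gxe_form[j] <- et$gxe_form[i]
      if (!is.null(et$gxe_group)) truth$gxe_group[j] <- et$gxe_group[i]
    }
    return(list(truth = truth, snps = snps))
  }

  plan <- config$effect_plan
  if (is.null(plan) || nrow(plan) == 0L || n_probes == 0L)
    return(list(truth = truth, snps = snps))

  cl_sizes <- table(probes$cluster)
  eligible <- as.integer(names(cl_sizes)[cl_sizes >= 2])
  need <- sum(plan$n_clusters)
  if (length(eligible) < need)
    stop("not enough probe clusters of size >= 2 (", length(eligible),
         ") to plant ", need, " effects", call. = FALSE)
  chosen <- sample(eligible, need)
  cont_envs <- vapply(config$env_specs,
                      function(s) if (s$type == "continuous") s$name else NA_character_,
                      character(1))
  cont_envs <- cont_envs[!is.na(cont_envs)]
  snps$uid <- seq_len(nrow(snps))

  ptr <- 0L
  for (r in seq_len(nrow(plan))) {
    for (k in seq_len(plan$n_clusters[r])) {
      ptr <- ptr + 1L
      cl <- chosen[ptr]
      members <- which(probes$cluster == cl)
      chrom <- probes$chrom[members[1]]
      anchor_pos <- probes$pos[members[1]]
      cls <- plan$class[r]

      snp_uid <- NA_integer_
      dist <- NA_real_
      if (cls %in% c("G", "GxE")) {
        dist <- round(runif(1, plan$dist_lo[r], plan$dist_hi[r]))
        cand <- which(snps$chrom == chrom & !snps$planted)
        if (length(cand) == 0L)
          stop("no free SNP on ", chrom, " to plant a cis partner",
               call. = FALSE)
        pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
        side <- sample(c(-1, 1), 1L)
        newpos <- anchor_pos + side * dist
        if (newpos < 1 || newpos > config$chrom_length_bp)
          newpos <- anchor_pos - side * dist
        snps$pos[pick] <- as.integer(newpos)
        snps$planted[pick] <- TRUE
        snp_uid <- snps$uid[pick]
      }
      env <- if (cls %in% c("E", "GxE")) sample(cont_envs, 1L) else NA_character_

      truth$class[members] <- cls
      truth$b0[members] <- runif(length(members), -0.5, 0.5)
      truth$b_g[members] <- plan$b_g[r]
      truth$b_e[members] <- plan$b_e[r]
      truth$b_gxe[members] <- plan$b_gxe[r]
      truth$gxe_form[members] <- if (cls == "GxE") plan$gxe_form[r] else NA
      truth$gxe_group[members] <- if (cls == "GxE") plan$gxe_group[r] else NA
      truth$env[members] <- env
      truth$cis[members] <- if (cls %in% c("G", "GxE")) TRUE else NA
      truth$target_dist_bp[members] <- dist
      if (!is.na(snp_uid)) truth$snp_id[members] <- as.character(snp_uid) # uid placeholder
    }
  }

  # re-sort SNPs after relocation; nudge exact position collisions forward
  repeat {
    snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
    dup <- duplicated(paste(snps$chrom, snps$pos))
    if (!any(dup)) break
    snps$pos[dup] <- snps$pos[dup] + 2L
  }
  snps$snp_id <- sprintf("snp%06d", seq_len(nrow(snps)))
  uid_to_id <- snps$snp_id[match(seq_len(nrow(snps)), snps$uid)]
  planted_rows <- !is.na(truth$snp_id)
  truth$snp_id[planted_rows] <- uid_to_id[as.integer(truth$snp_id[planted_rows])]
  m <- match(truth$snp_id, snps$snp_id)
  same <- !is.na(m) & snps$chrom[m] == probes$chrom
  truth$realized_dist_bp[which(same)] <-
    abs(snps$pos[m[which(same)]] - probes$pos[which(same)])
  snps$uid <- NULL
  rownames(snps) <- NULL
  list(truth = truth, snps = snps)
}

#' Generate genotypes under the Balding-Nichols model
#'
#' Ancestral allele frequencies are uniform on (0.05, 0.95); each ethnic
#' group's frequency is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F) so that the
#' between-group frequency variance is p(1-p)F; genotypes are Binomial(2, q)
#' alternate-allele counts recoded 1/2/3 (1 = homozygous reference). SNPs
#' flagged as planted partners draw their ancestral frequency from
#' `planted_maf_range` so planted effects segregate at usable frequencies.
#'
#' @param config a [sim_config()].
#' @param snp_map SNP map (from [generate_manifest()] or [plant_effects()]).
#' @return integer matrix (SNPs x samples) with values in 1/2/3; attributes
#'   `ancestral_p` (per SNP), `group_freq` (SNPs x groups matrix) and
#'   `groups` (per-sample group labels).
#' @export
generate_genotypes <- function(config, snp_map) {
  validate_sim_config(config)
  if (nrow(snp_map) == 0L) stop("snp_map is empty", call. = FALSE)
  set.seed(stage_seed(config$seed, 23L))
  n_snps <- nrow(snp_map)
  groups <- ethnic_assignment(config)
  g_labels <- names(config$ethnic_groups)
  fst <- config$fst

  p <- runif(n_snps, 0.05, 0.95)
  if (any(snp_map$planted))
    p[snp_map$planted] <- runif(sum(snp_map$planted),
                                config$planted_maf_range[1],
                                config$planted_maf_range[2])
  shape_scale <- (1 - fst) / fst
  group_freq <- vapply(g_labels, function(gl) {
    rbeta(n_snps, p * shape_scale, (1 - p) * shape_scale)
  }, numeric(n_snps))
  group_freq <- matrix(group_freq, nrow = n_snps,
                       dimnames = list(snp_map$snp_id, g_labels))

  geno <- matrix(NA_integer_, n_snps, config$n_samples,
                 dimnames = list(snp_map$snp_id,
                                 sample_ids(config$n_samples)))
  for (gi in seq_along(g_labels)) {
    cols <- which(groups == g_labels[gi])
    if (!length(cols)) next
    draws <- rbinom(n_snps * length(cols), 2L,
                    rep(group_freq[, gi], times = length(cols)))
    geno[, cols] <- matrix(draws + 1L, n_snps, length(cols))
  }
  attr(geno, "ancestral_p") <- p
  attr(geno, "group_freq") <- group_freq
  attr(geno, "groups") <- groups
  geno
}

sample_ids <- function(n) sprintf("S%04d", seq_len(n))

# deterministic exact group sizes by largest remainder
ethnic_assignment <- function(config) {
  props <- config$ethnic_groups
  n <- config$n_samples
  counts <- floor(props * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- props * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  rep(names(props), times = counts)
}

#' Generate the sample metadata table
#'
#' One column per environment spec, plus `sex` (0/1) and `ethnicity`.
#' Continuous variables are normal; binary variables are Bernoulli; ordinal
#' variables are sampled from the declared levels with the declared
#' probabilities.
#'
#' @param config a [sim_config()].
#' @return data frame with one row per sample.
#' @export
generate_environment <- function(config) {
  validate_sim_config(config)
  if (!length(config$env_specs)) stop("env_specs is empty", call. = FALSE)
  set.seed(stage_seed(config$seed, 37L))
  n <- config$n_samples
  out <- data.frame(sample_id = sample_ids(n),
                    sex = rbinom(n, 1L, 0.5),
                    ethnicity = ethnic_assignment(config),
                    stringsAsFactors = FALSE)
  for (spec in config$env_specs) {
    out[[spec$name]] <- switch(
      spec$type,
      continuous = rnorm(n, spec$mean, spec$sd),
      binary = rbinom(n, 1L, spec$prevalence),
      ordinal = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
      stop("unknown environment variable type: ", spec$type, call. = FALSE))
  }
  out
}

#' Generate the methylation beta-value matrix
#'
#' For each probe, the logit-scale methylation is
#' `m = b0 + b_sex*sex + b_G*g + b_E*e + b_GxE*g*e + noise`, where `g` is the
#' genotype centred on -1/0/+1 and `e` the z-scored partner environment;
#' group-form interactions instead apply an environment slope of `b_GxE` only
#' within the designated genotype class. Beta values are the logistic
#' transform, clamped infinitesimally inside (0, 1).
#'
#' @param config a [sim_config()].
#' @param genotypes matrix from [generate_genotypes()].
#' @param env_table data frame from [generate_environment()].
#' @param truth truth table from [plant_effects()].
#' @return numeric matrix (probes x samples) of beta values in (0, 1).
#' @export
generate_methylation <- function(config, genotypes, env_table, truth) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 53L))
  n <- config$n_samples
  n_probes <- nrow(truth)
  sex <- env_table$sex
  meth <- matrix(NA_real_, n_probes, n,
                 dimnames = list(truth$probe_id, env_table$sample_id))
  for (j in seq_len(n_probes)) {
    m <- rep(truth$b0[j], n) + config$b_sex * sex
    has_g <- !is.na(truth$snp_id[j])
    if (has_g) {
      g_raw <- genotypes[truth$snp_id[j], ]
      g <- as.numeric(g_raw) - 2
      m <- m + truth$b_g[j] * g
    }
    if (!is.na(truth$env[j])) {
      e_raw <- env_table[[truth$env[j]]]
      e <- as.numeric(scale(e_raw))
      m <- m + truth$b_e[j] * e
      if (truth$b_gxe[j] != 0) {
        if (!is.na(truth$gxe_form[j]) && truth$gxe_form[j] == "group") {
          m <- m + truth$b_gxe[j] * e * (g_raw == truth$gxe_group[j])
        } else {
          m <- m + truth$b_gxe[j] * g * e
        }
      }
    }
    if (config$noise_sd > 0) m <- m + rnorm(n, 0, config$noise_sd)
    meth[j, ] <- m
  }
  meth <- stats::plogis(meth)
  meth[meth <= 0] <- 1e-12
  meth[meth >= 1] <- 1 - 1e-12
  meth
}

#' Simulate a complete cohort
#'
#' Runs the full generative pipeline: manifest, effect planting, genotypes,
#' environment and methylation, and returns everything together with the
#' truth table for downstream verification.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `config`, `probes`,
#'   `snps`, `islands`, `truth`, `genotypes`, `env`, `meth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  manifest <- generate_manifest(config)
  planted <- plant_effects(config, manifest)
  genotypes <- generate_genotypes(config, planted$snps)
  env <- generate_environment(config)
  meth <- generate_methylation(config, genotypes, env, planted$truth)
  structure(list(config = config, probes = manifest$probes,
                 snps = planted$snps, islands = manifest$islands,
                 truth = planted$truth, genotypes = genotypes,
                 env = env, meth = meth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated methylome cohort\n")
  cat("  samples:     ", ncol(x$meth), "\n")
  cat("  probes:      ", nrow(x$probes), " (",
      sum(x$truth$class != "null"), " with planted effects)\n", sep = "")
  cat("  SNPs:        ", nrow(x$snps), "\n")
  cat("  islands:     ", nrow(x$islands), "\n")
  cat("  planted classes:",
      paste(sprintf("%s=%d", names(table(x$truth$class)),
                    table(x$truth$class)), collapse = ", "), "\n")
  invisible(x)
}
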