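# Synthetic cohort generator

test_that("manifest handles empty and boundary island fractions", {
  cfg0 <- sim_config(n_probes = 0, n_snps = 10, n_chromosomes = 2,
                     effect_plan = NULL)
  man0 <- generate_manifest(cfg0)
  expect_equal(nrow(man0$probes), 0)
  expect_equal(nrow(man0$islands), 0)

  cfg_noisl <- small_cfg(island_fraction = 0)
  man <- generate_manifest(cfg_noisl)
  expect_equal(nrow(man$islands), 0)
})

test_that("manifest geometry: sorted positions, disjoint islands, clusters", {
  man <- generate_manifest(small_cfg())
  for (ch in unique(man$probes$chrom)) {
    expect_true(all(diff(man$probes$pos[man$probes$chrom == ch]) > 0))
    expect_true(all(diff(man$snps$pos[man$snps$chrom == ch]) > 0))
    isl <- man$islands[man$islands$chrom == ch, ]
    if (nrow(isl) > 1)
      expect_true(all(isl$start[-1] > isl$end[-nrow(isl)]))
  }
  # clusters of >= 2 probes within 1 kb exist
  gaps <- unlist(tapply(man$probes$pos, man$probes$chrom,
                        function(p) diff(sort(p))))
  expect_true(any(gaps <= 1000))
})

test_that("island fraction of probes matches the target within 2%", {
  cfg <- sim_config(n_samples = 10, n_probes = 500, n_snps = 50,
                    n_chromosomes = 6, island_fraction = 0.3,
                    effect_plan = NULL, seed = 3)
  man <- generate_manifest(cfg)
  # containment by interval arithmetic, probe by probe
  inside <- vapply(seq_len(nrow(man$probes)), function(i) {
    isl <- man$islands[man$islands$chrom == man$probes$chrom[i], ]
    any(man$probes$pos[i] >= isl$start & man$probes$pos[i] <= isl$end)
  }, logical(1))
  expect_lt(abs(mean(inside) - 0.3), 0.02)
})

test_that("manifest refuses chromosomes too short for the request", {
  cfg <- sim_config(n_probes = 500, n_snps = 50, n_chromosomes = 1,
                    chrom_length_bp = 1e5, effect_plan = NULL)
  expect_error(generate_manifest(cfg), "too short")
})

test_that("Balding-Nichols genotypes: divergence-free limit and moments", {
  # fst -> 0: group frequencies collapse onto the ancestral frequency
  cfg <- sim_config(n_samples = 30, n_probes = 0, n_snps = 300,
                    n_chromosomes = 3, fst = 1e-6, effect_plan = NULL,
                    seed = 5)
  man <- generate_manifest(cfg)
  g <- generate_genotypes(cfg, man$snps)
  expect_true(all(g %in% 1:3))
  expect_lt(max(abs(attr(g, "group_freq") - attr(g, "ancestral_p"))), 1e-2)

  # fst = 0.1, 3 groups, 2000 SNPs: between-group frequency variance has
  # mean p(1-p)F (moment identity of the Beta draw)
  cfg2 <- sim_config(n_samples = 30, n_probes = 0, n_snps = 2000,
                     n_chromosomes = 4, fst = 0.1, effect_plan = NULL,
                     seed = 7)
  man2 <- generate_manifest(cfg2)
  g2 <- generate_genotypes(cfg2, man2$snps)
  gf <- attr(g2, "group_freq")
  p <- attr(g2, "ancestral_p")
  v_emp <- apply(gf, 1, function(x) mean((x - mean(x))^2))
  ratio <- mean(v_emp) / mean(p * (1 - p) * 0.1 * 2 / 3)  # E[s^2_ML] = (k-1)/k * var
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("genotype symmetry and empirical frequency convergence", {
  cfg <- sim_config(n_samples = 5000, n_probes = 0, n_snps = 60,
                    n_chromosomes = 3, fst = 1e-6,
                    ethnic_groups = c(one = 1), effect_plan = NULL,
                    seed = 11)
  man <- generate_manifest(cfg)
  g <- generate_genotypes(cfg, man$snps)
  p <- attr(g, "ancestral_p")
  # mean genotype converges to 1 + 2p per SNP
  expect_lt(max(abs(rowMeans(g) - (1 + 2 * p))), 0.05)
  expect_error(generate_genotypes(sim_config(fst = 0), man$snps), "fst")
  expect_error(generate_genotypes(sim_config(fst = 1), man$snps), "fst")
})

test_that("environment table has declared schema and distributions", {
  cfg <- sim_config(n_samples = 5000, n_probes = 0, n_snps = 10,
                    effect_plan = NULL, seed = 2)
  env <- generate_environment(cfg)
  env_cols <- setdiff(names(env), c("sample_id", "sex", "ethnicity"))
  expect_length(env_cols, 19)
  expect_true(all(env$sex %in% 0:1))
  expect_true(all(env$maternal_smoking %in% 0:1))
  # exact group sizes by largest remainder
  expect_equal(as.numeric(table(env$ethnicity)[c("chinese", "malay", "indian")]),
               round(5000 * c(131, 72, 34) / 237), tolerance = 1)
  # CLT bound on a continuous variable: mean within 3 sd / sqrt(n)
  expect_lt(abs(mean(env$birth_weight_kg) - 3.10), 3 * 0.42 / sqrt(5000))

  zero <- sim_config(n_samples = 200, n_probes = 0, n_snps = 10,
                     env_specs = list(list(name = "x", type = "binary",
                                           prevalence = 0)),
                     effect_plan = NULL)
  expect_true(all(generate_environment(zero)$x == 0))
  bad <- sim_config(n_samples = 10, n_probes = 0, n_snps = 10,
                    effect_plan = NULL)
  bad$env_specs <- list(list(name = "x", type = "exotic"))
  expect_error(generate_environment(bad), "unknown environment")
})

test_that("237-sample default reproduces the 131/72/34 group sizes", {
  cfg <- sim_config(n_probes = 0, n_snps = 10, effect_plan = NULL)
  env <- generate_environment(cfg)
  expect_equal(as.numeric(table(env$ethnicity)[c("chinese", "malay", "indian")]),
               c(131, 72, 34))
})

test_that("methylation generator: logistic identity and genotype levels", {
  n <- 40
  cfg <- sim_config(n_samples = n, n_chromosomes = 2, n_probes = 20,
                    n_snps = 30, noise_sd = 0, effect_plan = NULL,
                    effect_table = data.frame(probe = 1:20, class = "null",
                                              b0 = 0, b_g = 0, b_e = 0,
                                              b_gxe = 0),
                    seed = 4)
  co <- simulate_cohort(cfg)
  expect_true(all(co$meth == 0.5))

  # strong genotype effect, no noise: exactly one beta level per genotype
  cfg2 <- sim_config(n_samples = n, n_chromosomes = 2, n_probes = 20,
                     n_snps = 30, noise_sd = 0, effect_plan = NULL,
                     effect_table = data.frame(probe = 1, class = "G",
                                               snp = 5, b0 = 0, b_g = 2,
                                               b_e = 0, b_gxe = 0),
                     seed = 4)
  co2 <- simulate_cohort(cfg2)
  g <- co2$genotypes[co2$truth$snp_id[1], ]
  y <- co2$meth[1, ]
  expect_equal(length(unique(round(y, 12))), length(unique(g)))
  for (cl in unique(g))
    expect_equal(unname(y[g == cl][1]), plogis(2 * (cl - 2)))
})

test_that("planted genotype effects are recoverable by regression", {
  hits <- vapply(1:5, function(s) {
    cfg <- sim_config(n_samples = 250, n_chromosomes = 2, n_probes = 20,
                      n_snps = 30, noise_sd = 0.3, effect_plan = NULL,
                      effect_table = data.frame(probe = 3, class = "G",
                                                snp = 10, b0 = 0,
                                                b_g = 0.8, b_e = 0,
                                                b_gxe = 0),
                      seed = s)
    co <- simulate_cohort(cfg)
    g <- as.numeric(co$genotypes[co$truth$snp_id[3], ])
    fit <- summary(lm(co$meth[3, ] ~ g))
    fit$coefficients[2, 1] > 0 && fit$coefficients[2, 4] < 1e-6
  }, logical(1))
  expect_true(all(hits))
})

test_that("simulation is bit-reproducible and beta stays in (0,1)", {
  a <- simulate_cohort(small_cfg(seed = 9))
  b <- simulate_cohort(small_cfg(seed = 9))
  expect_identical(a$meth, b$meth)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth, b$truth)
  expect_identical(a$env, b$env)
  expect_true(all(a$meth > 0 & a$meth < 1))
})

test_that("truth table round-trips through the plain-text writer", {
  co <- get_small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  tr <- read_truth_tsv(file.path(dir, "truth.tsv"))
  expect_equal(tr$probe_id, co$truth$probe_id)
  expect_equal(tr$class, co$truth$class)
  expect_equal(tr$snp_id, co$truth$snp_id)
  expect_equal(tr$b_g, co$truth$b_g, tolerance = 1e-12)
  # planted cis partners lie on the probe's chromosome
  planted <- co$truth[!is.na(co$truth$snp_id), ]
  pc <- co$probes$chrom[match(planted$probe_id, co$probes$probe_id)]
  sc <- co$snps$chrom[match(planted$snp_id, co$snps$snp_id)]
  expect_true(all(pc == sc))
})
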