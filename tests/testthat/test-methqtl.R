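# methQTL scan, best-pair selection, skew diagnostic and pair analyses

test_that("scan matches lm coefficient tests on random small instances", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(12:30, 1)
    g <- sample(1:3, n, replace = TRUE)
    while (length(unique(g)) < 2) g <- sample(1:3, n, replace = TRUE)
    sex <- rbinom(n, 1, 0.5)
    y <- 0.4 + 0.05 * g + 0.02 * sex + rnorm(n, 0, 0.05)
    G <- matrix(g, nrow = 1, dimnames = list("s1", NULL))
    if (i %% 3 == 0) { G[1, 1] <- NA }   # exercise the complete-case path
    sc <- scan_cpg(y, G, sex, min_complete = 5)
    cc <- !is.na(G[1, ])
    fit <- summary(lm(y[cc] ~ G[1, cc] + sex[cc]))
    expect_equal(sc$estimate, unname(fit$coefficients[2, 1]),
                 tolerance = 1e-10)
    expect_equal(sc$p_value, unname(fit$coefficients[2, 4]),
                 tolerance = 1e-10)
    expect_equal(sc$r_squared, fit$r.squared, tolerance = 1e-10)
  }
})

test_that("a perfect genotype fit gives R2 = 1 and vanishing P", {
  g <- rep(1:3, each = 10)
  y <- 0.1 * g
  sc <- scan_cpg(y, matrix(g, 1, dimnames = list("s", NULL)),
                 sex = rep(0, 30))
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
  expect_lt(sc$p_value, 1e-200)
})

test_that("scan P-values are uniform under an unstructured null", {
  pass <- vapply(1:20, function(s) {
    set.seed(100 + s)
    n <- 100
    G <- matrix(sample(1:3, 1000 * n, replace = TRUE,
                       prob = c(0.25, 0.5, 0.25)), nrow = 1000)
    rownames(G) <- sprintf("s%04d", 1:1000)
    y <- sample(plogis(rnorm(n, 0, 0.3)))   # permuted labels
    sc <- scan_cpg(y, G, sex = rbinom(n, 1, 0.5))
    suppressWarnings(ks.test(sc$p_value, "punif")$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("scan is invariant to SNP order and best_pair to chunking", {
  co <- get_small_cohort()
  rep_probe <- co$truth$probe_id[co$truth$class == "G"][1]
  y <- co$meth[rep_probe, ]
  sc_full <- scan_cpg(y, co$genotypes, co$env$sex)
  perm <- sample(nrow(co$genotypes))
  sc_perm <- scan_cpg(y, co$genotypes[perm, ], co$env$sex)
  expect_equal(sc_perm[order(match(sc_perm$snp_id, sc_full$snp_id)), ]$p_value,
               sc_full$p_value)
  pm <- co$probes[co$probes$probe_id == rep_probe, ]
  bp_full <- best_pair(sc_full, co$snps, pm$chrom, pm$pos)
  half <- nrow(co$genotypes) %/% 2
  sc_a <- scan_cpg(y, co$genotypes[1:half, ], co$env$sex)
  sc_b <- scan_cpg(y, co$genotypes[(half + 1):nrow(co$genotypes), ],
                   co$env$sex)
  bp_chunk <- best_pair(rbind(sc_a, sc_b), co$snps, pm$chrom, pm$pos)
  expect_equal(bp_chunk$snp_id, bp_full$snp_id)
})

test_that("best_pair selects the minimum P with deterministic tie-breaks", {
  snp_map <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "chr1",
                        pos = c(100, 5000, 9000), stringsAsFactors = FALSE)
  sc <- data.frame(snp_id = c("s1", "s2"), estimate = c(0.1, 0.2),
                   p_value = c(0.01, 0.001), r_squared = c(0.1, 0.2),
                   n_used = 50L, stringsAsFactors = FALSE)
  expect_equal(best_pair(sc, snp_map, "chr1", 200)$snp_id, "s2")
  expect_equal(best_pair(sc[1, ], snp_map, "chr1", 200)$snp_id, "s1")
  # P tie -> larger |estimate|; then smaller distance
  sc2 <- data.frame(snp_id = c("s1", "s2", "s3"),
                    estimate = c(0.1, -0.3, 0.3),
                    p_value = c(0.01, 0.001, 0.001),
                    r_squared = 0.1, n_used = 50L, stringsAsFactors = FALSE)
  expect_equal(best_pair(sc2, snp_map, "chr1", 200)$snp_id, "s2")
  sc2$estimate <- c(0.1, 0.3, -0.3)
  expect_equal(best_pair(sc2, snp_map, "chr1", 4900)$snp_id, "s2")
  # all-null scan errors
  sc3 <- data.frame(snp_id = "s1", estimate = NA_real_, p_value = NA_real_,
                    r_squared = NA_real_, n_used = NA_integer_)
  expect_error(best_pair(sc3, snp_map, "chr1", 200), "no valid tests")
  # argmin oracle over a 500-SNP scan
  set.seed(3)
  big_map <- data.frame(snp_id = sprintf("t%03d", 1:500),
                        chrom = sample(c("chr1", "chr2"), 500, TRUE),
                        pos = sample.int(1e6, 500), stringsAsFactors = FALSE)
  big <- data.frame(snp_id = big_map$snp_id, estimate = rnorm(500),
                    p_value = runif(500), r_squared = runif(500),
                    n_used = 50L, stringsAsFactors = FALSE)
  expect_equal(best_pair(big, big_map, "chr1", 1)$snp_id,
               big$snp_id[which.min(big$p_value)])
})

test_that("skew test bins P-values as specified", {
  # a scan of 708,365 tests expects 708 P-values per bin under uniformity
  expect_equal(skew_test(runif(708365))$expected_per_bin, 708)
  # all P tiny: everything lands in the first bin
  sk <- skew_test(rep(5e-4, 100))
  expect_equal(sk$first_bin_count, 100)
  expect_true(sk$skewed)
  # exact uniform grid at bin centres: first bin equals expectation, not skewed
  grid <- seq(0.0005, 0.9995, by = 0.001)
  sk2 <- skew_test(grid)
  expect_equal(sk2$first_bin_count, 1)
  expect_equal(sk2$expected_per_bin, 1)
  expect_false(sk2$skewed)
  # bin counts always sum to the number of valid tests
  p <- c(runif(497), 0, 1, NA)
  expect_equal(sum(skew_test(p)$bin_counts), 499)
})

test_that("pair classification is positional", {
  expect_equal(classify_pair("chr1", 1000, "chr1", 1001), "disrupting")
  expect_equal(classify_pair("chr1", 1000, "chr1", 1000), "disrupting")
  expect_equal(classify_pair("chr1", 1000, "chr1", 51000), "cis")
  expect_equal(classify_pair("chr1", 1000, "chr2", 1001), "trans")
})

test_that("Kruskal-Wallis class comparison matches the rank formula", {
  pairs_eq <- data.frame(class = rep(c("cis", "trans"), each = 3),
                         neg_log10_p = c(1, 2, 3, 1, 2, 3))
  kt <- compare_classes(pairs_eq)
  expect_equal(unname(kt$statistic), 0, tolerance = 1e-12)
  expect_equal(kt$p.value, 1)
  # hand-computed H for {1,2,3} vs {10,11,12} vs {20,21,22}:
  # ranks 1..9, H = 12/(9*10) * 3*((2-5)^2 + 0 + (8-5)^2) = 7.2
  pairs3 <- data.frame(class = rep(c("disrupting", "cis", "trans"), each = 3),
                       neg_log10_p = c(1, 2, 3, 10, 11, 12, 20, 21, 22))
  expect_equal(unname(compare_classes(pairs3)$statistic), 7.2,
               tolerance = 1e-12)
  expect_error(compare_classes(data.frame(class = "cis", neg_log10_p = 1)),
               "two nonempty")
})

test_that("distance association recovers exact and planted decay", {
  flat <- data.frame(class = "cis", distance_bp = c(0, 2500, 5000),
                     neg_log10_p = 5)
  expect_equal(suppressWarnings(distance_association(flat)$slope), 0,
               tolerance = 1e-12)
  line <- data.frame(class = "cis", distance_bp = c(0, 2500, 5000),
                     neg_log10_p = c(10, 5, 0))
  expect_equal(suppressWarnings(distance_association(line)$slope), -0.002,
               tolerance = 1e-12)
  expect_warning(out <- distance_association(flat[1:2, ]), "fewer than 3")
  expect_true(is.na(out$slope))

  # simulated decay: association strength falls with distance
  ok <- vapply(1:5, function(s) {
    set.seed(400 + s)
    n <- 150
    d <- seq(100, 5000, length.out = 15)
    rows <- lapply(seq_along(d), function(i) {
      g <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
      b <- 0.9 * exp(-d[i] / 1500)
      y <- plogis(b * (g - 2) + rnorm(n, 0, 0.3))
      sc <- scan_cpg(y, matrix(g, 1, dimnames = list("s", NULL)),
                     sex = rbinom(n, 1, 0.5))
      data.frame(class = "cis", distance_bp = d[i],
                 neg_log10_p = -log10(max(sc$p_value, 1e-300)))
    })
    res <- distance_association(do.call(rbind, rows))
    res$slope < 0 && res$p_value < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("planted cis methQTLs attain the scan minimum and classes order", {
  co <- get_small_cohort()
  g_truth <- co$truth[co$truth$class == "G", ]
  reps <- vapply(split(g_truth$probe_id,
                       co$probes$cluster[match(g_truth$probe_id,
                                               co$probes$probe_id)]),
                 `[`, "", 1)
  pairs <- methqtl_pairs(co$meth, co$genotypes, co$snps, co$probes,
                         co$env$sex, reps)
  partner <- g_truth$snp_id[match(pairs$probe_id, g_truth$probe_id)]
  expect_gte(mean(pairs$snp_id == partner), 0.9)
  expect_true(all(pairs$class[pairs$snp_id == partner] == "cis"))
  expect_true(all(pairs$skewed[pairs$snp_id == partner]))
})
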