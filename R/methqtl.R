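# Genome-wide methQTL scan for VMR-CpGs.
#
# Each representative CpG's beta values are regressed on every heterologous
# SNP (genotype coded 1/2/3 and treated as continuous) with sex as a
# covariate. The scan is vectorised by residualising both the methylation
# vector and the genotype matrix on the [intercept, sex] design
# (Frisch-Waugh), after which each SNP's slope, t-test and model R-squared
# come from column sums. SNP columns with missing calls fall back to a
# per-SNP complete-case fit.

#' Scan one CpG against all SNPs
#'
#' @param meth_row numeric vector of beta values for one probe (named by
#'   sample).
#' @param genotypes genotype matrix (SNPs x samples), values 1/2/3 or NA,
#'   samples aligned with `meth_row`.
#' @param sex numeric 0/1 vector aligned with samples.
#' @param min_complete minimum complete cases per SNP regression (default
#'   10); SNPs below the floor get a null (NA) result, as do SNPs that are
#'   monomorphic within the complete cases.
#' @return data frame of class `methqtl_scan`: snp_id, estimate (genotype
#'   slope in beta units per genotype step), p_value (two-sided t-test on
#'   the genotype coefficient), r_squared (full-model R-squared), n_used.
#' @export
scan_cpg <- function(meth_row, genotypes, sex, min_complete = 10) {
  stopifnot(length(meth_row) == ncol(genotypes),
            length(sex) == length(meth_row))
  ok <- !is.na(meth_row) & !is.na(sex)
  y <- meth_row[ok]
  sx <- sex[ok]
  G <- genotypes[, ok, drop = FALSE]
  n_snps <- nrow(G)
  out <- data.frame(snp_id = rownames(G), estimate = NA_real_,
                    p_value = NA_real_, r_squared = NA_real_,
                    n_used = NA_integer_, stringsAsFactors = FALSE)

  X <- cbind(1, sx)
  qx <- qr(X)
  rank0 <- qx$rank
  has_na <- apply(G, 1, anyNA)

  if (any(!has_na)) {
    idx <- which(!has_na)
    y_r <- qr.resid(qx, y)
    G_r <- t(qr.resid(qx, t(G[idx, , drop = FALSE])))
    n <- length(y)
    df <- n - rank0 - 1L
    tss <- sum((y - mean(y))^2)
    syy <- sum(y_r^2)
    sgg <- rowSums(G_r^2)
    sgy <- as.numeric(G_r %*% y_r)
    valid <- sgg > 1e-12 & df > 0
    slope <- ifelse(valid, sgy / sgg, NA_real_)
    rss <- pmax(syy - ifelse(valid, sgy^2 / sgg, 0), 0)
    sigma2 <- rss / df
    tval <- slope / sqrt(sigma2 / sgg)
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    p[valid & sigma2 <= 1e-300] <- 0   # perfect fit underflow
    out$estimate[idx] <- ifelse(valid, slope, NA_real_)
    out$p_value[idx] <- ifelse(valid, p, NA_real_)
    out$r_squared[idx] <- ifelse(valid, 1 - rss / tss, NA_real_)
    out$n_used[idx] <- ifelse(valid, n, NA_integer_)
  }

  for (i in which(has_na)) {
    g <- G[i, ]
    cc <- !is.na(g)
    if (sum(cc) < min_complete) next
    fit <- scan_single(y[cc], g[cc], sx[cc])
    if (is.null(fit)) next
    out$estimate[i] <- fit$estimate
    out$p_value[i] <- fit$p_value
    out$r_squared[i] <- fit$r_squared
    out$n_used[i] <- fit$n
  }
  attr(out, "n_tests") <- sum(!is.na(out$p_value))
  class(out) <- c("methqtl_scan", "data.frame")
  out
}

# complete-case single-SNP fit used on SNPs with missing calls
scan_single <- function(y, g, sx) {
  if (length(unique(g)) < 2L) return(NULL)
  X0 <- cbind(1, sx)
  qx <- qr(X0)
  n <- length(y)
  df <- n - qx$rank - 1L
  if (df <= 0) return(NULL)
  y_r <- qr.resid(qx, y)
  g_r <- qr.resid(qx, g)
  sgg <- sum(g_r^2)
  if (sgg <= 1e-12) return(NULL)
  sgy <- sum(g_r * y_r)
  slope <- sgy / sgg
  rss <- max(sum(y_r^2) - sgy^2 / sgg, 0)
  sigma2 <- rss / df
  p <- if (sigma2 <= 1e-300) 0 else
    2 * stats::pt(abs(slope / sqrt(sigma2 / sgg)), df, lower.tail = FALSE)
  list(estimate = slope, p_value = p,
       r_squared = 1 - rss / sum((y - mean(y))^2), n = n)
}

#' Best CpG-SNP pair from a scan
#'
#' Selects the SNP with the lowest P-value; ties break by larger absolute
#' effect estimate, then smaller genomic distance (trans counts as
#' infinite), then SNP id.
#'
#' @param scan a `methqtl_scan` from [scan_cpg()].
#' @param snp_map SNP map (snp_id, chrom, pos).
#' @param probe_chrom,probe_pos coordinates of the scanned CpG.
#' @return one-row data frame: snp_id, p_value, r_squared, estimate, class,
#'   distance_bp (NA for trans).
#' @export
best_pair <- function(scan, snp_map, probe_chrom, probe_pos) {
  valid <- which(!is.na(scan$p_value))
  if (!length(valid)) stop("no valid tests in scan", call. = FALSE)
  s <- scan[valid, , drop = FALSE]
  m <- match(s$snp_id, snp_map$snp_id)
  dist <- ifelse(snp_map$chrom[m] == probe_chrom,
                 abs(snp_map$pos[m] - probe_pos), Inf)
  ord <- order(s$p_value, -abs(s$estimate), dist, s$snp_id)
  b <- ord[1]
  cls <- classify_pair(probe_chrom, probe_pos,
                       snp_map$chrom[m[b]], snp_map$pos[m[b]])
  data.frame(snp_id = s$snp_id[b], p_value = s$p_value[b],
             r_squared = s$r_squared[b], estimate = s$estimate[b],
             class = cls,
             distance_bp = if (is.finite(dist[b])) dist[b] else NA_real_,
             stringsAsFactors = FALSE)
}

#' P-value distribution skew diagnostic
#'
#' Bins the scan's P-values into `n_bins` equal-width bins over `[0,1]`
#' (half-open, last bin closed) and compares the first-bin count with the
#' count expected under uniformity, `floor(n_tests / n_bins)`. The
#' distribution is flagged skewed when the first bin strictly exceeds the
#' expectation.
#'
#' @param p_values numeric vector of P-values (NAs dropped).
#' @param n_bins number of bins (default 1000).
#' @return list: first_bin_count, expected_per_bin, skewed, bin_counts.
#' @export
skew_test <- function(p_values, n_bins = 1000) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no P-values to bin", call. = FALSE)
  idx <- pmin(n_bins, floor(p * n_bins) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  expected <- floor(length(p) / n_bins)
  list(first_bin_count = counts[1], expected_per_bin = expected,
       skewed = counts[1] > expected, bin_counts = counts)
}

#' Classify a CpG-SNP pair as disrupting, cis or trans
#'
#' Disrupting: the SNP sits inside the CpG dinucleotide itself (the probe
#' position or the base immediately after it, same chromosome). Cis: same
#' chromosome otherwise. Trans: different chromosomes. Classification is
#' positional; whether the allele chemically creates or destroys the CpG is
#' not assessed.
#'
#' @param probe_chrom,probe_pos CpG coordinates (1-based, position of the C).
#' @param snp_chrom,snp_pos SNP coordinates.
#' @return `"disrupting"`, `"cis"` or `"trans"` (vectorised).
#' @export
classify_pair <- function(probe_chrom, probe_pos, snp_chrom, snp_pos) {
  same <- snp_chrom == probe_chrom
  ifelse(same & (snp_pos == probe_pos | snp_pos == probe_pos + 1),
         "disrupting", ifelse(same, "cis", "trans"))
}

#' Scan all VMR-CpGs and build the best-pair table
#'
#' Runs [scan_cpg()], [best_pair()] and [skew_test()] for each representative
#' probe and assembles the per-CpG pair table.
#'
#' @param meth beta matrix (probes x samples).
#' @param genotypes genotype matrix (SNPs x samples), heterologous SNPs.
#' @param snp_map SNP map (snp_id, chrom, pos).
#' @param manifest probe manifest (probe_id, chrom, pos).
#' @param sex numeric 0/1 vector aligned with samples.
#' @param probe_ids representative CpGs to scan.
#' @param n_bins skew-test bin count.
#' @param min_complete complete-case floor per SNP regression.
#' @return data frame of class `methqtl_pairs`: one row per CpG with best
#'   SNP, association statistics, class, distance, skew diagnostics and
#'   -log10 P.
#' @export
methqtl_pairs <- function(meth, genotypes, snp_map, manifest, sex,
                          probe_ids, n_bins = 1000, min_complete = 10) {
  rows <- lapply(probe_ids, function(pid) {
    pm <- manifest[manifest$probe_id == pid, ]
    scan <- scan_cpg(meth[pid, ], genotypes, sex, min_complete)
    bp <- best_pair(scan, snp_map, pm$chrom, pm$pos)
    sk <- skew_test(scan$p_value, n_bins)
    data.frame(probe_id = pid, bp,
               n_tests = attr(scan, "n_tests"),
               first_bin_count = sk$first_bin_count,
               expected_per_bin = sk$expected_per_bin,
               skewed = sk$skewed,
               neg_log10_p = -log10(pmax(bp$p_value, 1e-300)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("methqtl_pairs", "data.frame")
  out
}

#' Compare association strength across pair classes
#'
#' Kruskal-Wallis rank test (tie-corrected) of -log10 P across the
#' disrupting / cis / trans classes.
#'
#' @param pairs a `methqtl_pairs` table (needs `class` and `neg_log10_p`).
#' @return `htest` object from [stats::kruskal.test()].
#' @export
compare_classes <- function(pairs) {
  cls <- factor(pairs$class)
  if (nlevels(droplevels(cls)) < 2L)
    stop("need at least two nonempty pair classes", call. = FALSE)
  stats::kruskal.test(pairs$neg_log10_p, droplevels(cls))
}

#' Distance decay of cis associations
#'
#' OLS of -log10 P on CpG-SNP distance among cis pairs within `max_dist`;
#' a negative slope indicates decaying association strength.
#'
#' @param pairs a `methqtl_pairs` table.
#' @param max_dist maximum distance in bp (default 5000).
#' @return list: slope (per bp), p_value, n; all NA with a warning when
#'   fewer than 3 pairs qualify.
#' @export
distance_association <- function(pairs, max_dist = 5000) {
  d <- pairs[pairs$class == "cis" & !is.na(pairs$distance_bp) &
               pairs$distance_bp <= max_dist, , drop = FALSE]
  if (nrow(d) < 3L) {
    warning("fewer than 3 cis pairs within ", max_dist,
            " bp; no distance fit", call. = FALSE)
    return(list(slope = NA_real_, p_value = NA_real_, n = nrow(d)))
  }
  fit <- stats::lm(neg_log10_p ~ distance_bp, data = d)
  cf <- summary(fit)$coefficients
  slope_p <- if (nrow(cf) > 1 && !is.na(cf[2, 4])) cf[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]), p_value = slope_p, n = nrow(d))
}

#' @export
print.methqtl_pairs <- function(x, ...) {
  cat("methQTL best-pair table: ", nrow(x), " CpGs\n", sep = "")
  tab <- table(factor(x$class, levels = c("disrupting", "cis", "trans")))
  cat("  classes: ", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n", sep = "")
  cat("  skewed P distributions: ", sum(x$skewed), " (",
      round(100 * mean(x$skewed)), "%)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Box plot of association strength by pair class
#' @param x a `methqtl_pairs` table.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.methqtl_pairs <- function(x, ...) {
  cls <- factor(x$class, levels = c("disrupting", "cis", "trans"))
  graphics::boxplot(x$neg_log10_p ~ cls, xlab = "pair class",
                    ylab = expression(-log[10] ~ italic(P)), ...)
  invisible(x)
}
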