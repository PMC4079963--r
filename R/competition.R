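# AIC competition of genotype, environment and gene-by-environment models.
#
# For each VMR-CpG three model families are fit by ordinary least squares on
# an identical complete-case sample subset (otherwise AICs are not
# comparable):
#   G:   meth ~ sex + genotype (categorical, best methQTL SNP)
#   E:   meth ~ sex + env          (best of the 19 environments by AIC)
#   GxE: meth ~ sex + genotype * env  (best SNP-environment pair by AIC)
# AIC uses the Gaussian closed form n*log(RSS/n) + 2*(k+2), counting the
# intercept and residual variance; any consistent constant would do since
# only AIC differences matter.

aic_gauss <- function(n, rss, k) {
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + 2 * (k + 2)
}

# QR-based OLS summary; k excludes the intercept, rank-deficiency tolerated
fit_ols <- function(y, X) {
  qx <- qr(X)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  n <- length(y)
  k <- qx$rank - 1L
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  list(n = n, k = k, rss = rss, r2 = r2,
       aic = aic_gauss(n, rss, k))
}

model_fit <- function(family, fit, snp_id = NA_character_,
                      env = NA_character_) {
  adj <- if (fit$n > fit$k + 1)
    adjusted_r2(fit$r2, fit$k, fit$n) else NA_real_
  list(family = family, snp_id = snp_id, env = env, n = fit$n, k = fit$k,
       rss = fit$rss, aic = fit$aic, r2 = fit$r2, adj_r2 = adj)
}

#' Genotype-only model fit
#'
#' OLS of methylation on sex plus the best methQTL SNP treated as a
#' categorical variable (dummy-coded, reference = lowest observed class).
#'
#' @param y beta values (complete cases).
#' @param snp genotype vector in 1/2/3 aligned with `y`.
#' @param sex numeric 0/1 vector.
#' @param snp_id id recorded in the fit.
#' @return a ModelFit list (family, snp_id, env, n, k, rss, aic, r2, adj_r2).
#' @export
fit_G <- function(y, snp, sex, snp_id = NA_character_) {
  X <- cbind(1, sex, genotype_dummies(snp))
  model_fit("G", fit_ols(y, X), snp_id = snp_id)
}

genotype_dummies <- function(snp) {
  lev <- sort(unique(snp))
  if (length(lev) < 2L) return(NULL)
  vapply(lev[-1], function(l) as.numeric(snp == l), numeric(length(snp)))
}

#' Environment-only model fit
#'
#' Fits sex + environment for every candidate environment variable and
#' returns the lowest-AIC fit, recording which environment won. Environments
#' with no variance on the fitted subset are skipped.
#'
#' @param y beta values (complete cases).
#' @param env_table sample metadata rows aligned with `y`.
#' @param sex numeric 0/1 vector.
#' @param env_names candidate environment column names.
#' @return a ModelFit list, or NULL if no environment was usable.
#' @export
fit_E <- function(y, env_table, sex, env_names) {
  best <- NULL
  n_eval <- 0L
  for (nm in env_names) {
    e <- as.numeric(env_table[[nm]])
    if (stats::var(e) <= 0) next
    n_eval <- n_eval + 1L
    f <- fit_ols(y, cbind(1, sex, e))
    if (is.null(best) || f$aic < best$aic) {
      best <- f; best_env <- nm
    }
  }
  if (is.null(best)) return(NULL)
  out <- model_fit("E", best, env = best_env)
  attr(out, "n_evaluated") <- n_eval
  out
}

#' Gene-by-environment model fit
#'
#' For every candidate (SNP, environment) pair fits sex + genotype
#' (categorical) + environment + genotype:environment and returns the
#' lowest-AIC fit with its SNP and environment recorded. Candidates whose
#' genotype has an observed class with fewer than 2 samples are skipped
#' (singular interaction design); the skip count is reported as an
#' attribute.
#'
#' @param y beta values (complete cases).
#' @param geno_cand genotype matrix (candidate SNPs x samples) aligned with
#'   `y`.
#' @param env_table sample metadata rows aligned with `y`.
#' @param sex numeric 0/1 vector.
#' @param env_names candidate environment column names.
#' @param interaction_only when TRUE, omit the environment main effect
#'   (sex + genotype + genotype:environment).
#' @return a ModelFit list (attribute `n_skipped`), or NULL if every
#'   candidate was skipped.
#' @export
fit_GxE <- function(y, geno_cand, env_table, sex, env_names,
                    interaction_only = FALSE) {
  if (is.null(dim(geno_cand))) geno_cand <- matrix(geno_cand, nrow = 1)
  envs <- lapply(env_names, function(nm) as.numeric(env_table[[nm]]))
  names(envs) <- env_names
  usable <- vapply(envs, function(e) stats::var(e) > 0, logical(1))
  envs <- envs[usable]
  best <- NULL; best_snp <- NA; best_env <- NA; skipped <- 0L
  for (i in seq_len(nrow(geno_cand))) {
    g <- geno_cand[i, ]
    cnt <- table(g)
    if (length(cnt) < 2L || any(cnt < 2L)) { skipped <- skipped + 1L; next }
    D <- genotype_dummies(g)
    base <- cbind(1, sex, D)
    for (nm in names(envs)) {
      e <- envs[[nm]]
      X <- if (interaction_only) cbind(base, D * e)
           else cbind(base, e, D * e)
      f <- fit_ols(y, X)
      if (is.null(best) || f$aic < best$aic) {
        best <- f; best_snp <- rownames(geno_cand)[i]; best_env <- nm
      }
    }
  }
  if (is.null(best)) return(NULL)
  out <- model_fit("GxE", best, snp_id = best_snp, env = best_env)
  attr(out, "n_skipped") <- skipped
  out
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)` for `p` predictors (excluding the
#' intercept) and `n` samples; undefined (error) when `n <= p + 1`.
#'
#' @param r2 sample R-squared.
#' @param p number of predictors, excluding the intercept.
#' @param n sample count.
#' @return the adjusted value (always `<= r2`).
#' @export
adjusted_r2 <- function(r2, p, n) {
  if (n <= p + 1) stop("adjusted R2 undefined for n <= p + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Declare the AIC winner among model families
#'
#' The family with the lowest AIC wins; the Akaike delta is the gap to the
#' next-best family. Exact AIC ties go to the family with fewer predictors,
#' and remaining ties follow the parsimony order G < E < GxE.
#'
#' @param fits named list of ModelFit lists (`G`, `E`, `GxE`); NULL entries
#'   allowed but at least two families must be present.
#' @return list: winner (family name), delta, fits (the input), winner_fit.
#' @export
compete <- function(fits) {
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) < 2L)
    stop("need at least two fitted families to compete", call. = FALSE)
  fam_order <- c(G = 1L, E = 2L, GxE = 3L)
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  ks <- vapply(fits, function(f) f$k, numeric(1))
  ord <- order(aics, ks, fam_order[names(fits)])
  winner <- names(fits)[ord[1]]
  delta <- aics[ord[2]] - aics[ord[1]]
  list(winner = winner, delta = unname(delta), fits = fits,
       winner_fit = fits[[winner]])
}

#' Run the model competition for every VMR-CpG
#'
#' For each row of the best-pair table, assembles the per-probe complete-case
#' subset (methylation, sex, every candidate environment, the best SNP and
#' all candidate G-by-E SNPs), fits the three families and declares the AIC
#' winner. The G-by-E candidate SNP set is, per the chosen policy, either
#' all SNPs on the CpG's chromosome plus the best methQTL SNP
#' (`"same_chrom"`) or the top-K same-chromosome SNPs by scan P-value plus
#' the best SNP (`"topk"`, the desk-scale default).
#'
#' @param meth beta matrix (probes x samples).
#' @param pairs a `methqtl_pairs` table.
#' @param genotypes genotype matrix (SNPs x samples).
#' @param snp_map SNP map (snp_id, chrom, pos).
#' @param manifest probe manifest.
#' @param env_table sample metadata (needs `sex` plus environment columns).
#' @param env_names environment column names (default: the 19 standard
#'   names present in `env_table`).
#' @param candidate_policy `"topk"` or `"same_chrom"`.
#' @param k_top K for the top-K policy (default 200).
#' @param interaction_only passed to [fit_GxE()].
#' @param min_complete complete-case floor for candidate ranking scans.
#' @return data frame of class `vmr_competition`: probe_id, per-family AIC,
#'   winner, delta, winner adjusted R2, winner SNP/env/class, confidence
#'   flag.
#' @export
compete_all <- function(meth, pairs, genotypes, snp_map, manifest,
                        env_table, env_names = NULL,
                        candidate_policy = c("topk", "same_chrom"),
                        k_top = 200, interaction_only = FALSE,
                        min_complete = 10) {
  candidate_policy <- match.arg(candidate_policy)
  if (is.null(env_names))
    env_names <- setdiff(names(env_table), c("sample_id", "sex", "ethnicity"))
  sex <- env_table$sex

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pid <- pairs$probe_id[i]
    best_snp <- pairs$snp_id[i]
    pm <- manifest[manifest$probe_id == pid, ]

    same_chrom <- snp_map$snp_id[snp_map$chrom == pm$chrom]
    cand <- if (candidate_policy == "same_chrom") same_chrom else {
      sc_scan <- scan_cpg(meth[pid, ],
                          genotypes[same_chrom, , drop = FALSE], sex,
                          min_complete)
      ok <- sc_scan$snp_id[!is.na(sc_scan$p_value)]
      pv <- sc_scan$p_value[!is.na(sc_scan$p_value)]
      ok[order(pv)][seq_len(min(k_top, length(ok)))]
    }
    cand <- union(cand, best_snp)

    y_all <- meth[pid, ]
    env_num <- vapply(env_names, function(nm) as.numeric(env_table[[nm]]),
                      numeric(length(y_all)))
    cc <- !is.na(y_all) & !is.na(sex) &
      rowSums(is.na(env_num)) == 0 &
      !is.na(genotypes[best_snp, ]) &
      colSums(is.na(genotypes[cand, , drop = FALSE])) == 0
    y <- y_all[cc]
    sx <- sex[cc]
    et <- env_table[cc, , drop = FALSE]

    fg <- fit_G(y, genotypes[best_snp, cc], sx, snp_id = best_snp)
    fe <- fit_E(y, et, sx, env_names)
    fge <- fit_GxE(y, genotypes[cand, cc, drop = FALSE], et, sx, env_names,
                   interaction_only = interaction_only)
    cmp <- compete(list(G = fg, E = fe, GxE = fge))
    wf <- cmp$winner_fit

    w_snp <- wf$snp_id
    w_class <- if (is.na(w_snp)) NA_character_ else {
      sm <- snp_map[match(w_snp, snp_map$snp_id), ]
      classify_pair(pm$chrom, pm$pos, sm$chrom, sm$pos)
    }
    data.frame(probe_id = pid,
               aic_g = if (is.null(fg)) NA_real_ else fg$aic,
               aic_e = if (is.null(fe)) NA_real_ else fe$aic,
               aic_gxe = if (is.null(fge)) NA_real_ else fge$aic,
               winner = cmp$winner, delta = cmp$delta,
               adj_r2 = wf$adj_r2, snp_id = w_snp, env = wf$env,
               snp_class = w_class, n_used = wf$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$passes_confidence <- out$delta > 2 & !is.na(out$adj_r2) &
    out$adj_r2 > 0.4
  class(out) <- c("vmr_competition", "data.frame")
  out
}

#' Confidence filter on competition results
#'
#' Retains CpGs with no substantial support for the runner-up (delta
#' strictly greater than `delta_min`) and a winner adjusted R-squared
#' strictly above `adjr2_min`.
#'
#' @param results a `vmr_competition` table.
#' @param delta_min Akaike delta threshold (default 2).
#' @param adjr2_min adjusted R-squared threshold (default 0.4).
#' @return the retained subset.
#' @export
confidence_filter <- function(results, delta_min = 2, adjr2_min = 0.4) {
  keep <- results$delta > delta_min & !is.na(results$adj_r2) &
    results$adj_r2 > adjr2_min
  results[keep, , drop = FALSE]
}

#' Genotype-segregated environment regressions
#'
#' For every CpG whose winning model is G-by-E, splits the subjects by the
#' winning SNP's genotype and regresses methylation on the winning
#' environment within each genotype class of at least `min_group_n` samples
#' (no sex covariate). Significance is Bonferroni-corrected by the total
#' number of regressions actually run in the batch; groups below the size
#' floor are skipped and not counted.
#'
#' @param competition a `vmr_competition` table.
#' @param meth beta matrix.
#' @param genotypes genotype matrix.
#' @param env_table sample metadata.
#' @param min_group_n minimum genotype-class size (default 10).
#' @return data frame of class `vmr_segregation`: probe_id, genotype class,
#'   n, slope, r_squared, p_value, best_group flag, significant flag;
#'   attribute `m` = total regressions run.
#' @export
segregate <- function(competition, meth, genotypes, env_table,
                      min_group_n = 10) {
  gxe <- competition[competition$winner == "GxE" &
                       !is.na(competition$snp_id) &
                       !is.na(competition$env), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(gxe))) {
    pid <- gxe$probe_id[i]
    g <- genotypes[gxe$snp_id[i], ]
    e <- as.numeric(env_table[[gxe$env[i]]])
    y <- meth[pid, ]
    for (cls in sort(unique(g[!is.na(g)]))) {
      idx <- which(!is.na(g) & g == cls & !is.na(y) & !is.na(e))
      if (length(idx) < min_group_n) next
      if (stats::var(e[idx]) <= 0) next
      fit <- stats::lm(y[idx] ~ e[idx])
      sm <- summary(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = pid, snp_id = gxe$snp_id[i], env = gxe$env[i],
        genotype = cls, n = length(idx),
        slope = unname(stats::coef(fit)[2]),
        r_squared = sm$r.squared,
        p_value = sm$coefficients[2, 4], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(probe_id = character(), snp_id = character(),
               env = character(), genotype = integer(), n = integer(),
               slope = numeric(), r_squared = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  m <- nrow(out)
  if (m) {
    out$significant <- out$p_value < 0.05 / m
    out$best_group <- FALSE
    for (pid in unique(out$probe_id)) {
      idx <- which(out$probe_id == pid)
      out$best_group[idx[which.max(out$r_squared[idx])]] <- TRUE
    }
  } else {
    out$significant <- logical()
    out$best_group <- logical()
  }
  rownames(out) <- NULL
  attr(out, "m") <- m
  class(out) <- c("vmr_segregation", "data.frame")
  out
}

#' @export
print.vmr_competition <- function(x, ...) {
  cat("Model competition: ", nrow(x), " CpGs\n", sep = "")
  tab <- table(factor(x$winner, levels = c("G", "E", "GxE")))
  prop <- round(100 * tab / nrow(x))
  cat("  winners: ", paste(sprintf("%s=%d (%d%%)", names(tab), tab, prop),
                           collapse = ", "), "\n", sep = "")
  cat("  pass confidence filter (delta > 2, adj R2 > 0.4): ",
      sum(x$passes_confidence), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' @export
summary.vmr_competition <- function(object, ...) {
  tab <- table(factor(object$winner, levels = c("G", "E", "GxE")))
  structure(list(n = nrow(object), winners = tab,
                 winner_prop = as.numeric(tab) / nrow(object),
                 n_confident = sum(object$passes_confidence),
                 delta_range = range(object$delta)),
            class = "summary.vmr_competition")
}

#' @export
print.summary.vmr_competition <- function(x, ...) {
  cat("Competition over", x$n, "CpGs\n")
  for (i in seq_along(x$winners))
    cat(sprintf("  %-3s %4d  (%.1f%%)\n", names(x$winners)[i],
                x$winners[i], 100 * x$winner_prop[i]))
  cat(sprintf("  Akaike delta range: %.4g - %.4g\n",
              x$delta_range[1], x$delta_range[2]))
  cat("  high-confidence CpGs:", x$n_confident, "\n")
  invisible(x)
}
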