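# Shared fixtures: small simulated cohorts built in code at test time.

# compact cohort: 60 samples, 4 chromosomes, 160 probes, 240 SNPs
small_cfg <- function(seed = 1, ...) {
  sim_config(n_samples = 60L, n_chromosomes = 4L, chrom_length_bp = 2e6,
             n_probes = 160L, n_snps = 240L,
             effect_plan = data.frame(
               class = c("G", "GxE", "E"), n_clusters = c(3L, 2L, 2L),
               b_g = c(0.8, 0.4, 0), b_e = c(0, 0.4, 0.8),
               b_gxe = c(0, 1.0, 0),
               gxe_form = c("linear", "linear", "linear"),
               gxe_group = c(NA, NA, NA),
               dist_lo = c(1e3, 1e3, NA), dist_hi = c(2e4, 2e4, NA),
               stringsAsFactors = FALSE),
             seed = seed, ...)
}

# memoised default small cohort (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
get_small_cohort <- function() {
  if (is.null(.fixture_env$co)) .fixture_env$co <- simulate_cohort(small_cfg())
  .fixture_env$co
}

# independent brute-force MAD: two-pass, sort-based medians
oracle_mad <- function(x) {
  med <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  med(abs(x - med(x)))
}

# independent brute-force VMR caller: enumerate above-threshold probes per
# chromosome and chain them greedily
oracle_vmrs <- function(scores, manifest, threshold, max_gap) {
  out <- list()
  for (ch in unique(manifest$chrom)) {
    m <- manifest[manifest$chrom == ch, ]
    m <- m[order(m$pos), ]
    hot <- m[scores[m$probe_id] > threshold, ]
    if (nrow(hot) == 0) next
    grp <- 1
    groups <- grp
    for (i in seq_len(nrow(hot))[-1]) {
      if (hot$pos[i] - hot$pos[i - 1] > max_gap) grp <- grp + 1
      groups <- c(groups, grp)
    }
    for (g in unique(groups)) {
      mem <- hot$probe_id[groups == g]
      if (length(mem) >= 2) out[[length(out) + 1]] <- mem
    }
  }
  out
}

# brute-force island-context classifier: loop over every island, nearest
# edge wins, tie -> lower-coordinate island
oracle_context <- function(chrom, pos, islands) {
  vapply(seq_along(pos), function(i) {
    isl <- islands[islands$chrom == chrom[i], , drop = FALSE]
    if (nrow(isl) == 0) return("open_sea")
    best_d <- Inf; best_side <- NA; inside <- FALSE
    for (j in order(isl$start)) {
      if (pos[i] >= isl$start[j] && pos[i] <= isl$end[j]) inside <- TRUE
      d_north <- isl$start[j] - pos[i]   # position below the island
      d_south <- pos[i] - isl$end[j]     # position above the island
      if (d_north > 0 && d_north < best_d) { best_d <- d_north; best_side <- "north" }
      if (d_south > 0 && d_south <= best_d) {
        # ties go to the lower-coordinate island, i.e. the south side
        if (d_south < best_d || best_side == "north") best_side <- "south"
        best_d <- d_south
      }
    }
    if (inside) return("island")
    if (best_d <= 2000) paste0(best_side, "_shore")
    else if (best_d <= 4000) paste0(best_side, "_shelf")
    else "open_sea"
  }, character(1))
}
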