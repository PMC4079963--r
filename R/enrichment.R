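# CpG-island context annotation and enrichment testing.
#
# Context tiers follow the array-annotation convention: the island interval
# itself ([start, end], 1-based inclusive), shores up to 2 kb beyond either
# edge, shelves a further 2 kb, and open sea elsewhere. North is the
# lower-coordinate side, south the higher-coordinate side (genomic
# direction, not transcriptional strand). Boundary convention: shore =
# (edge, edge + 2000], shelf = (edge + 2000, edge + 4000].

ISLAND_CATEGORIES <- c("island", "north_shore", "south_shore",
                       "north_shelf", "south_shelf", "open_sea")

#' Annotate positions with CpG-island context
#'
#' Each position gets exactly one of six mutually exclusive categories:
#' island, north/south shore (within 2 kb of the nearest island edge),
#' north/south shelf (2-4 kb), or open sea. When two islands compete, the
#' nearest edge decides; exact distance ties go to the lower-coordinate
#' island.
#'
#' @param chrom,pos vectors of 1-based positions to annotate.
#' @param islands data frame (chrom, start, end), 1-based inclusive,
#'   non-overlapping and sorted within chromosome.
#' @return character vector of categories.
#' @export
annotate_island_context <- function(chrom, pos, islands) {
  out <- rep("open_sea", length(pos))
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (nrow(isl) == 0L) next
    isl <- isl[order(isl$start), , drop = FALSE]
    p <- pos[qi]
    # index of the island starting at or before p (0 if none)
    left <- findInterval(p, isl$start)
    inside <- left > 0 & p <= isl$end[pmax(left, 1L)]
    # distance to previous island's end (position is south of it) and to the
    # next island's start (position is north of it)
    d_prev <- ifelse(left > 0, p - isl$end[pmax(left, 1L)], Inf)
    d_next <- ifelse(left < nrow(isl), isl$start[pmin(left + 1L, nrow(isl))] - p,
                     Inf)
    d_prev[d_prev < 0] <- Inf   # inside handled separately
    # nearest edge decides; tie -> lower-coordinate island (the previous one
    # has the lower coordinate, so ties go south)
    use_prev <- d_prev <= d_next
    d <- pmin(d_prev, d_next)
    side <- ifelse(use_prev, "south", "north")
    cat_out <- ifelse(d <= 2000, paste0(side, "_shore"),
                      ifelse(d <= 4000, paste0(side, "_shelf"), "open_sea"))
    cat_out[inside] <- "island"
    out[qi] <- cat_out
  }
  out
}

#' Hypergeometric enrichment of a probe list by island category
#'
#' For each of the six categories, tests whether the query probes contain at
#' least the observed number of category members, given the background
#' composition, by a one-tailed (upper) hypergeometric test.
#'
#' @param query_probes character vector of probe ids (subset of background).
#' @param background_probes character vector of probe ids.
#' @param annotations named character vector of categories (names = probe
#'   ids), covering the background.
#' @return data frame: category, query_count, background_count, query_total,
#'   background_total, p_value.
#' @export
enrichment_test <- function(query_probes, background_probes, annotations) {
  if (!length(query_probes)) stop("query is empty", call. = FALSE)
  if (!all(query_probes %in% background_probes))
    stop("query must be a subset of the background", call. = FALSE)
  ann_q <- annotations[query_probes]
  ann_b <- annotations[background_probes]
  N <- length(background_probes)
  nq <- length(query_probes)
  rows <- lapply(ISLAND_CATEGORIES, function(cat) {
    K <- sum(ann_b == cat)
    q <- sum(ann_q == cat)
    p <- stats::phyper(q - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(category = cat, query_count = q, background_count = K,
               query_total = nq, background_total = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ethnicity association of methylation
#'
#' One-way analysis-of-variance F-test per probe across ethnicity groups,
#' with Benjamini-Hochberg multiplicity correction. Groups below
#' `min_group_n` samples are dropped; at least two groups must remain.
#'
#' @param meth beta matrix (probes x samples).
#' @param ethnicity character vector of group labels aligned with samples.
#' @param min_group_n minimum group size (default 5).
#' @return data frame: probe_id, f_statistic, p_value, p_adjusted (BH).
#' @export
ethnicity_association <- function(meth, ethnicity, min_group_n = 5) {
  tab <- table(ethnicity)
  keep_groups <- names(tab)[tab >= min_group_n]
  if (length(keep_groups) < 2L)
    stop("need at least two ethnicity groups with >= ", min_group_n,
         " samples", call. = FALSE)
  idx <- ethnicity %in% keep_groups
  X <- meth[, idx, drop = FALSE]
  g <- factor(ethnicity[idx])
  n <- ncol(X)
  k <- nlevels(g)
  # one-way ANOVA decomposition, vectorised over probes
  gm <- rowMeans(X)
  group_means <- vapply(levels(g), function(l)
    rowMeans(X[, g == l, drop = FALSE]), numeric(nrow(X)))
  group_means <- matrix(group_means, nrow = nrow(X))
  ng <- as.numeric(table(g)[levels(g)])
  ssb <- as.numeric((group_means - gm)^2 %*% ng)
  sst <- rowSums((X - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  data.frame(probe_id = rownames(X), f_statistic = f, p_value = p,
             p_adjusted = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}
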