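# Variably methylated region (VMR) detection.
#
# Probe variability is scored by the unscaled median absolute deviation
# (MAD) of beta values across samples; a VMR is a run of >= 2 probes whose
# MAD exceeds the chosen percentile of the retained-probe MAD distribution,
# with consecutive above-threshold probes no more than 1 kb apart. An
# intervening below-threshold probe does not break a region unless it pushes
# the flanking above-threshold probes more than 1 kb apart.

#' Per-probe MAD scores
#'
#' Unscaled MAD (no 1.4826 consistency constant): the median absolute
#' deviation from the per-probe median beta, in beta units. Invariant to
#' sample order.
#'
#' @param meth beta matrix (probes x samples); at least 2 samples.
#' @return named numeric vector of MAD scores, one per probe.
#' @export
compute_mad <- function(meth) {
  if (ncol(meth) < 2L)
    stop("MAD requires at least 2 samples", call. = FALSE)
  scores <- apply(meth, 1, stats::mad, constant = 1, na.rm = TRUE)
  names(scores) <- rownames(meth)
  scores
}

#' Detect variably methylated regions
#'
#' Thresholds the MAD distribution at the given percentile (strictly greater
#' than), then chains above-threshold probes along each chromosome whenever
#' consecutive above-threshold probes are within `max_gap_bp`. Maximal runs
#' of at least two probes are reported as VMRs; the member with the highest
#' MAD (ties: lowest genomic position) is the representative VMR-CpG.
#'
#' @param scores named MAD vector from [compute_mad()].
#' @param manifest probe manifest (probe_id, chrom, pos), any order.
#' @param percentile MAD percentile defining "variable" (default 95).
#' @param max_gap_bp maximum distance between consecutive above-threshold
#'   member probes (default 1000).
#' @return data frame of class `vmr_set`: vmr_id, chrom, start, end,
#'   n_probes, probes (comma-separated, genomic order), rep_probe, rep_mad;
#'   attribute `threshold` holds the MAD cutoff used.
#' @export
detect_vmrs <- function(scores, manifest, percentile = 95,
                        max_gap_bp = 1000) {
  stopifnot(all(manifest$probe_id %in% names(scores)))
  threshold <- stats::quantile(scores[manifest$probe_id],
                               percentile / 100, names = FALSE)
  man <- manifest[order(manifest$chrom, manifest$pos), , drop = FALSE]
  man$mad <- scores[man$probe_id]
  hot <- man[man$mad > threshold, , drop = FALSE]

  out <- list()
  for (ch in unique(hot$chrom)) {
    h <- hot[hot$chrom == ch, , drop = FALSE]
    if (nrow(h) == 0L) next
    gap <- c(Inf, diff(h$pos))
    run <- cumsum(gap > max_gap_bp)
    for (r in unique(run)) {
      mem <- h[run == r, , drop = FALSE]
      if (nrow(mem) < 2L) next
      best <- which(mem$mad == max(mem$mad))
      best <- best[which.min(mem$pos[best])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(mem$pos), end = max(mem$pos),
        n_probes = nrow(mem),
        probes = paste(mem$probe_id, collapse = ","),
        rep_probe = mem$probe_id[best], rep_mad = mem$mad[best],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_probes = integer(), probes = character(),
               rep_probe = character(), rep_mad = numeric(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  if (nrow(res)) res$vmr_id <- sprintf("vmr%04d", seq_len(nrow(res)))
  else res$vmr_id <- character()
  res <- res[, c("vmr_id", "chrom", "start", "end", "n_probes", "probes",
                 "rep_probe", "rep_mad")]
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  attr(res, "percentile") <- percentile
  class(res) <- c("vmr_set", "data.frame")
  res
}

#' Member probes of a VMR row
#' @param vmrs a `vmr_set`.
#' @param i row index (default all).
#' @return list of character vectors of probe ids.
#' @export
vmr_members <- function(vmrs, i = seq_len(nrow(vmrs))) {
  strsplit(vmrs$probes[i], ",", fixed = TRUE)
}

#' Representative CpG of a probe set
#'
#' The member with the maximal MAD; exact ties go to the lowest genomic
#' position.
#'
#' @param members character vector of probe ids.
#' @param scores named MAD vector.
#' @param manifest probe manifest (probe_id, chrom, pos).
#' @return a single probe id.
#' @export
select_representative <- function(members, scores, manifest) {
  mads <- scores[members]
  pos <- manifest$pos[match(members, manifest$probe_id)]
  best <- which(mads == max(mads))
  members[best[which.min(pos[best])]]
}

#' Highest-MAD CpGs outside all VMRs
#'
#' @param scores named MAD vector.
#' @param vmrs a `vmr_set`.
#' @param n how many probes to return (default 1500); capped with a warning
#'   when fewer non-VMR probes exist.
#' @return character vector of probe ids, decreasing MAD.
#' @export
top_nonvmr_cpgs <- function(scores, vmrs, n = 1500) {
  in_vmr <- unlist(vmr_members(vmrs))
  pool <- scores[setdiff(names(scores), in_vmr)]
  if (n > length(pool)) {
    warning("only ", length(pool), " non-VMR probes available; capping n",
            call. = FALSE)
    n <- length(pool)
  }
  if (n == 0L) return(character())
  names(sort(pool, decreasing = TRUE))[seq_len(n)]
}

#' @export
print.vmr_set <- function(x, ...) {
  cat("VMR set: ", nrow(x), " regions (MAD threshold ",
      signif(attr(x, "threshold"), 4), " at the ", attr(x, "percentile"),
      "th percentile)\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Write a VMR set as BED plus a membership TSV
#' @param vmrs a `vmr_set`.
#' @param bed_path output BED path (name = representative probe, score =
#'   representative MAD).
#' @param tsv_path optional membership TSV path.
#' @export
write_vmrs <- function(vmrs, bed_path, tsv_path = NULL) {
  write_bed(vmrs[, c("chrom", "start", "end")], bed_path,
            extra = data.frame(vmrs$rep_probe, signif(vmrs$rep_mad, 6)))
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(vmrs), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}
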