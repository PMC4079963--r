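# Core containers, readers/writers and preprocessing filters.
#
# Matrices are plain numeric/integer matrices with probe or SNP ids as
# rownames and sample ids as colnames. Point features (probes, SNPs) use
# 1-based positions throughout; BED interval files are converted to 1-based
# inclusive coordinates at the reader boundary and back at the writer.

#' Load a genotype matrix from VCF or TSV
#'
#' VCF genotypes (GT field) are recoded 1/2/3: homozygous reference -> 1,
#' heterozygous -> 2, homozygous alternate -> 3; `./.` -> missing.
#' Multiallelic records are dropped (count reported); records whose GT is
#' not diploid are set missing with a warning. The TSV format is a matrix
#' with SNP ids in the first column and sample ids as the header, values in
#' {1, 2, 3} or NA.
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`; guessed from the extension by default.
#' @return list with `genotypes` (integer matrix, SNPs x samples) and `map`
#'   (snp_id, chrom, pos).
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    mat <- read_matrix_tsv(path)
    storage.mode(mat) <- "integer"
    bad <- !(mat %in% c(1L, 2L, 3L) | is.na(mat))
    if (any(bad)) stop("genotype TSV contains values outside {1,2,3,NA}: ",
                       path, call. = FALSE)
    return(list(genotypes = mat, map = NULL))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    message("dropping ", sum(multi), " multiallelic record(s)")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  geno <- recode_gt(gt)
  map <- data.frame(snp_id = rownames(gt), chrom = fix$CHROM,
                    pos = as.integer(fix$POS), stringsAsFactors = FALSE)
  dimnames(geno) <- dimnames(gt)
  list(genotypes = geno, map = map)
}

# GT string -> 1/2/3 coding; non-diploid records become NA with a warning
recode_gt <- function(gt) {
  g <- gsub("\\|", "/", as.character(gt))
  out <- rep(NA_integer_, length(g))
  out[g %in% c("0/0")] <- 1L
  out[g %in% c("0/1", "1/0")] <- 2L
  out[g %in% c("1/1")] <- 3L
  known_missing <- is.na(g) | g %in% c("./.", ".")
  odd <- !known_missing & is.na(out)
  if (any(odd))
    warning(sum(odd), " genotype call(s) were not diploid biallelic; ",
            "set to missing", call. = FALSE)
  matrix(out, nrow = nrow(gt), ncol = ncol(gt))
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits one biallelic record per SNP with placeholder REF/ALT alleles and a
#' GT-only FORMAT; the 1/2/3 coding maps back to 0/0, 0/1 and 1/1.
#'
#' @param genotypes integer matrix (SNPs x samples), values in 1/2/3 or NA.
#' @param map data frame (snp_id, chrom, pos) aligned with the matrix rows.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(genotypes, map, path) {
  stopifnot(nrow(genotypes) == nrow(map))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes],
                   nrow = nrow(genotypes))
  gt_str[is.na(gt_str)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=vmrqtl simulator (genotypes recoded 1/2/3 = 0/0,0/1,1/1)",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(genotypes)), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$snp_id, "A", "G", ".", "PASS", ".",
                "GT", apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a numeric matrix as TSV (ids in first column)
#' @param path file path.
#' @return numeric matrix with rownames/colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' @rdname read_matrix_tsv
#' @param mat matrix to write.
#' @param id_name header name for the id column.
#' @export
write_matrix_tsv <- function(mat, path, id_name = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write CpG-island intervals as BED
#'
#' BED uses 0-based half-open intervals; internally the package uses 1-based
#' inclusive coordinates, so `start` gains 1 on read and loses 1 on write.
#'
#' @param path BED file path.
#' @return data frame (chrom, start, end), 1-based inclusive.
#' @export
read_bed_islands <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' @rdname read_bed_islands
#' @param islands data frame (chrom, start, end), 1-based inclusive.
#' @param extra optional data frame of extra BED columns (name, score, ...).
#' @export
write_bed <- function(islands, path, extra = NULL) {
  df <- data.frame(islands$chrom, islands$start - 1L, islands$end)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Retain probes that vary in methylation
#'
#' Keeps probes whose beta range (max - min across samples) strictly exceeds
#' `min_range` (default 0.05, i.e. ">5%" variability). Probe order is
#' preserved; an empty matrix passes through unchanged.
#'
#' @param meth beta matrix (probes x samples), values in `[0,1]`.
#' @param min_range minimum range in beta units.
#' @return the filtered matrix.
#' @export
filter_variable_probes <- function(meth, min_range = 0.05) {
  if (nrow(meth) == 0L) return(meth)
  rng <- apply(meth, 1, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    max(x) - min(x)
  })
  meth[rng > min_range, , drop = FALSE]
}

#' Retain heterologous SNPs
#'
#' Keeps SNPs with at least two distinct non-missing genotype classes in the
#' cohort; monomorphic SNPs carry no information for regression.
#'
#' @param genotypes genotype matrix (SNPs x samples).
#' @return the filtered matrix.
#' @export
filter_heterologous_snps <- function(genotypes) {
  if (nrow(genotypes) == 0L) return(genotypes)
  keep <- apply(genotypes, 1, function(x) length(unique(x[!is.na(x)])) >= 2L)
  genotypes[keep, , drop = FALSE]
}

#' Apply probe exclusions
#'
#' Removes listed probes (e.g. cross-reactive probes) and, optionally, every
#' probe on a sex chromosome. Exclusion ids absent from the matrix are
#' ignored with a reported count.
#'
#' @param meth beta matrix (probes x samples).
#' @param manifest probe manifest (probe_id, chrom, pos).
#' @param exclude_ids character vector of probe ids to drop.
#' @param drop_sex_chromosomes drop chrX/chrY probes when TRUE.
#' @return the filtered matrix.
#' @export
apply_exclusions <- function(meth, manifest, exclude_ids = character(),
                             drop_sex_chromosomes = FALSE) {
  absent <- setdiff(exclude_ids, rownames(meth))
  if (length(absent))
    message(length(absent), " exclusion id(s) not present; ignored")
  drop <- rownames(meth) %in% exclude_ids
  if (drop_sex_chromosomes) {
    sex_probes <- manifest$probe_id[manifest$chrom %in%
                                      c("chrX", "chrY", "X", "Y")]
    drop <- drop | rownames(meth) %in% sex_probes
  }
  meth[!drop, , drop = FALSE]
}

#' Align methylation, genotype and metadata on a shared sample set
#'
#' Intersects sample ids across the three inputs and reorders each to the
#' identical ordered id vector that all downstream modules require.
#'
#' @param meth beta matrix (probes x samples).
#' @param genotypes genotype matrix (SNPs x samples).
#' @param env sample metadata data frame with a `sample_id` column.
#' @return list (`meth`, `genotypes`, `env`, `samples`).
#' @export
align_cohort <- function(meth, genotypes, env) {
  ids <- intersect(intersect(colnames(meth), colnames(genotypes)),
                   env$sample_id)
  if (!length(ids)) stop("no shared sample ids", call. = FALSE)
  ids <- sort(ids)
  out <- list(meth = meth[, ids, drop = FALSE],
              genotypes = genotypes[, ids, drop = FALSE],
              env = env[match(ids, env$sample_id), , drop = FALSE],
              samples = ids)
  stopifnot(identical(colnames(out$meth), ids),
            identical(colnames(out$genotypes), ids),
            identical(out$env$sample_id, ids))
  out
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits the methylation matrix and genotype matrix as TSV, genotypes also
#' as VCF, the probe manifest and SNP map as TSV, islands as BED, the truth
#' table as TSV, and a JSON echo of the configuration.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(round(cohort$meth, 6), p("methylation.tsv"), "probe_id")
  write_matrix_tsv(cohort$genotypes, p("genotypes.tsv"), "snp_id")
  write_genotypes_vcf(cohort$genotypes, cohort$snps, p("genotypes.vcf"))
  utils::write.table(cohort$probes, p("probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$snps, p("snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(cohort$islands, p("islands.bed"))
  utils::write.table(cohort$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$env, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg$effect_plan <- NULL; cfg$effect_table <- NULL; cfg$env_specs <- NULL
  jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a truth table written by [write_cohort()]
#' @param path TSV path.
#' @return data frame with one planted-effect record per probe.
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
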