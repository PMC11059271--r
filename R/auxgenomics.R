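#' Filter annotated variants by depth, region and population frequency
#'
#' Keeps variants with total read depth at least `min_depth` (inclusive),
#' a region class among `regions`, and every *present* population allele
#' frequency strictly below `max_af`. A missing frequency means the variant
#' is absent from that population database and, by default, passes that
#' check; set `missing_af_passes = FALSE` to fail such variants instead.
#'
#' @param variants data frame with columns total_depth, region_class and
#'   the frequency columns `af_exac_eas`, `af_gnomad_eas`, `af_korean`.
#' @param min_depth minimum depth (inclusive).
#' @param max_af frequency cutoff (strict) applied to each column.
#' @param regions allowed region classes.
#' @param missing_af_passes treat missing frequencies as passing.
#' @return the surviving rows.
#' @export
filter_variants <- function(variants, min_depth = 10, max_af = 0.01,
                            regions = c("exonic", "splicing"),
                            missing_af_passes = TRUE) {
  af_cols <- c("af_exac_eas", "af_gnomad_eas", "af_korean")
  stopifnot(all(c("total_depth", "region_class", af_cols) %in% names(variants)))
  for (col in af_cols) {
    x <- variants[[col]]
    if (!is.numeric(x) && !all(is.na(x))) {
      stop(sprintf("parse error: non-numeric frequency in column '%s'", col),
           call. = FALSE)
    }
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      stop(sprintf("parse error: frequency outside [0,1] in column '%s'", col),
           call. = FALSE)
    }
  }
  af_pass <- function(x) {
    ifelse(is.na(x), missing_af_passes, x < max_af)
  }
  keep <- variants$total_depth >= min_depth &
    variants$region_class %in% regions &
    af_pass(variants$af_exac_eas) &
    af_pass(variants$af_gnomad_eas) &
    af_pass(variants$af_korean)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor mutation burden
#'
#' Number of coding mutations divided by the length of the coding region in
#' megabases (RefSeq coding space is roughly 30 Mb).
#'
#' @param n_coding_mutations nonnegative mutation count.
#' @param coding_length_mb coding-region length in Mb (positive).
#' @return mutations per megabase.
#' @export
compute_tmb <- function(n_coding_mutations, coding_length_mb = 30) {
  if (!is.numeric(coding_length_mb) || coding_length_mb <= 0) {
    stop("coding_length_mb must be positive", call. = FALSE)
  }
  if (n_coding_mutations < 0) stop("mutation count must be nonnegative", call. = FALSE)
  n_coding_mutations / coding_length_mb
}

#' ZRPKM: z-score RPKM against a reference sample set
#'
#' Per feature, `z = (rpkm - median(reference)) / sd(reference)` with the
#' median and (sample) standard deviation taken over the reference samples
#' — the median-centering convention of read-depth CNV callers. Features
#' whose reference SD is zero are excluded and flagged. `center = "mean"`
#' swaps the median for the mean.
#'
#' @param rpkm features x samples matrix with row and column names.
#' @param reference_samples column names of the reference set (at least 2).
#' @param center `"median"` (default) or `"mean"`.
#' @return list with `z` (features x samples matrix over the retained
#'   features) and `excluded` (feature ids with zero reference SD).
#' @export
zrpkm <- function(rpkm, reference_samples, center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(is.matrix(rpkm), !is.null(rownames(rpkm)), !is.null(colnames(rpkm)))
  if (!all(reference_samples %in% colnames(rpkm))) {
    stop("unknown reference sample(s)", call. = FALSE)
  }
  if (length(reference_samples) < 2) {
    stop("at least 2 reference samples are required", call. = FALSE)
  }
  ref <- rpkm[, reference_samples, drop = FALSE]
  ctr <- if (center == "median") apply(ref, 1L, stats::median) else rowMeans(ref)
  s <- apply(ref, 1L, stats::sd)
  flagged <- rownames(rpkm)[s == 0]
  keep <- s > 0
  z <- sweep(sweep(rpkm[keep, , drop = FALSE], 1L, ctr[keep]), 1L, s[keep], "/")
  list(z = z, excluded = flagged)
}

#' Call copy-number state from log2 ratios
#'
#' Deletion when the log2 tumor-to-normal ratio is at most `del_threshold`
#' (inclusive), amplification when strictly above `amp_threshold`, neutral
#' otherwise.
#'
#' @param log2_values named numeric vector (or data frame feature_id,
#'   log2_ratio) of per-feature log2 ratios; all values must be finite.
#' @param del_threshold,amp_threshold state cutoffs.
#' @return data frame feature_id, log2_ratio, state in
#'   `{deletion, neutral, amplification}`.
#' @export
call_cnv <- function(log2_values, del_threshold = -0.4, amp_threshold = 0.3) {
  if (is.data.frame(log2_values)) {
    stopifnot(all(c("feature_id", "log2_ratio") %in% names(log2_values)))
    v <- stats::setNames(log2_values$log2_ratio, log2_values$feature_id)
  } else {
    v <- log2_values
    if (is.null(names(v))) names(v) <- sprintf("feature_%d", seq_along(v))
  }
  if (any(!is.finite(v))) {
    stop(sprintf("data error: non-finite log2 ratio for feature '%s'",
                 names(v)[!is.finite(v)][1]), call. = FALSE)
  }
  state <- ifelse(v <= del_threshold, "deletion",
           ifelse(v > amp_threshold, "amplification", "neutral"))
  data.frame(feature_id = names(v), log2_ratio = unname(v),
             state = unname(state), stringsAsFactors = FALSE)
}

#' Filter gene-fusion candidates
#'
#' A candidate survives when at least one partner is a protein-coding gene
#' and both the junction and spanning read counts are nonzero; exact
#' duplicates — same gene pair, same breakpoints, same junction and
#' spanning counts — are then collapsed to a single record. Orientation-
#' swapped pairs (B--A vs A--B) are distinct and not merged.
#'
#' @param fusions data frame with gene_a, gene_b, chrom_a, pos_a, chrom_b,
#'   pos_b, junction_reads, spanning_reads.
#' @param coding_genes non-empty character set of protein-coding gene ids.
#' @return the surviving rows (first occurrence of each duplicate group).
#' @export
filter_fusions <- function(fusions, coding_genes) {
  stopifnot(all(c("gene_a", "gene_b", "junction_reads", "spanning_reads")
                %in% names(fusions)))
  if (length(coding_genes) == 0) {
    stop("coding gene set must be non-empty", call. = FALSE)
  }
  keep <- (fusions$gene_a %in% coding_genes | fusions$gene_b %in% coding_genes) &
    fusions$junction_reads > 0 & fusions$spanning_reads > 0
  out <- fusions[keep, , drop = FALSE]
  bp_cols <- intersect(c("chrom_a", "pos_a", "chrom_b", "pos_b"), names(out))
  key <- do.call(paste, c(out[c("gene_a", "gene_b", bp_cols,
                                "junction_reads", "spanning_reads")],
                          sep = "|"))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
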