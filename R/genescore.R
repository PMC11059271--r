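#' Filter a differential-expression table to DEGs
#'
#' A gene is differentially expressed when the absolute log2 fold-change is
#' at least `min_abs_lfc` (inclusive), the adjusted p-value is below
#' `max_padj` (strict), and the baseMean is at least `min_basemean`
#' (inclusive). Genes with a missing adjusted p are excluded.
#'
#' @param de data frame with columns gene_id, log2fc, padj, basemean;
#'   gene ids must be unique.
#' @param min_abs_lfc,max_padj,min_basemean the three DEG thresholds.
#' @return the kept rows of `de`.
#' @export
filter_degs <- function(de, min_abs_lfc = 2, max_padj = 0.05,
                        min_basemean = 100) {
  stopifnot(all(c("gene_id", "log2fc", "padj", "basemean") %in% names(de)))
  dup <- unique(de$gene_id[duplicated(de$gene_id)])
  if (length(dup)) {
    stop(sprintf("duplicate gene_id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  keep <- !is.na(de$padj) &
    abs(de$log2fc) >= min_abs_lfc &
    de$padj < max_padj &
    de$basemean >= min_basemean
  out <- de[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign intersected CpGs to gene territories
#'
#' A CpG is assigned to every gene whose annotated interval (1-based,
#' inclusive on both ends) contains its position; a CpG inside overlapping
#' genes is counted in each. Overlap is computed with
#' `GenomicRanges::findOverlaps`.
#'
#' @param dmr_calls a `dmr_calls` frame from [call_dmrs()] (one row per
#'   intersected CpG).
#' @param gene_map data frame gene_id, chrom, start, end.
#' @param count_indeterminate whether `indeterminate` calls count as DMRs in
#'   the tallies (they satisfy the difference criterion; default yes).
#' @return list with `assignments` (gene_id, cpg row index, abs_diff,
#'   is_dmr) and `tally` (gene_id, n_cpgs, n_dmr), covering every gene in
#'   the map (zero tallies included).
#' @export
map_cpgs_to_genes <- function(dmr_calls, gene_map,
                              count_indeterminate = TRUE) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(gene_map)))
  if (any(gene_map$start > gene_map$end)) {
    bad <- gene_map$gene_id[gene_map$start > gene_map$end][1]
    stop(sprintf("annotation error: interval with start > end for gene '%s'", bad),
         call. = FALSE)
  }
  dmr_states <- if (count_indeterminate) c("hypo", "hyper", "indeterminate")
                else c("hypo", "hyper")
  if (nrow(dmr_calls) == 0L || nrow(gene_map) == 0L) {
    assignments <- data.frame(gene_id = character(), cpg = integer(),
                              abs_diff = numeric(), is_dmr = logical(),
                              stringsAsFactors = FALSE)
  } else {
    genes <- GenomicRanges::GRanges(gene_map$chrom,
                                    IRanges::IRanges(gene_map$start, gene_map$end))
    cpgs <- GenomicRanges::GRanges(dmr_calls$chrom,
                                   IRanges::IRanges(dmr_calls$pos, dmr_calls$pos))
    hits <- GenomicRanges::findOverlaps(cpgs, genes, ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    assignments <- data.frame(
      gene_id = gene_map$gene_id[si], cpg = qi,
      abs_diff = abs(dmr_calls$diff[qi]),
      is_dmr = as.character(dmr_calls$status[qi]) %in% dmr_states,
      stringsAsFactors = FALSE)
  }
  n_cpgs <- table(factor(assignments$gene_id, levels = gene_map$gene_id))
  n_dmr <- table(factor(assignments$gene_id[assignments$is_dmr],
                        levels = gene_map$gene_id))
  tally <- data.frame(gene_id = gene_map$gene_id,
                      n_cpgs = as.integer(n_cpgs),
                      n_dmr = as.integer(n_dmr), stringsAsFactors = FALSE)
  list(assignments = assignments, tally = tally)
}

#' Score DEGs by their DMR fraction
#'
#' For every DEG the fraction of its intersected CpGs that are DMRs is
#' computed, together with the median and mean of the per-CpG absolute
#' tumor-normal differences. A gene is eligible for ranking when it has
#' strictly more than `min_cpgs` CpGs and strictly more than `min_fraction`
#' of them are DMRs. A DEG with no mapped CpGs is scored (n_cpgs 0, fraction
#' `NA`) and ineligible.
#'
#' @param mapping output of [map_cpgs_to_genes()].
#' @param deg_set character vector of DEG ids (e.g. `filter_degs(...)$gene_id`).
#' @param min_cpgs,min_fraction eligibility thresholds (both strict).
#' @return data frame gene_id, n_cpgs, n_dmr, dmr_fraction, median_abs_diff,
#'   mean_abs_diff, eligible; one row per DEG.
#' @export
score_genes <- function(mapping, deg_set, min_cpgs = 10, min_fraction = 0.5) {
  tally <- mapping$tally
  idx <- match(deg_set, tally$gene_id)
  n_cpgs <- ifelse(is.na(idx), 0L, tally$n_cpgs[idx])
  n_dmr <- ifelse(is.na(idx), 0L, tally$n_dmr[idx])
  frac <- ifelse(n_cpgs > 0, n_dmr / n_cpgs, NA_real_)
  a <- mapping$assignments
  med <- mea <- rep(NA_real_, length(deg_set))
  by_gene <- split(a$abs_diff, a$gene_id)
  hit <- match(deg_set, names(by_gene))
  for (i in which(!is.na(hit))) {
    med[i] <- stats::median(by_gene[[hit[i]]])
    mea[i] <- mean(by_gene[[hit[i]]])
  }
  data.frame(gene_id = deg_set, n_cpgs = n_cpgs, n_dmr = n_dmr,
             dmr_fraction = frac, median_abs_diff = med, mean_abs_diff = mea,
             eligible = n_cpgs > min_cpgs & !is.na(frac) & frac > min_fraction,
             stringsAsFactors = FALSE)
}

#' Rank eligible genes by DMR fraction
#'
#' Eligible genes are sorted by DMR fraction descending, ties broken by
#' mean absolute difference descending and then gene id lexicographically,
#' so the ranking is deterministic.
#'
#' @param scores output of [score_genes()].
#' @param top_n number of ranked genes to return.
#' @return the top rows with a `rank` column set.
#' @export
rank_genes <- function(scores, top_n = 10) {
  el <- scores[scores$eligible, , drop = FALSE]
  if (nrow(el) == 0L) {
    el$rank <- integer(0)
    return(el)
  }
  ord <- order(-el$dmr_fraction, -el$mean_abs_diff, el$gene_id)
  el <- el[ord, , drop = FALSE]
  el <- utils::head(el, top_n)
  el$rank <- seq_len(nrow(el))
  rownames(el) <- NULL
  el
}
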