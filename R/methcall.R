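#' Read a Bismark-style cytosine report and collapse strands
#'
#' Parses a headerless cytosine report (chrom, 1-based position, strand,
#' methylated count, unmethylated count, context, trinucleotide). Cytosines
#' reported on the minus strand belong to the CpG whose plus-strand cytosine
#' sits one base upstream; they are collapsed onto that coordinate with
#' counts summed, so each CpG contributes the reads of both strands.
#' Collapsed records with total coverage below `min_coverage` are dropped.
#'
#' @param path cytosine-report TSV.
#' @param min_coverage minimum collapsed read total to keep a CpG; the
#'   default 1 keeps any covered site (intersection across samples is the
#'   pipeline's only default site filter).
#' @return data frame (chrom, pos, strand_sources, meth_count, total_count)
#'   sorted by (chrom, pos).
#' @export
read_cytosine_report <- function(path, min_coverage = 1L) {
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "pos", "strand",
                                    "count_methylated", "count_unmethylated",
                                    "context", "trinucleotide"),
                      colClasses = c("character", "integer", "character",
                                     "integer", "integer", "character",
                                     "character"),
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) return(NULL)
      stop(sprintf("parse error in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (is.null(raw) || nrow(raw) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand_sources = character(), meth_count = integer(),
                      total_count = integer(), stringsAsFactors = FALSE))
  }
  bad <- which(!(raw$strand %in% c("+", "-")) | is.na(raw$pos) |
                 is.na(raw$count_methylated) | is.na(raw$count_unmethylated) |
                 raw$count_methylated < 0 | raw$count_unmethylated < 0)
  if (length(bad)) {
    stop(sprintf("parse error in '%s': malformed record at line %d",
                 path, bad[1]), call. = FALSE)
  }
  collapse_strands(raw, min_coverage)
}

# Minus-strand C -> plus-strand CpG coordinate (pos - 1); sum counts per key.
collapse_strands <- function(raw, min_coverage) {
  cpg_pos <- ifelse(raw$strand == "-", raw$pos - 1L, raw$pos)
  if (any(cpg_pos < 1L)) {
    stop("data error: minus-strand cytosine at position 1 has no CpG partner",
         call. = FALSE)
  }
  key <- paste(raw$chrom, cpg_pos, sep = ":")
  meth <- rowsum(raw$count_methylated, key, reorder = FALSE)
  tot <- rowsum(raw$count_methylated + raw$count_unmethylated, key, reorder = FALSE)
  sources <- vapply(split(raw$strand, factor(key, levels = rownames(meth))),
                    function(s) paste(sort(unique(s)), collapse = ""),
                    character(1))
  first <- !duplicated(key)
  out <- data.frame(chrom = raw$chrom[first], pos = cpg_pos[first],
                    strand_sources = unname(sources),
                    meth_count = as.integer(meth[, 1]),
                    total_count = as.integer(tot[, 1]),
                    stringsAsFactors = FALSE)
  out <- out[out$total_count >= min_coverage, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a per-CpG methylation-ratio table across samples
#'
#' The methylation ratio of a CpG in a sample is its methylated read count
#' (both strands) divided by its total read count. CpGs absent from a
#' sample's record set are missing (`NA`) for that sample.
#'
#' @param records named list of per-sample record frames from
#'   [read_cytosine_report()].
#' @param group_labels named character vector sample -> `"tumor"`/`"normal"`,
#'   covering every sample in `records`.
#' @return a `ratio_table`: list with `keys` (chrom, pos), `ratio` and
#'   `total` matrices (CpGs x samples), and `groups`.
#' @export
compute_ratios <- function(records, group_labels) {
  stopifnot(is.list(records), length(records) > 0, !is.null(names(records)))
  missing_lab <- setdiff(names(records), names(group_labels))
  if (length(missing_lab)) {
    stop(sprintf("no group label for sample(s): %s",
                 paste(missing_lab, collapse = ", ")), call. = FALSE)
  }
  if (!all(group_labels[names(records)] %in% c("tumor", "normal"))) {
    stop("group labels must be 'tumor' or 'normal'", call. = FALSE)
  }
  for (s in names(records)) {
    if (any(records[[s]]$total_count == 0)) {
      stop(sprintf("data error: zero total count in sample '%s'", s), call. = FALSE)
    }
    if (any(records[[s]]$meth_count > records[[s]]$total_count)) {
      stop(sprintf("data error: meth_count exceeds total_count in sample '%s'", s),
           call. = FALSE)
    }
  }
  all_keys <- unique(do.call(rbind, lapply(records, function(r) r[c("chrom", "pos")])))
  all_keys <- all_keys[order(all_keys$chrom, all_keys$pos), , drop = FALSE]
  rownames(all_keys) <- NULL
  kstr <- paste(all_keys$chrom, all_keys$pos, sep = ":")
  n <- nrow(all_keys)
  ratio <- matrix(NA_real_, n, length(records),
                  dimnames = list(NULL, names(records)))
  total <- matrix(NA_integer_, n, length(records),
                  dimnames = list(NULL, names(records)))
  for (s in names(records)) {
    r <- records[[s]]
    idx <- match(paste(r$chrom, r$pos, sep = ":"), kstr)
    ratio[idx, s] <- r$meth_count / r$total_count
    total[idx, s] <- r$total_count
  }
  structure(list(keys = all_keys, ratio = ratio, total = total,
                 groups = group_labels[names(records)]),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("ratio_table: %d CpGs x %d samples (%d tumor, %d normal)\n",
              nrow(x$keys), length(x$groups),
              sum(x$groups == "tumor"), sum(x$groups == "normal")))
  cat(sprintf("  complete across all samples: %d CpGs\n",
              sum(stats::complete.cases(x$ratio))))
  invisible(x)
}

#' Restrict a ratio table to CpGs covered in the required samples
#'
#' Under the default `"all_samples"` policy the kept CpGs are the
#' intersection of every sample's covered set, reproducing the step of
#' intersecting tumor CpG sets with the normal sample. Key order is
#' preserved; an empty intersection yields a warning and an empty table.
#'
#' @param table a `ratio_table`.
#' @param policy `"all_samples"` (intersection over every sample) or
#'   `"all_normals"` (require coverage in all normal samples only).
#' @return a `ratio_table` with a subset of the input CpGs.
#' @export
intersect_cpgs <- function(table, policy = c("all_samples", "all_normals")) {
  stopifnot(inherits(table, "ratio_table"))
  policy <- match.arg(policy)
  if (!any(table$groups == "normal")) {
    stop("at least one normal sample is required", call. = FALSE)
  }
  cols <- if (policy == "all_samples") seq_along(table$groups)
          else which(table$groups == "normal")
  keep <- rowSums(is.na(table$ratio[, cols, drop = FALSE])) == 0L
  if (!any(keep)) warning("empty CpG intersection across samples")
  structure(list(keys = table$keys[keep, , drop = FALSE],
                 ratio = table$ratio[keep, , drop = FALSE],
                 total = table$total[keep, , drop = FALSE],
                 groups = table$groups),
            class = "ratio_table")
}

#' Call per-CpG differentially methylated regions by thresholds
#'
#' For each CpG the tumor and normal group mean ratios are compared; a CpG
#' is a DMR when the (absolute, by default) difference exceeds
#' `diff_threshold` — strictly, so a difference of exactly 0.4 is not a DMR.
#' DMRs are sub-classified by the tumor mean: hypomethylated below
#' `hypo_threshold`, hypermethylated above `hyper_threshold`, and
#' `indeterminate` when the tumor mean falls between the two (kept rather
#' than dropped so gene-level CpG counts stay complete).
#'
#' @param table a complete `ratio_table` (run [intersect_cpgs()] first).
#' @param diff_threshold minimum tumor-normal mean difference (strict).
#' @param hypo_threshold,hyper_threshold tumor-mean cutoffs for the hypo-
#'   and hypermethylated sub-states (strict).
#' @param signed if `TRUE`, compare the signed difference `tumor - normal`
#'   against `diff_threshold` instead of its absolute value.
#' @return a `dmr_calls` data frame: chrom, pos, normal_mean, tumor_mean,
#'   diff (tumor - normal), status in
#'   `{not_dmr, hypo, hyper, indeterminate}`; one row per input CpG.
#' @export
call_dmrs <- function(table, diff_threshold = 0.4, hypo_threshold = 0.3,
                      hyper_threshold = 0.7, signed = FALSE) {
  stopifnot(inherits(table, "ratio_table"))
  tum <- which(table$groups == "tumor")
  nor <- which(table$groups == "normal")
  if (!length(tum) || !length(nor)) {
    stop("configuration error: both a tumor and a normal group are required",
         call. = FALSE)
  }
  if (anyNA(table$ratio)) {
    stop("ratio table contains missing values; run intersect_cpgs() first",
         call. = FALSE)
  }
  tumor_mean <- rowMeans(table$ratio[, tum, drop = FALSE])
  normal_mean <- rowMeans(table$ratio[, nor, drop = FALSE])
  diff <- tumor_mean - normal_mean
  crit <- if (signed) diff else abs(diff)
  is_dmr <- crit > diff_threshold
  status <- rep("not_dmr", length(diff))
  status[is_dmr & tumor_mean < hypo_threshold] <- "hypo"
  status[is_dmr & tumor_mean > hyper_threshold] <- "hyper"
  status[is_dmr & tumor_mean >= hypo_threshold &
           tumor_mean <= hyper_threshold] <- "indeterminate"
  out <- data.frame(chrom = table$keys$chrom, pos = table$keys$pos,
                    normal_mean = normal_mean, tumor_mean = tumor_mean,
                    diff = diff,
                    status = factor(status, levels = c("not_dmr", "hypo",
                                                       "hyper", "indeterminate")),
                    stringsAsFactors = FALSE)
  class(out) <- c("dmr_calls", "data.frame")
  out
}

#' @export
summary.dmr_calls <- function(object, ...) {
  tab <- table(object$status)
  structure(list(n_cpgs = nrow(object), counts = tab,
                 n_dmr = sum(tab[c("hypo", "hyper", "indeterminate")])),
            class = "summary.dmr_calls")
}

#' @export
print.summary.dmr_calls <- function(x, ...) {
  cat(sprintf("DMR calls over %d intersected CpGs: %d DMRs\n", x$n_cpgs, x$n_dmr))
  print(x$counts)
  invisible(x)
}

#' Write DMR calls as a BED-like table plus a JSON summary
#'
#' Output intervals are 0-based half-open (`pos - 1`, `pos`), the BED
#' convention; in-memory calls stay 1-based.
#' @param calls a `dmr_calls` frame.
#' @param path output TSV path; the JSON summary (status counts, number of
#'   CpGs) goes to `sub("\\\\.tsv$", ".json", path)` unless `summary_path`
#'   is given.
#' @export
write_dmr_table <- function(calls, path, summary_path = NULL) {
  bed <- data.frame(chrom = calls$chrom, start = calls$pos - 1L,
                    end = calls$pos, normal_mean = calls$normal_mean,
                    tumor_mean = calls$tumor_mean, diff = calls$diff,
                    status = as.character(calls$status),
                    stringsAsFactors = FALSE)
  write_tsv(bed, path)
  if (is.null(summary_path)) summary_path <- sub("\\.tsv$", ".json", path)
  s <- summary(calls)
  jsonlite::write_json(list(n_cpgs = s$n_cpgs,
                            counts = as.list(as.integer(s$counts)) |>
                              stats::setNames(names(s$counts))),
                       summary_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dmr_table
#' @export
read_dmr_table <- function(path) {
  bed <- read_tsv(path)
  out <- data.frame(chrom = bed$chrom, pos = bed$end,
                    normal_mean = bed$normal_mean, tumor_mean = bed$tumor_mean,
                    diff = bed$diff,
                    status = factor(bed$status, levels = c("not_dmr", "hypo",
                                                           "hyper", "indeterminate")),
                    stringsAsFactors = FALSE)
  class(out) <- c("dmr_calls", "data.frame")
  out
}
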