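#' Pipeline configuration with the published default thresholds
#'
#' Collects every threshold and mode flag of the pipeline. The defaults are
#' the published analysis values: DMR difference 0.4 with hypo/hyper tumor
#' means 0.3/0.7; DEG |log2FC| >= 2, adjusted p < 0.05, baseMean >= 100;
#' gene eligibility > 10 CpGs with > half DMRs; probe specificity 0.4 and
#' extreme-probe delta 0.8; CNV deletion <= -0.4 and amplification > 0.3;
#' variant depth >= 10 with population frequencies < 0.01; coding length
#' 30 Mb for TMB. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    diff_threshold = 0.4, hypo_threshold = 0.3, hyper_threshold = 0.7,
    min_abs_lfc = 2, max_padj = 0.05, min_basemean = 100,
    min_cpgs = 10, min_fraction = 0.5,
    specificity_threshold = 0.4, extreme_delta = 0.8,
    del_threshold = -0.4, amp_threshold = 0.3,
    min_depth = 10, max_af = 0.01, coding_length_mb = 30,
    min_coverage = 1, signed_diff = FALSE, count_indeterminate = TRUE,
    specificity_mode = "per_class", normalize_mode = "center",
    missing_af_passes = TRUE, zrpkm_center = "median",
    perplexity = 30, top_n_genes = 10, seed = 1L)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(override)] <- override
  structure(defaults, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Validate pipeline inputs without mutating them
#'
#' Checks file existence, table formats, coordinate sanity, label
#' completeness and sample-name agreement across tables. Problems are
#' report entries, never errors.
#'
#' @param inputs named list of input paths / tables as accepted by
#'   [run_pipeline()].
#' @param config a [pipeline_config()].
#' @return character vector of problem descriptions (empty when clean).
#' @export
validate_inputs <- function(inputs, config = pipeline_config()) {
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))
  ss <- inputs$sample_sheet
  if (is.null(ss)) {
    note("sample_sheet is missing")
  } else {
    if (!all(c("sample", "group", "path") %in% names(ss))) {
      note("sample_sheet must have columns sample, group, path")
    } else {
      for (i in seq_len(nrow(ss))) {
        if (!file.exists(ss$path[i])) note("methylome file missing: %s", ss$path[i])
      }
      if (!all(ss$group %in% c("tumor", "normal"))) {
        note("sample_sheet groups must be 'tumor' or 'normal'")
      }
      if (!any(ss$group == "normal")) note("no normal sample in sample_sheet")
    }
  }
  for (nm in c("gene_map", "de", "fpkm", "links", "variants", "fusions", "cnv")) {
    p <- inputs[[paste0(nm, "_path")]]
    if (!is.null(p) && !file.exists(p)) note("%s file missing: %s", nm, p)
  }
  gp <- inputs$gene_map_path
  if (!is.null(gp) && file.exists(gp)) {
    gm <- read_tsv(gp)
    if (any(gm$start > gm$end)) note("gene_map has interval(s) with start > end")
    if (any(gm$start < 1)) note("gene_map has non-positive coordinates")
  }
  bp <- inputs$beta_path
  if (!is.null(bp) && file.exists(bp)) {
    bm <- read_tsv(bp, row.names = 1)
    bad <- which(as.matrix(bm) < 0 | as.matrix(bm) > 1, arr.ind = TRUE)
    for (k in seq_len(min(nrow(bad), 10))) {
      note("beta value out of [0,1] at probe %s, sample %s",
           rownames(bm)[bad[k, 1]], colnames(bm)[bad[k, 2]])
    }
    lp <- inputs$labels_path
    if (!is.null(lp) && file.exists(lp)) {
      lab <- read_tsv(lp)
      missing <- setdiff(colnames(bm), lab$sample)
      if (length(missing)) {
        note("cohort sample(s) without class label: %s",
             paste(missing, collapse = ", "))
      }
    }
  }
  fp <- inputs$fpkm_path
  if (!is.null(fp) && file.exists(fp) && !is.null(ss) &&
      all(c("sample") %in% names(ss))) {
    fm <- read_tsv(fp, row.names = 1)
    missing <- setdiff(ss$sample, colnames(fm))
    if (length(missing)) {
      note("sample(s) in sample_sheet absent from FPKM matrix: %s",
           paste(missing, collapse = ", "))
    }
  }
  problems
}

#' Run the integration pipeline end to end
#'
#' Chains methylation-ratio computation, CpG intersection, DMR calling, DEG
#' filtering, gene DMR-fraction scoring and ranking, methylation-expression
#' correlation, and (when the corresponding inputs are supplied) the
#' variant/TMB, CNV and fusion stages. All stage outputs are written under
#' `out_dir` together with a single consolidated JSON report; identical
#' inputs and configuration produce byte-identical reports.
#'
#' @param inputs named list: `sample_sheet` (data frame sample, group,
#'   path), `gene_map_path`, `de_path`, `fpkm_path`, optional `links_path`
#'   (probe_id, gene_id; probe ids are `chrom:pos` CpG keys), optional
#'   `variants_path`, `fusions_path` + `coding_genes`, `cnv_path`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @return (invisibly) the report list.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package = "methylink",
                 version = as.character(utils::packageVersion("methylink")),
                 config = unclass(config))

  ## -- methylation: ratios, intersection, DMR calls ------------------------
  ss <- inputs$sample_sheet
  records <- lapply(stats::setNames(ss$path, ss$sample),
                    read_cytosine_report, min_coverage = config$min_coverage)
  rt <- compute_ratios(records, stats::setNames(ss$group, ss$sample))
  rt_i <- intersect_cpgs(rt)
  calls <- call_dmrs(rt_i, diff_threshold = config$diff_threshold,
                     hypo_threshold = config$hypo_threshold,
                     hyper_threshold = config$hyper_threshold,
                     signed = config$signed_diff)
  write_dmr_table(calls, file.path(out_dir, "dmr_calls.tsv"))
  s <- summary(calls)
  report$methylation <- list(n_cpgs_total = nrow(rt$keys),
                             n_cpgs_intersected = s$n_cpgs,
                             n_dmr = s$n_dmr,
                             status_counts = as.list(as.integer(s$counts)) |>
                               stats::setNames(names(s$counts)))

  ## -- gene scoring ---------------------------------------------------------
  de <- read_tsv(inputs$de_path)
  gene_map <- read_tsv(inputs$gene_map_path)
  degs <- filter_degs(de, min_abs_lfc = config$min_abs_lfc,
                      max_padj = config$max_padj,
                      min_basemean = config$min_basemean)
  mapping <- map_cpgs_to_genes(calls, gene_map,
                               count_indeterminate = config$count_indeterminate)
  scores <- score_genes(mapping, degs$gene_id, min_cpgs = config$min_cpgs,
                        min_fraction = config$min_fraction)
  ranked <- rank_genes(scores, top_n = config$top_n_genes)
  write_tsv(scores, file.path(out_dir, "gene_scores.tsv"))
  write_tsv(ranked, file.path(out_dir, "top_genes.tsv"))
  if (nrow(ranked) == 0L) warning("no eligible gene to rank")
  report$genes <- list(n_de_input = nrow(de), n_degs = nrow(degs),
                       n_eligible = sum(scores$eligible),
                       top_genes = ranked$gene_id)

  ## -- methylation-expression correlation ----------------------------------
  if (!is.null(inputs$links_path) && !is.null(inputs$fpkm_path)) {
    fpkm <- as.matrix(read_tsv(inputs$fpkm_path, row.names = 1))
    norm <- normalize_fpkm(fpkm, mode = config$normalize_mode)
    probe_ratios <- rt_i$ratio
    rownames(probe_ratios) <- paste(rt_i$keys$chrom, rt_i$keys$pos, sep = ":")
    links <- read_tsv(inputs$links_path)
    fits <- batch_correlate(links, probe_ratios, norm)
    write_tsv(fits, file.path(out_dir, "meth_expr_fits.tsv"))
    report$correlation <- list(n_fits = nrow(fits),
                               n_negative_slope = sum(fits$slope < 0),
                               n_significant = sum(fits$p_value < 0.05))
  }

  ## -- auxiliary genomics ---------------------------------------------------
  if (!is.null(inputs$variants_path)) {
    variants <- read_tsv(inputs$variants_path)
    surv <- filter_variants(variants, min_depth = config$min_depth,
                            max_af = config$max_af,
                            missing_af_passes = config$missing_af_passes)
    write_tsv(surv, file.path(out_dir, "variants_filtered.tsv"))
    n_coding <- if ("coding_flag" %in% names(surv)) sum(surv$coding_flag)
                else nrow(surv)
    report$variants <- list(n_input = nrow(variants), n_kept = nrow(surv),
                            tmb = compute_tmb(n_coding, config$coding_length_mb))
  }
  if (!is.null(inputs$fusions_path)) {
    fus <- read_tsv(inputs$fusions_path)
    surv <- filter_fusions(fus, inputs$coding_genes)
    write_tsv(surv, file.path(out_dir, "fusions_filtered.tsv"))
    report$fusions <- list(n_input = nrow(fus), n_kept = nrow(surv))
  }
  if (!is.null(inputs$cnv_path)) {
    cnv <- read_tsv(inputs$cnv_path)
    states <- call_cnv(cnv, del_threshold = config$del_threshold,
                       amp_threshold = config$amp_threshold)
    write_tsv(states, file.path(out_dir, "cnv_calls.tsv"))
    report$cnv <- as.list(table(states$state))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
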