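#' Configuration for the synthetic methylome generator
#'
#' Bundles and validates every parameter of [simulate_methylome()]. The
#' defaults describe the study conditions the package is tested under: a
#' targeted bisulfite panel of 10,000 CpGs, 5 tumor and 2 normal methylomes
#' at mean coverage 30x, with 5% of CpGs planted as hypomethylated in tumor
#' (normal mean 0.85 dropping to 0.10).
#'
#' Background CpG methylation ratios are drawn once per CpG from a
#' Beta(`baseline_alpha`, `baseline_beta`) distribution and shared by both
#' groups, so background CpGs are never truly differential. Planted CpGs are
#' laid down in contiguous runs of `cluster_size` sites, mimicking the
#' regional character of real differentially methylated loci and giving
#' downstream gene territories with DMR fraction 1.
#'
#' @param n_cpgs number of CpG sites on the simulated panel.
#' @param n_tumor,n_normal samples per group.
#' @param mean_coverage Poisson mean of per-CpG read coverage.
#' @param baseline_alpha,baseline_beta Beta shape parameters of the
#'   background per-CpG methylation ratio (defaults give mean 0.8, the
#'   typical genome-wide CpG methylation level).
#' @param frac_hypo,frac_hyper proportions of CpGs planted as tumor-hypo-
#'   and tumor-hypermethylated; their sum must not exceed 1.
#' @param hypo_normal_mean,hypo_tumor_mean,hyper_normal_mean,hyper_tumor_mean
#'   true group mean ratios at planted CpGs, all in `[0,1]`.
#' @param cluster_size number of consecutive CpGs per planted run.
#' @param seed integer seed; all draws are reproducible from it.
#' @return a validated list of class `methyl_sim_config`.
#' @export
methyl_sim_config <- function(n_cpgs = 10000L, n_tumor = 5L, n_normal = 2L,
                              mean_coverage = 30, baseline_alpha = 8,
                              baseline_beta = 2, frac_hypo = 0.05,
                              frac_hyper = 0, hypo_normal_mean = 0.85,
                              hypo_tumor_mean = 0.10, hyper_normal_mean = 0.10,
                              hyper_tumor_mean = 0.85, cluster_size = 20L,
                              seed = 1L) {
  check_that(is.numeric(n_cpgs) && n_cpgs >= 0, "n_cpgs", "must be a nonnegative integer")
  check_that(is.numeric(n_tumor) && n_tumor >= 1, "n_tumor", "must be a positive integer")
  check_that(is.numeric(n_normal) && n_normal >= 1, "n_normal", "must be a positive integer")
  check_that(is.numeric(mean_coverage) && mean_coverage > 0, "mean_coverage", "must be positive")
  check_that(is.numeric(baseline_alpha) && baseline_alpha > 0, "baseline_alpha", "must be positive")
  check_that(is.numeric(baseline_beta) && baseline_beta > 0, "baseline_beta", "must be positive")
  check_that(is_proportion(frac_hypo), "frac_hypo", "must be in [0,1]")
  check_that(is_proportion(frac_hyper), "frac_hyper", "must be in [0,1]")
  check_that(frac_hypo + frac_hyper <= 1, "frac_hypo",
             "frac_hypo + frac_hyper must not exceed 1")
  for (nm in c("hypo_normal_mean", "hypo_tumor_mean",
               "hyper_normal_mean", "hyper_tumor_mean")) {
    check_that(is_proportion(get(nm)), nm, "must be a ratio in [0,1]")
  }
  check_that(hypo_tumor_mean < hypo_normal_mean, "hypo_tumor_mean",
             "must be below hypo_normal_mean")
  check_that(hyper_tumor_mean > hyper_normal_mean, "hyper_tumor_mean",
             "must be above hyper_normal_mean")
  check_that(is.numeric(cluster_size) && cluster_size >= 1, "cluster_size",
             "must be a positive integer")
  cfg <- list(n_cpgs = as.integer(n_cpgs), n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal), mean_coverage = mean_coverage,
              baseline_alpha = baseline_alpha, baseline_beta = baseline_beta,
              frac_hypo = frac_hypo, frac_hyper = frac_hyper,
              hypo_normal_mean = hypo_normal_mean, hypo_tumor_mean = hypo_tumor_mean,
              hyper_normal_mean = hyper_normal_mean, hyper_tumor_mean = hyper_tumor_mean,
              cluster_size = as.integer(cluster_size), seed = as.integer(seed))
  class(cfg) <- "methyl_sim_config"
  cfg
}

empty_truth_manifest <- function() {
  structure(list(params = list(), cpg = NULL, samples = NULL,
                 cluster_ratio = NULL, genes = NULL, de_method = NULL,
                 probes = NULL, aux = NULL, seeds = list()),
            class = "truth_manifest")
}

#' Simulate per-sample Bismark-style CpG count tables with planted truth
#'
#' Generates tumor and normal methylomes over one shared CpG coordinate set.
#' Per sample and CpG, read coverage is Poisson(`mean_coverage`) and the
#' methylated count is Binomial(coverage, true group ratio); a CpG with zero
#' coverage is simply absent from that sample's table. Cytosine rows
#' alternate deterministically between the plus strand (reported at the CpG
#' position) and the minus strand (reported at position + 1), so the
#' strand-collapsing path of [read_cytosine_report()] is always exercised.
#'
#' @param config a [methyl_sim_config()].
#' @return list with `samples` (named list of cytosine-report data frames:
#'   chrom, pos, strand, count_methylated, count_unmethylated, context,
#'   trinucleotide), and `truth`, a `truth_manifest` recording the true class
#'   (`background`/`hypo`/`hyper`) and group means of every CpG, the sample
#'   sheet, and per-sample realized mean ratios of each planted cluster.
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "methyl_sim_config"))
  n <- config$n_cpgs
  samples <- c(sprintf("tumor%02d", seq_len(config$n_tumor)),
               sprintf("normal%02d", seq_len(config$n_normal)))
  groups <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
  truth <- empty_truth_manifest()
  truth$params <- unclass(config)
  truth$seeds$methylome <- config$seed
  truth$samples <- data.frame(sample = samples, group = groups,
                              stringsAsFactors = FALSE)
  if (n == 0L) {
    truth$cpg <- data.frame(cpg_id = character(), chrom = character(),
                            pos = integer(), class = character(),
                            normal_mean = numeric(), tumor_mean = numeric(),
                            cluster = character(), stringsAsFactors = FALSE)
    empty <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), count_methylated = integer(),
                        count_unmethylated = integer(), context = character(),
                        trinucleotide = character(), stringsAsFactors = FALSE)
    return(list(samples = stats::setNames(rep(list(empty), length(samples)), samples),
                truth = truth))
  }

  pos <- 500L + (seq_len(n) - 1L) * 50L   # plus-strand C coordinates, chr1
  with_seed(config$seed, {
    ## plant hypo/hyper CpGs as contiguous runs of cluster_size sites
    n_hypo <- round(config$frac_hypo * n)
    n_hyper <- round(config$frac_hyper * n)
    cs <- min(config$cluster_size, n)
    n_blocks <- max(1L, n %/% cs)
    blocks_needed <- ceiling(n_hypo / cs) + ceiling(n_hyper / cs)
    if (blocks_needed > n_blocks) {
      stop("too many planted CpGs for the panel: increase n_cpgs or cluster_size",
           call. = FALSE)
    }
    chosen <- sample.int(n_blocks, blocks_needed)
    class_vec <- rep("background", n)
    cluster_vec <- rep(NA_character_, n)
    assign_runs <- function(count, block_ids, label) {
      left <- count
      for (k in seq_along(block_ids)) {
        if (left <= 0) break
        idx0 <- (block_ids[k] - 1L) * cs
        take <- min(cs, left)
        idx <- idx0 + seq_len(take)
        class_vec[idx] <<- label
        cluster_vec[idx] <<- sprintf("%s_run%03d", label, k)
        left <- left - take
      }
    }
    hypo_blocks <- chosen[seq_len(ceiling(n_hypo / cs))]
    hyper_blocks <- setdiff(chosen, hypo_blocks)
    if (n_hypo > 0) assign_runs(n_hypo, hypo_blocks, "hypo")
    if (n_hyper > 0) assign_runs(n_hyper, hyper_blocks, "hyper")

    base_ratio <- stats::rbeta(n, config$baseline_alpha, config$baseline_beta)
    normal_mean <- ifelse(class_vec == "hypo", config$hypo_normal_mean,
                   ifelse(class_vec == "hyper", config$hyper_normal_mean, base_ratio))
    tumor_mean <- ifelse(class_vec == "hypo", config$hypo_tumor_mean,
                  ifelse(class_vec == "hyper", config$hyper_tumor_mean, base_ratio))

    strand <- rep(c("+", "-"), length.out = n)
    report_pos <- ifelse(strand == "+", pos, pos + 1L)

    tabs <- vector("list", length(samples))
    names(tabs) <- samples
    ratio_mat <- matrix(NA_real_, nrow = n, ncol = length(samples),
                        dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      p_true <- if (groups[j] == "tumor") tumor_mean else normal_mean
      cov <- stats::rpois(n, config$mean_coverage)
      meth <- stats::rbinom(n, cov, p_true)
      keep <- cov > 0L
      ratio_mat[keep, j] <- meth[keep] / cov[keep]
      tabs[[j]] <- data.frame(
        chrom = "chr1", pos = report_pos[keep], strand = strand[keep],
        count_methylated = meth[keep],
        count_unmethylated = cov[keep] - meth[keep],
        context = "CG", trinucleotide = "CGG", stringsAsFactors = FALSE)
    }

    truth$cpg <- data.frame(
      cpg_id = sprintf("cpg_%06d", seq_len(n)), chrom = "chr1", pos = pos,
      class = class_vec, normal_mean = normal_mean, tumor_mean = tumor_mean,
      cluster = cluster_vec, stringsAsFactors = FALSE)

    planted <- unique(stats::na.omit(cluster_vec))
    if (length(planted)) {
      cr <- t(vapply(planted, function(cl) {
        colMeans(ratio_mat[which(cluster_vec == cl), , drop = FALSE], na.rm = TRUE)
      }, numeric(length(samples))))
      truth$cluster_ratio <- data.frame(cluster = planted, cr,
                                        check.names = FALSE,
                                        stringsAsFactors = FALSE)
    }
    list(samples = tabs, truth = truth)
  })
}

#' Simulate an expression matrix coupled to planted methylation clusters
#'
#' Driver genes sit exactly on planted hypomethylated CpG runs: their
#' log10(FPKM + 1) follows `intercept + slope * m + N(0, noise_sd)`, where
#' `m` is the sample's realized mean methylation ratio over the gene's CpGs.
#' With a negative slope, tumor hypomethylation therefore produces tumor
#' overexpression — the promoter-hypomethylation/oncogene-activation pattern
#' the pipeline is designed to recover. Non-driver genes tile the remaining
#' CpG blocks and draw from a log-normal background; `n_de_background` of
#' them additionally receive a tumor fold-change so the DEG filter has
#' passing genes without methylation support.
#'
#' The emitted differential-expression table is computed from the simulated
#' matrix by a Welch t-test on log2(FPKM + 1) with Benjamini-Hochberg
#' adjustment (recorded in the manifest as `de_method`); `basemean` is the
#' mean FPKM across all samples.
#'
#' @param truth `truth_manifest` from [simulate_methylome()].
#' @param n_genes total genes; must not exceed the number of CpG blocks.
#' @param n_driver genes planted on hypo clusters (`<= n_genes` and at most
#'   the number of planted hypo runs).
#' @param slope,noise_sd linear coupling of driver log-expression to
#'   methylation, and Gaussian noise SD on the log10 scale.
#' @param intercept log10(FPKM + 1) of a driver at methylation 0.
#' @param n_de_background background genes given a tumor expression shift.
#' @param seed integer seed.
#' @return list with `fpkm` (genes x samples matrix), `de` (gene_id, log2fc,
#'   padj, basemean), `gene_map` (gene_id, chrom, start, end; 1-based
#'   inclusive) and the updated `truth` manifest.
#' @export
simulate_expression <- function(truth, n_genes = 500L, n_driver = 5L,
                                slope = -1.2, noise_sd = 0.1,
                                intercept = 2.5, n_de_background = 20L,
                                seed = 1L) {
  stopifnot(inherits(truth, "truth_manifest"))
  if (n_driver > n_genes) stop("n_driver must not exceed n_genes", call. = FALSE)
  check_that(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd", "must be nonnegative")
  cpg <- truth$cpg
  samples <- truth$samples$sample
  groups <- truth$samples$group
  hypo_runs <- unique(cpg$cluster[cpg$class == "hypo"])
  if (n_driver > length(hypo_runs)) {
    stop("not enough planted hypo clusters for the requested drivers", call. = FALSE)
  }
  cs <- truth$params$cluster_size
  n_blocks <- nrow(cpg) %/% cs
  block_of <- (seq_len(nrow(cpg)) - 1L) %/% cs + 1L
  driver_blocks <- unique(block_of[!is.na(cpg$cluster) &
                                     cpg$cluster %in% hypo_runs[seq_len(n_driver)]])
  free_blocks <- setdiff(seq_len(n_blocks), driver_blocks)
  if (n_genes - n_driver > length(free_blocks)) {
    stop("n_genes exceeds the number of available CpG blocks", call. = FALSE)
  }

  with_seed(seed, {
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    driver_runs <- hypo_runs[seq_len(n_driver)]
    ## driver i occupies exactly its cluster's CpG span
    iv <- matrix(NA_integer_, n_genes, 2L)
    for (i in seq_len(n_driver)) {
      p <- cpg$pos[!is.na(cpg$cluster) & cpg$cluster == driver_runs[i]]
      iv[i, ] <- c(min(p), max(p) + 1L)
    }
    bg_blocks <- free_blocks[seq_len(n_genes - n_driver)]
    for (k in seq_along(bg_blocks)) {
      idx <- which(block_of == bg_blocks[k])
      iv[n_driver + k, ] <- c(min(cpg$pos[idx]), max(cpg$pos[idx]) + 1L)
    }
    gene_map <- data.frame(gene_id = gene_id, chrom = "chr1",
                           start = iv[, 1], end = iv[, 2],
                           stringsAsFactors = FALSE)

    ns <- length(samples)
    logv <- matrix(NA_real_, n_genes, ns, dimnames = list(gene_id, samples))
    cr <- truth$cluster_ratio
    for (i in seq_len(n_driver)) {
      m <- as.numeric(cr[cr$cluster == driver_runs[i], samples])
      logv[i, ] <- intercept + slope * m + stats::rnorm(ns, 0, noise_sd)
    }
    n_bg <- n_genes - n_driver
    if (n_bg > 0) {
      gene_mu <- stats::rnorm(n_bg, 1.2, 0.5)
      logv[n_driver + seq_len(n_bg), ] <-
        gene_mu + matrix(stats::rnorm(n_bg * ns, 0, 0.15), n_bg, ns)
    }
    de_bg <- integer(0)
    n_de_background <- min(n_de_background, n_bg)
    if (n_de_background > 0) {
      de_bg <- n_driver + seq_len(n_de_background)
      shift <- sample(c(-0.9, 0.9), n_de_background, replace = TRUE)
      logv[de_bg, ] <- 2.2 + matrix(stats::rnorm(n_de_background * ns, 0, 0.1),
                                    n_de_background, ns)
      logv[de_bg, groups == "tumor"] <- logv[de_bg, groups == "tumor"] + shift
    }
    fpkm <- pmax(10^logv - 1, 0)

    de <- de_table_from_fpkm(fpkm, groups)
    truth$genes <- data.frame(
      gene_id = gene_id, chrom = "chr1", start = iv[, 1], end = iv[, 2],
      driver = seq_len(n_genes) <= n_driver,
      cluster = c(driver_runs, rep(NA_character_, n_bg)),
      de_background = seq_len(n_genes) %in% de_bg,
      slope = c(rep(slope, n_driver), rep(NA_real_, n_bg)),
      intercept = c(rep(intercept, n_driver), rep(NA_real_, n_bg)),
      stringsAsFactors = FALSE)
    truth$de_method <- "student_t_log2_bh"
    truth$seeds$expression <- as.integer(seed)
    list(fpkm = fpkm, de = de, gene_map = gene_map, truth = truth)
  })
}

# Two-group DE summary of a simulated FPKM matrix: pooled-variance Student t
# on log2(FPKM+1), BH-adjusted (pooled rather than Welch so the test keeps
# power at the small normal-group sizes the generator defaults to);
# degenerate zero-variance genes get p 0 or 1 by mean equality.
de_table_from_fpkm <- function(fpkm, groups) {
  l2 <- log2(fpkm + 1)
  tum <- groups == "tumor"
  lfc <- rowMeans(l2[, tum, drop = FALSE]) - rowMeans(l2[, !tum, drop = FALSE])
  pv <- vapply(seq_len(nrow(l2)), function(i) {
    x <- l2[i, tum]; y <- l2[i, !tum]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    tryCatch(stats::t.test(x, y, var.equal = TRUE)$p.value,
             error = function(e) 1)
  }, numeric(1))
  data.frame(gene_id = rownames(fpkm), log2fc = lfc,
             padj = stats::p.adjust(pv, "BH"), basemean = rowMeans(fpkm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulate a multi-class reference beta-value cohort with specific probes
#'
#' Emulates a 450K-array-like reference set of CNS tumor classes. Background
#' probes share one Beta-distributed mean across all classes; planted
#' class-specific probes have that mean shifted by `specific_delta` (away
#' from the nearer bound, clipped to `[0.02, 0.98]`) in their class only.
#' Per-sample betas are Beta draws around the class mean with the given
#' `concentration`, so empirical class means concentrate tightly.
#'
#' @param n_probes number of array probes.
#' @param classes named integer vector: samples per class.
#' @param target_class class receiving planted probes (default the first).
#' @param n_specific planted specific probes (per class when `classwise`).
#' @param specific_delta mean shift of planted probes, in `[0, 1]`.
#' @param concentration Beta precision of per-sample draws around the mean.
#' @param classwise plant a disjoint specific set for every class instead of
#'   the target class only (used to make all classes separable in embeddings).
#' @param seed integer seed.
#' @param truth optional `truth_manifest` to extend (a fresh one by default).
#' @return list with `beta` (probes x samples matrix), `classes` (named
#'   character vector sample -> class) and updated `truth` manifest
#'   (`probes`: probe_id, specific_for, base_mean, shifted_mean).
#' @export
simulate_cohort <- function(n_probes = 2000L, classes = c(CN = 25L, A = 25L, B = 25L),
                            target_class = names(classes)[1], n_specific = 50L,
                            specific_delta = 0.6, concentration = 150,
                            classwise = FALSE, seed = 1L, truth = empty_truth_manifest()) {
  stopifnot(is.numeric(classes), !is.null(names(classes)), all(classes >= 1))
  if (!target_class %in% names(classes)) {
    stop(sprintf("unknown target class '%s'", target_class), call. = FALSE)
  }
  check_that(is.numeric(specific_delta) && specific_delta >= 0 && specific_delta <= 1,
             "specific_delta", "must be in [0,1]")
  need <- if (classwise) n_specific * length(classes) else n_specific
  if (need > n_probes) stop("n_specific exceeds n_probes", call. = FALSE)

  with_seed(seed, {
    probe_id <- sprintf("cg%08d", seq_len(n_probes))
    cls_names <- names(classes)
    sample_cls <- rep(cls_names, classes)
    sample_id <- sprintf("%s_s%02d", sample_cls,
                         unlist(lapply(classes, seq_len), use.names = FALSE))
    base_mean <- pmin(pmax(stats::rbeta(n_probes, 2, 2), 0.02), 0.98)
    specific_for <- rep(NA_character_, n_probes)
    shifted_mean <- base_mean
    planted_for <- if (classwise) cls_names else target_class
    pool <- sample.int(n_probes, need)
    for (k in seq_along(planted_for)) {
      idx <- pool[(k - 1L) * n_specific + seq_len(n_specific)]
      specific_for[idx] <- planted_for[k]
      shifted_mean[idx] <- pmin(pmax(
        ifelse(base_mean[idx] < 0.5, base_mean[idx] + specific_delta,
               base_mean[idx] - specific_delta), 0.02), 0.98)
    }
    beta <- matrix(NA_real_, n_probes, length(sample_id),
                   dimnames = list(probe_id, sample_id))
    for (j in seq_along(sample_id)) {
      m <- ifelse(!is.na(specific_for) & specific_for == sample_cls[j],
                  shifted_mean, base_mean)
      beta[, j] <- stats::rbeta(n_probes, m * concentration,
                                (1 - m) * concentration)
    }
    truth$probes <- data.frame(probe_id = probe_id, specific_for = specific_for,
                               base_mean = base_mean, shifted_mean = shifted_mean,
                               stringsAsFactors = FALSE)
    truth$seeds$cohort <- as.integer(seed)
    list(beta = beta,
         classes = stats::setNames(sample_cls, sample_id),
         truth = truth)
  })
}

#' Simulate variant, fusion and copy-number tables with known filter fates
#'
#' Emits small annotated tables whose rows deliberately straddle every
#' boundary of the downstream filters: variant read depths around the
#' minimum-depth cutoff, population allele frequencies at and around the
#' frequency cutoff (including missing values), exonic/splicing/other region
#' labels; fusion candidates with non-coding partners, zero junction or
#' spanning reads, and exact duplicates; and per-feature log2 copy ratios at
#' and around the deletion and amplification thresholds. The truth manifest
#' records the expected fate of every row, computed at generation time from
#' the published rules.
#'
#' @param seed integer seed.
#' @param sizes list with `n_variants`, `n_fusions`, `n_cnv` — counts of
#'   additional random rows beyond the deterministic boundary rows.
#' @param truth optional `truth_manifest` to extend (a fresh one by default).
#' @return list with `variants`, `fusions`, `cnv` data frames, the
#'   `coding_genes` character set, and updated `truth` (in `truth$aux`).
#' @export
simulate_aux_tables <- function(seed = 1L,
                                sizes = list(n_variants = 30L, n_fusions = 12L,
                                             n_cnv = 20L),
                                truth = empty_truth_manifest()) {
  stopifnot(all(unlist(sizes) >= 0))
  with_seed(seed, {
    ## --- variants: deterministic boundary rows, then random rows ---------
    bnd <- expand.grid(total_depth = c(9L, 10L, 11L),
                       region_class = c("exonic", "splicing", "other"),
                       af = c(NA, 0.009, 0.01, 0.011),
                       stringsAsFactors = FALSE)
    nv <- nrow(bnd) + sizes$n_variants
    vt <- data.frame(
      variant_id = sprintf("var_%04d", seq_len(nv)),
      chrom = "chr1", pos = 10000L + seq_len(nv) * 37L,
      ref = "A", alt = "T",
      total_depth = c(bnd$total_depth,
                      stats::rpois(sizes$n_variants, 45) + sample(0:15, sizes$n_variants, TRUE)),
      region_class = c(bnd$region_class,
                       sample(c("exonic", "splicing", "other", "intronic"),
                              sizes$n_variants, TRUE)),
      af_exac_eas = c(bnd$af, round(ifelse(stats::runif(sizes$n_variants) < 0.4, NA,
                                           stats::runif(sizes$n_variants, 0, 0.02)), 5)),
      af_gnomad_eas = c(rep(NA_real_, nrow(bnd)),
                        round(ifelse(stats::runif(sizes$n_variants) < 0.4, NA,
                                     stats::runif(sizes$n_variants, 0, 0.02)), 5)),
      af_korean = c(rep(NA_real_, nrow(bnd)),
                    round(ifelse(stats::runif(sizes$n_variants) < 0.4, NA,
                                 stats::runif(sizes$n_variants, 0, 0.02)), 5)),
      coding_flag = TRUE, stringsAsFactors = FALSE)
    af_ok <- function(x) is.na(x) | x < 0.01
    v_keep <- vt$total_depth >= 10L &
      vt$region_class %in% c("exonic", "splicing") &
      af_ok(vt$af_exac_eas) & af_ok(vt$af_gnomad_eas) & af_ok(vt$af_korean)

    ## --- fusions ----------------------------------------------------------
    coding_genes <- sprintf("CODG%02d", 1:10)
    noncoding <- sprintf("LINC%02d", 1:6)
    base <- data.frame(
      gene_a = c("CODG01", "CODG02", "LINC01", "LINC02", "CODG03", "CODG04"),
      gene_b = c("CODG05", "LINC03", "CODG06", "LINC04", "CODG07", "CODG08"),
      chrom_a = "chr2", pos_a = c(500L, 900L, 1300L, 1700L, 2100L, 2500L),
      chrom_b = "chr3", pos_b = c(600L, 1000L, 1400L, 1800L, 2200L, 2600L),
      junction_reads = c(8L, 5L, 4L, 7L, 0L, 6L),
      spanning_reads = c(3L, 2L, 6L, 5L, 4L, 0L), stringsAsFactors = FALSE)
    base <- rbind(base, base[1, ])   # exact duplicate -> one survivor
    extra <- sizes$n_fusions
    if (extra > 0) {
      rnd <- data.frame(
        gene_a = sample(c(coding_genes, noncoding), extra, TRUE),
        gene_b = sample(c(coding_genes, noncoding), extra, TRUE),
        chrom_a = "chr2", pos_a = 3000L + seq_len(extra) * 91L,
        chrom_b = "chr3", pos_b = 3100L + seq_len(extra) * 87L,
        junction_reads = stats::rpois(extra, 4),
        spanning_reads = stats::rpois(extra, 3), stringsAsFactors = FALSE)
      base <- rbind(base, rnd)
    }
    fus <- base
    fus$fusion_id <- sprintf("fus_%03d", seq_len(nrow(fus)))
    f_pass <- (fus$gene_a %in% coding_genes | fus$gene_b %in% coding_genes) &
      fus$junction_reads > 0L & fus$spanning_reads > 0L
    key <- with(fus, paste(gene_a, gene_b, chrom_a, pos_a, chrom_b, pos_b,
                           junction_reads, spanning_reads, sep = "|"))
    f_keep <- f_pass & !duplicated(key)

    ## --- copy number ------------------------------------------------------
    det <- c(-0.4, -0.41, -0.39, 0.3, 0.31, 0)
    l2 <- c(det, round(stats::runif(sizes$n_cnv, -1, 1), 3))
    cnv <- data.frame(feature_id = sprintf("feat_%03d", seq_along(l2)),
                      log2_ratio = l2, stringsAsFactors = FALSE)
    c_state <- ifelse(cnv$log2_ratio <= -0.4, "deletion",
               ifelse(cnv$log2_ratio > 0.3, "amplification", "neutral"))

    truth$aux <- list(
      variants = data.frame(variant_id = vt$variant_id, expected_keep = v_keep,
                            stringsAsFactors = FALSE),
      fusions = data.frame(fusion_id = fus$fusion_id, expected_keep = f_keep,
                           stringsAsFactors = FALSE),
      cnv = data.frame(feature_id = cnv$feature_id, expected_state = c_state,
                       stringsAsFactors = FALSE),
      coding_genes = coding_genes)
    truth$seeds$aux <- as.integer(seed)
    list(variants = vt, fusions = fus, cnv = cnv,
         coding_genes = coding_genes, truth = truth)
  })
}

#' Write and reload a truth manifest losslessly
#'
#' The manifest is serialized as JSON; data frames round-trip column-wise.
#' @param truth a `truth_manifest`.
#' @param path output JSON path.
#' @return `read_truth_manifest` returns the reconstructed `truth_manifest`.
#' @export
write_truth_manifest <- function(truth, path) {
  stopifnot(inherits(truth, "truth_manifest"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- empty_truth_manifest()
  for (nm in names(x)) out[[nm]] <- x[[nm]]
  out
}

#' Write simulated methylomes as Bismark cytosine-report files
#'
#' One headerless TSV per sample (chrom, position, strand, methylated count,
#' unmethylated count, context, trinucleotide), the dialect
#' [read_cytosine_report()] consumes.
#' @param sim output of [simulate_methylome()].
#' @param dir output directory (created if absent).
#' @return data frame sample sheet: sample, group, path.
#' @export
write_methylome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$samples), function(s) {
    p <- file.path(dir, paste0(s, ".cov.tsv"))
    utils::write.table(sim$samples[[s]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    p
  }, character(1))
  data.frame(sample = names(sim$samples),
             group = sim$truth$samples$group,
             path = unname(paths), stringsAsFactors = FALSE)
}
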