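test_that("empty panel yields empty tables and an empty truth record", {
  sim <- simulate_methylome(methyl_sim_config(n_cpgs = 0L, seed = 1L))
  expect_length(sim$samples, 7L)
  expect_true(all(vapply(sim$samples, nrow, integer(1)) == 0L))
  expect_equal(nrow(sim$truth$cpg), 0L)
})

test_that("planted hypo CpGs have ratio exactly zero when the tumor mean is zero", {
  cfg <- methyl_sim_config(n_cpgs = 200L, mean_coverage = 500,
                           frac_hypo = 0.1, hypo_tumor_mean = 0,
                           hypo_normal_mean = 0.85, seed = 3L)
  sim <- simulate_methylome(cfg)
  hypo_pos <- sim$truth$cpg$pos[sim$truth$cpg$class == "hypo"]
  for (s in sprintf("tumor%02d", 1:5)) {
    tab <- sim$samples[[s]]
    cpg_pos <- ifelse(tab$strand == "-", tab$pos - 1L, tab$pos)
    expect_true(all(tab$count_methylated[cpg_pos %in% hypo_pos] == 0L))
  }
})

test_that("all generators are byte-deterministic under a fixed seed", {
  cfg <- methyl_sim_config(n_cpgs = 500L, frac_hypo = 0.05, seed = 7L)
  a <- simulate_methylome(cfg)
  b <- simulate_methylome(cfg)
  expect_identical(a, b)
  expect_identical(simulate_expression(a$truth, n_genes = 25L, n_driver = 1L, seed = 9L),
                   simulate_expression(b$truth, n_genes = 25L, n_driver = 1L, seed = 9L))
  expect_identical(simulate_cohort(n_probes = 100L, seed = 5L),
                   simulate_cohort(n_probes = 100L, seed = 5L))
  expect_identical(simulate_aux_tables(seed = 2L), simulate_aux_tables(seed = 2L))
})

test_that("realized ratios stay in [0,1] and every row has one truth entry", {
  sim <- simulate_methylome(methyl_sim_config(n_cpgs = 300L, frac_hypo = 0.1,
                                              frac_hyper = 0.1, seed = 11L))
  truth_pos <- sim$truth$cpg$pos
  expect_false(any(duplicated(truth_pos)))
  for (tab in sim$samples) {
    tot <- tab$count_methylated + tab$count_unmethylated
    expect_true(all(tot > 0))
    r <- tab$count_methylated / tot
    expect_true(all(r >= 0 & r <= 1))
    cpg_pos <- ifelse(tab$strand == "-", tab$pos - 1L, tab$pos)
    expect_true(all(cpg_pos %in% truth_pos))
  }
  expect_true(all(sim$truth$cpg$normal_mean >= 0 & sim$truth$cpg$normal_mean <= 1))
  expect_true(all(sim$truth$cpg$tumor_mean >= 0 & sim$truth$cpg$tumor_mean <= 1))
})

test_that("empirical planted group means converge to the configured means", {
  cfg <- methyl_sim_config(n_cpgs = 500L, n_tumor = 20L, n_normal = 20L,
                           mean_coverage = 200, frac_hypo = 0.2, seed = 13L)
  sim <- simulate_methylome(cfg)
  hypo_pos <- sim$truth$cpg$pos[sim$truth$cpg$class == "hypo"]
  grp_mean <- function(samples) {
    mean(unlist(lapply(samples, function(tab) {
      cpg_pos <- ifelse(tab$strand == "-", tab$pos - 1L, tab$pos)
      keep <- cpg_pos %in% hypo_pos
      tab$count_methylated[keep] /
        (tab$count_methylated + tab$count_unmethylated)[keep]
    })))
  }
  tum <- grp_mean(sim$samples[sim$truth$samples$group == "tumor"])
  nor <- grp_mean(sim$samples[sim$truth$samples$group == "normal"])
  expect_lt(abs(tum - cfg$hypo_tumor_mean), 0.02)
  expect_lt(abs(nor - cfg$hypo_normal_mean), 0.02)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(methyl_sim_config(frac_hypo = 0.7, frac_hyper = 0.5), "frac_hypo")
  expect_error(methyl_sim_config(hypo_tumor_mean = 0.9, hypo_normal_mean = 0.8),
               "hypo_tumor_mean")
  expect_error(methyl_sim_config(mean_coverage = -1), "mean_coverage")
  sim <- simulate_methylome(methyl_sim_config(n_cpgs = 100L, seed = 1L))
  expect_error(simulate_expression(sim$truth, n_genes = 3L, n_driver = 5L),
               "n_driver")
})

test_that("noiseless drivers follow the planted line exactly", {
  cfg <- methyl_sim_config(n_cpgs = 100L, mean_coverage = 400, seed = 17L)
  sim <- simulate_methylome(cfg)
  ex0 <- simulate_expression(sim$truth, n_genes = 5L, n_driver = 1L,
                             slope = 0, noise_sd = 0, seed = 19L)
  drv <- ex0$truth$genes$gene_id[ex0$truth$genes$driver]
  expect_equal(diff(range(ex0$fpkm[drv, ])), 0)

  ex <- simulate_expression(sim$truth, n_genes = 5L, n_driver = 1L,
                            slope = -1.2, noise_sd = 0, seed = 19L)
  drv <- ex$truth$genes$gene_id[ex$truth$genes$driver]
  cl <- ex$truth$genes$cluster[ex$truth$genes$driver]
  cr <- sim$truth$cluster_ratio
  m <- as.numeric(cr[cr$cluster == cl, sim$truth$samples$sample])
  y <- log10(ex$fpkm[drv, ] + 1)
  fit <- lm(y ~ m)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_equal(unname(coef(fit)[2]), -1.2, tolerance = 1e-10)
})

test_that("cohort generator plants the largest target-vs-rest differences", {
  co <- simulate_cohort(n_probes = 400L, classes = c(CN = 40L, A = 40L, B = 40L),
                        n_specific = 20L, specific_delta = 0.6, seed = 23L)
  cls <- co$classes
  tgt <- rowMeans(co$beta[, cls == "CN"])
  rest <- rowMeans(co$beta[, cls != "CN"])
  top <- rownames(co$beta)[order(-abs(tgt - rest))][1:20]
  planted <- co$truth$probes$probe_id[!is.na(co$truth$probes$specific_for)]
  expect_setequal(top, planted)
})

test_that("a zero specificity delta plants nothing detectable", {
  co <- simulate_cohort(n_probes = 200L, n_specific = 20L,
                        specific_delta = 0, seed = 29L)
  sp <- specific_probes(co$beta, co$classes, "CN", threshold = 0.2)
  expect_equal(sum(sp$specific), 0L)
})

test_that("aux-table truth marks boundary rows correctly", {
  aux <- simulate_aux_tables(seed = 31L)
  v <- merge(aux$variants, aux$truth$aux$variants, by = "variant_id")
  expect_true(all(!v$expected_keep[v$total_depth == 9L]))
  dup_key <- with(aux$fusions, paste(gene_a, gene_b, pos_a, pos_b,
                                     junction_reads, spanning_reads))
  dups <- dup_key[duplicated(dup_key)]
  for (k in unique(dups)) {
    rows <- aux$truth$aux$fusions$expected_keep[dup_key == k]
    expect_lte(sum(rows), 1L)
  }
  zero <- unlist(lapply(list(aux$fusions$junction_reads,
                             aux$fusions$spanning_reads), function(x) which(x == 0)))
  expect_true(all(!aux$truth$aux$fusions$expected_keep[zero]))
  sizes0 <- list(n_variants = 0L, n_fusions = 0L, n_cnv = 0L)
  aux0 <- simulate_aux_tables(seed = 1L, sizes = sizes0)
  expect_equal(nrow(aux0$variants), 36L)   # only the deterministic boundary grid
})

test_that("truth manifests round-trip through JSON losslessly", {
  sim <- simulate_methylome(methyl_sim_config(n_cpgs = 120L, seed = 37L))
  ex <- simulate_expression(sim$truth, n_genes = 6L, n_driver = 1L, seed = 38L)
  p <- tempfile(fileext = ".json")
  write_truth_manifest(ex$truth, p)
  back <- read_truth_manifest(p)
  expect_equal(as.data.frame(back$cpg), ex$truth$cpg)
  expect_equal(as.data.frame(back$genes), ex$truth$genes)
  expect_equal(as.data.frame(back$cluster_ratio), ex$truth$cluster_ratio)
  expect_equal(back$de_method, ex$truth$de_method)
  expect_equal(back$params$n_cpgs, 120L)
})
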