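# Independent oracles and fixture builders shared across the suite.

# Build a ratio_table directly from a ratio matrix (tests bypass file IO).
make_ratio_table <- function(ratio, groups, chrom = "chr1",
                             pos = seq_len(nrow(ratio)) * 10L) {
  total <- matrix(10L, nrow(ratio), ncol(ratio), dimnames = dimnames(ratio))
  total[is.na(ratio)] <- NA_integer_
  structure(list(keys = data.frame(chrom = chrom, pos = pos,
                                   stringsAsFactors = FALSE),
                 ratio = ratio, total = total, groups = groups),
            class = "ratio_table")
}

# Brute-force, CpG-by-CpG evaluation of the three-threshold DMR rule;
# deliberately written as an explicit loop, independent of call_dmrs().
oracle_dmr_status <- function(ratio, groups, diff_threshold = 0.4,
                              hypo_threshold = 0.3, hyper_threshold = 0.7) {
  out <- character(nrow(ratio))
  for (i in seq_len(nrow(ratio))) {
    tm <- mean(ratio[i, groups == "tumor"])
    nm <- mean(ratio[i, groups == "normal"])
    if (abs(tm - nm) > diff_threshold) {
      out[i] <- if (tm < hypo_threshold) "hypo"
                else if (tm > hyper_threshold) "hyper"
                else "indeterminate"
    } else {
      out[i] <- "not_dmr"
    }
  }
  out
}

# Brute-force double loop assigning CpG positions to gene intervals.
oracle_gene_tally <- function(calls, gene_map, dmr_states) {
  n_cpgs <- n_dmr <- integer(nrow(gene_map))
  for (g in seq_len(nrow(gene_map))) {
    for (i in seq_len(nrow(calls))) {
      if (calls$chrom[i] == gene_map$chrom[g] &&
          calls$pos[i] >= gene_map$start[g] &&
          calls$pos[i] <= gene_map$end[g]) {
        n_cpgs[g] <- n_cpgs[g] + 1L
        if (as.character(calls$status[i]) %in% dmr_states) {
          n_dmr[g] <- n_dmr[g] + 1L
        }
      }
    }
  }
  data.frame(gene_id = gene_map$gene_id, n_cpgs = n_cpgs, n_dmr = n_dmr,
             stringsAsFactors = FALSE)
}

# Closed-form OLS via the normal equations, independent of stats::lm.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Population variance of a vector, missing values excluded.
oracle_pop_var <- function(x) {
  x <- x[!is.na(x)]
  mean((x - mean(x))^2)
}

# Write a cytosine-report file from a data frame of raw rows.
write_report_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

cyt_row <- function(pos, strand, meth, unmeth, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, strand = strand,
             count_methylated = meth, count_unmethylated = unmeth,
             context = "CG", trinucleotide = "CGG", stringsAsFactors = FALSE)
}

# Single-variant row builder for filter boundary cases.
vrow <- function(depth, region = "exonic", exac = NA, gnomad = NA, kor = NA) {
  data.frame(variant_id = "v", chrom = "chr1", pos = 1L, ref = "A", alt = "T",
             total_depth = depth, region_class = region, af_exac_eas = exac,
             af_gnomad_eas = gnomad, af_korean = kor, coding_flag = TRUE,
             stringsAsFactors = FALSE)
}

# Full on-disk pipeline fixture built from the synthetic generators.
make_pipeline_fixture <- function(dir, seed = 101L, n_cpgs = 2000L,
                                  n_genes = 100L, n_driver = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_methylome(methyl_sim_config(n_cpgs = n_cpgs, seed = seed))
  sheet <- write_methylome(sim, file.path(dir, "meth"))
  ex <- simulate_expression(sim$truth, n_genes = n_genes, n_driver = n_driver,
                            seed = seed + 1L)
  de_path <- file.path(dir, "de.tsv")
  write.table(ex$de, de_path, sep = "\t", quote = FALSE, row.names = FALSE)
  map_path <- file.path(dir, "gene_map.tsv")
  write.table(ex$gene_map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  fpkm_path <- file.path(dir, "fpkm.tsv")
  write.table(data.frame(gene_id = rownames(ex$fpkm), ex$fpkm,
                         check.names = FALSE),
              fpkm_path, sep = "\t", quote = FALSE, row.names = FALSE)
  # link three CpGs inside each driver gene to that gene
  drv <- ex$truth$genes[ex$truth$genes$driver, ]
  links <- do.call(rbind, lapply(seq_len(nrow(drv)), function(i) {
    cp <- sim$truth$cpg[sim$truth$cpg$pos >= drv$start[i] &
                          sim$truth$cpg$pos <= drv$end[i], ]
    data.frame(probe_id = paste(cp$chrom[1:3], cp$pos[1:3], sep = ":"),
               gene_id = drv$gene_id[i], stringsAsFactors = FALSE)
  }))
  links_path <- file.path(dir, "links.tsv")
  write.table(links, links_path, sep = "\t", quote = FALSE, row.names = FALSE)
  aux <- simulate_aux_tables(seed = seed + 2L, truth = ex$truth)
  var_path <- file.path(dir, "variants.tsv")
  write.table(aux$variants, var_path, sep = "\t", quote = FALSE, row.names = FALSE)
  fus_path <- file.path(dir, "fusions.tsv")
  write.table(aux$fusions, fus_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cnv_path <- file.path(dir, "cnv.tsv")
  write.table(aux$cnv, cnv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(inputs = list(sample_sheet = sheet, de_path = de_path,
                     gene_map_path = map_path, fpkm_path = fpkm_path,
                     links_path = links_path, variants_path = var_path,
                     fusions_path = fus_path, coding_genes = aux$coding_genes,
                     cnv_path = cnv_path),
       sim = sim, ex = ex, aux = aux)
}
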