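de_row <- function(gene_id, log2fc, padj, basemean) {
  data.frame(gene_id = gene_id, log2fc = log2fc, padj = padj,
             basemean = basemean, stringsAsFactors = FALSE)
}

test_that("DEG thresholds apply with the stated strict/inclusive boundaries", {
  de <- rbind(de_row("a", 2.0, 0.01, 150),    # kept: lfc inclusive
              de_row("b", 3.0, 0.05, 150),    # dropped: padj strict
              de_row("c", -2.5, 0.001, 100),  # kept: absolute lfc, basemean inclusive
              de_row("d", 1.99, 0.001, 500),  # dropped: lfc
              de_row("e", 4.0, NA, 500),      # dropped: missing padj
              de_row("f", 4.0, 0.001, 99.9))  # dropped: basemean
  kept <- filter_degs(de)
  expect_setequal(kept$gene_id, c("a", "c"))
})

test_that("duplicate gene ids in the DE table are rejected by name", {
  de <- rbind(de_row("a", 2, 0.01, 150), de_row("a", 3, 0.01, 150))
  expect_error(filter_degs(de), "duplicate gene_id.*a")
})

test_that("relaxing any DEG threshold never removes a kept gene", {
  set.seed(53)
  de <- de_row(sprintf("g%03d", 1:200), rnorm(200, 0, 2.5),
               runif(200), rlnorm(200, 4.5, 1))
  base <- filter_degs(de)$gene_id
  expect_true(all(base %in% filter_degs(de, min_abs_lfc = 1.5)$gene_id))
  expect_true(all(base %in% filter_degs(de, max_padj = 0.2)$gene_id))
  expect_true(all(base %in% filter_degs(de, min_basemean = 10)$gene_id))
})

fake_calls <- function(pos, status, diff = 0.5, chrom = "chr1") {
  out <- data.frame(chrom = chrom, pos = pos, normal_mean = 0.8,
                    tumor_mean = 0.8 + diff, diff = diff,
                    status = factor(status, levels = c("not_dmr", "hypo",
                                                       "hyper", "indeterminate")),
                    stringsAsFactors = FALSE)
  class(out) <- c("dmr_calls", "data.frame")
  out
}

test_that("CpGs are assigned by inclusive containment, to every overlapping gene", {
  calls <- fake_calls(c(100L, 150L, 201L), c("hypo", "not_dmr", "hypo"))
  gm <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                   start = c(100L, 140L), end = c(200L, 260L),
                   stringsAsFactors = FALSE)
  mp <- map_cpgs_to_genes(calls, gm)
  expect_equal(mp$tally$n_cpgs, c(2L, 2L))   # 100,150 in g1; 150,201 in g2
  expect_equal(mp$tally$n_dmr, c(1L, 1L))
  expect_error(map_cpgs_to_genes(calls, data.frame(gene_id = "bad", chrom = "chr1",
                                                   start = 10L, end = 5L)),
               "start > end")
})

test_that("gene tallies equal the brute-force double loop on random fixtures", {
  set.seed(59)
  calls <- fake_calls(sort(sample(1:5000, 400)),
                      sample(c("not_dmr", "hypo", "hyper", "indeterminate"),
                             400, TRUE))
  st <- sample(1:4500, 60)
  gm <- data.frame(gene_id = sprintf("g%02d", 1:60), chrom = "chr1",
                   start = st, end = st + sample(50:500, 60, TRUE),
                   stringsAsFactors = FALSE)
  for (ci in c(TRUE, FALSE)) {
    states <- if (ci) c("hypo", "hyper", "indeterminate") else c("hypo", "hyper")
    mp <- map_cpgs_to_genes(calls, gm, count_indeterminate = ci)
    expect_equal(mp$tally, oracle_gene_tally(calls, gm, states))
  }
})

test_that("eligibility uses strictly more than 10 CpGs and more than half DMRs", {
  mk <- function(n_cpgs, n_dmr) {
    calls <- fake_calls(seq_len(n_cpgs) * 10L,
                        c(rep("hypo", n_dmr), rep("not_dmr", n_cpgs - n_dmr)))
    gm <- data.frame(gene_id = "g", chrom = "chr1", start = 1L,
                     end = n_cpgs * 10L + 1L, stringsAsFactors = FALSE)
    score_genes(map_cpgs_to_genes(calls, gm), "g")
  }
  expect_false(mk(10L, 10L)$eligible)        # 10 CpGs: not more than 10
  expect_false(mk(20L, 10L)$eligible)        # fraction exactly 0.5
  s <- mk(12L, 7L)
  expect_true(s$eligible)
  expect_equal(s$dmr_fraction, 7 / 12)
})

test_that("a DEG with no mapped CpGs is scored and ineligible, not an error", {
  calls <- fake_calls(100L, "hypo")
  gm <- data.frame(gene_id = "g1", chrom = "chr1", start = 90L, end = 110L,
                   stringsAsFactors = FALSE)
  s <- score_genes(map_cpgs_to_genes(calls, gm), c("g1", "orphan"))
  expect_equal(s$n_cpgs[s$gene_id == "orphan"], 0L)
  expect_false(s$eligible[s$gene_id == "orphan"])
})

test_that("ranking is deterministic with the stated tie-breaks", {
  s <- data.frame(gene_id = c("b", "a", "c", "d"),
                  n_cpgs = c(12L, 12L, 15L, 12L), n_dmr = c(9L, 9L, 15L, 8L),
                  dmr_fraction = c(0.75, 0.75, 1.0, 8 / 12),
                  median_abs_diff = 0.5, mean_abs_diff = c(0.5, 0.5, 0.6, 0.4),
                  eligible = TRUE, stringsAsFactors = FALSE)
  r <- rank_genes(s, top_n = 10)
  expect_equal(r$gene_id, c("c", "a", "b", "d"))   # fraction, then lexicographic
  expect_equal(r$rank, 1:4)
  one <- rank_genes(s[s$gene_id == "d", , drop = FALSE])
  expect_equal(one$rank, 1L)
  none <- rank_genes(transform(s, eligible = FALSE))
  expect_equal(nrow(none), 0L)
})

test_that("DMR fraction is invariant to CpG input order", {
  set.seed(61)
  calls <- fake_calls(sort(sample(1:2000, 150)),
                      sample(c("not_dmr", "hypo"), 150, TRUE))
  gm <- data.frame(gene_id = sprintf("g%d", 1:10), chrom = "chr1",
                   start = (0:9) * 200L + 1L, end = (1:10) * 200L,
                   stringsAsFactors = FALSE)
  shuffled <- calls[sample(nrow(calls)), ]
  class(shuffled) <- class(calls)
  s1 <- score_genes(map_cpgs_to_genes(calls, gm), gm$gene_id)
  s2 <- score_genes(map_cpgs_to_genes(shuffled, gm), gm$gene_id)
  expect_equal(s1, s2)
})
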