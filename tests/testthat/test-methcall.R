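test_that("paired-strand cytosines collapse onto the plus-strand CpG with summed counts", {
  rows <- rbind(cyt_row(100L, "+", 3L, 1L), cyt_row(101L, "-", 1L, 3L),
                cyt_row(200L, "-", 2L, 0L))
  rec <- read_cytosine_report(write_report_file(rows))
  expect_equal(rec$pos, c(100L, 199L))
  expect_equal(rec$meth_count, c(4L, 2L))
  expect_equal(rec$total_count, c(8L, 2L))
  expect_equal(rec$strand_sources, c("+-", "-"))
})

test_that("an empty report yields an empty record set", {
  p <- tempfile(); file.create(p)
  rec <- read_cytosine_report(p)
  expect_equal(nrow(rec), 0L)
})

test_that("minimum-coverage filtering keeps exactly the records at the boundary", {
  rows <- rbind(cyt_row(100L, "+", 4L, 5L),   # total 9 -> dropped
                cyt_row(200L, "+", 5L, 5L))   # total 10 -> kept
  rec <- read_cytosine_report(write_report_file(rows), min_coverage = 10L)
  expect_equal(rec$pos, 200L)
  expect_equal(rec$total_count, 10L)
})

test_that("malformed report lines raise a parse error with the line number", {
  p <- tempfile()
  writeLines(c("chr1\t100\t+\t3\t1\tCG\tCGG", "chr1\t200\t*\t1\t1\tCG\tCGG"), p)
  expect_error(read_cytosine_report(p), "line 2")
})

test_that("methylation ratios are meth over total, missing where uncovered", {
  recs <- list(
    s1 = data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), strand_sources = "+",
                    meth_count = c(5L, 0L, 7L), total_count = c(10L, 8L, 7L),
                    stringsAsFactors = FALSE),
    s2 = data.frame(chrom = "chr1", pos = c(10L, 20L), strand_sources = "+",
                    meth_count = c(2L, 4L), total_count = c(4L, 8L),
                    stringsAsFactors = FALSE))
  rt <- compute_ratios(recs, c(s1 = "tumor", s2 = "normal"))
  expect_equal(rt$ratio[, "s1"], c(0.5, 0, 1))
  expect_equal(rt$ratio[, "s2"], c(0.5, 0.5, NA))
})

test_that("sample intersection equals brute-force set intersection", {
  # hand case: present sets {A,B,C}, {B,C,D}, {B,C} -> {B,C}
  m <- matrix(NA_real_, 4, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  rownames_sets <- list(s1 = 1:3, s2 = 2:4, s3 = 2:3)
  for (s in names(rownames_sets)) m[rownames_sets[[s]], s] <- 0.5
  rt <- make_ratio_table(m, c(s1 = "tumor", s2 = "tumor", s3 = "normal"))
  out <- intersect_cpgs(rt)
  expect_equal(out$keys$pos, c(20L, 30L))

  # single sample is the identity
  m1 <- matrix(runif(5), 5, 1, dimnames = list(NULL, "n1"))
  rt1 <- make_ratio_table(m1, c(n1 = "normal"))
  expect_equal(intersect_cpgs(rt1)$keys, rt1$keys)

  # simulated CpGs vs an explicit loop over presence sets
  set.seed(41)
  mm <- matrix(runif(3000), 1000, 3, dimnames = list(NULL, c("a", "b", "n")))
  mm[sample(length(mm), 600)] <- NA
  rt2 <- make_ratio_table(mm, c(a = "tumor", b = "tumor", n = "normal"))
  keep <- vapply(seq_len(1000), function(i) all(!is.na(mm[i, ])), logical(1))
  expect_equal(intersect_cpgs(rt2)$keys$pos, rt2$keys$pos[keep])
})

test_that("DMR statuses follow the threshold rule at and around its boundaries", {
  m <- rbind(c(0.10, 0.10, 0.85),   # hypo: diff -0.75, tumor mean 0.10
             c(0.90, 0.90, 0.50),   # diff exactly 0.40 -> not a DMR (strict)
             c(0.55, 0.55, 0.10),   # diff 0.45, tumor mean between -> indeterminate
             c(0.95, 0.95, 0.20))   # hyper: diff 0.75, tumor mean 0.95
  colnames(m) <- c("t1", "t2", "n1")
  rt <- make_ratio_table(m, c(t1 = "tumor", t2 = "tumor", n1 = "normal"))
  calls <- call_dmrs(rt)
  expect_equal(as.character(calls$status),
               c("hypo", "not_dmr", "indeterminate", "hyper"))
  expect_equal(calls$diff, c(-0.75, 0.40, 0.45, 0.75))
})

test_that("call_dmrs matches the brute-force rule evaluator CpG for CpG", {
  set.seed(43)
  m <- matrix(runif(1000 * 5), 1000, 5,
              dimnames = list(NULL, c("t1", "t2", "t3", "n1", "n2")))
  groups <- c(t1 = "tumor", t2 = "tumor", t3 = "tumor",
              n1 = "normal", n2 = "normal")
  rt <- make_ratio_table(m, groups)
  calls <- call_dmrs(rt)
  expect_equal(as.character(calls$status), oracle_dmr_status(m, groups))
})

test_that("calls are invariant to sample order within groups and monotone in meth count", {
  set.seed(47)
  m <- matrix(runif(200 * 5), 200, 5,
              dimnames = list(NULL, c("t1", "t2", "t3", "n1", "n2")))
  groups <- c(t1 = "tumor", t2 = "tumor", t3 = "tumor",
              n1 = "normal", n2 = "normal")
  perm <- c("t3", "t1", "t2", "n2", "n1")
  a <- call_dmrs(make_ratio_table(m, groups))
  b <- call_dmrs(make_ratio_table(m[, perm], groups[perm]))
  expect_equal(a, b)
  # ratio monotonicity: more methylated reads at fixed total never lowers the ratio
  totals <- 10L
  r <- (0:totals) / totals
  expect_true(all(diff(r) >= 0))
})

test_that("group and completeness preconditions are enforced", {
  m <- matrix(0.5, 2, 2, dimnames = list(NULL, c("t1", "t2")))
  expect_error(call_dmrs(make_ratio_table(m, c(t1 = "tumor", t2 = "tumor"))),
               "normal")
  m2 <- matrix(c(0.5, NA, 0.4, 0.6), 2, 2,
               dimnames = list(NULL, c("t1", "n1")))
  expect_error(call_dmrs(make_ratio_table(m2, c(t1 = "tumor", n1 = "normal"))),
               "missing")
  expect_warning(
    intersect_cpgs(make_ratio_table(m2[2, , drop = FALSE] * NA,
                                    c(t1 = "tumor", n1 = "normal"))),
    "empty")
})

test_that("DMR tables round-trip through the BED-like format", {
  m <- rbind(c(0.1, 0.9), c(0.5, 0.6))
  colnames(m) <- c("t1", "n1")
  calls <- call_dmrs(make_ratio_table(m, c(t1 = "tumor", n1 = "normal")))
  p <- tempfile(fileext = ".tsv")
  write_dmr_table(calls, p)
  bed <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(bed$start, calls$pos - 1L)   # 0-based half-open on disk only
  back <- read_dmr_table(p)
  expect_equal(back$pos, calls$pos)
  expect_equal(as.character(back$status), as.character(calls$status))
  js <- jsonlite::read_json(sub("\\.tsv$", ".json", p), simplifyVector = TRUE)
  expect_equal(js$n_cpgs, 2L)
})
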