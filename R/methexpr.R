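#' Normalize an FPKM matrix on the log10 scale
#'
#' Computes `v = log10(FPKM + 1)` and centers each gene across samples
#' (`v - mean(v)`), so per-gene normalized values sum to zero. The
#' `"literal"` mode instead returns `mean(v) - v`, the sign-flipped reading
#' of subtracting each value *from* the mean.
#'
#' @param fpkm genes x samples matrix of nonnegative FPKM values.
#' @param mode `"center"` (default) or `"literal"`.
#' @return matrix of the same shape.
#' @export
normalize_fpkm <- function(fpkm, mode = c("center", "literal")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(fpkm))
  if (any(fpkm < 0, na.rm = TRUE)) {
    stop("data error: negative FPKM value", call. = FALSE)
  }
  v <- log10(fpkm + 1)
  centered <- v - rowMeans(v, na.rm = TRUE)
  if (mode == "center") centered else -centered
}

#' Ordinary least-squares fit of expression on methylation
#'
#' Fits `expression = intercept + slope * ratio` by OLS over paired samples
#' and reports the Pearson correlation with a two-sided p-value from the
#' t-distribution with `n - 2` degrees of freedom (identical to the slope
#' test of the linear model).
#'
#' @param ratio per-sample methylation ratios.
#' @param expression per-sample expression values, same order.
#' @param probe_id,gene_id optional identifiers carried into the result.
#' @return object of class `meth_expr_fit`: probe_id, gene_id, slope,
#'   intercept, pearson_r, r_squared, p_value, n.
#' @export
fit_meth_expr <- function(ratio, expression, probe_id = NA_character_,
                          gene_id = NA_character_) {
  ok <- stats::complete.cases(ratio, expression)
  x <- ratio[ok]; y <- expression[ok]
  n <- length(x)
  if (n < 3) stop("insufficient data: need at least 3 paired samples", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate fit: methylation values are all identical", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- stats::cor(x, y)
  r2 <- r * r
  # slope t-test; guard the perfect-fit case where the SE is 0
  if (isTRUE(all.equal(r2, 1))) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(probe_id = probe_id, gene_id = gene_id, slope = slope,
                 intercept = intercept, pearson_r = r, r_squared = r2,
                 p_value = p, n = n),
            class = "meth_expr_fit")
}

#' @export
print.meth_expr_fit <- function(x, ...) {
  cat(sprintf("methylation-expression fit%s%s\n",
              if (!is.na(x$probe_id)) paste0(": ", x$probe_id) else "",
              if (!is.na(x$gene_id)) paste0(" ~ ", x$gene_id) else ""))
  cat(sprintf("  slope %.4g, intercept %.4g, r %.4f (r2 %.4f), p %.3g, n %d\n",
              x$slope, x$intercept, x$pearson_r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
coef.meth_expr_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Fit every linked probe-gene pair
#'
#' One OLS fit per unique (probe, gene) link with complete paired data
#' across the shared samples; links to genes absent from the expression
#' matrix (or probes absent from the ratio matrix) are skipped with a
#' warning. Results are sorted by p-value ascending, ties by probe id.
#'
#' @param links data frame probe_id, gene_id (duplicates collapsed).
#' @param probe_ratios probes x samples matrix of methylation ratios.
#' @param expression genes x samples matrix (normalized expression by
#'   default; any per-gene sample vector works).
#' @return data frame probe_id, gene_id, slope, intercept, pearson_r,
#'   r_squared, p_value, n.
#' @export
batch_correlate <- function(links, probe_ratios, expression) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(links)))
  links <- unique(links[c("probe_id", "gene_id")])
  rows <- vector("list", nrow(links))
  shared <- intersect(colnames(probe_ratios), colnames(expression))
  for (i in seq_len(nrow(links))) {
    pid <- links$probe_id[i]; gid <- links$gene_id[i]
    if (!pid %in% rownames(probe_ratios) || !gid %in% rownames(expression)) {
      warning(sprintf("skipping link %s ~ %s: unknown probe or gene", pid, gid))
      next
    }
    f <- fit_meth_expr(probe_ratios[pid, shared], expression[gid, shared],
                       probe_id = pid, gene_id = gid)
    rows[[i]] <- as.data.frame(unclass(f), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(probe_id = character(), gene_id = character(),
                      slope = numeric(), intercept = numeric(),
                      pearson_r = numeric(), r_squared = numeric(),
                      p_value = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$p_value, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
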