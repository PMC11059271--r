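#' Rank array probes by across-sample variance
#'
#' Probes are ordered by the population variance of their beta values across
#' samples (missing values excluded), descending; ties are broken by probe
#' id so the order is deterministic. This reproduces the common
#' "most variable probes" selection used before embedding methylation-array
#' cohorts.
#'
#' @param beta probes x samples matrix of beta values with probe rownames.
#' @param k how many probes to return (`k <=` number of probes).
#' @return character vector of `k` probe ids, most variable first.
#' @export
top_variable_probes <- function(beta, k) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > nrow(beta)) stop("k exceeds the number of probes", call. = FALSE)
  n_obs <- rowSums(!is.na(beta))
  mu <- rowMeans(beta, na.rm = TRUE)
  v <- rowSums((beta - mu)^2, na.rm = TRUE) / n_obs   # population variance
  ord <- order(-v, rownames(beta))
  rownames(beta)[ord][seq_len(k)]
}

check_classes <- function(beta, classes) {
  stopifnot(is.matrix(beta), !is.null(colnames(beta)))
  if (!all(colnames(beta) %in% names(classes))) {
    stop("every sample needs a class label", call. = FALSE)
  }
  classes[colnames(beta)]
}

# probes x classes matrix of per-class mean betas
class_means <- function(beta, classes) {
  cls <- check_classes(beta, classes)
  lv <- unique(cls)
  if (any(table(cls) == 0)) stop("class with zero samples", call. = FALSE)
  vapply(lv, function(cl) rowMeans(beta[, cls == cl, drop = FALSE], na.rm = TRUE),
         numeric(nrow(beta)))
}

#' Detect tumor-class-specific probes against a reference cohort
#'
#' A probe is specific to the target class when its mean beta in that class
#' differs from the mean of every other class by strictly more than
#' `threshold` (the per-class reading; `mode = "pooled"` instead compares
#' against the pooled mean of all other samples).
#'
#' @param beta probes x samples beta matrix.
#' @param classes named character vector sample -> class.
#' @param target_class class whose specific probes are sought.
#' @param threshold minimum absolute mean difference (strict).
#' @param mode `"per_class"` (default) or `"pooled"`.
#' @return data frame: probe_id, one mean column per class, `min_abs_diff`
#'   (or `pooled_abs_diff`), and logical `specific`.
#' @export
specific_probes <- function(beta, classes, target_class, threshold = 0.4,
                            mode = c("per_class", "pooled")) {
  mode <- match.arg(mode)
  cls <- check_classes(beta, classes)
  if (length(unique(cls)) < 2) stop("at least two classes required", call. = FALSE)
  if (!target_class %in% cls) {
    stop(sprintf("unknown target class '%s'", target_class), call. = FALSE)
  }
  cm <- class_means(beta, classes)
  others <- setdiff(colnames(cm), target_class)
  if (mode == "per_class") {
    diffs <- abs(cm[, others, drop = FALSE] - cm[, target_class])
    crit <- apply(diffs, 1L, min)
  } else {
    pooled <- rowMeans(beta[, cls != target_class, drop = FALSE], na.rm = TRUE)
    crit <- abs(cm[, target_class] - pooled)
  }
  out <- data.frame(probe_id = rownames(beta), cm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out[[if (mode == "per_class") "min_abs_diff" else "pooled_abs_diff"]] <- crit
  out$specific <- crit > threshold
  rownames(out) <- NULL
  out
}

#' Probes with extreme methylation differences against a reference class
#'
#' Keeps probes whose mean beta in the target class differs from the mean in
#' the reference (e.g. normal) class by strictly more than `delta`, sorted
#' by absolute difference descending. With `delta = 0.8` this reproduces the
#' selection of the most extreme tumor-vs-normal probes.
#'
#' @inheritParams specific_probes
#' @param reference_class class the target is compared against.
#' @param delta minimum absolute mean difference (strict).
#' @return data frame probe_id, target_mean, reference_mean, diff
#'   (target - reference), sorted by `abs(diff)` descending.
#' @export
extreme_probes <- function(beta, classes, target_class, reference_class,
                           delta = 0.8) {
  cls <- check_classes(beta, classes)
  for (cl in c(target_class, reference_class)) {
    if (!cl %in% cls) stop(sprintf("class '%s' not present", cl), call. = FALSE)
  }
  tm <- rowMeans(beta[, cls == target_class, drop = FALSE], na.rm = TRUE)
  rm_ <- rowMeans(beta[, cls == reference_class, drop = FALSE], na.rm = TRUE)
  d <- tm - rm_
  keep <- abs(d) > delta
  out <- data.frame(probe_id = rownames(beta)[keep], target_mean = tm[keep],
                    reference_mean = rm_[keep], diff = d[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$diff), out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Embed cohort samples in 2-D with t-SNE on selected probes
#'
#' Runs Barnes-Hut-free (exact, `theta = 0`) t-SNE on the samples using the
#' supplied probe subset, with PCA preprocessing disabled and a fixed seed,
#' so coordinates are reproducible.
#'
#' @param beta probes x samples beta matrix.
#' @param classes named character vector sample -> class.
#' @param probes probe ids to use (e.g. from [top_variable_probes()]);
#'   default all.
#' @param perplexity t-SNE perplexity; requires at least
#'   `3 * perplexity + 1` samples.
#' @param seed integer seed.
#' @return data frame sample, x, y, class.
#' @export
embed_tsne <- function(beta, classes, probes = rownames(beta),
                       perplexity = 30, seed = 1L) {
  cls <- check_classes(beta, classes)
  x <- t(beta[probes, , drop = FALSE])
  n <- nrow(x)
  if (n < 3 * perplexity + 1) {
    stop(sprintf(paste0("too few samples (%d) for perplexity %g; ",
                        "lower the perplexity below %g"),
                 n, perplexity, (n - 1) / 3), call. = FALSE)
  }
  emb <- with_seed(seed,
    Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, theta = 0,
                 pca = FALSE, check_duplicates = FALSE, max_iter = 500,
                 verbose = FALSE))
  data.frame(sample = rownames(x), x = emb$Y[, 1], y = emb$Y[, 2],
             class = unname(cls), stringsAsFactors = FALSE)
}

#' Nearest-centroid class agreement of an embedding
#'
#' Fraction of samples whose nearest class centroid in the 2-D embedding is
#' their own class — a simple separability score for synthetic cohorts.
#' @param embedding output of [embed_tsne()].
#' @return proportion in `[0, 1]`.
#' @export
embedding_class_agreement <- function(embedding) {
  cents <- do.call(rbind, lapply(split(embedding[c("x", "y")], embedding$class),
                                 colMeans))
  d2 <- outer(embedding$x, cents[, "x"], "-")^2 +
        outer(embedding$y, cents[, "y"], "-")^2
  pred <- rownames(cents)[apply(d2, 1L, which.min)]
  mean(pred == embedding$class)
}
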