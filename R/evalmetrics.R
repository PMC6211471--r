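# Caller evaluation statistics: recall / precision / F1 from confusion
# counts, Fisher exact precision comparisons between callers, and
# rank-based operating-characteristic curves.

# round half away from zero (tables print 2 dp with this convention)
round_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion metrics for a fusion caller
#'
#' Recall is the ratio of discovered true positives to the total
#' validated fusions; precision the ratio of true positives to the
#' caller's total candidate count; F1 their harmonic mean
#' (2 * precision * recall / (precision + recall), 0 when both are 0).
#' Full precision is retained; `print` rounds to 2 decimals.
#'
#' @param tp discovered true positives.
#' @param total total candidates reported by the caller.
#' @param validated number of validated fusions.
#' @return An `"eval_result"` list: `tp`, `total`, `validated`, `recall`,
#'   `precision`, `f1` (all `NA` when `total` or `validated` is 0).
#' @export
confusion_metrics <- function(tp, total, validated) {
  stopifnot(tp >= 0, total >= tp, validated >= tp)
  if (total == 0 || validated == 0) {
    recall <- precision <- f1 <- NA_real_
  } else {
    recall <- tp / validated
    precision <- tp / total
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
  }
  structure(list(tp = tp, total = total, validated = validated,
                 recall = recall, precision = precision, f1 = f1),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP %d / total %d / validated %d: recall %.2f, precision %.2f, F1 %.2f\n",
              x$tp, x$total, x$validated,
              round_away(x$recall), round_away(x$precision), round_away(x$f1)))
  invisible(x)
}

#' Fisher exact comparison of two callers' precision
#'
#' Two-sided exact test contrasting one caller's true-positive count
#' against its total discovery count with another's, on the 2x2 table
#' `[[tp1, total1], [tp2, total2]]` (the convention under which the
#' published comparisons of this method reproduce). The two-sided
#' p-value sums hypergeometric probabilities not exceeding that of the
#' observed table.
#'
#' @param tp1,total1 true positives and total candidates of caller 1.
#' @param tp2,total2 same for caller 2.
#' @return Two-sided p-value (1 for an all-zero table).
#' @export
precision_fisher <- function(tp1, total1, tp2, total2) {
  stopifnot(tp1 >= 0, tp2 >= 0, total1 >= tp1, total2 >= tp2)
  m <- matrix(c(tp1, total1, tp2, total2), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

truth_keys <- function(truth, ordered = FALSE) {
  if (is.data.frame(truth)) {
    g5 <- truth$gene5; g3 <- truth$gene3
  } else {
    parts <- strsplit(truth, "[~|]")
    g5 <- vapply(parts, `[`, character(1), 1)
    g3 <- vapply(parts, `[`, character(1), 2)
  }
  unique(if (ordered) paste(g5, g3, sep = "|") else pair_key_unordered(g5, g3))
}

#' Operating-characteristic curve
#'
#' Cumulative count of distinct true fusions among the top-n ranked
#' candidates, for every n. Candidates are ranked by decreasing score
#' (ties: more split-read support when present, then gene ids); in
#' multi-sample mode (a `sample` column) each gene pair is first reduced
#' to its maximum score across samples. Truth matching is unordered by
#' default.
#'
#' @param candidates data.frame with `gene5`, `gene3`, `score`, optional
#'   `sr_support` and `sample`.
#' @param truth data.frame with `gene5`, `gene3` (or pair-key vector).
#' @param ordered match gene-pair direction.
#' @return data.frame with `n_candidates`, `n_true_positives`.
#' @export
oc_curve <- function(candidates, truth, ordered = FALSE) {
  tk <- truth_keys(truth, ordered)
  df <- candidates
  key <- if (ordered) paste(df$gene5, df$gene3, sep = "|") else
    pair_key_unordered(df$gene5, df$gene3)
  df$._key <- key
  if (!is.null(df$sample)) {
    agg <- stats::aggregate(score ~ ._key, df, max)
    sr <- if (!is.null(df$sr_support))
      stats::aggregate(sr_support ~ ._key, df, max) else NULL
    df <- agg
    if (!is.null(sr)) df$sr_support <- sr$sr_support[match(df$._key, sr$._key)]
  } else {
    df <- df[!duplicated(df$._key), , drop = FALSE]
  }
  sr <- if (!is.null(df$sr_support)) df$sr_support else rep(0, nrow(df))
  ord <- order(-df$score, -sr, df$._key)
  df <- df[ord, , drop = FALSE]
  hit <- df$._key %in% tk
  data.frame(n_candidates = seq_len(nrow(df)),
             n_true_positives = cumsum(hit))
}

#' Evaluate calls against a truth set
#'
#' @param calls data.frame with `gene5`, `gene3` (e.g. a
#'   [detect_fusions()] table) or a `"fusion_result"`.
#' @param truth data.frame with `gene5`, `gene3`.
#' @param ordered match gene-pair direction.
#' @return An `"eval_result"` (see [confusion_metrics()]).
#' @export
evaluate_calls <- function(calls, truth, ordered = FALSE) {
  if (inherits(calls, "fusion_result")) calls <- calls$table
  tk <- truth_keys(truth, ordered)
  ck <- unique(if (ordered) paste(calls$gene5, calls$gene3, sep = "|") else
    pair_key_unordered(calls$gene5, calls$gene3))
  confusion_metrics(sum(tk %in% ck), length(ck), length(tk))
}
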