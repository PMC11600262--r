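# Evaluation harness: exact span/triple matching with per-class and pooled
# confusion counts, micro precision/recall/F1, Wilson score intervals, and
# the McNemar paired comparison.

count_matches <- function(gold, pred, keys, class_col) {
  g <- dplyr::count(gold, dplyr::across(dplyr::all_of(keys)), name = "n_gold")
  p <- dplyr::count(pred, dplyr::across(dplyr::all_of(keys)), name = "n_pred")
  j <- dplyr::full_join(g, p, by = keys)
  j$n_gold[is.na(j$n_gold)] <- 0L
  j$n_pred[is.na(j$n_pred)] <- 0L
  j$tp <- pmin(j$n_gold, j$n_pred)             # one-to-one pairing of identical keys
  j$fp <- j$n_pred - j$tp
  j$fn <- j$n_gold - j$tp
  per <- j |>
    dplyr::group_by(class = .data[[class_col]]) |>
    dplyr::summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
                     .groups = "drop")
  pooled <- tibble(class = "Overall", tp = sum(per$tp), fp = sum(per$fp),
                   fn = sum(per$fn))
  out <- dplyr::bind_rows(per, pooled)
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Match predicted entity spans against gold
#'
#' Exact-boundary, exact-label matching with one-to-one pairing; a span
#' with the right boundary but wrong label (or off-by-one boundary) counts
#' as both a false positive and a false negative.
#'
#' @param gold,pred Tibbles of entity spans on the same tokenization
#'   (`sentence`, `start`, `end`, `label`; `doc_id` if present in both is
#'   part of the matching key).
#' @return A `confusion_counts` tibble with per-class rows and a pooled
#'   `Overall` row (micro-averaged counts).
#' @export
match_spans <- function(gold, pred) {
  keys <- c(intersect("doc_id", intersect(names(gold), names(pred))),
            "sentence", "start", "end", "label")
  count_matches(gold, pred, keys, "label")
}

#' Match predicted relation triples against gold
#'
#' A prediction is a true positive iff subject span, predicate and object
#' span all match exactly (direction included); counts are reported per
#' predicate and pooled.
#'
#' @param gold,pred Tibbles of triples in the corpus span layout.
#' @return A `confusion_counts` tibble.
#' @export
match_triples <- function(gold, pred) {
  keys <- c(intersect("doc_id", intersect(names(gold), names(pred))),
            "sentence", "s_start", "s_end", "s_label", "predicate",
            "o_start", "o_end", "o_label")
  count_matches(gold, pred, keys, "predicate")
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = tp/(tp+fp)`, `R = tp/(tp+fn)`, `F1 = 2PR/(P+R)`. A zero denominator
#' yields 0 with a warning (documented convention), and `F1 = 0` when
#' `P = R = 0`.
#'
#' @param counts A `confusion_counts` tibble (or any tibble with `tp`,
#'   `fp`, `fn`).
#' @return The input with `precision`, `recall`, `f1` columns added.
#' @export
precision_recall_f1 <- function(counts) {
  p_den <- counts$tp + counts$fp
  r_den <- counts$tp + counts$fn
  if (any(p_den == 0) || any(r_den == 0)) {
    warn("zero denominator: metric defined as 0", class = "litnet_zero_denominator")
  }
  p <- ifelse(p_den > 0, counts$tp / p_den, 0)
  r <- ifelse(r_den > 0, counts$tp / r_den, 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  dplyr::mutate(counts, precision = p, recall = r, f1 = f1)
}

#' Wilson score confidence interval for a proportion
#'
#' @param k Successes.
#' @param n Trials (>= 1).
#' @param confidence Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)`; always contains `k/n`.
#' @export
wilson_ci <- function(k, n, confidence = 0.95) {
  if (length(n) != 1L || n < 1L) abort("n must be a positive count", class = "litnet_stats")
  if (k < 0 || k > n) abort("k must lie in [0, n]", class = "litnet_stats")
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Paired outcomes for two methods on the same items
#'
#' @param a_correct,b_correct Logical vectors: per-item success of methods
#'   A and B.
#' @return List with discordant counts `b` (A right, B wrong) and `c`
#'   (A wrong, B right) and `n` items.
#' @export
paired_outcomes <- function(a_correct, b_correct) {
  stopifnot(length(a_correct) == length(b_correct))
  list(b = sum(a_correct & !b_correct), c = sum(!a_correct & b_correct),
       n = length(a_correct))
}

#' McNemar paired test
#'
#' Exact binomial version (doubled smaller tail of `Binomial(b + c, 1/2)`,
#' capped at 1) when the discordant count is below `exact_cutoff`;
#' continuity-corrected chi-square otherwise. `b + c = 0` returns p = 1
#' with a warning.
#'
#' @param outcomes A [paired_outcomes()] list, or the discordant count `b`
#'   when `c` is given.
#' @param c_count Discordant count c (A wrong, B right) when `outcomes` is
#'   the scalar `b`.
#' @param exact_cutoff Discordant-pair threshold for the exact/asymptotic
#'   switch (default 25).
#' @return List with `b`, `c`, `p_value` and `method`.
#' @export
mcnemar_test <- function(outcomes, c_count = NULL, exact_cutoff = 25L) {
  if (is.list(outcomes)) {
    b <- outcomes$b; cc <- outcomes$c
  } else {
    b <- outcomes; cc <- c_count
  }
  stopifnot(b >= 0, cc >= 0)
  nd <- b + cc
  if (nd == 0L) {
    warn("no discordant pairs: p = 1 by convention", class = "litnet_no_discordant")
    return(list(b = b, c = cc, p_value = 1, method = "degenerate"))
  }
  if (nd < exact_cutoff) {
    p <- min(1, 2 * pbinom(min(b, cc), nd, 0.5))
    list(b = b, c = cc, p_value = p, method = "exact binomial")
  } else {
    stat <- (abs(b - cc) - 1)^2 / nd
    list(b = b, c = cc, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "continuity-corrected chi-square")
  }
}

#' Evaluate predicted annotations against gold
#'
#' Builds the full report for one evaluation level: per-class and pooled
#' precision/recall/F1 with Wilson 95% intervals and the raw counts.
#'
#' @param gold,pred Span tibbles (`level = "entity"`) or triple tibbles
#'   (`level = "relation"`), as produced by [corpus_entities()] /
#'   [predict_entities()] and [corpus_triples()] /
#'   [integrate_predictions()].
#' @param level `"entity"` or `"relation"`.
#' @param confidence Interval confidence level.
#' @return A `litnet_eval` tibble: class, counts, metrics and interval
#'   bounds.
#' @export
evaluate_extraction <- function(gold, pred, level = c("entity", "relation"),
                                confidence = 0.95) {
  level <- match.arg(level)
  counts <- if (level == "entity") match_spans(gold, pred) else match_triples(gold, pred)
  res <- suppressWarnings(precision_recall_f1(counts))
  ci <- purrr::pmap(res, function(tp, fp, fn, ...) {
    pl <- if (tp + fp > 0) wilson_ci(tp, tp + fp, confidence) else c(lower = NA, upper = NA)
    rl <- if (tp + fn > 0) wilson_ci(tp, tp + fn, confidence) else c(lower = NA, upper = NA)
    tibble(precision_lower = pl[["lower"]], precision_upper = pl[["upper"]],
           recall_lower = rl[["lower"]], recall_upper = rl[["upper"]])
  })
  out <- dplyr::bind_cols(res, dplyr::bind_rows(ci))
  out <- dplyr::mutate(out, level = level, .before = 1)
  class(out) <- c("litnet_eval", class(tibble()))
  out
}

#' @method tidy litnet_eval
#' @export
tidy.litnet_eval <- function(x, ...) {
  as_tibble(x)
}

#' @method glance litnet_eval
#' @export
glance.litnet_eval <- function(x, ...) {
  ov <- x[x$class == "Overall", , drop = FALSE]
  tibble(level = ov$level, precision = ov$precision, recall = ov$recall,
         f1 = ov$f1, tp = ov$tp, fp = ov$fp, fn = ov$fn)
}

#' @method autoplot litnet_eval
#' @export
autoplot.litnet_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s-level evaluation", object$level[1])) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report as JSON
#'
#' Mirrors the per-class / overall table layout: each class carries
#' precision, recall and F1 with `n/N` counts and 95% intervals.
#'
#' @param eval_result A `litnet_eval`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval_result, path) {
  rows <- purrr::pmap(eval_result, function(level, class, tp, fp, fn, precision,
                                            recall, f1, precision_lower,
                                            precision_upper, recall_lower,
                                            recall_upper, ...) {
    list(class = class,
         precision = list(value = precision, n = tp, N = tp + fp,
                          ci95 = c(precision_lower, precision_upper)),
         recall = list(value = recall, n = tp, N = tp + fn,
                       ci95 = c(recall_lower, recall_upper)),
         f1 = f1)
  })
  obj <- list(level = eval_result$level[1], classes = rows)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
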