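# Expression-based edge confidence: Pearson correlation between edge
# endpoints over an expression matrix, and median-split rank-sum tests for
# directional support.

new_expression_matrix <- function(values) {
  if (anyDuplicated(rownames(values))) {
    abort("duplicate gene symbols in expression matrix", class = "litnet_expr")
  }
  if (!all(is.finite(values))) {
    abort("expression matrix contains non-finite values", class = "litnet_expr")
  }
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values), class = "expression_matrix")
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Dialect: first column gene symbol, header row of sample ids, tab
#' separated. Values are taken as already normalized (e.g. log2); no
#' transformation is applied.
#'
#' @param path TSV file path.
#' @return An `expression_matrix`: list with `genes`, `samples` and the
#'   numeric `values` matrix (genes x samples).
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  new_expression_matrix(m)
}

#' @rdname read_expression_tsv
#' @param expr An `expression_matrix`.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix: %d genes x %d samples>\n",
              length(x$genes), length(x$samples)))
  invisible(x)
}

#' Pearson correlation between two expression profiles
#'
#' Product-moment correlation with the degenerate cases rejected rather
#' than silently returning `NA`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("need equal-length vectors with n >= 3", class = "litnet_stats")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("non-finite values", class = "litnet_stats")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("zero variance: correlation undefined", class = "litnet_zero_variance")
  }
  cor(x, y, method = "pearson")
}

mann_whitney_u <- function(high, low) {
  # U for the high group, with 0.5 per tie
  sum(vapply(high, function(h) sum(h > low) + 0.5 * sum(h == low), numeric(1)))
}

#' Median-split rank-sum test
#'
#' Samples are partitioned at the split gene's median expression (values
#' equal to the median go to the low group), then the test gene's values in
#' the two groups are compared with a Mann-Whitney U test. The p-value is
#' exact — by enumeration of all group assignments of the observed values,
#' which also handles ties — when the combined n is at most `exact_max`;
#' otherwise the normal approximation with tie correction is used. The
#' two-sided exact p is the permutation probability of a U at least as far
#' from its null mean `n1*n2/2` as observed.
#'
#' @param expr An `expression_matrix`.
#' @param split_gene Gene whose median defines the high/low groups.
#' @param test_gene Gene whose expression is compared between groups.
#' @param exact_max Largest combined n for which the exact enumeration is
#'   used (default 20).
#' @return List with `u` (U statistic of the high group), `p_value`,
#'   `n_high`, `n_low` and `method`.
#' @export
median_split_ranksum <- function(expr, split_gene, test_gene, exact_max = 20L) {
  for (g in c(split_gene, test_gene)) {
    if (!g %in% expr$genes) {
      abort(paste0("gene not in expression matrix: ", g), class = "litnet_stats")
    }
  }
  sv <- expr$values[split_gene, ]
  tv <- expr$values[test_gene, ]
  high <- sv > median(sv)              # ties at the median go to the low group
  n1 <- sum(high); n2 <- sum(!high)
  if (n1 < 2L || n2 < 2L) {
    abort("degenerate group after median split (need >= 2 per group)",
          class = "litnet_degenerate")
  }
  u <- mann_whitney_u(tv[high], tv[!high])
  n <- n1 + n2
  if (n <= exact_max) {
    picks <- combn(n, n1)
    mu <- n1 * n2 / 2
    us <- apply(picks, 2, function(ix) mann_whitney_u(tv[ix], tv[-ix]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    list(u = u, p_value = p, n_high = n1, n_low = n2, method = "exact")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(tv[high], tv[!high],
                                              exact = FALSE, correct = TRUE))
    list(u = u, p_value = wt$p.value, n_high = n1, n_low = n2,
         method = "normal approximation with tie correction")
  }
}

#' Annotate graph edges with expression-based confidence
#'
#' Every regulatory (Promotes/Inhibits/Upstream) edge whose two endpoints
#' are both present in the expression matrix gains the Pearson correlation
#' `r` between the endpoint profiles and a qualitative band on `|r|`
#' (`weak < 0.3 <= moderate < 0.6 <= strong` by default). Edges without
#' expression data — and non-regulatory edges — are marked `"no-data"`.
#'
#' @param graph A `regulatory_graph` with normalized gene nodes.
#' @param expr An `expression_matrix`.
#' @param thresholds Band cut points `c(weak, strong)` on `|r|`.
#' @return The graph with `r` and `confidence` columns on its edges and an
#'   `annotated` flag set.
#' @export
attach_confidence <- function(graph, expr, thresholds = c(weak = 0.3, strong = 0.6)) {
  stopifnot(inherits(graph, "regulatory_graph"))
  edges <- graph$edges
  r <- rep(NA_real_, nrow(edges))
  band <- rep("no-data", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    if (!edges$predicate[i] %in% REGULATORY_PREDICATES) next
    a <- edges$subject[i]; b <- edges$object[i]
    if (a %in% expr$genes && b %in% expr$genes) {
      ri <- tryCatch(pearson_r(expr$values[a, ], expr$values[b, ]),
                     litnet_zero_variance = function(e) NA_real_)
      r[i] <- ri
      if (!is.na(ri)) {
        band[i] <- if (abs(ri) < thresholds[["weak"]]) "weak"
        else if (abs(ri) < thresholds[["strong"]]) "moderate"
        else "strong"
      }
    }
  }
  graph$edges$r <- r
  graph$edges$confidence <- band
  graph$annotated <- TRUE
  graph
}
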