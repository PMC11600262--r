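expr_fixture <- function(values) {
  # values: named list gene -> numeric vector
  m <- do.call(rbind, values)
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  df <- data.frame(gene = names(values), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_expression_tsv(path)
}

test_that("pearson_r evaluates the product-moment formula", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, c(3, 2, 1)), -1)
  expect_equal(pearson_r(x, c(1, 3, 2)), 0.5)

  # independent oracle: explicit formula
  set.seed(51)
  for (rep in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    hand <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_r(a, b), hand, tolerance = 1e-12)
    # symmetry and positive-affine invariance
    expect_equal(pearson_r(a, b), pearson_r(b, a))
    expect_equal(pearson_r(2.5 * a + 1, b), pearson_r(a, b), tolerance = 1e-12)
  }

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), class = "litnet_zero_variance")
  expect_error(pearson_r(1:2, 1:2), class = "litnet_stats")
})

test_that("median-split rank-sum matches its enumeration example and symmetry", {
  # split gene separates samples into (1,2) vs (3,4) on the test gene:
  # U = 0 and the exact two-sided p over the 6 equal-size assignments is 1/3
  ex <- expr_fixture(list(SPLIT = c(5, 6, 1, 2), TEST = c(1, 2, 3, 4)))
  res <- median_split_ranksum(ex, "SPLIT", "TEST")
  expect_equal(res$u, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$method, "exact")

  # constant test gene: no separation, p = 1
  cst <- expr_fixture(list(SPLIT = c(5, 6, 1, 2), TEST = c(2, 2, 2, 2)))
  expect_equal(median_split_ranksum(cst, "SPLIT", "TEST")$p_value, 1)

  # swapping the group labels leaves the two-sided p unchanged
  swapped <- expr_fixture(list(SPLIT = c(1, 2, 5, 6), TEST = c(1, 2, 3, 4)))
  expect_equal(median_split_ranksum(swapped, "SPLIT", "TEST")$p_value,
               res$p_value)

  expect_error(median_split_ranksum(ex, "SPLIT", "NOPE"), class = "litnet_stats")
  # ties at the median go low: a degenerate high group errors
  deg <- expr_fixture(list(SPLIT = c(1, 1, 1, 9), TEST = c(1, 2, 3, 4)))
  expect_error(median_split_ranksum(deg, "SPLIT", "TEST"),
               class = "litnet_degenerate")
})

test_that("exact rank-sum p matches wilcox.test's exact distribution without ties", {
  set.seed(52)
  for (rep in 1:15) {
    n <- sample(6:10, 1)
    sv <- sample(seq(1, 50), n)              # distinct: clean median split
    tv <- sample(seq(51, 150), n)            # distinct: no ties in the test gene
    ex <- expr_fixture(list(SP = sv, TS = tv))
    res <- tryCatch(median_split_ranksum(ex, "SP", "TS"),
                    litnet_degenerate = function(e) NULL)
    if (is.null(res)) next
    high <- sv > median(sv)
    wt <- stats::wilcox.test(tv[high], tv[!high], exact = TRUE)
    expect_equal(res$u, unname(wt$statistic))
    expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(53)
  sv <- rnorm(30); tv <- sample(rep(1:10, 3))
  ex <- expr_fixture(list(SP = sv, TS = tv))
  res <- median_split_ranksum(ex, "SP", "TS")
  high <- sv > median(sv)
  wt <- suppressWarnings(stats::wilcox.test(tv[high], tv[!high], exact = FALSE,
                                            correct = TRUE))
  expect_equal(res$p_value, wt$p.value)
  expect_match(res$method, "normal")
})

test_that("attach_confidence annotates regulatory edges and flags missing data", {
  syn <- synonym_table(tibble::tibble(Symbol = c("WNT4", "STAT3"),
                                      Synonyms = c("", "")))
  triples <- dplyr::bind_rows(
    tibble::tibble(doc_id = "P1", year = 2015L, sentence = 0L,
                   s_start = 0L, s_end = 1L, s_label = "Gene", s_surface = "WNT4",
                   predicate = "Promotes",
                   o_start = 2L, o_end = 3L, o_label = "Gene", o_surface = "STAT3"),
    tibble::tibble(doc_id = "P2", year = 2016L, sentence = 0L,
                   s_start = 0L, s_end = 1L, s_label = "Gene", s_surface = "STAT3",
                   predicate = "Function",
                   o_start = 2L, o_end = 4L, o_label = "BiologicalFunction",
                   o_surface = "cell migration"),
    tibble::tibble(doc_id = "P3", year = 2017L, sentence = 0L,
                   s_start = 0L, s_end = 1L, s_label = "Gene", s_surface = "WNT4",
                   predicate = "Inhibits",
                   o_start = 2L, o_end = 3L, o_label = "Gene", o_surface = "MISSING9"))
  g <- build_graph(triples, syn)
  set.seed(54)
  z <- rnorm(20)
  ex <- expr_fixture(list(WNT4 = z + rnorm(20, sd = 0.3),
                          STAT3 = z + rnorm(20, sd = 0.3)))
  ann <- attach_confidence(g, ex)
  expect_true(ann$annotated)
  ed <- ann$edges
  reg <- ed[ed$predicate == "Promotes", ]
  expect_false(is.na(reg$r))
  expect_true(reg$confidence %in% c("weak", "moderate", "strong"))
  expect_equal(ed$confidence[ed$predicate == "Function"], "no-data")
  expect_equal(ed$confidence[ed$object == "missing9"], "no-data")

  # a graph with no regulatory edges passes through annotated but unchanged
  gf <- filter_graph(g, predicates = "Function")
  annf <- attach_confidence(gf, ex)
  expect_true(all(annf$edges$confidence == "no-data"))
})

test_that("sample correlations recover a planted correlation at n = 50", {
  cfg <- generator_config(seed = 77, n_genes = 5)
  for (rho in c(0, 0.5, 0.9)) {
    R <- diag(5)
    dimnames(R) <- list(c("WNT4", "STAT3", "IGF2", "GENA1", "GENA2"),
                        c("WNT4", "STAT3", "IGF2", "GENA1", "GENA2"))
    R["WNT4", "STAT3"] <- R["STAT3", "WNT4"] <- rho
    rs <- vapply(1:40, function(i) {
      c2 <- generator_config(seed = 77 + i, n_genes = 5, planted = R)
      ex <- generate_expression(c2, n_samples = 50)
      pearson_r(ex$values["WNT4", ], ex$values["STAT3", ])
    }, numeric(1))
    expect_lt(abs(mean(rs) - rho), 0.05)
  }
})
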