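span_row <- function(doc, s, a, b, lab) {
  tibble::tibble(doc_id = doc, sentence = s, start = a, end = b, label = lab)
}

test_that("span matching is exact-boundary, exact-label, one-to-one", {
  gold <- dplyr::bind_rows(span_row("D1", 0L, 0L, 1L, "Gene"),
                           span_row("D1", 0L, 4L, 6L, "Cancer"))
  same <- match_spans(gold, gold)
  ov <- same[same$class == "Overall", ]
  expect_equal(ov$tp, 2L); expect_equal(ov$fp, 0L); expect_equal(ov$fn, 0L)

  # boundary off by one token: fp + fn
  off <- dplyr::bind_rows(span_row("D1", 0L, 0L, 2L, "Gene"),
                          span_row("D1", 0L, 4L, 6L, "Cancer"))
  co <- match_spans(gold, off)
  ovo <- co[co$class == "Overall", ]
  expect_equal(ovo$tp, 1L); expect_equal(ovo$fp, 1L); expect_equal(ovo$fn, 1L)

  # right boundary, wrong label: fp + fn
  wl <- dplyr::bind_rows(span_row("D1", 0L, 0L, 1L, "Cancer"),
                         span_row("D1", 0L, 4L, 6L, "Cancer"))
  cw <- match_spans(gold, wl)
  ovw <- cw[cw$class == "Overall", ]
  expect_equal(ovw$tp, 1L); expect_equal(ovw$fp, 1L); expect_equal(ovw$fn, 1L)
})

test_that("triple matching is directed and predicate-sensitive", {
  corpus <- fixture_corpus(fixture_docs())
  gold <- corpus_triples(corpus)
  same <- match_triples(gold, gold)
  expect_equal(same$fp, rep(0L, nrow(same)))
  expect_equal(same$fn, rep(0L, nrow(same)))

  # reversed direction: fp + fn
  rev1 <- gold
  rev1[1, c("s_start", "s_end", "s_label", "s_surface",
            "o_start", "o_end", "o_label", "o_surface")] <-
    gold[1, c("o_start", "o_end", "o_label", "o_surface",
              "s_start", "s_end", "s_label", "s_surface")]
  cr <- match_triples(gold, rev1)
  ov <- cr[cr$class == "Overall", ]
  expect_equal(ov$tp, nrow(gold) - 1L)
  expect_equal(ov$fp, 1L); expect_equal(ov$fn, 1L)

  # right pair, wrong predicate
  wp <- gold
  wp$predicate[1] <- ifelse(gold$predicate[1] == "Promotes", "Inhibits", "Promotes")
  cp <- match_triples(gold, wp)
  ovp <- cp[cp$class == "Overall", ]
  expect_equal(ovp$fp, 1L); expect_equal(ovp$fn, 1L)
})

test_that("matching counts are conserved", {
  set.seed(61)
  for (rep in 1:20) {
    gold <- dplyr::bind_rows(lapply(1:sample(3:10, 1), function(i) {
      span_row("D1", sample(0:2, 1), i * 3L, i * 3L + sample(1:2, 1),
               sample(entity_labels(), 1))
    }))
    pred <- dplyr::bind_rows(lapply(1:sample(3:10, 1), function(i) {
      span_row("D1", sample(0:2, 1), i * 3L, i * 3L + sample(1:2, 1),
               sample(entity_labels(), 1))
    }))
    cc <- match_spans(gold, pred)
    ov <- cc[cc$class == "Overall", ]
    expect_equal(ov$tp + ov$fp, nrow(pred))
    expect_equal(ov$tp + ov$fn, nrow(gold))
    expect_lte(ov$tp, min(nrow(gold), nrow(pred)))
  }
})

test_that("precision/recall/F1 reproduce the published confusion fractions", {
  # overall NER row: 4835 true positives of 5131 predicted / 4948 gold
  counts <- tibble::tibble(class = "Overall", tp = 4835L, fp = 296L, fn = 113L)
  m <- precision_recall_f1(counts)
  expect_equal(round(100 * m$precision, 2), 94.23)
  expect_equal(round(100 * m$recall, 2), 97.72)
  expect_equal(round(100 * m$f1, 2), 95.94)

  # gene row: 2582/2682 and 2582/2619 give F1 97.42
  gene <- precision_recall_f1(tibble::tibble(class = "Gene", tp = 2582L,
                                             fp = 100L, fn = 37L))
  expect_equal(round(100 * gene$f1, 2), 97.42)

  # harmonic-mean identity and the zero conventions
  eq <- precision_recall_f1(tibble::tibble(class = "x", tp = 10L, fp = 5L, fn = 5L))
  expect_equal(eq$f1, eq$precision)
  expect_warning(
    z <- precision_recall_f1(tibble::tibble(class = "x", tp = 0L, fp = 0L, fn = 0L)),
    class = "litnet_zero_denominator")
  expect_equal(z$f1, 0)
})

test_that("min(P, R) <= F1 <= max(P, R)", {
  set.seed(62)
  for (rep in 1:30) {
    cc <- tibble::tibble(class = "x", tp = sample(1:50, 1), fp = sample(0:30, 1),
                         fn = sample(0:30, 1))
    m <- precision_recall_f1(cc)
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("wilson_ci reproduces the published intervals and matches prop.test", {
  expect_equal(round(wilson_ci(4835, 5131), 4),
               c(lower = 0.9356, upper = 0.9484))
  expect_equal(round(wilson_ci(2593, 2830), 4),
               c(lower = 0.9055, upper = 0.9259))
  expect_equal(wilson_ci(0, 10)[["lower"]], 0)

  # independent oracle: prop.test without continuity correction is Wilson
  set.seed(63)
  for (rep in 1:20) {
    n <- sample(5:500, 1); k <- sample(0:n, 1)
    pt <- stats::prop.test(k, n, correct = FALSE)$conf.int
    w <- wilson_ci(k, n)
    expect_equal(unname(w), as.numeric(pt), tolerance = 1e-10)
    expect_gte(k / n, w[["lower"]]); expect_lte(k / n, w[["upper"]])
  }

  # width shrinks in n at fixed k/n
  widths <- vapply(c(50, 100, 400, 1600), function(n) {
    diff(wilson_ci(round(0.8 * n), n))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  expect_error(wilson_ci(3, 0), class = "litnet_stats")
  expect_error(wilson_ci(5, 3), class = "litnet_stats")
})

test_that("McNemar exact p is the doubled binomial tail; asymptotic matches stats", {
  expect_equal(mcnemar_test(8, 2)$p_value, 0.109375)
  expect_equal(mcnemar_test(5, 5)$p_value, 1)
  expect_equal(mcnemar_test(1, 0)$p_value, 1)
  expect_warning(p0 <- mcnemar_test(0, 0), class = "litnet_no_discordant")
  expect_equal(p0$p_value, 1)

  # full-enumeration oracle for b + c <= 12
  for (n in 1:12) {
    for (b in 0:n) {
      got <- mcnemar_test(b, n - b, exact_cutoff = 25L)$p_value
      probs <- dbinom(0:n, n, 0.5)
      want <- min(1, 2 * sum(probs[0:n <= min(b, n - b)]))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }

  # asymptotic branch equals the continuity-corrected chi-square test
  res <- mcnemar_test(40, 18, exact_cutoff = 25L)
  ref <- stats::mcnemar.test(matrix(c(10, 18, 40, 10), 2, 2), correct = TRUE)
  expect_equal(res$p_value, unname(ref$p.value))

  # paired outcome bookkeeping
  po <- paired_outcomes(c(TRUE, TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(po$b, 2L); expect_equal(po$c, 1L)
})

test_that("evaluation reports mirror the per-class table layout", {
  corpus <- fixture_corpus(fixture_docs())
  gold <- corpus_entities(corpus)
  pred <- gold[-1, ]                        # one miss
  ev <- evaluate_extraction(gold, pred, "entity")
  expect_s3_class(ev, "litnet_eval")
  expect_true("Overall" %in% ev$class)
  ov <- ev[ev$class == "Overall", ]
  expect_equal(ov$tp, nrow(gold) - 1L)
  expect_equal(ov$fn, 1L)
  expect_true(all(ev$precision_lower <= ev$precision + 1e-12, na.rm = TRUE))
  expect_equal(glance(ev)$f1, ov$f1)
  expect_s3_class(autoplot(ev), "ggplot")

  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(ev, path)
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(rep$level, "entity")
  classes <- vapply(rep$classes, `[[`, character(1), "class")
  expect_true("Overall" %in% classes)
  ovj <- rep$classes[[which(classes == "Overall")]]
  expect_equal(ovj$precision$N, ov$tp + ov$fp)
})
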