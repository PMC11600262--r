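fixture_synonyms <- function() {
  synonym_table(tibble::tibble(
    Symbol = c("WNT4", "STAT3", "IGF2", "GENX1", "GENX2"),
    Synonyms = c("WNT-4|Wnt4", "STAT-3|Stat3", "IGF-II|Igf2", "", "")))
}

triple_row <- function(doc_id, year, s, pred, o, sentence = 0L,
                       s_label = "Gene", o_label = "Gene") {
  tibble::tibble(doc_id = doc_id, year = year, sentence = sentence,
                 s_start = 0L, s_end = 1L, s_label = s_label, s_surface = s,
                 predicate = pred,
                 o_start = 2L, o_end = 3L, o_label = o_label, o_surface = o)
}

test_that("alias normalization maps through the synonym table", {
  syn <- fixture_synonyms()
  expect_equal(normalize_surface("Wnt-4", "Gene", syn), "WNT4")
  expect_equal(normalize_surface("WNT4", "Gene", syn), "WNT4")
  expect_equal(normalize_surface("cell  migration", "BiologicalFunction", syn),
               "cell migration")
  # unknown gene surfaces fall back to the folded surface
  expect_equal(normalize_surface("NOVL1", "Gene", syn), "novl1")

  # ambiguous aliases stay unresolved, with a warning
  expect_warning(
    amb <- synonym_table(tibble::tibble(Symbol = c("A1", "B1"),
                                        Synonyms = c("shared", "shared"))),
    class = "litnet_ambiguous_alias")
  expect_equal(normalize_surface("shared", "Gene", amb), "shared")
  expect_equal(normalize_surface("A1", "Gene", amb), "A1")
})

test_that("aggregation merges normalized mentions and counts support", {
  syn <- fixture_synonyms()
  triples <- dplyr::bind_rows(
    triple_row("P1", 2015L, "Wnt-4", "Promotes", "IGF-II"),
    triple_row("P2", 2020L, "WNT4", "Promotes", "IGF2"))
  g <- build_graph(triples, syn)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 2L)
  expect_equal(g$edges$subject, "WNT4")
  expect_equal(g$edges$object, "IGF2")
  expect_equal(nrow(g$edges$provenance[[1]]), 2L)

  empty <- build_graph(NULL, syn)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(empty$nodes), 0L)
})

test_that("aggregation is order-invariant and conserves triple counts", {
  syn <- fixture_synonyms()
  set.seed(41)
  surfaces <- c("WNT4", "Wnt-4", "STAT3", "Stat3", "IGF2", "GENX1", "GENX2")
  triples <- dplyr::bind_rows(lapply(1:30, function(i) {
    s <- sample(surfaces, 1); o <- sample(setdiff(surfaces, s), 1)
    triple_row(sprintf("P%d", sample(1:6, 1)), sample(2010:2020, 1),
               s, sample(c("Promotes", "Inhibits", "Upstream", "Function"), 1), o,
               sentence = sample(0:2, 1))
  }))
  g1 <- suppressWarnings(build_graph(triples, syn))
  g2 <- suppressWarnings(build_graph(triples[sample(nrow(triples)), ], syn))
  expect_equal(g1$edges, g2$edges)
  expect_equal(g1$nodes, g2$nodes)

  # conservation: total weight = number of distinct non-self-loop
  # normalized (doc, sentence, triple) facts
  norm <- triples
  norm$s <- normalize_surface(norm$s_surface, norm$s_label, syn)
  norm$o <- normalize_surface(norm$o_surface, norm$o_label, syn)
  norm <- dplyr::distinct(norm[norm$s != norm$o, ],
                          s, predicate, o, doc_id, sentence)
  expect_equal(sum(g1$edges$weight), nrow(norm))
})

test_that("same-sentence duplicates count once; self-loops are dropped", {
  syn <- fixture_synonyms()
  dup <- dplyr::bind_rows(
    triple_row("P1", 2015L, "WNT4", "Promotes", "IGF2"),
    triple_row("P1", 2015L, "WNT4", "Promotes", "IGF2"))
  g <- build_graph(dup, syn)
  expect_equal(g$edges$weight, 1L)

  loop <- triple_row("P1", 2015L, "WNT4", "Promotes", "Wnt-4")
  expect_warning(g2 <- build_graph(loop, syn), class = "litnet_self_loop")
  expect_equal(nrow(g2$edges), 0L)
})

test_that("abbreviation triples extend the synonym scope instead of adding edges", {
  syn <- fixture_synonyms()
  triples <- dplyr::bind_rows(
    triple_row("P1", 2015L, "GENX9", "Abbreviation", "gx9"),
    triple_row("P2", 2016L, "GENX9", "Promotes", "IGF2"),
    triple_row("P3", 2017L, "gx9", "Promotes", "IGF2"))
  g <- build_graph(triples, syn)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 2L)          # both mentions merged via the abbreviation
  expect_false("Abbreviation" %in% g$edges$predicate)
})

test_that("filters compose, prune orphans, and leave the input unmodified", {
  syn <- fixture_synonyms()
  triples <- dplyr::bind_rows(
    triple_row("P1", 2012L, "WNT4", "Promotes", "STAT3"),
    triple_row("P2", 2016L, "WNT4", "Promotes", "STAT3"),
    triple_row("P3", 2018L, "STAT3", "Inhibits", "IGF2"),
    triple_row("P4", 2022L, "IGF2", "Upstream", "GENX1"))
  g <- build_graph(triples, syn)
  before <- g$edges

  expect_equal(filter_graph(g)$edges, g$edges)   # no active filter: identity

  byw <- filter_graph(g, min_weight = 2)
  expect_equal(byw$edges$subject, "WNT4")
  expect_true(all(byw$nodes$id %in% c("WNT4", "STAT3")))

  byp <- filter_graph(g, predicates = "Promotes")
  expect_true(all(byp$edges$predicate == "Promotes"))

  byy <- filter_graph(g, year_range = c(2015, 2020))
  expect_setequal(byy$edges$predicate, c("Promotes", "Inhibits"))

  # composition is order-independent
  ab <- filter_graph(filter_graph(g, predicates = c("Promotes", "Inhibits")),
                     year_range = c(2015, 2020))
  ba <- filter_graph(filter_graph(g, year_range = c(2015, 2020)),
                     predicates = c("Promotes", "Inhibits"))
  expect_equal(ab$edges, ba$edges)

  # edges lacking a provenance year pass year filters
  noyr <- triple_row("P9", NA_integer_, "WNT4", "Inhibits", "GENX1")
  gny <- build_graph(noyr, syn)
  expect_equal(nrow(filter_graph(gny, year_range = c(1990, 1991))$edges), 1L)

  expect_identical(g$edges, before)
})

test_that("intermediary search ranks the strongest short path first", {
  syn <- fixture_synonyms()
  triples <- dplyr::bind_rows(
    triple_row("P1", 2015L, "WNT4", "Promotes", "STAT3"),
    triple_row("P2", 2016L, "WNT4", "Promotes", "STAT3"),
    triple_row("P3", 2016L, "WNT4", "Promotes", "STAT3"),
    triple_row("P4", 2017L, "STAT3", "Promotes", "IGF2"),
    triple_row("P5", 2018L, "STAT3", "Promotes", "IGF2"),
    triple_row("P6", 2018L, "STAT3", "Inhibits", "IGF2"),
    triple_row("P7", 2018L, "WNT4", "Promotes", "GENX1"),
    triple_row("P8", 2019L, "GENX1", "Promotes", "GENX2"),
    triple_row("P9", 2019L, "GENX2", "Promotes", "IGF2"))
  g <- build_graph(triples, syn)
  res <- find_intermediaries(g, "WNT4", "IGF2", max_len = 3)
  expect_gt(nrow(res), 1L)
  expect_equal(res$intermediaries[[1]], "STAT3")
  expect_equal(res$path[[1]], c("WNT4", "STAT3", "IGF2"))
  expect_true(all(diff(res$length) >= 0))

  # a direct edge ranks first as a length-1 path with no intermediaries
  direct <- dplyr::bind_rows(triples, triple_row("PA", 2020L, "WNT4", "Promotes", "IGF2"))
  gd <- build_graph(direct, syn)
  rd <- find_intermediaries(gd, "WNT4", "IGF2", max_len = 3)
  expect_equal(rd$length[1], 1L)
  expect_equal(length(rd$intermediaries[[1]]), 0L)

  expect_error(find_intermediaries(g, "WNT4", "NOPE"), class = "litnet_missing_node")
  # unreachable target: empty result, not an error
  g2 <- build_graph(dplyr::bind_rows(
    triple_row("P1", 2015L, "WNT4", "Promotes", "STAT3"),
    triple_row("P2", 2016L, "GENX1", "Promotes", "IGF2")), syn)
  expect_equal(nrow(find_intermediaries(g2, "STAT3", "GENX1", 3)), 0L)
})

test_that("path enumeration agrees with igraph's all_simple_paths on random graphs", {
  syn <- synonym_table(tibble::tibble(Symbol = character(0), Synonyms = character(0)))
  set.seed(42)
  for (rep in 1:15) {
    n_nodes <- sample(5:12, 1)
    nodes <- paste0("n", seq_len(n_nodes))
    k <- sample(6:18, 1)
    triples <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      s <- sample(nodes, 1); o <- sample(setdiff(nodes, s), 1)
      triple_row(sprintf("D%d", i), 2020L, s, "Promotes", o)
    }))
    g <- build_graph(triples, syn)
    src <- sample(g$nodes$id, 1); tgt <- sample(setdiff(g$nodes$id, src), 1)
    max_len <- sample(2:4, 1)
    got <- find_intermediaries(g, src, tgt, max_len)
    ig <- as_igraph(g)
    want <- igraph::all_simple_paths(ig, from = src, to = tgt, mode = "out",
                                     cutoff = max_len)
    want_keys <- sort(vapply(want, function(p) paste(names(p), collapse = ">"),
                             character(1)))
    got_keys <- sort(vapply(got$path, paste, character(1), collapse = ">"))
    expect_equal(got_keys, unique(want_keys))
  }
})

test_that("graph exports round trip and produce parseable files", {
  syn <- fixture_synonyms()
  triples <- dplyr::bind_rows(
    triple_row("P1", 2015L, "WNT4", "Promotes", "STAT3"),
    triple_row("P2", 2018L, "STAT3", "Inhibits", "IGF2"))
  g <- build_graph(triples, syn)

  json_path <- withr::local_tempfile(fileext = ".json")
  graph_to_node_link(g, json_path)
  back <- read_graph_node_link(json_path)
  expect_equal(back$nodes, g$nodes)
  expect_equal(back$edges$weight, g$edges$weight)
  expect_equal(back$edges$provenance, g$edges$provenance)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graph_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), nrow(g$nodes))
  expect_equal(igraph::gsize(ig), nrow(g$edges))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_graph_edge_tsv(g, tsv)
  ed <- utils::read.delim(tsv)
  expect_equal(nrow(ed), 2L)

  # broom-style accessors
  expect_equal(nrow(tidy(g)), 2L)
  expect_equal(glance(g)$n_edges, 2L)
  expect_s3_class(autoplot(g), "ggplot")
})

test_that("synonym tables load from gene_info-style TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Symbol\tSynonyms", "WNT4\tWNT-4|Wnt4", "STAT3\t-"), path)
  syn <- read_synonym_table(path)
  expect_equal(normalize_surface("wnt-4", "Gene", syn), "WNT4")
  expect_equal(normalize_surface("STAT3", "Gene", syn), "STAT3")
})
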