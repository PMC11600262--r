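# Shared fixtures and independent oracles for the test suite.

# Build a tiny annotated corpus in memory by writing JSONL and reading it
# back through the package's own loader (so fixtures exercise the schema).
fixture_corpus <- function(docs) {
  path <- withr::local_tempfile(fileext = ".jsonl", .local_envir = parent.frame())
  writeLines(vapply(docs, function(d) {
    jsonlite::toJSON(d, auto_unbox = TRUE, null = "null")
  }, character(1)), path)
  read_corpus_jsonl(path)
}

# Five hand-annotated single-relation documents covering all predicates.
fixture_docs <- function() {
  list(
    list(doc_id = "D1", year = 2018L, text = "WNT4 promotes IGF2 in colon cancer.",
         entities = list(
           list(sentence = 0L, start = 0L, end = 1L, label = "Gene"),
           list(sentence = 0L, start = 2L, end = 3L, label = "Gene"),
           list(sentence = 0L, start = 4L, end = 6L, label = "Cancer")),
         relations = list(
           list(subject_idx = 0L, predicate = "Promotes", object_idx = 1L))),
    list(doc_id = "D2", year = 2019L, text = "STAT3 inhibits the WNT pathway in melanoma.",
         entities = list(
           list(sentence = 0L, start = 0L, end = 1L, label = "Gene"),
           list(sentence = 0L, start = 3L, end = 5L, label = "SignalPathway"),
           list(sentence = 0L, start = 6L, end = 7L, label = "Cancer")),
         relations = list(
           list(subject_idx = 0L, predicate = "Inhibits", object_idx = 1L))),
    list(doc_id = "D3", year = 2020L, text = "IGF2 acts upstream of STAT3 in breast cancer.",
         entities = list(
           list(sentence = 0L, start = 0L, end = 1L, label = "Gene"),
           list(sentence = 0L, start = 4L, end = 5L, label = "Gene"),
           list(sentence = 0L, start = 6L, end = 8L, label = "Cancer")),
         relations = list(
           list(subject_idx = 0L, predicate = "Upstream", object_idx = 1L))),
    list(doc_id = "D4", year = 2021L, text = "WNT4, also known as Wnt-4, is overexpressed in melanoma.",
         entities = list(
           list(sentence = 0L, start = 0L, end = 1L, label = "Gene"),
           list(sentence = 0L, start = 5L, end = 6L, label = "Gene"),
           list(sentence = 0L, start = 10L, end = 11L, label = "Cancer")),
         relations = list(
           list(subject_idx = 0L, predicate = "Abbreviation", object_idx = 1L))),
    list(doc_id = "D5", year = 2022L, text = "STAT3 regulates cell migration in colon cancer.",
         entities = list(
           list(sentence = 0L, start = 0L, end = 1L, label = "Gene"),
           list(sentence = 0L, start = 2L, end = 4L, label = "BiologicalFunction"),
           list(sentence = 0L, start = 5L, end = 7L, label = "Cancer")),
         relations = list(
           list(subject_idx = 0L, predicate = "Function", object_idx = 1L)))
  )
}

# Exhaustive-path CRF oracle: enumerate all T^L sequences.
crf_brute <- function(emissions, crf, mask = NULL) {
  L <- nrow(emissions); T_ <- ncol(emissions)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(T_)), L)))
  score_one <- function(y) {
    s <- crf$start[y[1]] + sum(emissions[cbind(seq_len(L), y)]) + crf$stop[y[L]]
    if (L > 1L) s <- s + sum(crf$trans[cbind(y[-L], y[-1])])
    s
  }
  valid <- rep(TRUE, nrow(seqs))
  if (!is.null(mask)) {
    valid <- vapply(seq_len(nrow(seqs)), function(i) {
      y <- seqs[i, ]
      if (mask$start[y[1]]) return(FALSE)
      if (L > 1L && any(mask$trans[cbind(y[-L], y[-1])])) return(FALSE)
      TRUE
    }, logical(1))
  }
  scores <- apply(seqs, 1, score_one)
  m <- max(scores)
  list(log_partition = m + log(sum(exp(scores - m))),
       best_score = max(scores[valid]),
       best_path = seqs[valid, , drop = FALSE][which.max(scores[valid]), ])
}

# Brute-force (s, r, o) enumeration oracle for interaction-map decoding.
decode_brute <- function(map, threshold) {
  L <- nrow(map) - 5L
  out <- list()
  preds <- predicate_labels()
  if (L >= 1L) {
    for (s in seq_len(L)) for (r in seq_len(5L)) for (o in seq_len(L)) {
      if (s == o) next
      slot <- L + r
      if (map[s, o] >= threshold && map[s, slot] >= threshold &&
          map[slot, o] >= threshold) {
        out[[length(out) + 1L]] <- data.frame(s_head = s - 1L,
                                              predicate = preds[r],
                                              o_head = o - 1L)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(s_head = integer(0), predicate = character(0),
                      o_head = integer(0)))
  }
  do.call(rbind, out)
}

triple_key <- function(d) {
  paste(if (!is.null(d$doc_id)) d$doc_id else "", d$sentence,
        d$s_head %||% d$s_start, d$predicate, d$o_head %||% d$o_start)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random non-overlapping entity sets over n tokens (for BIO round trips).
random_entities <- function(n_tokens) {
  labs <- entity_labels()
  k <- sample(0:min(4L, n_tokens %/% 2L), 1)
  cuts <- sort(sample(0:n_tokens, size = 2L * k, replace = FALSE))
  if (length(cuts) < 2) return(tibble::tibble(start = integer(0), end = integer(0),
                                              label = character(0)))
  starts <- cuts[seq(1, length(cuts), by = 2)]
  ends <- cuts[seq(2, length(cuts), by = 2)]
  keep <- starts < ends
  tibble::tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]),
                 label = sample(labs, sum(keep), replace = TRUE))
}

expect_same_triple_set <- function(a, b) {
  expect_setequal(triple_key(a), triple_key(b))
}
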