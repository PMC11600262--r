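# Document model: rule-based tokenization, BIO tag encoding/decoding, and
# JSONL annotated-corpus interchange.
#
# Conventions used throughout the package:
#   * character offsets are 0-based, half-open [start, end)
#   * entity spans are token-index spans within one sentence, 0-based,
#     half-open [start, end)
#   * sentence and token indices are 0-based

# Sentence-final period is suppressed after these (case-insensitive) words.
ABBREV_STOPLIST <- c("e.g", "i.e", "et", "al", "fig", "figs", "vs", "cf",
                     "dr", "no", "approx", "resp")

LEAD_PUNCT <- c("(", "[", "{", "\"", "'")
TRAIL_PUNCT <- c(")", "]", "}", "\"", "'", ",", ".", ";", ":", "!", "?", "%")

#' Tokenize an abstract into sentences and tokens
#'
#' Deterministic rule-based segmentation: sentences end at `.`, `!` or `?`
#' followed by whitespace and an uppercase letter, digit or opening bracket,
#' unless the preceding word is on a short abbreviation stoplist. Tokens are
#' whitespace-delimited chunks with leading/trailing punctuation split off as
#' separate tokens; internal hyphens are kept, so gene names like `WNT-4`
#' stay one token.
#'
#' @param text Non-empty character scalar (an abstract).
#' @param doc_id Document identifier (PMID-like string).
#' @param year Publication year (integer, optional).
#' @param journal Journal name (optional).
#'
#' @return A `litnet_document`: list with `doc_id`, `year`, `journal`,
#'   `text`, `sentences` (tibble of 0-based half-open character intervals)
#'   and `tokens` (tibble with `sentence`, `token`, `start`, `end`,
#'   `surface`).
#' @examples
#' doc <- tokenize("WNT4 promotes IGF2.")
#' doc$tokens$surface
#' @export
tokenize <- function(text, doc_id = "doc", year = NA_integer_, journal = NA_character_) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    abort("`text` must be a non-empty character scalar.", class = "litnet_empty_text")
  }
  sent <- split_sentences(text)
  toks <- purrr::map2_dfr(sent$start, sent$end, function(s, e) {
    tokenize_span(text, s, e)
  }, .id = NULL)
  toks$sentence <- findInterval(toks$start, sent$start) - 1L
  toks <- dplyr::group_by(toks, .data$sentence)
  toks <- dplyr::mutate(toks, token = dplyr::row_number() - 1L)
  toks <- dplyr::ungroup(toks)
  toks <- dplyr::select(toks, "sentence", "token", "start", "end", "surface")
  structure(
    list(doc_id = doc_id, year = as.integer(year), journal = journal,
         text = text, sentences = sent, tokens = toks),
    class = "litnet_document"
  )
}

#' @export
print.litnet_document <- function(x, ...) {
  cat(sprintf("<litnet_document %s: %d sentence(s), %d token(s)>\n",
              x$doc_id, nrow(x$sentences), nrow(x$tokens)))
  invisible(x)
}

split_sentences <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  breaks <- integer(0)  # 1-based index of the terminal punctuation character
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      # absorb runs of terminal punctuation ("?!", "...")
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?")) j <- j + 1L
      after <- j + 1L
      while (after <= n && grepl("^\\s$", chars[after])) after <- after + 1L
      followed_ok <- after > j + 1L &&
        (after > n || grepl("^[A-Z0-9(\"\\[]$", chars[after]))
      if (j == n) followed_ok <- TRUE
      is_abbrev <- FALSE
      if (ch == "." && i > 1L) {
        prev <- sub(".*?([A-Za-z.]+)$", "\\1", substr(text, max(1L, i - 12L), i - 1L))
        is_abbrev <- tolower(sub("\\.$", "", prev)) %in% ABBREV_STOPLIST
      }
      if (followed_ok && !is_abbrev) breaks <- c(breaks, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(breaks) == 0L || breaks[length(breaks)] < n) {
    # trailing material without terminal punctuation forms a final sentence
    last_non_ws <- max(which(!grepl("^\\s$", chars)))
    if (length(breaks) == 0L || last_non_ws > breaks[length(breaks)]) {
      breaks <- c(breaks, last_non_ws)
    }
  }
  starts <- integer(length(breaks))
  prev_end <- 0L
  for (k in seq_along(breaks)) {
    s <- prev_end + 1L
    while (s <= n && grepl("^\\s$", chars[s])) s <- s + 1L
    starts[k] <- s - 1L            # to 0-based
    prev_end <- breaks[k]
  }
  tibble(start = starts, end = breaks)  # end is 1-based inclusive == 0-based exclusive
}

tokenize_span <- function(text, s0, e0) {
  seg <- substr(text, s0 + 1L, e0)
  m <- gregexpr("\\S+", seg)[[1]]
  if (m[1] == -1L) return(tibble(start = integer(0), end = integer(0), surface = character(0)))
  starts <- as.integer(m) - 1L + s0
  lens <- attr(m, "match.length")
  out_s <- integer(0); out_e <- integer(0)
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- starts[k] + lens[k]   # 0-based half-open chunk
    # peel leading punctuation
    while (a < b && substr(text, a + 1L, a + 1L) %in% LEAD_PUNCT) {
      out_s <- c(out_s, a); out_e <- c(out_e, a + 1L); a <- a + 1L
    }
    # identify trailing punctuation run
    t0 <- b
    while (t0 > a && substr(text, t0, t0) %in% TRAIL_PUNCT) t0 <- t0 - 1L
    if (t0 > a) { out_s <- c(out_s, a); out_e <- c(out_e, t0) }
    if (t0 < b) {
      for (p in seq.int(t0, b - 1L)) { out_s <- c(out_s, p); out_e <- c(out_e, p + 1L) }
    }
  }
  tibble(start = out_s, end = out_e,
         surface = substr(rep(text, length(out_s)), out_s + 1L, out_e))
}

#' Encode entity spans as a BIO tag sequence
#'
#' @param entities Tibble with columns `start`, `end` (token-index span,
#'   half-open) and `label` (one of the four entity labels), all within one
#'   sentence.
#' @param n_tokens Number of tokens in the sentence.
#' @return Character vector of BIO tags, length `n_tokens`.
#' @export
bio_encode <- function(entities, n_tokens) {
  tags <- rep("O", n_tokens)
  if (is.null(entities) || nrow(entities) == 0L) return(tags)
  stopifnot(all(entities$label %in% ENTITY_LABELS))
  if (any(entities$start < 0L) || any(entities$end > n_tokens) ||
      any(entities$start >= entities$end)) {
    abort("entity span out of range for the sentence", class = "litnet_bad_span")
  }
  cov <- unlist(purrr::map2(entities$start, entities$end, ~ seq.int(.x, .y - 1L)))
  if (anyDuplicated(cov)) {
    abort("overlapping entity spans are not valid gold annotation",
          class = "litnet_overlap")
  }
  for (i in seq_len(nrow(entities))) {
    s <- entities$start[i]; e <- entities$end[i]; lab <- entities$label[i]
    tags[s + 1L] <- paste0("B-", lab)
    if (e - s > 1L) tags[(s + 2L):e] <- paste0("I-", lab)
  }
  tags
}

#' Decode a BIO tag sequence into entity spans
#'
#' Ill-formed sequences (an `I-X` not preceded by `B-X` or `I-X`), which can
#' arise from model prediction, are repaired losslessly by promoting the
#' offending `I-X` to `B-X`.
#'
#' @param tags Character vector over the BIO alphabet.
#' @return Tibble with `start`, `end`, `label` (token-index spans).
#' @export
bio_decode <- function(tags) {
  bad <- setdiff(unique(tags), bio_alphabet())
  if (length(bad)) {
    abort(paste0("unknown BIO tag(s): ", paste(bad, collapse = ", ")),
          class = "litnet_bad_tag")
  }
  starts <- integer(0); ends <- integer(0); labs <- character(0)
  cur_lab <- NULL; cur_start <- NA_integer_
  close_run <- function(i) {
    if (!is.null(cur_lab)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, i - 1L); labs <<- c(labs, cur_lab)
    }
    cur_lab <<- NULL
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") { close_run(i); next }
    kind <- substr(tg, 1, 1); lab <- substring(tg, 3)
    if (kind == "B" || is.null(cur_lab) || cur_lab != lab) {
      close_run(i)                       # I-X without matching run: promote
      cur_lab <- lab; cur_start <- i - 1L
    }
  }
  close_run(length(tags) + 1L)
  tibble(start = starts, end = ends, label = labs)
}

entity_surface <- function(doc, sentence, start, end) {
  purrr::pmap_chr(list(sentence, start, end), function(s, a, b) {
    tk <- doc$tokens[doc$tokens$sentence == s, ]
    paste(tk$surface[(a + 1L):b], collapse = " ")
  })
}

empty_entities <- function() {
  tibble(sentence = integer(0), start = integer(0), end = integer(0),
         label = character(0), surface = character(0))
}

empty_triples <- function() {
  tibble(sentence = integer(0),
         s_start = integer(0), s_end = integer(0), s_label = character(0),
         s_surface = character(0), predicate = character(0),
         o_start = integer(0), o_end = integer(0), o_label = character(0),
         o_surface = character(0))
}

validate_doc_annotations <- function(doc, entities, relations, line = NA_integer_) {
  where <- if (is.na(line)) "" else sprintf(" (line %d)", line)
  n_sent <- nrow(doc$sentences)
  if (nrow(entities)) {
    if (!all(entities$label %in% ENTITY_LABELS)) {
      abort(sprintf("invalid entity label%s: %s", where,
                    paste(setdiff(entities$label, ENTITY_LABELS), collapse = ", ")),
            class = "litnet_schema")
    }
    for (i in seq_len(nrow(entities))) {
      s <- entities$sentence[i]
      if (is.na(s) || s < 0L || s >= n_sent) {
        abort(sprintf("entity sentence index out of range%s", where), class = "litnet_schema")
      }
      ntok <- sum(doc$tokens$sentence == s)
      if (entities$start[i] < 0L || entities$end[i] > ntok ||
          entities$start[i] >= entities$end[i]) {
        abort(sprintf("entity token span out of range%s", where), class = "litnet_schema")
      }
    }
  }
  if (nrow(relations)) {
    if (!all(relations$predicate %in% PREDICATES)) {
      abort(sprintf("invalid predicate%s: %s", where,
                    paste(setdiff(relations$predicate, PREDICATES), collapse = ", ")),
            class = "litnet_schema")
    }
    ok_idx <- function(ix) !is.na(ix) & ix >= 0L & ix < nrow(entities)
    if (!all(ok_idx(relations$subject_idx)) || !all(ok_idx(relations$object_idx))) {
      abort(sprintf("relation entity index out of range%s", where), class = "litnet_schema")
    }
    same_sent <- entities$sentence[relations$subject_idx + 1L] ==
      entities$sentence[relations$object_idx + 1L]
    if (!all(same_sent)) {
      abort(sprintf("relation crosses a sentence boundary%s", where), class = "litnet_schema")
    }
    if (any(relations$subject_idx == relations$object_idx)) {
      abort(sprintf("relation subject equals object%s", where), class = "litnet_schema")
    }
  }
  invisible(TRUE)
}

#' Read an annotated corpus from JSONL
#'
#' One document per line with fields `doc_id`, `year`, optional `journal`,
#' `text`, `entities` (objects with `sentence`, `start`, `end`, `label`;
#' token-index spans) and `relations` (objects with `subject_idx`,
#' `predicate`, `object_idx` indexing the entity array, 0-based). Schema
#' violations are reported with their line number.
#'
#' @param path Path to a JSONL file.
#' @return A `litnet_corpus`: tibble with one row per document and
#'   list-columns `document` (the tokenized [tokenize()] result), `entities`
#'   and `relations` (span-level tibbles).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty corpus file", class = "litnet_schema")
  rows <- purrr::imap(lines, function(ln, i) {
    rec <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = TRUE),
                    error = function(e) abort(sprintf("line %d: invalid JSON (%s)",
                                                      i, conditionMessage(e)),
                                              class = "litnet_schema"))
    for (f in c("doc_id", "text")) {
      if (is.null(rec[[f]])) abort(sprintf("line %d: missing field `%s`", i, f),
                                   class = "litnet_schema")
    }
    doc <- tokenize(rec$text, doc_id = as.character(rec$doc_id),
                    year = rec$year %||% NA_integer_,
                    journal = rec$journal %||% NA_character_)
    ents <- if (is.null(rec$entities) || length(rec$entities) == 0L) {
      tibble(sentence = integer(0), start = integer(0), end = integer(0), label = character(0))
    } else {
      as_tibble(rec$entities)
    }
    need <- setdiff(c("sentence", "start", "end", "label"), names(ents))
    if (nrow(ents) && length(need)) {
      abort(sprintf("line %d: entities missing field(s) %s", i, paste(need, collapse = ", ")),
            class = "litnet_schema")
    }
    ents <- dplyr::mutate(ents, dplyr::across(c("sentence", "start", "end"), as.integer))
    rels <- if (is.null(rec$relations) || length(rec$relations) == 0L) {
      tibble(subject_idx = integer(0), predicate = character(0), object_idx = integer(0))
    } else {
      as_tibble(rec$relations)
    }
    need <- setdiff(c("subject_idx", "predicate", "object_idx"), names(rels))
    if (nrow(rels) && length(need)) {
      abort(sprintf("line %d: relations missing field(s) %s", i, paste(need, collapse = ", ")),
            class = "litnet_schema")
    }
    rels <- dplyr::mutate(rels, dplyr::across(c("subject_idx", "object_idx"), as.integer))
    validate_doc_annotations(doc, ents, rels, line = i)
    if (nrow(ents)) {
      ents$surface <- entity_surface(doc, ents$sentence, ents$start, ents$end)
    } else {
      ents <- empty_entities()
    }
    triples <- if (nrow(rels)) {
      si <- rels$subject_idx + 1L; oi <- rels$object_idx + 1L
      tibble(sentence = ents$sentence[si],
             s_start = ents$start[si], s_end = ents$end[si],
             s_label = ents$label[si], s_surface = ents$surface[si],
             predicate = rels$predicate,
             o_start = ents$start[oi], o_end = ents$end[oi],
             o_label = ents$label[oi], o_surface = ents$surface[oi])
    } else {
      empty_triples()
    }
    tibble(doc_id = doc$doc_id, year = doc$year, journal = doc$journal,
           text = doc$text, document = list(doc),
           entities = list(ents), relations = list(triples))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("litnet_corpus", class(out))
  out
}

#' Write an annotated corpus to JSONL
#'
#' Inverse of [read_corpus_jsonl()]; relations are serialized by entity
#' index.
#'
#' @param corpus A `litnet_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    ents <- corpus$entities[[i]]
    rels <- corpus$relations[[i]]
    key <- function(s, a, b) paste(s, a, b, sep = ":")
    ek <- key(ents$sentence, ents$start, ents$end)
    rel_list <- purrr::pmap(rels, function(sentence, s_start, s_end, s_label, s_surface,
                                           predicate, o_start, o_end, o_label, o_surface) {
      list(subject_idx = match(key(sentence, s_start, s_end), ek) - 1L,
           predicate = predicate,
           object_idx = match(key(sentence, o_start, o_end), ek) - 1L)
    })
    rec <- list(doc_id = corpus$doc_id[i], year = corpus$year[i],
                journal = corpus$journal[i], text = corpus$text[i],
                entities = purrr::pmap(ents[c("sentence", "start", "end", "label")], list),
                relations = rel_list)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null"), con)
  }
  invisible(path)
}

# Flat per-corpus views ------------------------------------------------------

#' Flatten corpus annotations
#'
#' `corpus_entities()` returns all gold entity spans with their `doc_id`;
#' `corpus_triples()` returns all gold relation triples with `doc_id` and
#' `year` (the provenance used by [build_graph()]).
#'
#' @param corpus A `litnet_corpus`.
#' @return A tibble.
#' @export
corpus_entities <- function(corpus) {
  dplyr::bind_rows(purrr::map2(corpus$doc_id, corpus$entities,
                               ~ dplyr::bind_cols(tibble(doc_id = .x), .y)))
}

#' @rdname corpus_entities
#' @export
corpus_triples <- function(corpus) {
  dplyr::bind_rows(purrr::pmap(list(corpus$doc_id, corpus$year, corpus$relations),
                               function(id, yr, tr) {
                                 if (!nrow(tr)) return(NULL)
                                 dplyr::bind_cols(tibble(doc_id = id, year = yr), tr)
                               }))
}
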