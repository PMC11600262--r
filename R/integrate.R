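# Fusion of NER spans with RE head-level triples under entity-type /
# relation-type compatibility constraints. Integration is a pure filter: it
# anchors relation heads inside recognized entity spans, restores the full
# typed spans, and drops type-incompatible candidates; it never invents a
# triple.

#' Default entity-type / relation-type compatibility table
#'
#' Relation types between entities are contextually constrained; in
#' particular an abbreviation relation between a gene and a biological
#' function is impossible. The defaults are biologically conservative:
#' Promotes/Inhibits/Upstream require a Gene or SignalPathway subject and
#' any of the four types as object; Function links Gene/SignalPathway
#' subjects to BiologicalFunction objects only; Abbreviation is allowed only
#' between mentions of the same entity type. The table is total over the
#' 4 x 5 x 4 label space and fully overridable (see
#' [read_compatibility_tsv()]).
#'
#' @return Tibble with `s_label`, `predicate`, `o_label`, `allowed`.
#' @export
default_compatibility <- function() {
  grid <- tidyr::expand_grid(s_label = ENTITY_LABELS, predicate = PREDICATES,
                             o_label = ENTITY_LABELS)
  dplyr::mutate(grid, allowed = dplyr::case_when(
    predicate %in% REGULATORY_PREDICATES ~
      s_label %in% c("Gene", "SignalPathway"),
    predicate == "Function" ~
      s_label %in% c("Gene", "SignalPathway") & o_label == "BiologicalFunction",
    predicate == "Abbreviation" ~ s_label == o_label
  ))
}

#' Read or write a compatibility table as TSV
#'
#' Columns `s_label`, `predicate`, `o_label`, `allowed` (logical). The
#' table must cover the full 4 x 5 x 4 label space.
#'
#' @param path TSV path.
#' @return A compatibility tibble.
#' @export
read_compatibility_tsv <- function(path) {
  df <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("s_label", "predicate", "o_label", "allowed")
  if (!all(need %in% names(df))) {
    abort("compatibility TSV needs columns s_label, predicate, o_label, allowed",
          class = "litnet_schema")
  }
  df$allowed <- as.logical(df$allowed)
  validate_compatibility(df)
  df[need]
}

#' @rdname read_compatibility_tsv
#' @param table A compatibility tibble.
#' @export
write_compatibility_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_compatibility <- function(table) {
  full <- tidyr::expand_grid(s_label = ENTITY_LABELS, predicate = PREDICATES,
                             o_label = ENTITY_LABELS)
  got <- dplyr::distinct(table[, c("s_label", "predicate", "o_label")])
  if (nrow(got) != nrow(table) || nrow(dplyr::anti_join(full, got,
      by = c("s_label", "predicate", "o_label"))) > 0L) {
    abort("compatibility table must be total over the 4 x 5 x 4 label space",
          class = "litnet_schema")
  }
  gene_fun_abbrev <- dplyr::filter(
    table, .data$predicate == "Abbreviation",
    (.data$s_label == "Gene" & .data$o_label == "BiologicalFunction") |
      (.data$s_label == "BiologicalFunction" & .data$o_label == "Gene"))
  if (any(gene_fun_abbrev$allowed)) {
    abort("a Gene/BiologicalFunction abbreviation relation is never allowed",
          class = "litnet_schema")
  }
  invisible(table)
}

#' Integrate NER spans with RE head triples
#'
#' A head-level candidate `(s_head, predicate, o_head)` survives iff both
#' heads fall inside recognized entity spans of the same sentence and the
#' `(subject label, predicate, object label)` combination is allowed by the
#' compatibility table; surviving candidates are restored to full typed
#' spans. Output is always a subset of the anchored candidates.
#'
#' @param entities Tibble of entity spans (`sentence`, `start`, `end`,
#'   `label`, `surface`, optional `doc_id`).
#' @param head_triples Tibble of head-level candidates (`sentence`,
#'   `s_head`, `predicate`, `o_head`, optional `doc_id`).
#' @param compat Compatibility table (default [default_compatibility()]).
#' @return Tibble of full relation triples in the corpus span layout.
#' @export
integrate_predictions <- function(entities, head_triples,
                                  compat = default_compatibility()) {
  validate_compatibility(compat)
  if (is.null(head_triples) || nrow(head_triples) == 0L) {
    out <- empty_triples()
    if ("doc_id" %in% names(entities)) {
      out <- dplyr::bind_cols(tibble(doc_id = character(0)), out)
    }
    return(out)
  }
  has_doc <- "doc_id" %in% names(head_triples)
  if (has_doc && !"doc_id" %in% names(entities)) {
    abort("entities lack doc_id while head_triples carry one", class = "litnet_schema")
  }
  keys <- if (has_doc) c("doc_id", "sentence") else "sentence"
  ent <- dplyr::rename(entities, e_start = "start", e_end = "end",
                       e_label = "label", e_surface = "surface")
  anchor <- function(tr, head_col, prefix) {
    j <- dplyr::inner_join(tr, ent, by = keys, relationship = "many-to-many")
    j <- dplyr::filter(j, .data[[head_col]] >= .data$e_start,
                       .data[[head_col]] < .data$e_end)
    nm <- c(e_start = paste0(prefix, "_start"), e_end = paste0(prefix, "_end"),
            e_label = paste0(prefix, "_label"), e_surface = paste0(prefix, "_surface"))
    dplyr::rename(j, dplyr::all_of(stats::setNames(names(nm), unname(nm))))
  }
  out <- anchor(head_triples, "s_head", "s")
  out <- anchor(out, "o_head", "o")
  out <- dplyr::semi_join(out, dplyr::filter(compat, .data$allowed),
                          by = c("s_label", "predicate", "o_label"))
  out <- dplyr::filter(out, !(.data$s_start == .data$o_start &
                                .data$s_end == .data$o_end))
  cols <- c(if (has_doc) "doc_id", "sentence",
            "s_start", "s_end", "s_label", "s_surface", "predicate",
            "o_start", "o_end", "o_label", "o_surface")
  dplyr::distinct(dplyr::select(out, dplyr::all_of(cols)))
}

#' Convert full triples to head-level candidates
#'
#' The head of a span is its first token; used to re-feed integrated output
#' through [integrate_predictions()] (idempotence) and by the evaluation
#' harness.
#'
#' @param triples Tibble in the corpus span layout.
#' @return Tibble with `sentence`, `s_head`, `predicate`, `o_head` (and
#'   `doc_id` if present).
#' @export
triples_to_heads <- function(triples) {
  cols <- c(if ("doc_id" %in% names(triples)) "doc_id", "sentence")
  dplyr::select(dplyr::mutate(triples, s_head = .data$s_start, o_head = .data$o_start),
                dplyr::all_of(c(cols, "s_head", "predicate", "o_head")))
}

#' Run the full extraction pipeline
#'
#' NER, RE and integration in one pass: predicts entity spans and
#' head-level relation candidates per document, then fuses them under the
#' compatibility table.
#'
#' @param ner_model A fitted `litnet_ner`.
#' @param re_model A fitted `litnet_re`.
#' @param x A `litnet_document` or `litnet_corpus`.
#' @param compat Compatibility table (default [default_compatibility()]).
#' @return Tibble of typed relation triples (corpus span layout, with
#'   `doc_id` for a corpus).
#' @export
extract_relations <- function(ner_model, re_model, x,
                              compat = default_compatibility()) {
  entities <- predict_entities(ner_model, x)
  heads <- predict_triples(re_model, x)
  integrate_predictions(entities, heads, compat)
}
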