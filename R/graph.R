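# Regulatory knowledge graph: alias normalization against a gene_info-style
# synonym table, deduplicating aggregation of typed triples into directed
# provenance-weighted edges, composable filters, and intermediary-path
# queries.

#' Read a gene synonym table
#'
#' NCBI gene_info-style TSV with columns `Symbol` and `Synonyms`
#' (pipe-separated aliases; `-` or empty for none). Aliases mapping to more
#' than one standard symbol are treated as unresolvable: they are removed
#' from the lookup (the surface form will stay its own node) and reported
#' via a warning.
#'
#' @param path TSV path.
#' @return A `synonym_table`: list with `rows` (the source tibble) and
#'   `lookup` (named character vector, case-folded alias -> symbol).
#' @export
read_synonym_table <- function(path) {
  df <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("Symbol", "Synonyms") %in% names(df))) {
    abort("synonym TSV needs columns Symbol and Synonyms", class = "litnet_schema")
  }
  synonym_table(df)
}

#' @rdname read_synonym_table
#' @param rows Tibble with `Symbol` and `Synonyms` columns.
#' @export
synonym_table <- function(rows) {
  rows$Symbol <- as.character(rows$Symbol)
  pairs <- tibble(alias = character(0), symbol = character(0))
  if (nrow(rows)) {
    pairs <- purrr::map2_dfr(rows$Symbol, rows$Synonyms, function(sym, syn) {
      al <- if (is.na(syn) || syn %in% c("", "-")) character(0) else
        strsplit(syn, "|", fixed = TRUE)[[1]]
      tibble(alias = fold_surface(c(sym, al)), symbol = sym)
    })
  }
  pairs <- dplyr::distinct(pairs)
  amb <- dplyr::filter(dplyr::add_count(pairs, .data$alias), .data$n > 1L)
  if (nrow(amb)) {
    drop <- unique(amb$alias)
    warn(paste0("ambiguous alias(es) left unresolved: ", paste(drop, collapse = ", ")),
         class = "litnet_ambiguous_alias")
    # a standard symbol always resolves to itself even if it doubles as an
    # alias of another gene; only non-symbol ambiguous aliases are dropped
    keep_self <- pairs$alias %in% fold_surface(rows$Symbol) &
      fold_surface(pairs$symbol) == pairs$alias
    pairs <- pairs[!(pairs$alias %in% drop) | keep_self, , drop = FALSE]
  }
  structure(list(rows = rows,
                 lookup = stats::setNames(pairs$symbol, pairs$alias)),
            class = "synonym_table")
}

#' @export
print.synonym_table <- function(x, ...) {
  cat(sprintf("<synonym_table: %d symbols, %d alias mappings>\n",
              nrow(x$rows), length(x$lookup)))
  invisible(x)
}

fold_surface <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Normalize an entity surface to a node identifier
#'
#' Gene surfaces are resolved case-insensitively through the synonym table
#' to their standard symbol; unknown gene surfaces and non-gene entities
#' become their case-folded, whitespace-collapsed surface.
#'
#' @param surface Character vector of mention surfaces.
#' @param label Matching entity labels.
#' @param table A `synonym_table`.
#' @return Character vector of node identifiers.
#' @export
normalize_surface <- function(surface, label, table) {
  folded <- fold_surface(surface)
  out <- folded
  is_gene <- label == "Gene"
  hit <- table$lookup[folded[is_gene]]
  out[is_gene] <- ifelse(is.na(hit), folded[is_gene], hit)
  out
}

#' Aggregate relation triples into a regulatory graph
#'
#' Triples are normalized (gene aliases to standard symbols), deduplicated
#' at `(doc_id, sentence)` granularity per normalized
#' `(subject, predicate, object)` key, and merged into directed weighted
#' edges whose weight is the number of supporting mentions and whose
#' provenance lists the `(doc_id, year, sentence)` records. Abbreviation
#' triples do not become edges: each one extends the synonym lookup for the
#' scope of the aggregation (its object surface becomes an alias of the
#' normalized subject), which is what keeps node identifiers unique.
#' Self-loops arising from normalization are dropped.
#'
#' @param triples Tibble of typed triples with `doc_id`, `year`, `sentence`
#'   and the span columns (see [corpus_triples()]).
#' @param synonyms A `synonym_table` (or `NULL` for surface-only
#'   normalization).
#' @return A `regulatory_graph`: list of `nodes` (tibble `id`, `label`) and
#'   `edges` (tibble `subject`, `predicate`, `object`, `weight`,
#'   `provenance` list-column).
#' @export
build_graph <- function(triples, synonyms = NULL) {
  if (is.null(synonyms)) {
    synonyms <- synonym_table(tibble(Symbol = character(0), Synonyms = character(0)))
  }
  stopifnot(inherits(synonyms, "synonym_table"))
  if (is.null(triples) || nrow(triples) == 0L) {
    return(new_regulatory_graph(
      nodes = tibble(id = character(0), label = character(0)),
      edges = tibble(subject = character(0), predicate = character(0),
                     object = character(0), weight = integer(0),
                     provenance = list())))
  }
  if (!"year" %in% names(triples)) triples$year <- NA_integer_
  # abbreviation triples extend the alias lookup within this aggregation
  abbr <- dplyr::filter(triples, .data$predicate == "Abbreviation")
  lookup <- synonyms$lookup
  if (nrow(abbr)) {
    std <- normalize_surface(abbr$s_surface, abbr$s_label, synonyms)
    ali <- fold_surface(abbr$o_surface)
    new <- !(ali %in% names(lookup)) & abbr$s_label == "Gene"
    if (any(new)) {
      add <- stats::setNames(std[new], ali[new])
      add <- add[!duplicated(names(add))]
      lookup <- c(lookup, add)
    }
  }
  scoped <- structure(list(rows = synonyms$rows, lookup = lookup),
                      class = "synonym_table")
  rel <- dplyr::filter(triples, .data$predicate != "Abbreviation")
  if (!nrow(rel)) {
    return(new_regulatory_graph(
      nodes = tibble(id = character(0), label = character(0)),
      edges = tibble(subject = character(0), predicate = character(0),
                     object = character(0), weight = integer(0),
                     provenance = list())))
  }
  rel$subject <- normalize_surface(rel$s_surface, rel$s_label, scoped)
  rel$object <- normalize_surface(rel$o_surface, rel$o_label, scoped)
  loops <- rel$subject == rel$object
  if (any(loops)) {
    warn(sprintf("dropping %d self-loop(s) produced by normalization", sum(loops)),
         class = "litnet_self_loop")
    rel <- rel[!loops, , drop = FALSE]
  }
  # dedup: the same normalized fact in the same (doc, sentence) counts once
  rel <- dplyr::distinct(rel, .data$subject, .data$predicate, .data$object,
                         .data$doc_id, .data$sentence,
                         .keep_all = TRUE)
  edges <- rel |>
    dplyr::group_by(.data$subject, .data$predicate, .data$object) |>
    dplyr::arrange(.data$doc_id, .data$sentence, .by_group = TRUE) |>
    dplyr::summarise(weight = dplyr::n(),
                     provenance = list(as_tibble(dplyr::pick("doc_id", "year", "sentence"))),
                     .groups = "drop") |>
    dplyr::arrange(.data$subject, .data$predicate, .data$object)
  node_rows <- dplyr::bind_rows(
    tibble(id = rel$subject, label = rel$s_label),
    tibble(id = rel$object, label = rel$o_label))
  nodes <- node_rows |>
    dplyr::count(.data$id, .data$label) |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_max(.data$n, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("id", "label") |>
    dplyr::arrange(.data$id)
  new_regulatory_graph(nodes = nodes, edges = edges)
}

new_regulatory_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges, annotated = FALSE),
            class = "regulatory_graph")
}

#' @export
print.regulatory_graph <- function(x, ...) {
  cat(sprintf("<regulatory_graph: %d nodes, %d edges (total weight %d)>\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' @method tidy regulatory_graph
#' @export
tidy.regulatory_graph <- function(x, ...) {
  dplyr::mutate(x$edges,
                n_documents = purrr::map_int(.data$provenance,
                                             ~ dplyr::n_distinct(.x$doc_id)))
}

#' @method glance regulatory_graph
#' @export
glance.regulatory_graph <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         total_weight = sum(x$edges$weight),
         n_predicates = dplyr::n_distinct(x$edges$predicate),
         annotated = isTRUE(x$annotated))
}

#' Filter a regulatory graph
#'
#' Composable, order-independent filters: keep edges whose predicate is in
#' `predicates`, whose weight is at least `min_weight`, and with at least
#' one provenance year inside `year_range` (edges whose provenance has no
#' recorded year pass year filters). Nodes left without any edge are
#' pruned. The input graph is unmodified.
#'
#' @param graph A `regulatory_graph`.
#' @param predicates Optional character vector of predicates to keep.
#' @param min_weight Optional minimum edge weight.
#' @param year_range Optional inclusive `c(from, to)` publication years.
#' @return A filtered `regulatory_graph`.
#' @export
filter_graph <- function(graph, predicates = NULL, min_weight = NULL,
                         year_range = NULL) {
  stopifnot(inherits(graph, "regulatory_graph"))
  edges <- graph$edges
  keep <- rep(TRUE, nrow(edges))
  if (!is.null(predicates)) keep <- keep & edges$predicate %in% predicates
  if (!is.null(min_weight)) keep <- keep & edges$weight >= min_weight
  if (!is.null(year_range)) {
    keep <- keep & purrr::map_lgl(edges$provenance, function(pr) {
      yr <- pr$year
      any(is.na(yr)) || any(yr >= year_range[1] & yr <= year_range[2], na.rm = TRUE)
    })
  }
  edges <- edges[keep, , drop = FALSE]
  used <- unique(c(edges$subject, edges$object))
  out <- graph
  out$edges <- edges
  out$nodes <- graph$nodes[graph$nodes$id %in% used, , drop = FALSE]
  out
}

#' Rank intermediary molecules between two nodes
#'
#' Enumerates directed simple paths from `source` to `target` of length at
#' most `max_len` using only regulatory (Promotes/Inhibits/Upstream) edges,
#' ranked by path length (ascending) and then by the minimum edge weight
#' along the path (descending). The interior nodes of a path are the
#' candidate intermediary molecules.
#'
#' @param graph A `regulatory_graph`.
#' @param source,target Node identifiers.
#' @param max_len Maximum number of edges per path.
#' @return Tibble with `path` (list of node-id vectors), `intermediaries`
#'   (list of interior node ids), `length` and `min_weight`, best path
#'   first; zero rows when no path exists.
#' @export
find_intermediaries <- function(graph, source, target, max_len = 3L) {
  stopifnot(inherits(graph, "regulatory_graph"))
  if (!source %in% graph$nodes$id || !target %in% graph$nodes$id) {
    abort("source and target must both be graph nodes", class = "litnet_missing_node")
  }
  edges <- dplyr::filter(graph$edges, .data$predicate %in% REGULATORY_PREDICATES)
  adj <- split(seq_len(nrow(edges)), edges$subject)
  paths <- list()
  walk <- function(node, visited, eweights) {
    if (length(eweights) > 0L && node == target) {
      paths[[length(paths) + 1L]] <<- list(path = visited, min_weight = min(eweights))
      return(invisible(NULL))  # simple paths: do not extend through target
    }
    if (length(eweights) >= max_len) return(invisible(NULL))
    for (i in adj[[node]] %||% integer(0)) {
      nxt <- edges$object[i]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), c(eweights, edges$weight[i]))
    }
  }
  walk(source, source, numeric(0))
  if (!length(paths)) {
    return(tibble(path = list(), intermediaries = list(),
                  length = integer(0), min_weight = numeric(0)))
  }
  out <- tibble(
    path = purrr::map(paths, "path"),
    intermediaries = purrr::map(paths, ~ .x$path[-c(1L, length(.x$path))]),
    length = purrr::map_int(paths, ~ length(.x$path) - 1L),
    min_weight = purrr::map_dbl(paths, "min_weight"))
  # parallel edges (several predicates on one node pair) revisit the same
  # node sequence: keep the best-supported copy
  out$key <- purrr::map_chr(out$path, paste, collapse = "\r")
  out <- out |>
    dplyr::group_by(.data$key) |>
    dplyr::slice_max(.data$min_weight, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"key")
  dplyr::arrange(out, .data$length, dplyr::desc(.data$min_weight))
}

# Export ---------------------------------------------------------------------

#' Export a regulatory graph
#'
#' `graph_to_node_link()` returns (or writes) the node-link JSON
#' representation (`nodes[]`, `links[]` with weight and provenance);
#' `write_graph_graphml()` writes GraphML (via igraph);
#' `write_graph_edge_tsv()` writes a flat edge list.
#'
#' @param graph A `regulatory_graph`.
#' @param path Output file; for `graph_to_node_link()`, `NULL` returns the
#'   JSON string instead.
#' @return The path (or JSON string), invisibly where written.
#' @export
graph_to_node_link <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "regulatory_graph"))
  obj <- list(
    directed = TRUE,
    nodes = purrr::pmap(graph$nodes, function(id, label, ...) list(id = id, label = label)),
    links = purrr::pmap(graph$edges, function(subject, predicate, object, weight,
                                              provenance, ...) {
      extra <- list(...)
      link <- list(source = subject, target = object, predicate = predicate,
                   weight = weight,
                   provenance = purrr::pmap(provenance, function(doc_id, year, sentence) {
                     list(doc_id = doc_id, year = year, sentence = sentence)
                   }))
      if (!is.null(extra$r)) {
        link$r <- if (is.na(extra$r)) NULL else extra$r
        link$confidence <- extra$confidence
      }
      link
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null",
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' @rdname graph_to_node_link
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "regulatory_graph"))
  ed <- graph$edges
  igraph::graph_from_data_frame(
    d = data.frame(from = ed$subject, to = ed$object,
                   predicate = ed$predicate, weight = ed$weight,
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$id, label = graph$nodes$label,
                          stringsAsFactors = FALSE))
}

#' @rdname graph_to_node_link
#' @export
write_graph_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname graph_to_node_link
#' @export
write_graph_edge_tsv <- function(graph, path) {
  ed <- tidy.regulatory_graph(graph)
  ed$provenance <- purrr::map_chr(ed$provenance, function(pr) {
    paste(sprintf("%s:%s", pr$doc_id, pr$sentence), collapse = ",")
  })
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Node-link JSON reader
#'
#' Inverse of [graph_to_node_link()].
#'
#' @param path JSON file path.
#' @return A `regulatory_graph`.
#' @export
read_graph_node_link <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- dplyr::bind_rows(purrr::map(obj$nodes, as_tibble))
  if (!length(obj$links)) {
    return(new_regulatory_graph(nodes = nodes,
                                edges = tibble(subject = character(0),
                                               predicate = character(0),
                                               object = character(0),
                                               weight = integer(0),
                                               provenance = list())))
  }
  edges <- dplyr::bind_rows(purrr::map(obj$links, function(l) {
    tibble(subject = l$source, predicate = l$predicate, object = l$target,
           weight = as.integer(l$weight),
           provenance = list(dplyr::bind_rows(purrr::map(l$provenance, function(p) {
             tibble(doc_id = p$doc_id,
                    year = if (is.null(p$year)) NA_integer_ else as.integer(p$year),
                    sentence = as.integer(p$sentence))
           }))),
           r = if (is.null(l$r)) NA_real_ else l$r,
           confidence = if (is.null(l$confidence)) NA_character_ else l$confidence)
  }))
  if (all(is.na(edges$r))) edges$r <- NULL
  if ("confidence" %in% names(edges) && all(is.na(edges$confidence))) {
    edges$confidence <- NULL
  }
  g <- new_regulatory_graph(nodes = nodes, edges = edges)
  g$annotated <- "r" %in% names(g$edges)
  g
}

#' @method autoplot regulatory_graph
#' @export
autoplot.regulatory_graph <- function(object, layout_seed = 1L, ...) {
  if (!nrow(object$edges)) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty regulatory graph"))
  }
  ig <- as_igraph(object)
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(ig)
  nd <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  ed <- dplyr::left_join(object$edges,
                         stats::setNames(nd[c("id", "x", "y")], c("subject", "x0", "y0")),
                         by = "subject")
  ed <- dplyr::left_join(ed,
                         stats::setNames(nd[c("id", "x", "y")], c("object", "x1", "y1")),
                         by = "object")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       colour = .data$predicate,
                                       linewidth = .data$weight),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          alpha = 0.7) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6)) +
    ggplot2::geom_point(data = nd, ggplot2::aes(x = .data$x, y = .data$y,
                                                shape = .data$label), size = 2) +
    ggplot2::geom_text(data = nd, ggplot2::aes(x = .data$x, y = .data$y,
                                               label = .data$id),
                       vjust = -1, size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "relation", shape = "entity type",
                  linewidth = "support")
}
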