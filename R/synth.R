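# Seeded synthetic-data generator: templated annotated abstracts covering
# the four entity types and five relation predicates, an accompanying gene
# synonym table, and planted-correlation expression matrices. Everything a
# pipeline stage needs to train and be evaluated offline is derived from one
# seed.

SYNTH_PATHWAYS <- c("JAK-STAT", "WNT", "PI3K-AKT", "MAPK", "NF-kB",
                    "TGF-beta", "NOTCH", "Hedgehog")
SYNTH_CANCERS <- c("colon cancer", "breast cancer", "gastric cancer",
                   "lung cancer", "hepatocellular carcinoma",
                   "ovarian cancer", "prostate cancer", "melanoma")
SYNTH_FUNCTIONS <- c("cell migration", "cell proliferation", "cell adhesion",
                     "apoptosis", "angiogenesis", "autophagy", "glycolysis",
                     "metastasis", "invasion", "epithelial-mesenchymal transition")

#' Synthetic-corpus generator configuration
#'
#' Defaults define the generator's study conditions: documents of 2–5
#' templated sentences over four entity classes, a uniform mix of the five
#' relation predicates, 30% of gene mentions using an alias, publication
#' years 2010–2024, and a 14-sample expression matrix with planted
#' correlation 0.9 on the WNT4–STAT3 and STAT3–IGF2 pairs.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_documents Number of abstracts.
#' @param n_genes,n_pathways,n_cancers,n_functions Vocabulary sizes per
#'   entity class (genes beyond the three demo symbols are synthetic
#'   `GENA*` names; pathways/cancers/functions are drawn from fixed
#'   domain lists, so are capped at those lists' lengths).
#' @param relation_mix Proportions over the predicates (Promotes, Inhibits,
#'   Upstream, Abbreviation, Function); must sum to 1.
#' @param alias_prob Chance a gene mention uses an alias instead of its
#'   standard symbol.
#' @param distractor_prob Chance a sentence carries entities but no
#'   relation, giving the relation extractor true negatives.
#' @param year_range Inclusive publication-year range.
#' @param split Proportions for the by-document train/test/validation split.
#' @param n_samples Expression-matrix sample count.
#' @param planted Optional planted correlation matrix (genes x genes,
#'   dimnames = symbols); defaults to identity plus the WNT4/STAT3/IGF2
#'   chain at 0.9.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_documents = 100L, n_genes = 30L,
                             n_pathways = 8L, n_cancers = 8L, n_functions = 10L,
                             relation_mix = rep(0.2, 5), alias_prob = 0.3,
                             distractor_prob = 0.25,
                             year_range = c(2010L, 2024L),
                             split = c(train = 0.7, test = 0.15, validation = 0.15),
                             n_samples = 14L, planted = NULL) {
  if (abs(sum(relation_mix) - 1) > 1e-8 || length(relation_mix) != 5L ||
      any(relation_mix < 0)) {
    abort("relation_mix must be 5 non-negative proportions summing to 1",
          class = "litnet_config")
  }
  if (n_genes < 3L || n_pathways < 1L || n_cancers < 1L || n_functions < 1L ||
      n_pathways > length(SYNTH_PATHWAYS) || n_cancers > length(SYNTH_CANCERS) ||
      n_functions > length(SYNTH_FUNCTIONS)) {
    abort("inconsistent vocabulary sizes", class = "litnet_config")
  }
  if (abs(sum(split) - 1) > 1e-8) {
    abort("split proportions must sum to 1", class = "litnet_config")
  }
  structure(list(seed = as.integer(seed), n_documents = as.integer(n_documents),
                 n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
                 n_cancers = as.integer(n_cancers), n_functions = as.integer(n_functions),
                 relation_mix = stats::setNames(relation_mix, PREDICATES),
                 alias_prob = alias_prob, distractor_prob = distractor_prob,
                 year_range = as.integer(year_range), split = split,
                 n_samples = as.integer(n_samples), planted = planted),
            class = "generator_config")
}

synth_gene_vocab <- function(n_genes) {
  symbols <- c("WNT4", "STAT3", "IGF2",
               if (n_genes > 3L) paste0("GENA", seq_len(n_genes - 3L)))
  aliases <- list(WNT4 = c("WNT-4", "Wnt4"), STAT3 = c("STAT-3", "Stat3"),
                  IGF2 = c("IGF-II", "Igf2"))
  for (s in setdiff(symbols, names(aliases))) {
    k <- sub("GENA", "", s)
    aliases[[s]] <- c(paste0("Gena", k), paste0("GA-", k))
  }
  list(symbols = symbols, aliases = aliases)
}

# One templated sentence. Returns the sentence string plus entity mention
# descriptors (surface, label) in left-to-right order and relation wiring by
# mention position.
synth_sentence <- function(kind, genes, cfg, used_aliases) {
  pick_gene <- function() {
    sym <- sample(genes$symbols, 1L)
    if (runif(1) < cfg$alias_prob) {
      surface <- sample(genes$aliases[[sym]], 1L)
    } else {
      surface <- sym
    }
    list(symbol = sym, surface = surface)
  }
  g1 <- pick_gene()
  cancer <- sample(SYNTH_CANCERS[seq_len(cfg$n_cancers)], 1L)
  fun <- sample(SYNTH_FUNCTIONS[seq_len(cfg$n_functions)], 1L)
  pathway <- sample(SYNTH_PATHWAYS[seq_len(cfg$n_pathways)], 1L)
  if (kind %in% c("Promotes", "Upstream")) {
    repeat {
      g2 <- pick_gene()
      if (g2$symbol != g1$symbol) break
    }
    verb <- if (kind == "Promotes") "promotes" else "acts upstream of"
    list(text = sprintf("%s %s %s in %s.", g1$surface, verb, g2$surface, cancer),
         mentions = list(list(surface = g1$surface, label = "Gene"),
                         list(surface = g2$surface, label = "Gene"),
                         list(surface = cancer, label = "Cancer")),
         relations = list(list(s = 1L, predicate = kind, o = 2L)),
         aliases = c(g1$surface, g2$surface))
  } else if (kind == "Inhibits") {
    list(text = sprintf("%s inhibits the %s pathway in %s.",
                        g1$surface, pathway, cancer),
         mentions = list(list(surface = g1$surface, label = "Gene"),
                         list(surface = paste(pathway, "pathway"), label = "SignalPathway"),
                         list(surface = cancer, label = "Cancer")),
         relations = list(list(s = 1L, predicate = "Inhibits", o = 2L)),
         aliases = g1$surface)
  } else if (kind == "Abbreviation") {
    # with alias_prob = 0 the corpus must introduce no aliases at all, so
    # the abbreviation mention falls back to the standard symbol
    alias <- if (cfg$alias_prob > 0) sample(genes$aliases[[g1$symbol]], 1L) else g1$symbol
    list(text = sprintf("%s, also known as %s, is overexpressed in %s.",
                        g1$symbol, alias, cancer),
         mentions = list(list(surface = g1$symbol, label = "Gene"),
                         list(surface = alias, label = "Gene"),
                         list(surface = cancer, label = "Cancer")),
         relations = list(list(s = 1L, predicate = "Abbreviation", o = 2L)),
         aliases = alias)
  } else if (kind == "Function") {
    list(text = sprintf("%s regulates %s in %s.", g1$surface, fun, cancer),
         mentions = list(list(surface = g1$surface, label = "Gene"),
                         list(surface = fun, label = "BiologicalFunction"),
                         list(surface = cancer, label = "Cancer")),
         relations = list(list(s = 1L, predicate = "Function", o = 2L)),
         aliases = g1$surface)
  } else {  # distractor: entities, no relation
    list(text = sprintf("The role of %s in %s remains unclear.",
                        g1$surface, cancer),
         mentions = list(list(surface = g1$surface, label = "Gene"),
                         list(surface = cancer, label = "Cancer")),
         relations = list(),
         aliases = g1$surface)
  }
}

# Locate each mention's token span within a tokenized sentence, scanning
# left to right so repeated surfaces resolve to successive occurrences.
locate_mentions <- function(token_surfaces, mentions) {
  pos <- 1L
  spans <- vector("list", length(mentions))
  for (k in seq_along(mentions)) {
    mtoks <- strsplit(mentions[[k]]$surface, " ", fixed = TRUE)[[1]]
    found <- NA_integer_
    for (i in seq.int(pos, length(token_surfaces) - length(mtoks) + 1L)) {
      if (all(token_surfaces[i:(i + length(mtoks) - 1L)] == mtoks)) {
        found <- i
        break
      }
    }
    if (is.na(found)) {
      abort("internal: template mention not found in tokenization")
    }
    spans[[k]] <- c(start = found - 1L, end = found - 1L + length(mtoks))
    pos <- found + length(mtoks)
  }
  spans
}

#' Generate a synthetic annotated corpus
#'
#' Emits templated abstracts with exact gold entity spans and relation
#' triples, a by-document train/test/validation split, and the synonym
#' table covering every gene alias actually used.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (a `litnet_corpus` with a `split` column) and
#'   `synonyms` (tibble with `Symbol`, `Synonyms` pipe-separated).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  genes <- synth_gene_vocab(config$n_genes)
  used_aliases <- stats::setNames(vector("list", length(genes$symbols)), genes$symbols)
  rows <- vector("list", config$n_documents)
  for (d in seq_len(config$n_documents)) {
    n_sent <- sample(2:5, 1L)
    sents <- vector("list", n_sent)
    for (s in seq_len(n_sent)) {
      kind <- if (runif(1) < config$distractor_prob) {
        "Distractor"
      } else {
        sample(PREDICATES, 1L, prob = config$relation_mix)
      }
      sents[[s]] <- synth_sentence(kind, genes, config, used_aliases)
    }
    text <- paste(vapply(sents, `[[`, character(1), "text"), collapse = " ")
    doc_id <- sprintf("SYN%05d", d)
    year <- sample(config$year_range[1]:config$year_range[2], 1L)
    doc <- tokenize(text, doc_id = doc_id, year = year, journal = "Synthetic Reports")
    if (nrow(doc$sentences) != n_sent) {
      abort("internal: template sentence segmentation mismatch")
    }
    ents <- list(); rels <- list()
    for (s in seq_len(n_sent)) {
      surf <- doc$tokens$surface[doc$tokens$sentence == s - 1L]
      spans <- locate_mentions(surf, sents[[s]]$mentions)
      base <- length(ents)
      for (k in seq_along(spans)) {
        m <- sents[[s]]$mentions[[k]]
        ents[[base + k]] <- tibble(sentence = s - 1L,
                                   start = spans[[k]][["start"]],
                                   end = spans[[k]][["end"]],
                                   label = m$label, surface = m$surface)
        if (m$label == "Gene") {
          sym <- names(which(vapply(genes$aliases, function(a) m$surface %in% a,
                                    logical(1))))
          if (length(sym)) {
            used_aliases[[sym[1]]] <- union(used_aliases[[sym[1]]], m$surface)
          }
        }
      }
      for (r in sents[[s]]$relations) {
        si <- base + r$s; oi <- base + r$o
        rels[[length(rels) + 1L]] <- tibble(
          sentence = s - 1L,
          s_start = ents[[si]]$start, s_end = ents[[si]]$end,
          s_label = ents[[si]]$label, s_surface = ents[[si]]$surface,
          predicate = r$predicate,
          o_start = ents[[oi]]$start, o_end = ents[[oi]]$end,
          o_label = ents[[oi]]$label, o_surface = ents[[oi]]$surface)
      }
    }
    rows[[d]] <- tibble(doc_id = doc_id, year = year, journal = doc$journal,
                        text = text, document = list(doc),
                        entities = list(if (length(ents)) dplyr::bind_rows(ents)
                                        else empty_entities()),
                        relations = list(if (length(rels)) dplyr::bind_rows(rels)
                                         else empty_triples()))
  }
  corpus <- dplyr::bind_rows(rows)
  n <- nrow(corpus)
  n_train <- round(config$split[["train"]] * n)
  n_test <- round(config$split[["test"]] * n)
  lab <- rep("validation", n)
  ord <- sample.int(n)
  lab[ord[seq_len(n_train)]] <- "train"
  if (n_test > 0) lab[ord[n_train + seq_len(min(n_test, n - n_train))]] <- "test"
  corpus$split <- lab
  class(corpus) <- c("litnet_corpus", class(tibble()))
  syn <- tibble(
    Symbol = genes$symbols,
    Synonyms = vapply(genes$symbols, function(s) {
      paste(used_aliases[[s]] %||% character(0), collapse = "|")
    }, character(1))
  )
  list(corpus = corpus, synonyms = syn)
}

#' Generate a planted-correlation expression matrix
#'
#' Multivariate-normal draws whose population correlation matrix is the
#' planted one; rows are genes (the corpus gene symbols), columns samples.
#'
#' @param config A [generator_config()]; `config$planted` may carry a
#'   custom positive semi-definite correlation matrix with gene-symbol
#'   dimnames.
#' @param n_samples Overrides `config$n_samples` when given.
#' @return An `expression_matrix` (see [read_expression_tsv()]).
#' @export
generate_expression <- function(config = generator_config(), n_samples = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 7919L)
  n <- as.integer(n_samples %||% config$n_samples)
  genes <- synth_gene_vocab(config$n_genes)$symbols
  R <- config$planted
  if (is.null(R)) {
    R <- diag(length(genes))
    dimnames(R) <- list(genes, genes)
    R["WNT4", "STAT3"] <- R["STAT3", "WNT4"] <- 0.9
    R["STAT3", "IGF2"] <- R["IGF2", "STAT3"] <- 0.9
    R["WNT4", "IGF2"] <- R["IGF2", "WNT4"] <- 0.81
  }
  if (is.null(dimnames(R)[[1]])) {
    abort("planted correlation matrix needs gene-symbol dimnames", class = "litnet_config")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort("planted correlation matrix is not positive semi-definite",
          class = "litnet_not_psd")
  }
  ch <- chol(R + diag(1e-10, nrow(R)))
  Z <- matrix(rnorm(n * nrow(R)), n, nrow(R)) %*% ch
  values <- t(Z)
  rownames(values) <- rownames(R)
  colnames(values) <- sprintf("S%03d", seq_len(n))
  new_expression_matrix(values)
}
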