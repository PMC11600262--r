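# Named-entity tagger: pluggable embedding providers merged by a linear
# layer, a single-layer bidirectional recurrent encoder, and a CRF output
# layer trained by conditional maximum likelihood (forward algorithm) and
# decoded with BIO-masked Viterbi.

#' NER training configuration
#'
#' @param hidden Recurrent hidden size per direction.
#' @param merge_dim Output dimension of the linear layer merging the
#'   embedding providers.
#' @param recurrence `"tanh"` (plain recurrent cell) or `"gru"`.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param seed Integer seed funnelling all randomness (initialization and
#'   epoch shuffling).
#' @param providers List of [lookup_provider()]-style embedding providers.
#' @return A named list of settings.
#' @export
ner_config <- function(hidden = 16L, merge_dim = 24L,
                       recurrence = c("tanh", "gru"),
                       epochs = 20L, lr = 0.02, seed = 1L,
                       providers = list(lookup_provider(24L), char_window_provider(16L))) {
  list(hidden = as.integer(hidden), merge_dim = as.integer(merge_dim),
       recurrence = match.arg(recurrence), epochs = as.integer(epochs),
       lr = lr, seed = as.integer(seed), providers = providers)
}

# Turn a corpus into per-sentence training instances (surfaces + gold tags).
corpus_sentences <- function(corpus) {
  out <- list()
  for (i in seq_len(nrow(corpus))) {
    doc <- corpus$document[[i]]
    ents <- corpus$entities[[i]]
    for (s in unique(doc$tokens$sentence)) {
      surf <- doc$tokens$surface[doc$tokens$sentence == s]
      es <- ents[ents$sentence == s, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        doc_id = doc$doc_id, sentence = s, tokens = surf,
        tags = bio_encode(es, length(surf)),
        triples = corpus$relations[[i]][corpus$relations[[i]]$sentence == s, , drop = FALSE])
    }
  }
  out
}

ner_init_params <- function(config, vocab) {
  T_ <- length(bio_alphabet())
  d_in <- provider_total_dim(config$providers)
  lookup <- purrr::detect(config$providers, ~ isTRUE(.x$trainable))
  params <- list(
    Wm = glorot(d_in, config$merge_dim), bm = numeric(config$merge_dim),
    rnn_f = rnn_init(config$merge_dim, config$hidden, config$recurrence),
    rnn_b = rnn_init(config$merge_dim, config$hidden, config$recurrence),
    We = glorot(2L * config$hidden, T_), be = numeric(T_),
    trans = matrix(0, T_, T_), start = numeric(T_), stop = numeric(T_)
  )
  if (!is.null(lookup)) {
    params$E <- matrix(rnorm(length(vocab) * lookup$dim, sd = 0.3),
                       length(vocab), lookup$dim)
  }
  params
}

# Token representations: [trainable lookup | static providers] -> merge.
ner_embed <- function(params, config, vocab, tokens) {
  stat <- static_embed(config$providers, tokens)
  lookup <- purrr::detect(config$providers, ~ isTRUE(.x$trainable))
  if (!is.null(lookup)) {
    ids <- vocab_ids(vocab, tokens)
    X <- cbind(params$E[ids, , drop = FALSE], stat)
  } else {
    ids <- NULL
    X <- stat
  }
  list(X = X, ids = ids)
}

# Forward pass to emissions; cache intermediates for backprop.
ner_forward <- function(params, config, vocab, tokens) {
  emb <- ner_embed(params, config, vocab, tokens)
  M <- emb$X %*% params$Wm + matrix(params$bm, nrow(emb$X), length(params$bm), byrow = TRUE)
  rnn <- birnn_forward(params$rnn_f, params$rnn_b, M, config$recurrence)
  E <- rnn$H2 %*% params$We + matrix(params$be, nrow(M), length(params$be), byrow = TRUE)
  list(emissions = E, M = M, rnn = rnn, emb = emb)
}

crf_of <- function(params) list(trans = params$trans, start = params$start, stop = params$stop)

# Loss and full parameter gradient for one sentence.
ner_sentence_grad <- function(params, config, vocab, tokens, tags_idx) {
  fw <- ner_forward(params, config, vocab, tokens)
  L <- length(tokens); T_ <- ncol(fw$emissions)
  fb <- crf_forward_backward(fw$emissions, crf_of(params))
  gold <- crf_path_score(fw$emissions, crf_of(params), tags_idx)
  loss <- fb$log_partition - gold
  one_hot <- matrix(0, L, T_); one_hot[cbind(seq_len(L), tags_idx)] <- 1
  dE <- fb$node_marginals - one_hot
  gtrans <- fb$edge_marginals
  if (L > 1L) {
    for (t in 1:(L - 1L)) gtrans[tags_idx[t], tags_idx[t + 1L]] <-
        gtrans[tags_idx[t], tags_idx[t + 1L]] - 1
  }
  gstart <- fb$start_marginals; gstart[tags_idx[1]] <- gstart[tags_idx[1]] - 1
  gstop <- fb$stop_marginals; gstop[tags_idx[L]] <- gstop[tags_idx[L]] - 1
  dH2 <- dE %*% t(params$We)
  gWe <- crossprod(fw$rnn$H2, dE)
  gbe <- colSums(dE)
  bk <- birnn_backward(params$rnn_f, params$rnn_b, fw$M, fw$rnn, dH2, config$recurrence)
  gWm <- crossprod(fw$emb$X, bk$dX)
  gbm <- colSums(bk$dX)
  dX <- bk$dX %*% t(params$Wm)
  grads <- list(Wm = gWm, bm = gbm, rnn_f = bk$gf, rnn_b = bk$gb,
                We = gWe, be = gbe, trans = gtrans, start = gstart, stop = gstop)
  if (!is.null(fw$emb$ids)) {
    lookup <- purrr::detect(config$providers, ~ isTRUE(.x$trainable))
    gE <- matrix(0, nrow(params$E), ncol(params$E))
    dlook <- dX[, seq_len(lookup$dim), drop = FALSE]
    for (t in seq_along(fw$emb$ids)) {
      gE[fw$emb$ids[t], ] <- gE[fw$emb$ids[t], ] + dlook[t, ]
    }
    grads$E <- gE
  }
  list(loss = loss, grads = grads)
}

#' Fit the named-entity tagger
#'
#' Minimizes the CRF negative conditional log-likelihood (log-partition
#' minus gold path score), averaged over sentences, with per-sentence Adam
#' updates. All randomness flows through `config$seed`.
#'
#' @param corpus A `litnet_corpus` with gold entities ([read_corpus_jsonl()]
#'   or [generate_corpus()]).
#' @param config Settings from [ner_config()].
#' @return A fitted `litnet_ner` model.
#' @export
ner_fit <- function(corpus, config = ner_config()) {
  if (is.null(corpus) || nrow(corpus) == 0L) {
    abort("empty training corpus", class = "litnet_empty_corpus")
  }
  labels <- unique(unlist(purrr::map(corpus$entities, "label")))
  bad <- setdiff(labels, ENTITY_LABELS)
  if (length(bad)) {
    abort(paste0("entity label(s) outside the four-type set: ",
                 paste(bad, collapse = ", ")), class = "litnet_schema")
  }
  sents <- corpus_sentences(corpus)
  tags <- bio_alphabet()
  vocab <- c(sort(unique(unlist(purrr::map(sents, "tokens")))), "<unk>")
  set.seed(config$seed)
  params <- ner_init_params(config, vocab)
  state <- adam_init(params)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(sents))
    tot <- 0
    for (k in ord) {
      inst <- sents[[k]]
      tags_idx <- match(inst$tags, tags)
      sg <- ner_sentence_grad(params, config, vocab, inst$tokens, tags_idx)
      tot <- tot + sg$loss
      st <- adam_step(params, sg$grads, state, lr = config$lr)
      params <- st$params; state <- st$state
    }
    losses[ep] <- tot / length(sents)
  }
  structure(list(params = params, config = config, vocab = vocab,
                 tag_vocab = tags, losses = losses,
                 n_sentences = length(sents)),
            class = "litnet_ner")
}

#' @export
print.litnet_ner <- function(x, ...) {
  cat(sprintf(paste0("<litnet_ner: %s recurrence, hidden %d, %d-token vocab, ",
                     "%d epochs, final NLL %.4f>\n"),
              x$config$recurrence, x$config$hidden, length(x$vocab),
              x$config$epochs, tail(x$losses, 1)))
  invisible(x)
}

ner_decode_sentence <- function(model, tokens) {
  fw <- ner_forward(model$params, model$config, model$vocab, tokens)
  vt <- viterbi_decode(fw$emissions, crf_of(model$params), mask = bio_transition_mask())
  model$tag_vocab[vt$tags_idx]
}

#' Predict entity spans
#'
#' Runs the tagger per sentence (masked Viterbi, then BIO decoding) and
#' returns typed spans.
#'
#' @param model A fitted `litnet_ner`.
#' @param x A `litnet_document` or a `litnet_corpus`.
#' @return Tibble with `sentence`, `start`, `end`, `label`, `surface` (plus
#'   `doc_id` for a corpus).
#' @export
predict_entities <- function(model, x) {
  if (inherits(x, "litnet_corpus")) {
    out <- purrr::map(x$document, ~ predict_entities(model, .x))
    return(dplyr::bind_rows(purrr::map2(x$doc_id, out,
                                        ~ dplyr::bind_cols(tibble(doc_id = .x), .y))))
  }
  stopifnot(inherits(x, "litnet_document"))
  res <- list()
  for (s in unique(x$tokens$sentence)) {
    surf <- x$tokens$surface[x$tokens$sentence == s]
    spans <- bio_decode(ner_decode_sentence(model, surf))
    if (nrow(spans)) {
      spans$sentence <- s
      spans$surface <- entity_surface(x, spans$sentence, spans$start, spans$end)
      res[[length(res) + 1L]] <- spans[, c("sentence", "start", "end", "label", "surface")]
    }
  }
  if (!length(res)) return(empty_entities())
  dplyr::bind_rows(res)
}

#' @method tidy litnet_ner
#' @export
tidy.litnet_ner <- function(x, ...) {
  tibble(epoch = seq_along(x$losses), nll = x$losses)
}

#' @method glance litnet_ner
#' @export
glance.litnet_ner <- function(x, ...) {
  tibble(epochs = x$config$epochs, final_nll = tail(x$losses, 1),
         hidden = x$config$hidden, recurrence = x$config$recurrence,
         vocab_size = length(x$vocab), n_sentences = x$n_sentences,
         seed = x$config$seed)
}

#' @method autoplot litnet_ner
#' @export
autoplot.litnet_ner <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$nll)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean NLL per sentence",
                  title = "NER training loss") +
    ggplot2::theme_minimal()
}

#' Save or load a fitted model
#'
#' Single-file checkpoint holding weights, vocabularies and configuration.
#'
#' @param model A `litnet_ner` or `litnet_re` object.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
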