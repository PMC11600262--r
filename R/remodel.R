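# Joint relation extraction over a unified interaction map: a square matrix
# on the token sequence with five relation slots appended. A gold triple
# (s, r, o) lights three cells — entity-entity (head(s), head(o)),
# subject-relation (head(s), slot(r)) and relation-object (slot(r),
# head(o)) — and a predicted map is decoded by requiring all three cells to
# clear the decision threshold. The scorer is a scaled dot-product
# attention between contextualized token representations and learned
# relation-slot embeddings, squashed by a sigmoid and trained with binary
# cross-entropy against the gold map.

N_SLOTS <- 5L  # fixed slot order = PREDICATES

slot_index <- function(predicate, n_tokens) {
  n_tokens + match(predicate, PREDICATES)
}

#' Build the gold interaction map for one sentence
#'
#' @param n_tokens Number of tokens L; the map is `(L+5) x (L+5)` with
#'   relation slots in the fixed order Promotes, Inhibits, Upstream,
#'   Abbreviation, Function after the tokens.
#' @param head_triples Tibble with `s_head`, `predicate`, `o_head`
#'   (0-based head-token indices). The head of a span is its first token.
#' @return Binary matrix; exactly three cells are set per triple.
#' @export
build_gold_interaction_map <- function(n_tokens, head_triples) {
  n <- n_tokens + N_SLOTS
  map <- matrix(0, n, n)
  if (is.null(head_triples) || nrow(head_triples) == 0L) return(map)
  if (any(head_triples$s_head < 0L) || any(head_triples$s_head >= n_tokens) ||
      any(head_triples$o_head < 0L) || any(head_triples$o_head >= n_tokens)) {
    abort("triple head index out of token range", class = "litnet_bad_span")
  }
  if (!all(head_triples$predicate %in% PREDICATES)) {
    abort("predicate outside the five-type set", class = "litnet_schema")
  }
  for (i in seq_len(nrow(head_triples))) {
    s <- head_triples$s_head[i] + 1L
    o <- head_triples$o_head[i] + 1L
    r <- slot_index(head_triples$predicate[i], n_tokens)
    map[s, o] <- 1
    map[s, r] <- 1
    map[r, o] <- 1
  }
  map
}

#' Decode relation triples from an interaction map
#'
#' Emits `(s, r, o)` iff the entity-entity, subject-relation and
#' relation-object cells all reach the threshold, for distinct token
#' indices `s != o`; output sorted by `(s, slot, o)`.
#'
#' @param map `(L+5) x (L+5)` probability matrix.
#' @param threshold Decision threshold in `(0, 1)`.
#' @return Tibble with `s_head`, `predicate`, `o_head` (0-based heads).
#' @export
decode_triples <- function(map, threshold = 0.5) {
  stopifnot(is.matrix(map), nrow(map) == ncol(map),
            threshold > 0, threshold < 1)
  L <- nrow(map) - N_SLOTS
  stopifnot(L >= 0L)
  hits <- map >= threshold
  out <- list()
  if (L >= 1L) {
    for (r in seq_len(N_SLOTS)) {
      slot <- L + r
      # tokens s with (s, slot) on, tokens o with (slot, o) on
      ss <- which(hits[seq_len(L), slot])
      oo <- which(hits[slot, seq_len(L)])
      for (s in ss) for (o in oo) {
        if (s != o && hits[s, o]) {
          out[[length(out) + 1L]] <- tibble(s_head = s - 1L,
                                            predicate = PREDICATES[r],
                                            o_head = o - 1L)
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(s_head = integer(0), predicate = character(0), o_head = integer(0)))
  }
  res <- dplyr::bind_rows(out)
  res$slot <- match(res$predicate, PREDICATES)
  res <- dplyr::arrange(res, .data$s_head, .data$slot, .data$o_head)
  res$slot <- NULL
  res
}

#' Mean binary cross-entropy between interaction maps
#'
#' @param predicted Probability matrix in `[0, 1]`.
#' @param gold Binary matrix of the same shape.
#' @param clamp Probabilities are clamped to `[clamp, 1 - clamp]` for
#'   numerical stability.
#' @return Mean elementwise BCE (non-negative).
#' @export
bce_loss <- function(predicted, gold, clamp = 1e-12) {
  if (!all(dim(predicted) == dim(gold))) {
    abort("interaction map shape mismatch", class = "litnet_shape")
  }
  p <- pmin(pmax(predicted, clamp), 1 - clamp)
  -mean(gold * log(p) + (1 - gold) * log(1 - p))
}

#' RE training configuration
#'
#' The token encoder reuses the embedding-provider stack and bidirectional
#' recurrent contextualizer of the tagger (role information — is this gene
#' mention a subject or an object here? — is contextual, not lexical), then
#' projects tokens and the five learned relation-slot embeddings into a
#' shared attention space.
#'
#' @inheritParams ner_config
#' @param attn_dim Dimension of the query/key attention space.
#' @param threshold Decision threshold for [decode_triples()].
#' @param max_tokens Sentences longer than this are skipped with a warning
#'   (inputs are pre-split per sentence, so this is a guard rail).
#' @return A named list of settings.
#' @export
re_config <- function(hidden = 16L, merge_dim = 24L, attn_dim = 24L,
                      epochs = 40L, lr = 0.005, seed = 1L, threshold = 0.5,
                      max_tokens = 120L,
                      providers = list(lookup_provider(24L), char_window_provider(16L))) {
  list(hidden = as.integer(hidden), merge_dim = as.integer(merge_dim),
       attn_dim = as.integer(attn_dim), recurrence = "tanh",
       epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
       threshold = threshold, max_tokens = as.integer(max_tokens),
       providers = providers)
}

re_init_params <- function(config, vocab) {
  d2h <- 2L * config$hidden
  params <- list(
    Wm = glorot(provider_total_dim(config$providers), config$merge_dim),
    bm = numeric(config$merge_dim),
    rnn_f = rnn_init(config$merge_dim, config$hidden, "tanh"),
    rnn_b = rnn_init(config$merge_dim, config$hidden, "tanh"),
    S = glorot(N_SLOTS, d2h),
    Wq = glorot(d2h, config$attn_dim), bq = numeric(config$attn_dim),
    Wk = glorot(d2h, config$attn_dim), bk = numeric(config$attn_dim)
  )
  lookup <- purrr::detect(config$providers, ~ isTRUE(.x$trainable))
  if (!is.null(lookup)) {
    params$E <- matrix(rnorm(length(vocab) * lookup$dim, sd = 0.3),
                       length(vocab), lookup$dim)
  }
  params
}

re_forward <- function(params, config, vocab, tokens) {
  emb <- ner_embed(params, config, vocab, tokens)
  L <- length(tokens)
  M <- emb$X %*% params$Wm + matrix(params$bm, L, length(params$bm), byrow = TRUE)
  rnn <- birnn_forward(params$rnn_f, params$rnn_b, M, "tanh")
  U <- rbind(rnn$H2, params$S)                        # (L+K) unit representations
  n <- nrow(U)
  Q <- U %*% params$Wq + matrix(params$bq, n, config$attn_dim, byrow = TRUE)
  K <- U %*% params$Wk + matrix(params$bk, n, config$attn_dim, byrow = TRUE)
  scores <- tcrossprod(Q, K) / sqrt(config$attn_dim)
  P <- sigmoid(scores)
  list(P = P, Q = Q, K = K, U = U, M = M, rnn = rnn, emb = emb, L = L)
}

re_sentence_grad <- function(params, config, vocab, tokens, gold_map) {
  fw <- re_forward(params, config, vocab, tokens)
  n <- nrow(fw$P)
  loss <- bce_loss(fw$P, gold_map)
  dscore <- (fw$P - gold_map) / (n * n) / sqrt(config$attn_dim)
  dQ <- dscore %*% fw$K
  dK <- crossprod(dscore, fw$Q)
  gWq <- crossprod(fw$U, dQ); gbq <- colSums(dQ)
  gWk <- crossprod(fw$U, dK); gbk <- colSums(dK)
  dU <- dQ %*% t(params$Wq) + dK %*% t(params$Wk)
  L <- fw$L
  dH2 <- dU[seq_len(L), , drop = FALSE]
  gS <- dU[L + seq_len(N_SLOTS), , drop = FALSE]
  bk_ <- birnn_backward(params$rnn_f, params$rnn_b, fw$M, fw$rnn, dH2, "tanh")
  gWm <- crossprod(fw$emb$X, bk_$dX)
  gbm <- colSums(bk_$dX)
  dX <- bk_$dX %*% t(params$Wm)
  grads <- list(Wm = gWm, bm = gbm, rnn_f = bk_$gf, rnn_b = bk_$gb,
                S = gS, Wq = gWq, bq = gbq, Wk = gWk, bk = gbk)
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

#' Fit the relation extractor
#'
#' Minimizes the mean binary cross-entropy between predicted and gold
#' interaction maps over sentences, with per-sentence Adam updates.
#' Sentences longer than `config$max_tokens` are skipped with a warning
#' (inputs are already pre-split per sentence).
#'
#' @param corpus A `litnet_corpus` with gold relations.
#' @param config Settings from [re_config()].
#' @return A fitted `litnet_re` model.
#' @export
re_fit <- function(corpus, config = re_config()) {
  if (is.null(corpus) || nrow(corpus) == 0L) {
    abort("empty training corpus", class = "litnet_empty_corpus")
  }
  preds <- unique(unlist(purrr::map(corpus$relations, "predicate")))
  bad <- setdiff(preds, PREDICATES)
  if (length(bad)) {
    abort(paste0("predicate(s) outside the five-type set: ",
                 paste(bad, collapse = ", ")), class = "litnet_schema")
  }
  sents <- corpus_sentences(corpus)
  overlong <- vapply(sents, function(s) length(s$tokens) > config$max_tokens, logical(1))
  if (any(overlong)) {
    warn(sprintf("skipping %d overlong sentence(s) (> %d tokens)",
                 sum(overlong), config$max_tokens), class = "litnet_overlong")
    sents <- sents[!overlong]
  }
  vocab <- c(sort(unique(unlist(purrr::map(sents, "tokens")))), "<unk>")
  golds <- lapply(sents, function(s) {
    build_gold_interaction_map(length(s$tokens), triples_to_heads(s$triples))
  })
  set.seed(config$seed)
  params <- re_init_params(config, vocab)
  state <- adam_init(params)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(sents))
    tot <- 0
    for (k in ord) {
      sg <- re_sentence_grad(params, config, vocab, sents[[k]]$tokens, golds[[k]])
      tot <- tot + sg$loss
      st <- adam_step(params, sg$grads, state, lr = config$lr)
      params <- st$params; state <- st$state
    }
    losses[ep] <- tot / length(sents)
  }
  structure(list(params = params, config = config, vocab = vocab,
                 losses = losses, n_sentences = length(sents)),
            class = "litnet_re")
}

#' @export
print.litnet_re <- function(x, ...) {
  cat(sprintf("<litnet_re: hidden %d, attn %d, threshold %.2f, %d epochs, final BCE %.5f>\n",
              x$config$hidden, x$config$attn_dim, x$config$threshold,
              x$config$epochs, tail(x$losses, 1)))
  invisible(x)
}

#' Score the interaction map for one sentence
#'
#' @param model A fitted `litnet_re`.
#' @param tokens Character vector of token surfaces.
#' @return `(L+5) x (L+5)` matrix of probabilities in `(0, 1)`.
#' @export
score_interaction_map <- function(model, tokens) {
  stopifnot(length(tokens) >= 1L)
  re_forward(model$params, model$config, model$vocab, tokens)$P
}

#' Predict head-level relation triples
#'
#' Scores and decodes the interaction map per sentence.
#'
#' @param model A fitted `litnet_re`.
#' @param x A `litnet_document` or `litnet_corpus`.
#' @param threshold Decision threshold (default from the model config).
#' @return Tibble with `sentence`, `s_head`, `predicate`, `o_head` (plus
#'   `doc_id` for a corpus).
#' @export
predict_triples <- function(model, x, threshold = NULL) {
  threshold <- threshold %||% model$config$threshold
  if (inherits(x, "litnet_corpus")) {
    out <- purrr::map(x$document, ~ predict_triples(model, .x, threshold))
    return(dplyr::bind_rows(purrr::map2(x$doc_id, out,
                                        ~ dplyr::bind_cols(tibble(doc_id = .x), .y))))
  }
  stopifnot(inherits(x, "litnet_document"))
  res <- list()
  for (s in unique(x$tokens$sentence)) {
    surf <- x$tokens$surface[x$tokens$sentence == s]
    if (length(surf) > model$config$max_tokens) {
      warn(sprintf("skipping overlong sentence %d of %s", s, x$doc_id),
           class = "litnet_overlong")
      next
    }
    tr <- decode_triples(score_interaction_map(model, surf), threshold)
    if (nrow(tr)) {
      tr <- dplyr::bind_cols(tibble(sentence = rep(s, nrow(tr))), tr)
      res[[length(res) + 1L]] <- tr
    }
  }
  if (!length(res)) {
    return(tibble(sentence = integer(0), s_head = integer(0),
                  predicate = character(0), o_head = integer(0)))
  }
  dplyr::bind_rows(res)
}

#' @method tidy litnet_re
#' @export
tidy.litnet_re <- function(x, ...) {
  tibble(epoch = seq_along(x$losses), bce = x$losses)
}

#' @method glance litnet_re
#' @export
glance.litnet_re <- function(x, ...) {
  tibble(epochs = x$config$epochs, final_bce = tail(x$losses, 1),
         hidden = x$config$hidden, attn_dim = x$config$attn_dim,
         threshold = x$config$threshold, vocab_size = length(x$vocab),
         n_sentences = x$n_sentences, seed = x$config$seed)
}

#' @method autoplot litnet_re
#' @export
autoplot.litnet_re <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$bce)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean BCE per sentence",
                  title = "RE training loss") +
    ggplot2::theme_minimal()
}
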