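# Pluggable token-embedding providers. A provider maps one sentence's token
# surfaces to a matrix of real vectors (one row per token, fixed dimension).
# Two desk-scale providers ship: a trainable lookup table (weights live in
# the model) and a deterministic character-window provider (hashed character
# trigrams + word-shape flags) that supplies subword morphology. Pre-trained
# contextual embeddings can be plugged in as a static provider.

#' Token embedding providers
#'
#' `lookup_provider()` declares a trainable lookup-table embedding whose
#' weight matrix is initialized and updated by the model fit.
#' `char_window_provider()` is a deterministic, non-trainable provider
#' encoding word shape (all-caps, initial-cap, digit, hyphen flags) plus
#' L2-normalized hashed character trigram counts; it gives related surface
#' forms (`WNT4`, `Wnt-4`) nearby representations. `static_provider()` wraps
#' any user function `encode(tokens) -> matrix`, e.g. precomputed contextual
#' embeddings.
#'
#' @param dim Embedding dimension.
#' @param encode Function mapping a character vector of token surfaces to an
#'   `length(tokens) x dim` numeric matrix.
#' @param name Provider name (must be unique within a model).
#' @return A `litnet_provider` object.
#' @export
lookup_provider <- function(dim = 24L) {
  structure(list(name = "lookup", dim = as.integer(dim), trainable = TRUE),
            class = "litnet_provider")
}

#' @rdname lookup_provider
#' @export
char_window_provider <- function(dim = 16L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 8L)
  structure(list(name = "char", dim = dim, trainable = FALSE,
                 encode = function(tokens) char_window_encode(tokens, dim)),
            class = "litnet_provider")
}

#' @rdname lookup_provider
#' @export
static_provider <- function(name, dim, encode) {
  stopifnot(is.function(encode))
  structure(list(name = name, dim = as.integer(dim), trainable = FALSE, encode = encode),
            class = "litnet_provider")
}

char_window_encode <- function(tokens, dim) {
  nhash <- dim - 4L
  out <- matrix(0, length(tokens), dim)
  for (i in seq_along(tokens)) {
    w <- tokens[i]
    flags <- c(w == toupper(w) && grepl("[A-Z]", w),
               grepl("^[A-Z]", w),
               grepl("[0-9]", w),
               grepl("-", w, fixed = TRUE))
    padded <- paste0("^", tolower(w), "$")
    cp <- utf8ToInt(padded)
    v <- numeric(nhash)
    if (length(cp) >= 3L) {
      for (k in seq_len(length(cp) - 2L)) {
        h <- (cp[k] * 7919L + cp[k + 1L] * 31L + cp[k + 2L]) %% nhash
        v[h + 1L] <- v[h + 1L] + 1
      }
    } else {
      h <- sum(cp) %% nhash
      v[h + 1L] <- 1
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    out[i, ] <- c(as.numeric(flags), v)
  }
  out
}

# Assemble the static (non-trainable) part of the token representation.
static_embed <- function(providers, tokens) {
  mats <- lapply(providers, function(p) {
    if (isTRUE(p$trainable)) NULL else p$encode(tokens)
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!length(mats)) return(matrix(0, length(tokens), 0L))
  do.call(cbind, mats)
}

provider_total_dim <- function(providers) sum(vapply(providers, `[[`, integer(1), "dim"))

vocab_ids <- function(vocab, tokens) {
  ix <- match(tokens, vocab)
  ix[is.na(ix)] <- match("<unk>", vocab)
  ix
}
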