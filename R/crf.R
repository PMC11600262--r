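# Linear-chain CRF: forward-algorithm normalization, forward-backward
# marginals (training gradients), and masked Viterbi decoding.
#
# A CRF instance is a list with
#   trans : T x T transition score matrix (from row -> to column)
#   start : length-T start scores
#   stop  : length-T stop scores
# Emissions are an L x T matrix for one sentence. The path score of a tag
# sequence y is start[y1] + sum_t emis[t, yt] + sum_t trans[y_{t-1}, y_t] +
# stop[yL]; the partition sums exp(path score) over all T^L sequences.

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

col_logsumexp <- function(M) {
  m <- apply(M, 2, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) {
    out[ok] <- m[ok] + log(colSums(exp(sweep(M[, ok, drop = FALSE], 2, m[ok]))))
  }
  out
}

check_emissions <- function(emissions) {
  if (!is.matrix(emissions) || nrow(emissions) < 1L) {
    abort("emissions must be a matrix with at least one row", class = "litnet_crf")
  }
  if (!all(is.finite(emissions))) {
    abort("non-finite emission scores", class = "litnet_crf")
  }
}

#' CRF log-partition (forward algorithm)
#'
#' Computes \eqn{\log \sum_y \exp(\mathrm{score}(y))} over all \eqn{T^L} tag
#' sequences, where a path scores the sum of its emissions, transitions and
#' start/stop scores.
#'
#' @param emissions L x T matrix of per-token tag scores.
#' @param crf List with `trans` (T x T), `start`, `stop` (length-T vectors).
#' @return Log-partition scalar.
#' @export
crf_log_partition <- function(emissions, crf) {
  check_emissions(emissions)
  L <- nrow(emissions)
  alpha <- crf$start + emissions[1, ]
  if (L > 1L) {
    for (t in 2:L) {
      alpha <- col_logsumexp(alpha + crf$trans) + emissions[t, ]
    }
  }
  logsumexp(alpha + crf$stop)
}

crf_path_score <- function(emissions, crf, tags_idx) {
  L <- nrow(emissions)
  s <- crf$start[tags_idx[1]] + sum(emissions[cbind(seq_len(L), tags_idx)]) +
    crf$stop[tags_idx[L]]
  if (L > 1L) {
    s <- s + sum(crf$trans[cbind(tags_idx[-L], tags_idx[-1])])
  }
  s
}

# Forward-backward: returns log-partition plus expected-count marginals used
# by the NLL gradient (d NLL / d emissions = node marginals - gold one-hot,
# and likewise for transitions and start/stop).
crf_forward_backward <- function(emissions, crf) {
  check_emissions(emissions)
  L <- nrow(emissions); T_ <- ncol(emissions)
  alpha <- matrix(0, L, T_); beta <- matrix(0, L, T_)
  alpha[1, ] <- crf$start + emissions[1, ]
  if (L > 1L) {
    for (t in 2:L) alpha[t, ] <- col_logsumexp(alpha[t - 1L, ] + crf$trans) + emissions[t, ]
    beta[L, ] <- crf$stop
    for (t in (L - 1L):1L) {
      beta[t, ] <- col_logsumexp(t(crf$trans) + (beta[t + 1L, ] + emissions[t + 1L, ]))
    }
  } else {
    beta[1, ] <- crf$stop
  }
  logZ <- logsumexp(alpha[L, ] + crf$stop)
  node <- exp(alpha + beta - logZ)
  edge <- matrix(0, T_, T_)
  if (L > 1L) {
    for (t in 1:(L - 1L)) {
      lp <- outer(alpha[t, ], beta[t + 1L, ] + emissions[t + 1L, ], "+") + crf$trans - logZ
      edge <- edge + exp(lp)
    }
  }
  list(log_partition = logZ, node_marginals = node, edge_marginals = edge,
       start_marginals = node[1, ], stop_marginals = node[L, ])
}

#' BIO transition mask
#'
#' Hard constraints used at decode time: a transition into `I-X` is valid
#' only from `B-X` or `I-X`, and no sequence may start with `I-X`. Masked
#' moves score `-Inf` during Viterbi, so decoded sequences are always
#' well-formed BIO.
#'
#' @param tags Tag alphabet (default [bio_alphabet()]).
#' @return List with `trans` (T x T logical, `TRUE` = forbidden) and
#'   `start` (length-T logical).
#' @export
bio_transition_mask <- function(tags = bio_alphabet()) {
  T_ <- length(tags)
  forbid <- matrix(FALSE, T_, T_, dimnames = list(tags, tags))
  start_forbid <- rep(FALSE, T_); names(start_forbid) <- tags
  for (j in seq_len(T_)) {
    if (startsWith(tags[j], "I-")) {
      lab <- substring(tags[j], 3)
      ok_from <- tags %in% c(paste0("B-", lab), paste0("I-", lab))
      forbid[!ok_from, j] <- TRUE
      start_forbid[j] <- TRUE
    }
  }
  list(trans = forbid, start = start_forbid)
}

#' Viterbi decoding
#'
#' Returns a maximum-scoring tag sequence, optionally under a hard
#' transition mask (used to enforce BIO validity).
#'
#' @inheritParams crf_log_partition
#' @param mask Optional mask from [bio_transition_mask()]; masked
#'   transitions and start tags contribute `-Inf`.
#' @return List with `tags_idx` (integer path, 1-based tag indices) and
#'   `score`.
#' @export
viterbi_decode <- function(emissions, crf, mask = NULL) {
  check_emissions(emissions)
  L <- nrow(emissions); T_ <- ncol(emissions)
  trans <- crf$trans; start <- crf$start
  if (!is.null(mask)) {
    trans[mask$trans] <- -Inf
    start[mask$start] <- -Inf
  }
  delta <- start + emissions[1, ]
  back <- matrix(0L, L, T_)
  if (L > 1L) {
    for (t in 2:L) {
      M <- delta + trans                  # M[i, j]: best-so-far ending i, move to j
      back[t, ] <- max.col(t(M), ties.method = "first")
      delta <- M[cbind(back[t, ], seq_len(T_))] + emissions[t, ]
    }
  }
  final <- delta + crf$stop
  if (!any(is.finite(final))) {
    abort("all tag paths are masked", class = "litnet_crf")
  }
  j <- which.max(final)
  path <- integer(L)
  path[L] <- j
  if (L > 1L) {
    for (t in L:2) path[t - 1L] <- back[t, path[t]]
  }
  list(tags_idx = path, score = final[j])
}
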