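# Single-layer recurrent cells (plain tanh and GRU) with hand-derived
# backpropagation-through-time, plus a bidirectional wrapper and an Adam
# optimizer over nested parameter lists. Hidden sizes here are small (tens),
# so dense base-R matrix algebra is the right tool.

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

rnn_init <- function(input_dim, hidden, recurrence = c("tanh", "gru")) {
  recurrence <- match.arg(recurrence)
  if (recurrence == "tanh") {
    list(W = glorot(input_dim, hidden), U = glorot(hidden, hidden), b = numeric(hidden))
  } else {
    list(Wz = glorot(input_dim, hidden), Uz = glorot(hidden, hidden), bz = numeric(hidden),
         Wr = glorot(input_dim, hidden), Ur = glorot(hidden, hidden), br = numeric(hidden),
         Wc = glorot(input_dim, hidden), Uc = glorot(hidden, hidden), bc = numeric(hidden))
  }
}

sigmoid <- function(x) 1 / (1 + exp(-x))

rnn_forward <- function(p, X, recurrence) {
  L <- nrow(X); H <- length(p$b %||% p$bz)
  Hs <- matrix(0, L, H)
  h <- numeric(H)
  if (recurrence == "tanh") {
    XW <- X %*% p$W
    for (t in seq_len(L)) {
      h <- tanh(XW[t, ] + h %*% p$U + p$b)
      Hs[t, ] <- h
    }
    list(H = Hs, cache = NULL)
  } else {
    Z <- matrix(0, L, H); R <- matrix(0, L, H); C <- matrix(0, L, H)
    XWz <- X %*% p$Wz; XWr <- X %*% p$Wr; XWc <- X %*% p$Wc
    for (t in seq_len(L)) {
      z <- sigmoid(XWz[t, ] + h %*% p$Uz + p$bz)
      r <- sigmoid(XWr[t, ] + h %*% p$Ur + p$br)
      cc <- tanh(XWc[t, ] + (r * h) %*% p$Uc + p$bc)
      h <- (1 - z) * h + z * cc
      Z[t, ] <- z; R[t, ] <- r; C[t, ] <- cc; Hs[t, ] <- h
    }
    list(H = Hs, cache = list(Z = Z, R = R, C = C))
  }
}

rnn_backward <- function(p, X, fwd, dH, recurrence) {
  L <- nrow(X); H <- ncol(fwd$H)
  Hs <- fwd$H
  dX <- matrix(0, L, ncol(X))
  hprev <- function(t) if (t > 1L) Hs[t - 1L, ] else numeric(H)
  if (recurrence == "tanh") {
    g <- list(W = matrix(0, nrow(p$W), H), U = matrix(0, H, H), b = numeric(H))
    dh_next <- numeric(H)
    for (t in L:1) {
      dh <- dH[t, ] + dh_next
      da <- dh * (1 - Hs[t, ]^2)
      g$W <- g$W + tcrossprod(X[t, ], da)[, , drop = FALSE]
      g$U <- g$U + tcrossprod(hprev(t), da)
      g$b <- g$b + da
      dX[t, ] <- da %*% t(p$W)
      dh_next <- as.numeric(da %*% t(p$U))
    }
    list(grads = g, dX = dX)
  } else {
    Z <- fwd$cache$Z; R <- fwd$cache$R; C <- fwd$cache$C
    g <- list(Wz = matrix(0, nrow(p$Wz), H), Uz = matrix(0, H, H), bz = numeric(H),
              Wr = matrix(0, nrow(p$Wr), H), Ur = matrix(0, H, H), br = numeric(H),
              Wc = matrix(0, nrow(p$Wc), H), Uc = matrix(0, H, H), bc = numeric(H))
    dh_next <- numeric(H)
    for (t in L:1) {
      dh <- dH[t, ] + dh_next
      hp <- hprev(t)
      z <- Z[t, ]; r <- R[t, ]; cc <- C[t, ]
      dz <- dh * (cc - hp)
      dc <- dh * z
      dh_prev <- dh * (1 - z)
      da_c <- dc * (1 - cc^2)
      g$Wc <- g$Wc + tcrossprod(X[t, ], da_c)
      g$Uc <- g$Uc + tcrossprod(r * hp, da_c)
      g$bc <- g$bc + da_c
      drh <- as.numeric(da_c %*% t(p$Uc))
      dr <- drh * hp
      dh_prev <- dh_prev + drh * r
      da_z <- dz * z * (1 - z)
      g$Wz <- g$Wz + tcrossprod(X[t, ], da_z)
      g$Uz <- g$Uz + tcrossprod(hp, da_z)
      g$bz <- g$bz + da_z
      dh_prev <- dh_prev + as.numeric(da_z %*% t(p$Uz))
      da_r <- dr * r * (1 - r)
      g$Wr <- g$Wr + tcrossprod(X[t, ], da_r)
      g$Ur <- g$Ur + tcrossprod(hp, da_r)
      g$br <- g$br + da_r
      dh_prev <- dh_prev + as.numeric(da_r %*% t(p$Ur))
      dX[t, ] <- da_c %*% t(p$Wc) + da_z %*% t(p$Wz) + da_r %*% t(p$Wr)
      dh_next <- dh_prev
    }
    list(grads = g, dX = dX)
  }
}

# Bidirectional wrapper: forward pass over X and over the reversed sequence,
# hidden states concatenated columnwise.
birnn_forward <- function(pf, pb, X, recurrence) {
  L <- nrow(X)
  f <- rnn_forward(pf, X, recurrence)
  b <- rnn_forward(pb, X[L:1, , drop = FALSE], recurrence)
  list(H2 = cbind(f$H, b$H[L:1, , drop = FALSE]), f = f, b = b)
}

birnn_backward <- function(pf, pb, X, fwd, dH2, recurrence) {
  L <- nrow(X); H <- ncol(fwd$f$H)
  dHf <- dH2[, seq_len(H), drop = FALSE]
  dHb <- dH2[, H + seq_len(H), drop = FALSE][L:1, , drop = FALSE]
  bf <- rnn_backward(pf, X, fwd$f, dHf, recurrence)
  bb <- rnn_backward(pb, X[L:1, , drop = FALSE], fwd$b, dHb, recurrence)
  list(gf = bf$grads, gb = bb$grads, dX = bf$dX + bb$dX[L:1, , drop = FALSE])
}

# Adam over nested lists of numeric arrays ----------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.02, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), upd)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- upd(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}
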