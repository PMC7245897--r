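# Neural primitives shared by the tagging and relation models.
# Hidden states are columns; a sentence of T tokens encoded by the
# BiLSTM is a (2 * lstm_state) x T matrix.

softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# column-wise softmax with max subtraction
softmax_cols <- function(M) {
  if (!length(M)) return(M)
  mx <- apply(M, 2L, max)
  Z <- exp(sweep(M, 2L, mx, "-"))
  sweep(Z, 2L, colSums(Z), "/")
}

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

#' Encode a token vector sequence with a bidirectional LSTM
#'
#' Runs one LSTM left-to-right and a second right-to-left over the input
#' columns and concatenates their states per time step, so every token's
#' hidden state combines past and future context. Deterministic in
#' evaluation mode; during training an inverted-dropout mask is applied
#' to the inputs of the recurrent layer.
#'
#' @param X `embed_dim x T` input matrix (T >= 1).
#' @param params BiLSTM parameter list with elements `fwd` and `bwd`,
#'   each holding `Wx` (`4S x d`), `Wh` (`4S x S`), `b` (`4S`).
#' @param dropout Dropout rate applied to `X` when `training = TRUE`.
#' @param training Logical; enables dropout.
#' @return List with `H` (`2S x T` hidden states) and the internal
#'   caches needed for backpropagation.
#' @export
encode_bilstm <- function(X, params, dropout = 0, training = FALSE) {
  if (!is.matrix(X) || ncol(X) < 1L) stop("encoder input must be non-empty")
  mask <- NULL
  if (training && dropout > 0) {
    mask <- matrix(rbinom(length(X), 1L, 1 - dropout), nrow(X), ncol(X)) /
      (1 - dropout)
    X <- X * mask
  }
  Tn <- ncol(X)
  f <- lstm_forward_cpp(X, params$fwd$Wx, params$fwd$Wh, params$fwd$b)
  Xr <- X[, Tn:1, drop = FALSE]
  b <- lstm_forward_cpp(Xr, params$bwd$Wx, params$bwd$Wh, params$bwd$b)
  Hb <- b$H[, Tn:1, drop = FALSE]
  list(H = rbind(f$H, Hb), X = X, fcache = f, bcache = b, mask = mask)
}

# backward through encode_bilstm; dH is 2S x T
bilstm_backward <- function(dH, enc, params) {
  S <- nrow(enc$fcache$H)
  Tn <- ncol(enc$X)
  dHf <- dH[seq_len(S), , drop = FALSE]
  dHb <- dH[S + seq_len(S), , drop = FALSE]
  gf <- lstm_backward_cpp(dHf, enc$X, params$fwd$Wx, params$fwd$Wh,
                          enc$fcache)
  Xr <- enc$X[, Tn:1, drop = FALSE]
  gb <- lstm_backward_cpp(dHb[, Tn:1, drop = FALSE], Xr, params$bwd$Wx,
                          params$bwd$Wh, enc$bcache)
  list(fwd = list(Wx = gf$dWx, Wh = gf$dWh, b = gf$db),
       bwd = list(Wx = gb$dWx, Wh = gb$dWh, b = gb$db))
}

init_bilstm_params <- function(d, S) {
  list(fwd = list(Wx = glorot(4L * S, d), Wh = glorot(4L * S, S),
                  b = init_lstm_bias(S)),
       bwd = list(Wx = glorot(4L * S, d), Wh = glorot(4L * S, S),
                  b = init_lstm_bias(S)))
}

# forget-gate bias at 1 (standard LSTM initialization)
init_lstm_bias <- function(S) {
  b <- numeric(4L * S)
  b[(S + 1L):(2L * S)] <- 1
  b
}

#' Bilinear knowledge-base attention over related-entity vectors
#'
#' Given a hidden state `h` and a set `V` of vectors of KB-related
#' entities, computes attention weights `alpha_i` proportional to
#' `exp(v_i' U h)` (softmax with max-subtraction for numerical
#' stability), the KB summary `s = sum_i alpha_i v_i`, and the fused
#' state `h' = h + s`. When the KB-vector dimension differs from the
#' hidden dimension, `s` is first projected by the linear map `P`
#' (`length(h) x nrow(V)`). When `V` is empty the KB contributes
#' nothing: `s = 0` and `h'` is returned bit-identical to `h`.
#'
#' @param h Hidden state vector.
#' @param V `dv x K` matrix of KB entity vectors (columns), or a
#'   [kb_vectors()] result; `K = 0` allowed.
#' @param U Bilinear form, `dv x length(h)`.
#' @param P Optional projection applied to `s` before fusion; required
#'   when `dv != length(h)`.
#' @return List with `alpha` (length K), `s` (length `dv`), and
#'   `h_prime`.
#' @export
kb_attention <- function(h, V, U, P = NULL) {
  if (is.list(V) && !is.null(V$vectors)) V <- V$vectors
  if (is.null(V) || !length(V) || NCOL(V) == 0L) {
    dv <- if (is.matrix(V)) nrow(V) else length(h)
    return(list(alpha = numeric(0), s = numeric(dv), h_prime = h))
  }
  V <- as.matrix(V)
  if (nrow(U) != nrow(V) || ncol(U) != length(h)) {
    stop("bilinear form U must be dv x dh (",
         nrow(V), " x ", length(h), ")")
  }
  logits <- unname(drop(crossprod(V, U %*% h)))
  alpha <- softmax_vec(logits)
  s <- unname(drop(V %*% alpha))
  if (length(s) == length(h)) {
    hp <- h + if (is.null(P)) s else drop(P %*% s)
  } else {
    if (is.null(P)) {
      stop("KB vector dimension ", length(s), " differs from hidden ",
           "dimension ", length(h), "; a projection P is required")
    }
    hp <- h + drop(P %*% s)
  }
  list(alpha = alpha, s = s, h_prime = hp)
}

#' Attentive pooling of per-token states into a sentence vector
#'
#' Word-level attention with a learned context vector: token scores
#' `u' tanh(g_t)` are softmax-normalized into weights that form a convex
#' combination of the fused states. Identical states therefore pool to
#' the common state, and a single state is returned unchanged.
#'
#' @param G `dh x T` matrix of (fused) per-token states.
#' @param u Context vector of length `dh`.
#' @return List with `weights` (length T, summing to 1) and `vector`
#'   (length `dh`).
#' @export
merge_sentence <- function(G, u) {
  G <- as.matrix(G)
  stopifnot(ncol(G) >= 1L, length(u) == nrow(G))
  scores <- drop(crossprod(tanh(G), u))
  w <- softmax_vec(scores)
  list(weights = w, vector = drop(G %*% w))
}

#' Softmax classification of a state vector
#'
#' `probs = softmax(W h + b)`; the predicted label is the argmax, with
#' ties broken toward the lowest label index so decoding is
#' deterministic.
#'
#' @param h Input vector.
#' @param W `|Y| x length(h)` weight matrix.
#' @param b Optional bias (defaults to zero).
#' @param labels Optional label names for the output.
#' @return List with `probs`, `argmax` (1-based index), and `label`
#'   (when `labels` given).
#' @export
classify_softmax <- function(h, W, b = NULL, labels = NULL) {
  if (ncol(W) != length(h)) stop("W has ", ncol(W), " columns; input has ",
                                 length(h))
  if (is.null(b)) b <- numeric(nrow(W))
  p <- softmax_vec(drop(W %*% h) + b)
  k <- which.max(p)   # which.max takes the first (lowest-index) maximum
  out <- list(probs = p, argmax = k)
  if (!is.null(labels)) out$label <- labels[k]
  out
}

#' Viterbi decoding of a linear-chain CRF
#'
#' Finds the tag sequence maximizing the score
#' `start[y1] + sum_t em[t, y_t] + sum_t trans[y_{t-1}, y_t] + stop[yT]`
#' by dynamic programming; exact for any length. Ties are broken toward
#' the lowest tag index.
#'
#' @param emissions `T x K` matrix of per-token tag scores.
#' @param transitions `K x K` matrix of transition scores
#'   (`transitions[i, j]` scores tag `i` followed by tag `j`).
#' @param start,stop Optional length-`K` boundary scores (default zero).
#' @return Integer vector of length `T` with the argmax tag indices.
#' @export
crf_decode <- function(emissions, transitions, start = NULL, stop = NULL) {
  emissions <- as.matrix(emissions)
  Tn <- nrow(emissions); K <- ncol(emissions)
  stopifnot(Tn >= 1L, all(dim(transitions) == c(K, K)))
  if (is.null(start)) start <- numeric(K)
  if (is.null(stop)) stop <- numeric(K)
  delta <- start + emissions[1L, ]
  back <- matrix(0L, Tn, K)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      cand <- delta + transitions          # K x K: prev tag x next tag
      back[t, ] <- apply(cand, 2L, which.max)
      delta <- cand[cbind(back[t, ], seq_len(K))] + emissions[t, ]
    }
  }
  delta <- delta + stop
  y <- integer(Tn)
  y[Tn] <- which.max(delta)
  if (Tn > 1L) {
    for (t in Tn:2) y[t - 1L] <- back[t, y[t]]
  }
  y
}

# log-sum-exp over a vector
lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# CRF negative log-likelihood and its gradients for one sentence.
# gold is an integer tag sequence. Returns marginals-based gradients for
# emissions, transitions, start and stop scores.
crf_nll_grad <- function(emissions, transitions, start, stop, gold) {
  Tn <- nrow(emissions); K <- ncol(emissions)
  # forward (alpha) and backward (beta) in log space
  la <- matrix(-Inf, Tn, K)
  la[1L, ] <- start + emissions[1L, ]
  if (Tn > 1L) {
    for (t in 2:Tn) {
      for (k in seq_len(K)) {
        la[t, k] <- lse(la[t - 1L, ] + transitions[, k]) + emissions[t, k]
      }
    }
  }
  logZ <- lse(la[Tn, ] + stop)
  lb <- matrix(0, Tn, K)
  lb[Tn, ] <- stop
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) {
      for (k in seq_len(K)) {
        lb[t, k] <- lse(transitions[k, ] + emissions[t + 1L, ] + lb[t + 1L, ])
      }
    }
  }
  marg <- exp(la + lb - logZ)              # T x K unary marginals
  d_em <- marg
  d_start <- marg[1L, ]
  d_stop <- marg[Tn, ]
  d_tr <- matrix(0, K, K)
  if (Tn > 1L) {
    for (t in 2:Tn) {
      pair <- outer(la[t - 1L, ], emissions[t, ] + lb[t, ], "+") + transitions
      d_tr <- d_tr + exp(pair - logZ)
    }
  }
  # subtract gold counts
  score <- start[gold[1L]] + sum(emissions[cbind(seq_len(Tn), gold)]) +
    stop[gold[Tn]]
  for (t in seq_len(Tn)) d_em[t, gold[t]] <- d_em[t, gold[t]] - 1
  d_start[gold[1L]] <- d_start[gold[1L]] - 1
  d_stop[gold[Tn]] <- d_stop[gold[Tn]] - 1
  if (Tn > 1L) {
    for (t in 2:Tn) {
      score <- score + transitions[gold[t - 1L], gold[t]]
      d_tr[gold[t - 1L], gold[t]] <- d_tr[gold[t - 1L], gold[t]] - 1
    }
  }
  list(nll = logZ - score, d_emissions = d_em, d_transitions = d_tr,
       d_start = d_start, d_stop = d_stop)
}
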