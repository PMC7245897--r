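# Relation classifier: embed -> BiLSTM -> per-step bilinear KB attention
# -> attentive pooling -> softmax. Gradients are hand-derived and checked
# against numerical differentiation in the test suite.

#' Select the input token window for a relation instance
#'
#' Two constructions: `whole_sentence` uses every token; in
#' `between_entities` mode the window runs from the textually first
#' entity's first token minus `window_expand` through the textually last
#' entity's last token plus `window_expand`, clamped to the sentence —
#' the expansion keeps enough context when the pair is adjacent. Entity
#' tokens are always included.
#'
#' @param sentence Sentence element of a [standoff_document()].
#' @param e1,e2 Entity rows (data frames with `char_start`, `char_end`)
#'   lying in the sentence.
#' @param mode `"whole_sentence"` or `"between_entities"`.
#' @param window_expand Non-negative context size.
#' @return Integer vector of token indices into `sentence$tokens`.
#' @export
build_relation_input <- function(sentence, e1, e2,
                                 mode = c("between_entities", "whole_sentence"),
                                 window_expand = 2L) {
  mode <- match.arg(mode)
  toks <- sentence$tokens
  Tn <- nrow(toks)
  if (mode == "whole_sentence") return(seq_len(Tn))
  tok_range <- function(e) {
    idx <- which(toks$char_start >= e$char_start & toks$char_end <= e$char_end)
    if (!length(idx)) stop("entity at [", e$char_start, ",", e$char_end,
                           ") is outside the sentence")
    range(idx)
  }
  r1 <- tok_range(e1); r2 <- tok_range(e2)
  lo <- max(1L, min(r1[1L], r2[1L]) - window_expand)
  hi <- min(Tn, max(r1[2L], r2[2L]) + window_expand)
  seq.int(lo, hi)
}

#' Initialize relation-model parameters
#'
#' BiLSTM weights use Glorot initialization with forget-gate bias 1; the
#' bilinear form `U` and the pooling context vector start small and
#' random; the KB projection `P` starts identity-like (stacked scaled
#' identity blocks when the hidden dimension is a multiple of the KB
#' dimension) so that fusion begins close to plain addition.
#'
#' @param cfg A [model_config()].
#' @param n_labels Number of output labels.
#' @return Named list of parameter tensors.
#' @export
init_relation_params <- function(cfg, n_labels) {
  set.seed(cfg$seed)
  d <- cfg$embed_dim
  dh <- 2L * cfg$lstm_state
  p <- list(lstm = init_bilstm_params(d, cfg$lstm_state),
            u = runif(dh, -0.1, 0.1),
            W = glorot(n_labels, dh),
            b = numeric(n_labels))
  if (cfg$use_kb) {
    p$U <- glorot(d, dh) * 0.1
    p$P <- init_projection(dh, d)
  }
  p
}

# identity-like projection dv -> dh
init_projection <- function(dh, dv) {
  if (dh %% dv == 0L) {
    k <- dh %/% dv
    P <- do.call(rbind, replicate(k, diag(dv), simplify = FALSE)) / k
  } else if (dv %% dh == 0L) {
    k <- dv %/% dh
    P <- do.call(cbind, replicate(k, diag(dh), simplify = FALSE)) / k
  } else {
    P <- glorot(dh, dv)
  }
  P
}

relation_forward <- function(params, X, V, cfg, y = NULL, training = FALSE) {
  enc <- encode_bilstm(X, params$lstm, cfg$dropout, training)
  H <- enc$H
  use_kb <- cfg$use_kb && !is.null(V) && NCOL(V) > 0L
  if (use_kb) {
    L <- crossprod(V, params$U %*% H)          # K x T logits
    A <- softmax_cols(L)
    Smat <- V %*% A                            # d x T
    G <- H + params$P %*% Smat
  } else {
    A <- NULL; Smat <- NULL
    G <- H
  }
  mrg <- merge_sentence(G, params$u)
  logits <- drop(params$W %*% mrg$vector) + params$b
  probs <- softmax_vec(logits)
  loss <- if (!is.null(y)) -log(max(probs[y], 1e-12)) else NA_real_
  list(enc = enc, H = H, A = A, Smat = Smat, G = G, mrg = mrg,
       probs = probs, pred = which.max(probs), loss = loss,
       use_kb = use_kb, V = V)
}

relation_backward <- function(params, fw, X, cfg, y) {
  probs <- fw$probs
  dlogits <- probs
  dlogits[y] <- dlogits[y] - 1
  m <- fw$mrg$vector
  w <- fw$mrg$weights
  G <- fw$G
  gr <- list(W = outer(dlogits, m), b = dlogits)
  dm <- drop(crossprod(params$W, dlogits))
  # attentive pooling backward
  tG <- tanh(G)
  dw <- drop(crossprod(G, dm))
  dG <- outer(dm, w)
  dscores <- w * (dw - sum(w * dw))
  dG <- dG + outer(params$u, dscores) * (1 - tG^2)
  gr$u <- drop(tG %*% dscores)
  # KB attention backward
  if (fw$use_kb) {
    V <- fw$V; A <- fw$A
    dSmat <- crossprod(params$P, dG)           # d x T
    gr$P <- dG %*% t(fw$Smat)
    dA <- crossprod(V, dSmat)                  # K x T
    dL <- A * sweep(dA, 2L, colSums(A * dA), "-")
    gr$U <- V %*% dL %*% t(fw$H)
    dH <- dG + crossprod(params$U, V %*% dL)
  } else {
    dH <- dG
    if (cfg$use_kb) {
      gr$U <- matrix(0, nrow(params$U), ncol(params$U))
      gr$P <- matrix(0, nrow(params$P), ncol(params$P))
    }
  }
  gr$lstm <- bilstm_backward(dH, fw$enc, params$lstm)
  gr
}
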