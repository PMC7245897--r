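# Two-stage entity extraction.
# Stage 1 tags token positions (BIOE) with a BiLSTM over token vectors,
# per-token KB attention when enabled, and either independent softmaxes
# or a linear-chain CRF over the tag sequence.
# Stage 2 classifies each decoded span's type (Gene/Protein) from its
# entity representation fused with KB attention over its own related
# entities.

#' Initialize entity-model parameters
#' @param cfg A [model_config()].
#' @return Named list with stage-1 (tagging) and stage-2 (typing)
#'   parameter tensors.
#' @export
init_entity_params <- function(cfg) {
  set.seed(cfg$seed + 1L)
  d <- cfg$embed_dim
  dh <- 2L * cfg$lstm_state
  K <- cfg$num_entity_tags
  p <- list(lstm = init_bilstm_params(d, cfg$lstm_state),
            W_em = glorot(K, dh), b_em = numeric(K),
            W_type = glorot(cfg$num_entity_types, d),
            b_type = numeric(cfg$num_entity_types),
            U_type = glorot(d, d) * 0.1)
  if (cfg$use_kb) {
    p$U <- glorot(d, dh) * 0.1
    p$P <- init_projection(dh, d)
  }
  if (cfg$use_crf) {
    p$trans <- matrix(0, K, K)
    p$start <- numeric(K)
    p$stop <- numeric(K)
  }
  p
}

tagger_forward <- function(params, X, V, cfg, gold = NULL, training = FALSE) {
  enc <- encode_bilstm(X, params$lstm, cfg$dropout, training)
  H <- enc$H
  use_kb <- cfg$use_kb && !is.null(V) && NCOL(V) > 0L
  if (use_kb) {
    L <- crossprod(V, params$U %*% H)
    A <- softmax_cols(L)
    Smat <- V %*% A
    G <- H + params$P %*% Smat
  } else {
    A <- NULL; Smat <- NULL; G <- H
  }
  em <- t(params$W_em %*% G + params$b_em)     # T x K scores
  loss <- NA_real_; crf <- NULL
  if (!is.null(gold)) {
    if (cfg$use_crf) {
      crf <- crf_nll_grad(em, params$trans, params$start, params$stop, gold)
      loss <- crf$nll
    } else {
      P <- t(apply(em, 1L, softmax_vec))
      loss <- -sum(log(pmax(P[cbind(seq_along(gold), gold)], 1e-12)))
    }
  }
  tags <- if (cfg$use_crf) {
    crf_decode(em, params$trans, params$start, params$stop)
  } else {
    apply(em, 1L, which.max)
  }
  list(enc = enc, H = H, A = A, Smat = Smat, G = G, em = em, crf = crf,
       tags = tags, loss = loss, use_kb = use_kb, V = V)
}

tagger_backward <- function(params, fw, X, cfg, gold) {
  Tn <- nrow(fw$em); K <- ncol(fw$em)
  gr <- list()
  if (cfg$use_crf) {
    d_em <- fw$crf$d_emissions
    gr$trans <- fw$crf$d_transitions
    gr$start <- fw$crf$d_start
    gr$stop <- fw$crf$d_stop
  } else {
    P <- t(apply(fw$em, 1L, softmax_vec))
    d_em <- P
    d_em[cbind(seq_len(Tn), gold)] <- d_em[cbind(seq_len(Tn), gold)] - 1
  }
  G <- fw$G
  gr$W_em <- t(d_em) %*% t(G)
  gr$b_em <- colSums(d_em)
  dG <- crossprod(params$W_em, t(d_em))        # dh x T
  if (fw$use_kb) {
    V <- fw$V; A <- fw$A
    dSmat <- crossprod(params$P, dG)
    gr$P <- dG %*% t(fw$Smat)
    dA <- crossprod(V, dSmat)
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

#' Tag the tokens of a sentence with BIOE position labels
#'
#' Runs the stage-1 tagger (BiLSTM, optional per-token KB attention,
#' softmax or CRF decoding) and returns a structurally valid-or-repaired
#' tag sequence over `{B, I, O, E}`.
#'
#' @param sentence Sentence element of a [standoff_document()].
#' @param params Parameters from [init_entity_params()] or
#'   [train_entity_model()].
#' @param cfg The [model_config()] used to build `params`.
#' @param table An [embedding_table()].
#' @param store Optional [kb_store()]; when `cfg$use_kb`, related-entity
#'   vectors for the sentence are pooled from every token surface with a
#'   KB record.
#' @return Character vector of tags, one per token.
#' @export
tag_entities <- function(sentence, params, cfg, table, store = NULL) {
  toks <- sentence$tokens$surface
  if (!length(toks)) stop("empty sentence")
  X <- embed_tokens(toks, table)
  V <- if (cfg$use_kb && !is.null(store)) {
    sentence_kb_vectors(toks, store, table)
  } else NULL
  fw <- tagger_forward(params, X, V, cfg)
  bioe_tags()[fw$tags]
}

# pooled related-entity vectors for a sentence: union over token
# surfaces that resolve in the store
sentence_kb_vectors <- function(tokens, store, table) {
  rel <- unique(unlist(lapply(unique(tokens), function(tk) {
    related_entities(tk, store)
  })))
  if (!length(rel)) return(NULL)
  kb_vectors(rel, table)$vectors
}

#' Predict the type of a decoded entity span
#'
#' Stage 2: the span's entity representation (word + type-agnostic
#' annotation components) is fused with KB attention over the span's own
#' related entities — both in the embedding dimension, so fusion is
#' plain addition — and classified with a softmax over the entity types.
#'
#' @param rep_vector Entity representation vector (see
#'   [entity_representation()]; built without the type component, which
#'   is what is being predicted).
#' @param params Entity-model parameters.
#' @param V Optional `d x K` matrix of related-entity vectors.
#' @param labels Type label names; defaults to [entity_types()].
#' @return A classification as from [classify_softmax()].
#' @export
type_entities <- function(rep_vector, params, V = NULL,
                          labels = entity_types()) {
  att <- kb_attention(rep_vector, V, params$U_type)
  classify_softmax(att$h_prime, params$W_type, params$b_type, labels)
}

type_forward_backward <- function(params, r, V, y) {
  use_kb <- !is.null(V) && NCOL(V) > 0L
  if (use_kb) {
    logits_a <- drop(crossprod(V, params$U_type %*% r))
    alpha <- softmax_vec(logits_a)
    s <- drop(V %*% alpha)
    hp <- r + s
  } else {
    hp <- r
  }
  p <- softmax_vec(drop(params$W_type %*% hp) + params$b_type)
  loss <- -log(max(p[y], 1e-12))
  dlog <- p; dlog[y] <- dlog[y] - 1
  gr <- list(W_type = outer(dlog, hp), b_type = dlog)
  if (use_kb) {
    dhp <- drop(crossprod(params$W_type, dlog))
    dalpha <- drop(crossprod(V, dhp))
    dl <- alpha * (dalpha - sum(alpha * dalpha))
    gr$U_type <- (V %*% dl) %*% t(r)
  } else {
    gr$U_type <- matrix(0, nrow(params$U_type), ncol(params$U_type))
  }
  list(loss = loss, grads = gr, probs = p)
}
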