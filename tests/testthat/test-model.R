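test_that("bilinear attention matches the hand-computed example", {
  V <- cbind(c(1, 0), c(0, 1))
  att <- kb_attention(c(1, 0), V, diag(2))
  expect_equal(att$alpha, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(att$alpha, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(att$s, att$alpha)   # s = alpha1*v1 + alpha2*v2 here
})

test_that("empty V gives s = 0 and h' bit-identical to h; |V| = 1 gives alpha 1", {
  h <- rnorm(6)
  att <- kb_attention(h, matrix(0, 3, 0), matrix(0, 3, 6))
  expect_identical(att$h_prime, h)
  expect_equal(att$s, numeric(3))
  expect_length(att$alpha, 0L)
  v <- rnorm(6)
  att1 <- kb_attention(h, cbind(v), matrix(rnorm(36), 6, 6))
  expect_equal(att1$alpha, 1)
  expect_equal(att1$s, v)
})

test_that("attention equals brute-force enumeration, is permutation-equivariant and shift-stable", {
  set.seed(23)
  for (i in 1:100) {
    dv <- sample(2:6, 1); dh <- sample(2:8, 1); K <- sample(1:10, 1)
    V <- matrix(rnorm(dv * K), dv, K)
    h <- rnorm(dh)
    U <- matrix(rnorm(dv * dh), dv, dh)
    P <- matrix(rnorm(dh * dv), dh, dv)
    got <- kb_attention(h, V, U, P)
    want <- attention_oracle(h, V, U, P)
    expect_equal(got$alpha, want$alpha, tolerance = 1e-9)
    expect_equal(got$s, want$s, tolerance = 1e-9)
    expect_equal(got$h_prime, want$h_prime, tolerance = 1e-9)
    expect_true(all(got$alpha >= 0) && abs(sum(got$alpha) - 1) < 1e-12)
    # permuting V permutes alpha and leaves s unchanged
    pi <- sample(K)
    gp <- kb_attention(h, V[, pi, drop = FALSE], U, P)
    expect_equal(gp$alpha, got$alpha[pi], tolerance = 1e-9)
    expect_equal(gp$s, got$s, tolerance = 1e-9)
  }
  # adding a constant to all logits leaves alpha unchanged (max-subtraction)
  V <- matrix(rnorm(8), 2, 4); h <- rnorm(2)
  a1 <- kb_attention(h, V, diag(2))$alpha
  # scale logits additively by using logits + c via an augmented h trick:
  # alpha computed from logits l and l + 700 must agree and stay finite
  l <- drop(crossprod(V, diag(2) %*% h))
  big <- exp((l + 700) - max(l + 700)) / sum(exp((l + 700) - max(l + 700)))
  expect_equal(a1, big, tolerance = 1e-12)
})

test_that("attention at reference dimensions (200/400) matches the oracle", {
  set.seed(29)
  h <- rnorm(400)
  V <- matrix(rnorm(200 * 5), 200, 5)
  U <- matrix(rnorm(200 * 400, sd = 0.05), 200, 400)
  P <- matrix(rnorm(400 * 200, sd = 0.05), 400, 200)
  got <- kb_attention(h, V, U, P)
  want <- attention_oracle(h, V, U, P)
  expect_equal(got$alpha, want$alpha, tolerance = 1e-9)
  expect_equal(got$h_prime, want$h_prime, tolerance = 1e-9)
  # dimension mismatch without a projection is an error
  expect_error(kb_attention(h, V, U), "projection")
  expect_error(kb_attention(h, V, matrix(0, 200, 3)), "U must be")
})

test_that("attentive pooling is a convex combination with the stated degeneracies", {
  set.seed(5)
  g <- rnorm(6)
  G <- cbind(g, g, g)
  u <- rnorm(6)
  m <- merge_sentence(G, u)
  expect_equal(m$vector, g)
  expect_equal(sum(m$weights), 1)
  expect_equal(merge_sentence(cbind(g), u)$vector, g)
  G2 <- matrix(rnorm(18), 6, 3)
  w <- merge_sentence(G2, u)$weights
  expect_true(all(w >= 0) && abs(sum(w) - 1) < 1e-12)
})

test_that("softmax classifier honors the closed form and tie rule", {
  h <- c(1, 1)
  expect_equal(classify_softmax(h, matrix(0, 3, 2))$probs, rep(1/3, 3))
  W <- rbind(c(log(2), 0), c(0, 0))
  got <- classify_softmax(c(1, 0), W)
  expect_equal(got$probs, c(2/3, 1/3), tolerance = 1e-12)
  expect_equal(sum(got$probs), 1, tolerance = 1e-9)
  # exact tie -> lowest label index
  expect_equal(classify_softmax(c(0, 0), matrix(0, 4, 2))$argmax, 1L)
  expect_error(classify_softmax(c(1, 2, 3), W), "columns")
})

test_that("Viterbi decoding equals exhaustive enumeration", {
  set.seed(17)
  # degenerate cases
  em1 <- matrix(c(0.3, 2, -1, 0), 1, 4)
  expect_equal(crf_decode(em1, matrix(0, 4, 4)), 2L)
  emz <- matrix(rnorm(20), 5, 4)
  expect_equal(crf_decode(emz, matrix(0, 4, 4)),
               unname(apply(emz, 1, which.max)))
  # random instances vs brute force over 4^T sequences
  for (i in 1:50) {
    Tn <- sample(1:6, 1)
    em <- matrix(rnorm(Tn * 4), Tn, 4)
    tr <- matrix(rnorm(16), 4, 4)
    st <- rnorm(4); sp <- rnorm(4)
    expect_identical(crf_decode(em, tr, st, sp), crf_oracle(em, tr, st, sp))
  }
})

test_that("BiLSTM encoding has the shape/determinism/reversal contracts", {
  set.seed(9)
  d <- 5L; S <- 4L; Tn <- 7L
  params <- kbrelex:::init_bilstm_params(d, S)
  X <- matrix(rnorm(d * Tn), d, Tn)
  enc <- encode_bilstm(X, params)
  expect_equal(dim(enc$H), c(2L * S, Tn))
  expect_identical(encode_bilstm(X, params)$H, enc$H)   # eval determinism
  expect_error(encode_bilstm(matrix(0, d, 0), params), "non-empty")
  # with tied directions the backward stream equals the reversed
  # forward stream of the reversed input
  tied <- params; tied$bwd <- tied$fwd
  enc_t <- encode_bilstm(X, tied)
  rev_enc <- encode_bilstm(X[, Tn:1, drop = FALSE], tied)
  expect_equal(enc_t$H[S + seq_len(S), ],
               rev_enc$H[seq_len(S), Tn:1, drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
  # dropout only acts in training mode
  expect_identical(encode_bilstm(X, params, dropout = 0.5)$H, enc$H)
})

test_that("relation input windows clamp and cover the pair", {
  sent <- stub_sentence(10L)
  e <- function(i, j) data.frame(char_start = sent$tokens$char_start[i],
                                 char_end = sent$tokens$char_end[j])
  idx <- build_relation_input(sent, e(3, 3), e(8, 8), "between_entities", 2L)
  expect_equal(idx, 1:10)
  expect_equal(build_relation_input(sent, e(1, 1), e(10, 10),
                                    "between_entities", 2L), 1:10)
  expect_equal(build_relation_input(sent, e(5, 5), e(6, 6),
                                    "whole_sentence", 2L), 1:10)
  expect_equal(build_relation_input(sent, e(5, 5), e(6, 6),
                                    "between_entities", 0L), 5:6)
  # argument order does not change the textual window
  expect_equal(build_relation_input(sent, e(8, 8), e(3, 3),
                                    "between_entities", 2L), 1:10)
  expect_error(build_relation_input(sent, data.frame(char_start = 999L,
                                                     char_end = 1005L),
                                    e(3, 3), "between_entities", 2L),
               "outside")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(42)
  d <- 5L; S <- 3L; Tn <- 5L; K <- 3L; nl <- 4L
  mcfg <- model_config(embed_dim = d, lstm_state = S, dropout = 0,
                       use_kb = TRUE, seed = 7)
  params <- init_relation_params(mcfg, nl)
  X <- matrix(rnorm(d * Tn), d, Tn)
  V <- matrix(rnorm(d * K), d, K)
  y <- 2L
  fw <- kbrelex:::relation_forward(params, X, V, mcfg, y)
  gr <- kbrelex:::relation_backward(params, fw, X, mcfg, y)
  eps <- 1e-6
  check <- function(path) {
    get_leaf <- function(p) { for (nm in path) p <- p[[nm]]; p }
    set_leaf <- function(p, l) {
      if (length(path) == 1L) p[[path[1]]] <- l
      else if (length(path) == 2L) p[[path[1]]][[path[2]]] <- l
      else p[[path[1]]][[path[2]]][[path[3]]] <- l
      p
    }
    leaf <- get_leaf(params)
    ag <- get_leaf(gr)
    idx <- sample(length(leaf), min(8L, length(leaf)))
    for (i in idx) {
      l1 <- leaf; l1[i] <- l1[i] + eps
      l2 <- leaf; l2[i] <- l2[i] - eps
      ng <- (kbrelex:::relation_forward(set_leaf(params, l1), X, V, mcfg,
                                        y)$loss -
             kbrelex:::relation_forward(set_leaf(params, l2), X, V, mcfg,
                                        y)$loss) / (2 * eps)
      expect_equal(ag[i], ng, tolerance = 1e-5)
    }
  }
  for (path in list("W", "b", "u", "U", "P",
                    c("lstm", "fwd", "Wx"), c("lstm", "fwd", "Wh"),
                    c("lstm", "bwd", "Wx"), c("lstm", "bwd", "b"))) {
    check(path)
  }
})

test_that("no-KB and empty-V paths give bit-identical classifier inputs", {
  set.seed(8)
  d <- 4L; S <- 3L
  cfg_kb <- model_config(embed_dim = d, lstm_state = S, dropout = 0,
                         use_kb = TRUE, seed = 3)
  cfg_no <- model_config(embed_dim = d, lstm_state = S, dropout = 0,
                         use_kb = FALSE, seed = 3)
  p_kb <- init_relation_params(cfg_kb, 3L)
  p_no <- init_relation_params(cfg_no, 3L)
  X <- matrix(rnorm(d * 6), d, 6)
  f1 <- kbrelex:::relation_forward(p_kb, X, NULL, cfg_kb)
  f2 <- kbrelex:::relation_forward(p_no, X, NULL, cfg_no)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$mrg$vector, f2$mrg$vector)
  expect_identical(f1$probs, f2$probs)
})

test_that("untrained taggers still emit shape-valid output", {
  sent <- stub_sentence(6L)
  tab <- embedding_table(dim = 5L)
  cfg <- model_config(embed_dim = 5, lstm_state = 3, use_kb = FALSE,
                      use_crf = TRUE, seed = 2)
  params <- init_entity_params(cfg)
  tags <- tag_entities(sent, params, cfg, tab)
  expect_length(tags, 6L)
  expect_true(all(tags %in% bioe_tags()))
  # stage 2 with symmetric (zero) weights is uniform over the two types
  params$W_type[] <- 0; params$b_type[] <- 0
  ty <- type_entities(rnorm(5), params)
  expect_equal(ty$probs, c(0.5, 0.5))
  empty_sent <- list(tokens = data.frame(surface = character(0),
                                         char_start = integer(0),
                                         char_end = integer(0)))
  expect_error(tag_entities(empty_sent, params, cfg, tab), "empty")
})
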