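# Shared fixture builders: everything is generated in code at test time.

# minimal standoff triple on disk; returns the directory
write_tiny_standoff <- function(dir = tempfile("standoff"),
                                text = "LEC1 binds X.",
                                a1 = "T1\tGene 0 4\tLEC1",
                                a2 = NULL, id = "doc1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeChar(text, file.path(dir, paste0(id, ".txt")), eos = NULL)
  writeLines(a1, file.path(dir, paste0(id, ".a1")))
  if (!is.null(a2)) writeLines(a2, file.path(dir, paste0(id, ".a2")))
  dir
}

# embedding table with fixed, known vectors
fixed_table <- function(tokens, dim = 4L, scale = seq_along(tokens)) {
  vecs <- lapply(seq_along(tokens), function(i) {
    v <- numeric(dim)
    v[(i - 1L) %% dim + 1L] <- scale[i]
    v
  })
  names(vecs) <- tokens
  embedding_table(vecs, dim = dim, oov_seed = 99L)
}

# store with one record per surface and given reactions
toy_store <- function(surfaces, reactions) {
  records <- lapply(surfaces, function(s) {
    kb_record(paste0("ACC_", s), s, function_text = "")
  })
  rx <- lapply(seq_along(reactions), function(i) {
    kb_reaction(paste0("rx", i), reactions[[i]])
  })
  kb_store(records, list(kb_reaction_model("m1", rx)))
}

# the fixture store shipped with the package (ATERF1 walk-through +
# Contactin-2 record)
fixture_store <- function() {
  read_kb_store(system.file("extdata", "synthetic_kb_store.json",
                            package = "kbrelex"))
}

# brute-force attention oracle: direct exp/normalize enumeration
attention_oracle <- function(h, V, U, P = NULL) {
  K <- ncol(V)
  logits <- numeric(K)
  for (i in seq_len(K)) logits[i] <- sum(V[, i] * (U %*% h))
  e <- exp(logits - max(logits))
  alpha <- e / sum(e)
  s <- numeric(nrow(V))
  for (i in seq_len(K)) s <- s + alpha[i] * V[, i]
  sp <- if (is.null(P)) s else drop(P %*% s)
  list(alpha = alpha, s = s, h_prime = h + sp)
}

# brute-force CRF decoder: enumerate all K^T tag sequences
crf_oracle <- function(emissions, transitions, start, stop) {
  Tn <- nrow(emissions); K <- ncol(emissions)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  best <- -Inf; best_y <- NULL
  for (r in seq_len(nrow(grid))) {
    y <- grid[r, ]
    sc <- start[y[1]] + stop[y[Tn]] +
      sum(emissions[cbind(seq_len(Tn), y)])
    if (Tn > 1) sc <- sc + sum(transitions[cbind(y[-Tn], y[-1])])
    if (sc > best + 1e-12) { best <- sc; best_y <- y }
  }
  unname(best_y)
}

# random valid span configuration over n tokens: non-overlapping spans
random_spans <- function(n_tokens) {
  spans <- list()
  t <- 1L
  while (t <= n_tokens) {
    if (runif(1) < 0.4) {
      len <- sample.int(min(3L, n_tokens - t + 1L), 1L)
      spans[[length(spans) + 1L]] <- c(t, t + len - 1L)
      t <- t + len
    } else {
      t <- t + 1L
    }
  }
  spans
}

# sentence stub with n whitespace-separated tokens
stub_sentence <- function(n_tokens) {
  toks <- sprintf("tk%02d", seq_len(n_tokens))
  starts <- cumsum(c(0L, nchar(toks) + 1L))[seq_len(n_tokens)]
  list(tokens = data.frame(surface = toks, char_start = starts,
                           char_end = starts + nchar(toks),
                           pos = NA, lemma = NA,
                           stringsAsFactors = FALSE),
       char_start = 0L, char_end = starts[n_tokens] + nchar(toks[n_tokens]))
}

# entity data frame for token-index spans of a stub sentence
spans_as_entities <- function(sent, spans) {
  if (!length(spans)) {
    return(data.frame(char_start = integer(0), char_end = integer(0)))
  }
  do.call(rbind, lapply(spans, function(sp) {
    data.frame(char_start = sent$tokens$char_start[sp[1]],
               char_end = sent$tokens$char_end[sp[2]])
  }))
}
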