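#' In-memory word embedding table with a deterministic OOV policy
#'
#' Wraps a token-to-vector map of fixed dimension. Tokens missing from
#' the table receive a pseudo-random vector with components drawn from
#' Uniform(-0.25, 0.25), seeded by a hash of the token together with
#' `oov_seed`, and cached — so the same unknown token always maps to the
#' same vector within and across sessions.
#'
#' @param vectors Named list or matrix-free map of token -> numeric
#'   vector, all of length `dim`; may be empty.
#' @param dim Embedding dimension (the reference tables are
#'   200-dimensional).
#' @param oov_seed Integer seed mixed into the per-token hash.
#' @return Object of class `embedding_table`.
#' @export
embedding_table <- function(vectors = list(), dim = 200L, oov_seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(dim > 0L)
  env <- new.env(parent = emptyenv())
  if (length(vectors)) {
    stopifnot(!is.null(names(vectors)))
    for (nm in names(vectors)) {
      v <- as.numeric(vectors[[nm]])
      if (length(v) != dim) stop("vector for '", nm, "' has wrong length")
      env[[nm]] <- v
    }
  }
  structure(list(dim = dim, table = env, oov_seed = as.integer(oov_seed),
                 oov_cache = new.env(parent = emptyenv())),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d vectors, dim %d, oov_seed %d\n",
              length(ls(x$table)), x$dim, x$oov_seed))
  invisible(x)
}

# 32-bit polynomial hash of a token mixed with the OOV seed
token_hash <- function(token, seed) {
  h <- (as.double(seed) %% 2147483647) + 1
  for (b in utf8ToInt(token)) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

#' Load word embeddings from whitespace-delimited text
#'
#' word2vec-style text format: one token followed by `dim` floats per
#' line; an optional first line `count dim` (two integers) is tolerated
#' and skipped. Duplicate tokens keep their first occurrence with a
#' warning; a row with the wrong number of fields is a parse error
#' naming the line.
#'
#' @param path Path to the embedding file.
#' @param dim Expected vector dimension.
#' @param oov_seed Seed for the OOV policy of the resulting table.
#' @return An [embedding_table()].
#' @export
load_embeddings <- function(path, dim = 200L, oov_seed = 1L) {
  dim <- as.integer(dim)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  start <- 1L
  if (length(lines)) {
    f1 <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(f1) == 2L && !anyNA(suppressWarnings(as.integer(f1)))) {
      start <- 2L
    }
  }
  tab <- embedding_table(dim = dim, oov_seed = oov_seed)
  dups <- 0L
  for (ln in seq.int(start, length.out = max(0L, length(lines) - start + 1L))) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) != dim + 1L) {
      stop(sprintf("%s:%d: expected token + %d values, found %d fields",
                   path, ln, dim, length(f)))
    }
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop(sprintf("%s:%d: non-numeric embedding value", path, ln))
    if (!is.null(tab$table[[f[1]]])) {
      dups <- dups + 1L
      next
    }
    tab$table[[f[1]]] <- v
  }
  if (dups > 0L) warning(dups, " duplicate token(s) kept first occurrence")
  tab
}

#' Embedding vector for a token
#'
#' Known tokens return the stored vector; unknown tokens fall back to the
#' table's deterministic OOV policy (see [embedding_table()]).
#'
#' @param token Character scalar.
#' @param table An [embedding_table()].
#' @return Numeric vector of length `table$dim`.
#' @export
embed_token <- function(token, table) {
  stopifnot(inherits(table, "embedding_table"))
  v <- table$table[[token]]
  if (!is.null(v)) return(v)
  cached <- table$oov_cache[[token]]
  if (!is.null(cached)) return(cached)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(token_hash(token, table$oov_seed))
  v <- runif(table$dim, -0.25, 0.25)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  table$oov_cache[[token]] <- v
  v
}

#' Embed a vector of tokens as a matrix
#' @param tokens Character vector.
#' @param table An [embedding_table()].
#' @return `dim x length(tokens)` numeric matrix (columns are tokens).
#' @export
embed_tokens <- function(tokens, table) {
  if (!length(tokens)) return(matrix(0, table$dim, 0))
  vapply(tokens, embed_token, numeric(table$dim), table = table)
}

#' Annotation vector of a set of KB records
#'
#' Tokenizes the concatenation of every name and the functional
#' annotation text of every record and returns the *sum* of their token
#' vectors (annotations are a bag of evidence; each occurrence adds its
#' vector). With no records the annotation vector is zero.
#'
#' @param records List of [kb_record()]s (possibly empty).
#' @param table An [embedding_table()].
#' @return Numeric vector of length `table$dim`.
#' @export
annotation_vector <- function(records, table) {
  v <- numeric(table$dim)
  if (!length(records)) return(v)
  text <- paste(unlist(lapply(records, function(r) {
    c(collect_names(r), r$function_text)
  })), collapse = " ")
  toks <- tokenize(text)$surface
  for (tk in toks) v <- v + embed_token(tk, table)
  v
}

#' Build the representation of an entity mention
#'
#' Three components, each in the embedding space: the entity word vector
#' (the *mean* of the vectors of the entity's surface tokens), the type
#' vector (the embedding of the lowercased type name, `"gene"` or
#' `"protein"`), and the annotation vector of its KB records. The entity
#' representation is their elementwise sum, staying in the same
#' dimension.
#'
#' @param surface Entity surface string (at least one token).
#' @param etype Entity type name.
#' @param records List of [kb_record()]s for this entity (may be empty).
#' @param table An [embedding_table()].
#' @return List with `vector` (the combined representation) and
#'   `components` (`word`, `type`, `annotation`).
#' @export
entity_representation <- function(surface, etype, records, table) {
  toks <- tokenize(surface)$surface
  if (!length(toks)) stop("entity surface has zero tokens")
  wm <- embed_tokens(toks, table)
  word <- rowMeans(wm)
  type <- embed_token(tolower(etype), table)
  ann <- annotation_vector(records, table)
  list(vector = word + type + ann,
       components = list(word = word, type = type, annotation = ann))
}

#' Vectors for KB-related entity names
#'
#' Converts each related entity name into a vector — the mean of its
#' token vectors, matching the entity-word-vector convention and staying
#' length-invariant in the name's token count. Order is preserved.
#'
#' @param related_names Character vector (possibly empty) as returned by
#'   [related_entities()].
#' @param table An [embedding_table()].
#' @return List with `entity_names` and `vectors`, a `dim x K` matrix
#'   (zero columns when no names).
#' @export
kb_vectors <- function(related_names, table) {
  K <- length(related_names)
  V <- matrix(0, table$dim, K)
  for (i in seq_len(K)) {
    toks <- tokenize(related_names[i])$surface
    if (length(toks)) V[, i] <- rowMeans(embed_tokens(toks, table))
  }
  list(entity_names = as.character(related_names), vectors = V)
}
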