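#' @title Standoff corpus object model
#' @description
#' A document couples raw text with sentence/token structure and standoff
#' annotations: entity mentions (`Gene`/`Protein`) and directed binary
#' relations over the eight relation types of the gene-regulation task,
#' plus `NONE` for unannotated candidate pairs.
#' @name standoff-model
NULL

#' Closed set of entity types retained by the loader
#' @return Character vector `c("Gene", "Protein")`.
#' @export
entity_types <- function() c("Gene", "Protein")

#' Closed set of relation types (plus the null label)
#' @param include_none Append `"NONE"`, the label for candidate pairs
#'   without an annotated relation.
#' @return Character vector of relation type names.
#' @export
relation_types <- function(include_none = FALSE) {
  rt <- c("Is_Functionally_Equivalent_To", "Interacts_With",
          "Has_Sequence_Identical_To", "Transcribes_Or_Translates_To",
          "Regulates_Expression", "Is_Linked_To", "Binds_To",
          "Regulates_Molecule_Activity")
  if (include_none) c(rt, "NONE") else rt
}

empty_entities <- function() {
  data.frame(id = character(0), etype = character(0),
             char_start = integer(0), char_end = integer(0),
             surface = character(0), sentence = integer(0),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(0), rtype = character(0),
             arg1 = character(0), arg2 = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a standoff document
#'
#' Tokenizes and sentence-splits `text`, validates entity spans against
#' it, and assigns each entity to the single sentence containing it.
#' Entities crossing sentence boundaries are rejected with a warning, as
#' are relations whose arguments do not survive.
#'
#' @param id Document identifier.
#' @param text Full document text.
#' @param entities Data frame with columns `id`, `etype`, `char_start`,
#'   `char_end`, `surface` (0-based, end-exclusive offsets).
#' @param relations Data frame with columns `id`, `rtype`, `arg1`, `arg2`
#'   (entity ids), or `NULL`.
#' @param skipped_entity_count Count of entities dropped upstream (e.g.
#'   by the Gene/Protein type screen); carried for reporting.
#' @return An object of class `standoff_document`.
#' @export
standoff_document <- function(id, text, entities = empty_entities(),
                              relations = NULL,
                              skipped_entity_count = 0L) {
  stopifnot(is.character(text), length(text) == 1L)
  spans <- split_sentences(text)
  sentences <- lapply(seq_len(nrow(spans)), function(i) {
    seg <- substr(text, spans$char_start[i] + 1L, spans$char_end[i])
    toks <- tokenize(seg)
    toks$char_start <- toks$char_start + spans$char_start[i]
    toks$char_end <- toks$char_end + spans$char_start[i]
    list(tokens = toks, char_start = spans$char_start[i],
         char_end = spans$char_end[i])
  })
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  if (nrow(entities)) {
    entities <- entities[, c("id", "etype", "char_start", "char_end",
                             "surface"), drop = FALSE]
    slice <- substr(rep(text, nrow(entities)),
                    entities$char_start + 1L, entities$char_end)
    bad <- slice != entities$surface
    if (any(bad)) {
      stop("entity surface mismatch for id(s): ",
           paste(entities$id[bad], collapse = ", "))
    }
    entities$sentence <- vapply(seq_len(nrow(entities)), function(i) {
      hit <- which(entities$char_start[i] >= spans$char_start &
                     entities$char_end[i] <= spans$char_end)
      if (length(hit) == 1L) hit else NA_integer_
    }, integer(1))
    if (anyNA(entities$sentence)) {
      drop_ids <- entities$id[is.na(entities$sentence)]
      warning("dropping ", length(drop_ids),
              " cross-sentence entit(ies): ",
              paste(drop_ids, collapse = ", "))
      entities <- entities[!is.na(entities$sentence), , drop = FALSE]
    }
  } else {
    entities <- empty_entities()
  }
  if (is.null(relations)) relations <- empty_relations()
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (nrow(relations)) {
    keep <- relations$arg1 %in% entities$id & relations$arg2 %in% entities$id
    if (!all(keep)) {
      warning("dropping ", sum(!keep),
              " relation(s) with screened-out arguments")
      relations <- relations[keep, , drop = FALSE]
    }
    stopifnot(all(relations$arg1 != relations$arg2))
  }
  structure(list(id = id, text = text, sentences = sentences,
                 entities = entities, relations = relations,
                 skipped_entity_count = as.integer(skipped_entity_count)),
            class = "standoff_document")
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("<standoff_document> %s: %d chars, %d sentences, %d entities, %d relations\n",
              x$id, nchar(x$text), length(x$sentences),
              nrow(x$entities), nrow(x$relations)))
  invisible(x)
}

#' Read a document from BioNLP-ST standoff files
#'
#' Reads raw text (`.txt`), entity annotations (`.a1`, tab-separated
#' `ID<TAB>TYPE START END<TAB>SURFACE`), and optionally binary relations
#' (`.a2`, `ID<TAB>RELTYPE Arg1:Tid Arg2:Tid`). Only `Gene` and `Protein`
#' entities are kept; others are skipped and counted (the knowledge bases
#' used downstream only cover genes and proteins). A relation whose
#' argument id never appears in the `.a1` file is an integrity error; a
#' relation whose argument was screened out by type is dropped with a
#' warning.
#'
#' @param txt_path Path to the `.txt` file.
#' @param a1_path Path to the `.a1` file.
#' @param a2_path Optional path to the `.a2` file.
#' @param id Document id; defaults to the `.txt` basename.
#' @return A [standoff_document()].
#' @export
read_standoff <- function(txt_path, a1_path, a2_path = NULL, id = NULL) {
  if (!file.exists(txt_path)) stop("no such file: ", txt_path)
  text <- readChar(txt_path, file.info(txt_path)$size, useBytes = FALSE)
  if (is.null(id)) id <- sub("\\.txt$", "", basename(txt_path))

  a1_lines <- readLines(a1_path, warn = FALSE)
  a1_lines <- a1_lines[nzchar(a1_lines)]
  ids <- character(0); etype <- character(0)
  cs <- integer(0); ce <- integer(0); surf <- character(0)
  all_a1_ids <- character(0)
  skipped <- 0L
  for (ln in seq_along(a1_lines)) {
    f <- strsplit(a1_lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L) {
      stop(sprintf("%s:%d: malformed .a1 line (expected 3 tab fields)",
                   a1_path, ln))
    }
    mid <- strsplit(f[2], " ", fixed = TRUE)[[1]]
    if (length(mid) != 3L || anyNA(suppressWarnings(as.integer(mid[2:3])))) {
      stop(sprintf("%s:%d: malformed span field '%s'", a1_path, ln, f[2]))
    }
    all_a1_ids <- c(all_a1_ids, f[1])
    if (!mid[1] %in% entity_types()) {
      skipped <- skipped + 1L
      next
    }
    ids <- c(ids, f[1]); etype <- c(etype, mid[1])
    cs <- c(cs, as.integer(mid[2])); ce <- c(ce, as.integer(mid[3]))
    surf <- c(surf, f[3])
  }
  if (skipped > 0L) {
    message(sprintf("%s: skipped %d entit(ies) of non-Gene/Protein type",
                    basename(a1_path), skipped))
  }
  entities <- data.frame(id = ids, etype = etype, char_start = cs,
                         char_end = ce, surface = surf,
                         stringsAsFactors = FALSE)

  relations <- NULL
  if (!is.null(a2_path)) {
    a2_lines <- readLines(a2_path, warn = FALSE)
    a2_lines <- a2_lines[nzchar(a2_lines)]
    rid <- character(0); rtype <- character(0)
    a1 <- character(0); a2 <- character(0)
    for (ln in seq_along(a2_lines)) {
      f <- strsplit(a2_lines[ln], "\t", fixed = TRUE)[[1]]
      if (length(f) != 2L) {
        stop(sprintf("%s:%d: malformed .a2 line", a2_path, ln))
      }
      mid <- strsplit(f[2], " ", fixed = TRUE)[[1]]
      if (length(mid) != 3L || !grepl("^Arg1:", mid[2]) ||
          !grepl("^Arg2:", mid[3])) {
        stop(sprintf("%s:%d: malformed relation field '%s'",
                     a2_path, ln, f[2]))
      }
      e1 <- sub("^Arg1:", "", mid[2])
      e2 <- sub("^Arg2:", "", mid[3])
      if (!e1 %in% all_a1_ids || !e2 %in% all_a1_ids) {
        stop(sprintf("%s:%d: relation %s references entity id absent from .a1",
                     a2_path, ln, f[1]))
      }
      rid <- c(rid, f[1]); rtype <- c(rtype, mid[1])
      a1 <- c(a1, e1); a2 <- c(a2, e2)
    }
    relations <- data.frame(id = rid, rtype = rtype, arg1 = a1, arg2 = a2,
                            stringsAsFactors = FALSE)
  }
  standoff_document(id, text, entities, relations,
                    skipped_entity_count = skipped)
}

#' Write a document back to standoff files
#'
#' Emits `.txt`, `.a1` and (when relations exist) `.a2` files in the
#' standard column order, so that [read_standoff()] reproduces the
#' document.
#'
#' @param doc A [standoff_document()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_standoff <- function(doc, dir) {
  stopifnot(inherits(doc, "standoff_document"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  txt <- file.path(dir, paste0(doc$id, ".txt"))
  a1 <- file.path(dir, paste0(doc$id, ".a1"))
  writeChar(doc$text, txt, eos = NULL)
  a1_lines <- sprintf("%s\t%s %d %d\t%s", doc$entities$id,
                      doc$entities$etype, doc$entities$char_start,
                      doc$entities$char_end, doc$entities$surface)
  writeLines(a1_lines, a1)
  paths <- c(txt, a1)
  if (nrow(doc$relations)) {
    a2 <- file.path(dir, paste0(doc$id, ".a2"))
    a2_lines <- sprintf("%s\t%s Arg1:%s Arg2:%s", doc$relations$id,
                        doc$relations$rtype, doc$relations$arg1,
                        doc$relations$arg2)
    writeLines(a2_lines, a2)
    paths <- c(paths, a2)
  }
  invisible(paths)
}

#' Read every standoff document in a directory
#' @param dir Directory containing `.txt`/`.a1`(/`.a2`) triples.
#' @return List of [standoff_document()] objects, ordered by file name.
#' @export
read_corpus <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tp) {
    base <- sub("\\.txt$", "", tp)
    a2 <- paste0(base, ".a2")
    read_standoff(tp, paste0(base, ".a1"),
                  if (file.exists(a2)) a2 else NULL)
  })
}

#' Enumerate ordered candidate entity pairs within a sentence
#'
#' Relations are directed, so both orders of each co-sentential entity
#' pair are candidates; pairs never span sentences.
#'
#' @param doc A [standoff_document()].
#' @param sentence_index Sentence number (1-based).
#' @return Data frame with columns `arg1`, `arg2` (entity ids),
#'   `n * (n - 1)` rows for `n` co-sentential entities.
#' @export
candidate_pairs <- function(doc, sentence_index) {
  ents <- doc$entities[doc$entities$sentence == sentence_index, , drop = FALSE]
  n <- nrow(ents)
  if (n < 2L) {
    return(data.frame(arg1 = character(0), arg2 = character(0),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  grid <- grid[grid$i != grid$j, , drop = FALSE]
  grid <- grid[order(grid$i, grid$j), , drop = FALSE]
  data.frame(arg1 = ents$id[grid$i], arg2 = ents$id[grid$j],
             stringsAsFactors = FALSE)
}

#' Summary statistics for a standoff corpus
#' @param docs List of documents from [read_corpus()].
#' @return One-row data frame of corpus-level counts.
#' @export
corpus_stats <- function(docs) {
  data.frame(
    documents = length(docs),
    sentences = sum(vapply(docs, function(d) length(d$sentences), 1L)),
    entities = sum(vapply(docs, function(d) nrow(d$entities), 1L)),
    relations = sum(vapply(docs, function(d) nrow(d$relations), 1L)),
    skipped_entities = sum(vapply(docs, function(d) d$skipped_entity_count, 1L))
  )
}
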