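#' BIOE tag alphabet
#' @return `c("B", "I", "O", "E")` in the canonical order used by the
#'   tagging models.
#' @export
bioe_tags <- function() c("B", "I", "O", "E")

#' Encode entity spans of one sentence as a BIOE tag sequence
#'
#' Each token of an entity is tagged by position: `B`egin, `I`nside,
#' `O`utside, `E`nd. A k-token entity becomes `B, I x (k-2), E`; a
#' single-token entity is tagged `B` alone (begin with implicit end),
#' keeping the four-tag alphabet closed. Entities must align exactly with
#' token boundaries and must not overlap.
#'
#' @param sentence A sentence element of a [standoff_document()] (list
#'   with a `tokens` data frame).
#' @param entities Data frame of entity mentions lying in this sentence
#'   (columns `char_start`, `char_end` at document offsets).
#' @return Character vector over `{B, I, O, E}`, one tag per token.
#' @export
spans_to_bioe <- function(sentence, entities) {
  toks <- sentence$tokens
  tags <- rep("O", nrow(toks))
  if (is.null(entities) || nrow(entities) == 0L) return(tags)
  claimed <- rep(FALSE, nrow(toks))
  for (i in seq_len(nrow(entities))) {
    first <- which(toks$char_start == entities$char_start[i])
    last <- which(toks$char_end == entities$char_end[i])
    if (length(first) != 1L || length(last) != 1L || last < first) {
      stop("entity at [", entities$char_start[i], ",", entities$char_end[i],
           ") is not aligned to token boundaries")
    }
    idx <- first:last
    if (any(claimed[idx])) stop("overlapping entities in sentence")
    claimed[idx] <- TRUE
    k <- length(idx)
    if (k == 1L) {
      tags[idx] <- "B"
    } else {
      tags[idx] <- c("B", rep("I", k - 2L), "E")
    }
  }
  tags
}

#' Decode a BIOE tag sequence into token spans
#'
#' The inverse of [spans_to_bioe()], with lenient repair of structurally
#' invalid model output (decoding never raises): an `I` or `E` without a
#' preceding `B` opens a span at that token, and an unclosed `B`/`I` run
#' closes at its last token. A `B` not followed by `I` or `E` is a closed
#' singleton.
#'
#' @param tags Character vector over `{B, I, O, E}`.
#' @param sentence Optional sentence; when given, document character
#'   offsets are attached to each span.
#' @return Data frame with 1-based token indices `first`, `last` (and
#'   `char_start`, `char_end` when `sentence` is supplied).
#' @export
bioe_to_spans <- function(tags, sentence = NULL) {
  stopifnot(all(tags %in% bioe_tags()))
  if (!is.null(sentence)) {
    stopifnot(length(tags) == nrow(sentence$tokens))
  }
  first <- integer(0); last <- integer(0)
  open <- NA_integer_
  close_at <- function(end_idx) {
    first <<- c(first, open)
    last <<- c(last, end_idx)
    open <<- NA_integer_
  }
  for (t in seq_along(tags)) {
    tag <- tags[t]
    if (tag == "B") {
      if (!is.na(open)) close_at(t - 1L)   # unclosed run ends before new B
      open <- t
    } else if (tag == "I") {
      if (is.na(open)) open <- t           # repair: I opens a span
    } else if (tag == "E") {
      if (is.na(open)) open <- t           # repair: bare E is a singleton
      close_at(t)
    } else {                               # O
      if (!is.na(open)) close_at(t - 1L)
    }
  }
  if (!is.na(open)) close_at(length(tags))
  out <- data.frame(first = first, last = last)
  if (!is.null(sentence) && nrow(out)) {
    out$char_start <- sentence$tokens$char_start[out$first]
    out$char_end <- sentence$tokens$char_end[out$last]
  }
  out
}
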