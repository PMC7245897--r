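#' Rule-based tokenizer with exact character offsets
#'
#' Splits text on whitespace, then peels leading/trailing punctuation
#' (`()[]{},.;:!?"'`) into single-character tokens and splits on internal
#' forward slashes. Hyphens and digits stay inside tokens so biomedical
#' names such as `14-3-3` survive intact. Offsets are 0-based,
#' end-exclusive, and exact: `substr(text, char_start + 1, char_end)`
#' always reproduces the surface.
#'
#' @param text A single character string (may be empty).
#' @return A data frame with columns `surface`, `char_start`, `char_end`,
#'   `pos`, `lemma` (the last two `NA` unless supplied externally), one
#'   row per token, ordered by `char_start`.
#' @examples
#' tokenize("LEC1 (LEAFY)")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(empty_tokens())
  punct <- c("(", ")", "[", "]", "{", "}", ",", ".", ";", ":", "!", "?",
             "\"", "'")
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty_tokens())
  starts0 <- as.integer(m) - 1L                      # 0-based chunk starts
  lens <- attr(m, "match.length")
  surf <- character(0); cs <- integer(0)
  emit <- function(s, at) {
    surf[[length(surf) + 1L]] <<- s
    cs[[length(cs) + 1L]] <<- at
  }
  for (k in seq_along(starts0)) {
    chunk <- substr(text, starts0[k] + 1L, starts0[k] + lens[k])
    at <- starts0[k]
    # peel leading punctuation
    while (nchar(chunk) > 1L && substr(chunk, 1L, 1L) %in% punct) {
      emit(substr(chunk, 1L, 1L), at)
      chunk <- substr(chunk, 2L, nchar(chunk))
      at <- at + 1L
    }
    # peel trailing punctuation (collected, emitted after the core)
    trail <- character(0); tat <- integer(0)
    while (nchar(chunk) > 1L &&
           substr(chunk, nchar(chunk), nchar(chunk)) %in% punct) {
      n <- nchar(chunk)
      trail <- c(substr(chunk, n, n), trail)
      tat <- c(at + n - 1L, tat)
      chunk <- substr(chunk, 1L, n - 1L)
    }
    # split the core on internal '/'
    if (grepl("/", chunk, fixed = TRUE) && nchar(chunk) > 1L) {
      parts <- strsplit(chunk, "(?<=/)|(?=/)", perl = TRUE)[[1]]
      off <- at
      for (p in parts) {
        emit(p, off)
        off <- off + nchar(p)
      }
    } else {
      emit(chunk, at)
    }
    for (j in seq_along(trail)) emit(trail[j], tat[j])
  }
  data.frame(surface = surf, char_start = cs,
             char_end = cs + nchar(surf),
             pos = NA_character_, lemma = NA_character_,
             stringsAsFactors = FALSE)
}

empty_tokens <- function() {
  data.frame(surface = character(0), char_start = integer(0),
             char_end = integer(0), pos = character(0),
             lemma = character(0), stringsAsFactors = FALSE)
}

#' Default abbreviation protection list for sentence splitting
#'
#' Word forms (ending in a period) after which a period is never treated
#' as a sentence terminator.
#' @return Character vector of protected abbreviations.
#' @export
protected_abbreviations <- function() {
  c("Fig.", "Figs.", "Tab.", "al.", "e.g.", "i.e.", "cf.", "vs.", "ca.",
    "approx.", "No.", "Dr.", "Prof.", "sp.", "spp.")
}

#' Split document text into sentence spans
#'
#' A sentence boundary is placed after `.`, `!` or `?` when it is followed
#' by whitespace and an uppercase letter, unless the whitespace-delimited
#' word ending at the period is on the protected abbreviation list.
#'
#' @param doc_text Document text (single string).
#' @param abbreviations Protected abbreviations;
#'   defaults to [protected_abbreviations()].
#' @return Data frame with 0-based, end-exclusive `char_start`/`char_end`
#'   spans, one row per sentence, covering all non-whitespace text.
#' @export
split_sentences <- function(doc_text, abbreviations = protected_abbreviations()) {
  stopifnot(is.character(doc_text), length(doc_text) == 1L)
  if (is.na(doc_text) || !grepl("\\S", doc_text)) {
    return(data.frame(char_start = integer(0), char_end = integer(0)))
  }
  chars <- strsplit(doc_text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  boundaries <- integer(0)               # exclusive end offsets (0-based)
  for (i in seq_len(n)) {
    if (!chars[i] %in% c(".", "!", "?")) next
    if (i >= n) next
    # require whitespace then an uppercase letter
    j <- i + 1L
    if (!grepl("^\\s$", chars[j])) next
    while (j <= n && grepl("^\\s$", chars[j])) j <- j + 1L
    if (j > n || !grepl("^[A-Z]$", chars[j])) next
    if (chars[i] == ".") {
      # the whitespace-delimited word ending at this period
      k <- i
      while (k > 1L && !grepl("^\\s$", chars[k - 1L])) k <- k - 1L
      word <- paste(chars[k:i], collapse = "")
      if (word %in% abbreviations) next
    }
    boundaries <- c(boundaries, i)       # end-exclusive offset == i (0-based)
  }
  cut_end <- c(boundaries, n)
  cut_start <- c(0L, boundaries)
  starts <- integer(0); ends <- integer(0)
  for (s in seq_along(cut_end)) {
    a <- cut_start[s]; b <- cut_end[s]
    # trim surrounding whitespace
    while (a < b && grepl("^\\s$", chars[a + 1L])) a <- a + 1L
    while (b > a && grepl("^\\s$", chars[b])) b <- b - 1L
    if (b > a) {
      starts <- c(starts, a)
      ends <- c(ends, b)
    }
  }
  data.frame(char_start = starts, char_end = ends)
}
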