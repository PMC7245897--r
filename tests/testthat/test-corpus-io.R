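test_that("tokenizer splits punctuation and slashes with exact offsets", {
  tk <- tokenize("LEC1 (LEAFY)")
  expect_equal(tk$surface, c("LEC1", "(", "LEAFY", ")"))
  expect_equal(tk$char_start, c(0L, 5L, 6L, 11L))
  expect_equal(tk$char_end, c(4L, 6L, 11L, 12L))

  expect_equal(nrow(tokenize("")), 0L)
  expect_equal(nrow(tokenize("a b")), 2L)

  # hyphens and digits stay inside tokens; slash splits
  expect_equal(tokenize("14-3-3")$surface, "14-3-3")
  expect_equal(tokenize("LEC1/FUS3")$surface, c("LEC1", "/", "FUS3"))
  expect_equal(tokenize("(X).")$surface, c("(", "X", ")", "."))
})

test_that("token offsets always reconstruct the original text", {
  set.seed(7)
  pieces <- c("LEC1", "binds", "(FUS3),", "the", "14-3-3", "protein.",
              "a/b", "X!", "\"quoted\"", "p53's")
  for (rep in 1:50) {
    text <- paste(sample(pieces, sample(3:8, 1), replace = TRUE),
                  collapse = " ")
    tk <- tokenize(text)
    for (i in seq_len(nrow(tk))) {
      expect_identical(substr(text, tk$char_start[i] + 1L, tk$char_end[i]),
                       tk$surface[i])
    }
    # tokens are ordered and non-overlapping
    if (nrow(tk) > 1L) {
      expect_true(all(diff(tk$char_start) > 0))
      expect_true(all(tk$char_start[-1] >= tk$char_end[-nrow(tk)]))
    }
  }
})

test_that("sentence splitting honors terminators and abbreviations", {
  expect_equal(nrow(split_sentences("A binds B. C binds D.")), 2L)
  expect_equal(nrow(split_sentences("no terminator here")), 1L)
  expect_equal(nrow(split_sentences("Fig. 2 shows X.")), 1L)
  # lowercase after period: no split
  expect_equal(nrow(split_sentences("A binds B. and more")), 1L)
  s <- split_sentences("A binds B.  C binds D.")
  expect_identical(substr("A binds B.  C binds D.", s$char_start[2] + 1,
                          s$char_end[2]), "C binds D.")
})

test_that("read_standoff loads entities, screens types, checks integrity", {
  d <- write_tiny_standoff()
  doc <- read_standoff(file.path(d, "doc1.txt"), file.path(d, "doc1.a1"))
  expect_s3_class(doc, "standoff_document")
  expect_equal(nrow(doc$entities), 1L)
  expect_equal(nrow(doc$relations), 0L)
  expect_equal(doc$entities$surface, "LEC1")

  # non-Gene/Protein entity is dropped and counted
  d2 <- write_tiny_standoff(text = "LEC1 binds mRNA.",
                            a1 = c("T1\tGene 0 4\tLEC1",
                                   "T2\tRNA 11 15\tmRNA"))
  expect_message(
    doc2 <- read_standoff(file.path(d2, "doc1.txt"),
                          file.path(d2, "doc1.a1")),
    "skipped 1")
  expect_equal(nrow(doc2$entities), 1L)
  expect_equal(doc2$skipped_entity_count, 1L)

  # relation referencing an id absent from .a1 is an integrity error
  d3 <- write_tiny_standoff(text = "LEC1 binds FUS3.",
                            a1 = c("T1\tGene 0 4\tLEC1",
                                   "T2\tProtein 11 15\tFUS3"),
                            a2 = "R1\tBinds_To Arg1:T1 Arg2:T9")
  expect_error(read_standoff(file.path(d3, "doc1.txt"),
                             file.path(d3, "doc1.a1"),
                             file.path(d3, "doc1.a2")),
               "absent from \\.a1")

  # malformed a1 line names file and line
  d4 <- write_tiny_standoff(a1 = "T1 Gene 0 4 LEC1")
  expect_error(read_standoff(file.path(d4, "doc1.txt"),
                             file.path(d4, "doc1.a1")),
               "doc1\\.a1:1")
})

test_that("write_standoff then read_standoff is the identity", {
  d <- write_tiny_standoff(text = "LEC1 binds FUS3. FUS3 binds LEC1.",
                           a1 = c("T1\tGene 0 4\tLEC1",
                                  "T2\tProtein 11 15\tFUS3",
                                  "T3\tProtein 17 21\tFUS3",
                                  "T4\tGene 28 32\tLEC1"),
                           a2 = c("R1\tBinds_To Arg1:T1 Arg2:T2",
                                  "R2\tBinds_To Arg1:T3 Arg2:T4"))
  doc <- read_standoff(file.path(d, "doc1.txt"), file.path(d, "doc1.a1"),
                       file.path(d, "doc1.a2"))
  out <- tempfile("roundtrip")
  write_standoff(doc, out)
  doc2 <- read_standoff(file.path(out, "doc1.txt"),
                        file.path(out, "doc1.a1"),
                        file.path(out, "doc1.a2"))
  expect_identical(doc$text, doc2$text)
  expect_identical(doc$entities, doc2$entities)
  expect_identical(doc$relations, doc2$relations)
  # and byte-identical files
  for (f in c("doc1.txt", "doc1.a1", "doc1.a2")) {
    expect_identical(readLines(file.path(d, f), warn = FALSE),
                     readLines(file.path(out, f), warn = FALSE))
  }
})

test_that("candidate pairs are all ordered co-sentential pairs", {
  text <- "A1 binds B2 and C3. D4 alone."
  ents <- data.frame(id = c("T1", "T2", "T3", "T4"),
                     etype = c("Gene", "Protein", "Gene", "Gene"),
                     char_start = c(0L, 9L, 16L, 20L),
                     char_end = c(2L, 11L, 18L, 22L),
                     surface = c("A1", "B2", "C3", "D4"),
                     stringsAsFactors = FALSE)
  doc <- standoff_document("d", text, ents)
  p1 <- candidate_pairs(doc, 1L)
  expect_equal(nrow(p1), 3L * 2L)            # n(n-1)
  expect_false(any(p1$arg1 == p1$arg2))
  expect_equal(nrow(candidate_pairs(doc, 2L)), 0L)  # one entity -> none
  # no pair crosses the sentence boundary
  expect_false("T4" %in% c(p1$arg1, p1$arg2))
})

test_that("cross-sentence entities are rejected with a warning", {
  text <- "A binds B. C binds D."
  ents <- data.frame(id = "T1", etype = "Gene", char_start = 8L,
                     char_end = 12L, surface = "B. C",
                     stringsAsFactors = FALSE)
  expect_warning(doc <- standoff_document("d", text, ents),
                 "cross-sentence")
  expect_equal(nrow(doc$entities), 0L)
})
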