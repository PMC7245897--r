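test_that("P/R/F1 reproduces the worked example and conventions", {
  pred <- data.frame(rtype = c("Binds_To", "Binds_To", "Binds_To"),
                     arg1 = c("T1", "T2", "T3"),
                     arg2 = c("T2", "T3", "T4"))
  gold <- data.frame(rtype = c("Binds_To", "Binds_To", "Binds_To",
                               "Binds_To"),
                     arg1 = c("T1", "T2", "T5", "T6"),
                     arg2 = c("T2", "T3", "T6", "T7"))
  r <- evaluate_prf(pred, gold)   # tp=2 fp=1 fn=2
  expect_equal(unname(r$micro["precision"]), 2/3, tolerance = 1e-12)
  expect_equal(unname(r$micro["recall"]), 1/2, tolerance = 1e-12)
  expect_equal(unname(r$micro["f1"]), 4/7, tolerance = 1e-12)
  expect_equal(round(unname(r$micro[c("precision", "recall", "f1")]), 4),
               c(0.6667, 0.5, 0.5714))

  # perfect agreement
  r2 <- evaluate_prf(gold, gold)
  expect_equal(unname(r2$micro[c("precision", "recall", "f1")]), c(1, 1, 1))

  # no predictions against non-empty gold: all-zero by convention
  r3 <- evaluate_prf(pred[0, ], gold)
  expect_equal(unname(r3$micro[c("precision", "recall", "f1")]), c(0, 0, 0))

  # NONE predictions are abstentions, not false positives
  r4 <- evaluate_prf(data.frame(rtype = "NONE", arg1 = "T1", arg2 = "T2"),
                     gold)
  expect_equal(unname(r4$micro["fp"]), 0)

  # direction matters
  r5 <- evaluate_prf(data.frame(rtype = "Binds_To", arg1 = "T2",
                                arg2 = "T1"), gold)
  expect_equal(unname(r5$micro["tp"]), 0)
})

test_that("P/R/F1 agrees with a counting oracle on fuzzed cases", {
  set.seed(31)
  labels <- c("Binds_To", "Interacts_With", "Regulates_Expression")
  for (i in 1:1000) {
    mk <- function(n) {
      if (n == 0) return(data.frame(rtype = character(0),
                                    arg1 = character(0),
                                    arg2 = character(0)))
      unique(data.frame(rtype = sample(labels, n, TRUE),
                        arg1 = sample(paste0("T", 1:5), n, TRUE),
                        arg2 = sample(paste0("T", 1:5), n, TRUE),
                        stringsAsFactors = FALSE))
    }
    pred <- mk(sample(0:8, 1)); gold <- mk(sample(0:8, 1))
    r <- evaluate_prf(pred, gold)
    pk <- paste(pred$rtype, pred$arg1, pred$arg2)
    gk <- paste(gold$rtype, gold$arg1, gold$arg2)
    tp <- length(intersect(pk, gk))
    fp <- length(setdiff(pk, gk))
    fn <- length(setdiff(gk, pk))
    expect_equal(unname(r$micro["tp"]), tp)
    expect_equal(unname(r$micro["fp"]), fp)
    expect_equal(unname(r$micro["fn"]), fn)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    rr <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + rr > 0) 2 * p * rr / (p + rr) else 0
    expect_equal(unname(r$micro["f1"]), f)
    # micro counts equal the per-label sums
    expect_equal(sum(r$per_label$tp), tp)
  }
})

test_that("training configuration enforces the admitted learning rates", {
  expect_error(train_config(lr = 0.5), "0.8, 0.9, 1.0")
  expect_silent(train_config(lr = 0.9))
  cfg <- train_config()
  expect_equal(cfg$lr, 1.0)
  expect_equal(cfg$l2, 1e-5)
  expect_equal(cfg$batch_size, 10L)
})

test_that("a separable lexical corpus is learned to high training F1", {
  cfg <- synth_config(n_documents = 10, sentences_per_doc = 5,
                      p_trigger = 1, kb_signal = 0, seed = 11)
  docs <- generate_corpus(cfg)
  ep <- tempfile(fileext = ".txt")
  generate_embeddings(cfg, docs, ep, dim = 24)
  tab <- load_embeddings(ep, dim = 24)
  mcfg <- model_config(embed_dim = 24, lstm_state = 16, use_kb = FALSE,
                       seed = 11)
  tcfg <- train_config(max_epochs = 30, seed = 11)
  ck <- train_relation_model(docs, NULL, tab, mcfg, tcfg)
  expect_true(all(diff(ck$log$train_loss[c(1, 10, 30)]) < 0))
  b <- build_relation_instances(docs, NULL, tab, mcfg, ck$labels)
  pred <- vapply(b$instances, function(it) {
    kbrelex:::relation_forward(ck$params, it$X, it$V, mcfg)$pred
  }, 1L)
  gold <- vapply(b$instances, function(it) it$y, 1L)
  f1 <- kbrelex:::instance_micro_f1(pred, gold, length(ck$labels))
  expect_gte(unname(f1), 0.95)
})

test_that("training is seed-reproducible and seed-sensitive", {
  cfg <- synth_config(n_documents = 4, sentences_per_doc = 3, seed = 2)
  docs <- generate_corpus(cfg)
  ep <- tempfile(fileext = ".txt")
  generate_embeddings(cfg, docs, ep, dim = 12)
  tab <- load_embeddings(ep, dim = 12)
  mcfg <- model_config(embed_dim = 12, lstm_state = 8, use_kb = FALSE,
                       seed = 4)
  tcfg <- train_config(max_epochs = 3, seed = 4)
  ck1 <- train_relation_model(docs, NULL, tab, mcfg, tcfg)
  ck2 <- train_relation_model(docs, NULL, tab, mcfg, tcfg)
  expect_identical(ck1$params, ck2$params)
  expect_identical(ck1$log, ck2$log)
  mcfg2 <- model_config(embed_dim = 12, lstm_state = 8, use_kb = FALSE,
                        seed = 5)
  ck3 <- train_relation_model(docs, NULL, tab, mcfg2, tcfg)
  expect_false(identical(ck1$params$W, ck3$params$W))
  expect_error(train_relation_model(list(), NULL, tab, mcfg, tcfg),
               "empty corpus")
})

test_that("prediction suppresses NONE, is deterministic, and survives empty docs", {
  cfg <- synth_config(n_documents = 4, sentences_per_doc = 3,
                      p_trigger = 1, seed = 6)
  docs <- generate_corpus(cfg)
  ep <- tempfile(fileext = ".txt")
  generate_embeddings(cfg, docs, ep, dim = 12)
  tab <- load_embeddings(ep, dim = 12)
  mcfg <- model_config(embed_dim = 12, lstm_state = 8, use_kb = FALSE,
                       seed = 6)
  ck <- train_relation_model(docs, NULL, tab, mcfg,
                             train_config(max_epochs = 10, seed = 6))
  p1 <- predict_document(docs[[1]], ck, NULL, tab)
  p2 <- predict_document(docs[[1]], ck, NULL, tab)
  expect_identical(p1$relations, p2$relations)
  expect_false(any(p1$relations$rtype == "NONE"))
  # a document with no entities yields no relations
  bare <- standoff_document("empty", "Nothing to see here.")
  expect_equal(nrow(predict_document(bare, ck, NULL, tab)$relations), 0L)
})

test_that("checkpoints round-trip and the emitted run config is faithful", {
  mcfg <- model_config(embed_dim = 6, lstm_state = 4, seed = 1)
  params <- init_relation_params(mcfg, 3L)
  ck <- structure(list(params = params, model_cfg = mcfg,
                       labels = c("A", "B", "NONE"), task = "relation",
                       log = data.frame()), class = "kbx_checkpoint")
  p <- tempfile(fileext = ".ckpt")
  save_checkpoint(ck, p)
  ck2 <- load_checkpoint(p)
  expect_identical(ck$params, ck2$params)
  expect_identical(ck$labels, ck2$labels)

  yml <- tempfile(fileext = ".yaml")
  write_run_config(model_config(), train_config(), yml)
  rc <- read_run_config(yml)
  expect_equal(rc$model$embed_dim, 200L)
  expect_equal(rc$train$lr, 1.0)
  expect_true(is.infinite(rc$train$negative_ratio))
})

test_that("the entity tagger learns to recover planted spans and types", {
  cfg <- synth_config(n_documents = 6, sentences_per_doc = 5,
                      entities_per_sentence = 1, p_positive = 0, seed = 21)
  docs <- generate_corpus(cfg)
  ep <- tempfile(fileext = ".txt")
  generate_embeddings(cfg, docs, ep, dim = 24)
  tab <- load_embeddings(ep, dim = 24)
  for (crf in c(FALSE, TRUE)) {
    mcfg <- model_config(embed_dim = 24, lstm_state = 12, use_kb = FALSE,
                         use_crf = crf, seed = 21)
    ck <- train_entity_model(docs, NULL, tab, mcfg,
                             train_config(max_epochs = 60, seed = 21))
    expect_lt(tail(ck$log$train_loss, 1), ck$log$train_loss[1])
    pd <- predict_entities(docs[[1]], ck, NULL, tab)
    g <- docs[[1]]$entities
    hits <- sum(paste(pd$entities$char_start, pd$entities$char_end) %in%
                  paste(g$char_start, g$char_end))
    expect_gte(hits, nrow(g) - 1L)   # recovers (almost) all planted spans
  }
})
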