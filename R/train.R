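# Training: AdaDelta over nested parameter lists, relation/entity
# training loops, prediction, and checkpoints.

# ---- AdaDelta over a nested list of numeric tensors ------------------

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  p * 0
}

accumulate_grads <- function(acc, g) {
  if (is.list(acc)) {
    for (nm in names(acc)) acc[[nm]] <- accumulate_grads(acc[[nm]], g[[nm]])
    return(acc)
  }
  acc + g
}

scale_grads <- function(g, f) {
  if (is.list(g)) return(lapply(g, scale_grads, f = f))
  g * f
}

adadelta_state <- function(params) {
  list(Eg = zeros_like(params), Ed = zeros_like(params))
}

# one AdaDelta update; g already includes any L2 term
adadelta_step <- function(params, g, st, cfg) {
  walk <- function(p, g, eg, ed) {
    if (is.list(p)) {
      out_p <- p; out_eg <- eg; out_ed <- ed
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], eg[[nm]], ed[[nm]])
        out_p[[nm]] <- r$p; out_eg[[nm]] <- r$eg; out_ed[[nm]] <- r$ed
      }
      return(list(p = out_p, eg = out_eg, ed = out_ed))
    }
    eg <- cfg$rho * eg + (1 - cfg$rho) * g^2
    delta <- -sqrt(ed + cfg$epsilon) / sqrt(eg + cfg$epsilon) * g * cfg$lr
    ed <- cfg$rho * ed + (1 - cfg$rho) * delta^2
    list(p = p + delta, eg = eg, ed = ed)
  }
  r <- walk(params, g, st$Eg, st$Ed)
  list(params = r$p, state = list(Eg = r$eg, Ed = r$ed))
}

add_l2 <- function(g, params, l2) {
  if (l2 <= 0) return(g)
  walk <- function(g, p) {
    if (is.list(g)) {
      for (nm in names(g)) g[[nm]] <- walk(g[[nm]], p[[nm]])
      return(g)
    }
    g + l2 * p
  }
  walk(g, params)
}

# ---- relation instances ----------------------------------------------

#' Build relation classification instances from a corpus
#'
#' One instance per ordered candidate entity pair per sentence: the input
#' token window (per the configured mode), the pair-level KB vector set
#' (the deduplicated union of the related entities of both arguments —
#' one shared attention memory for the pair), and the gold label, with
#' unannotated pairs labeled `NONE`.
#'
#' @param docs List of [standoff_document()]s.
#' @param store A [kb_store()] (may be `NULL` when `cfg$use_kb` is
#'   `FALSE`).
#' @param table An [embedding_table()].
#' @param cfg A [model_config()].
#' @param labels Label set (last label must be `"NONE"`); defaults to
#'   the relation types present in the corpus plus `NONE`.
#' @return List with `instances` (each holding `X`, `V`, `y`, ids) and
#'   `labels`.
#' @export
build_relation_instances <- function(docs, store, table, cfg, labels = NULL) {
  if (is.null(labels)) {
    pos <- sort(unique(unlist(lapply(docs, function(d) d$relations$rtype))))
    labels <- c(pos, "NONE")
  }
  stopifnot(labels[length(labels)] == "NONE")
  kb_cache <- new.env(parent = emptyenv())
  rel_of <- function(surface) {
    key <- normalize_name(surface)
    hit <- kb_cache[[key]]
    if (is.null(hit)) {
      hit <- list(v = related_entities(surface, store))
      kb_cache[[key]] <- hit
    }
    hit$v
  }
  instances <- list()
  for (doc in docs) {
    gold <- doc$relations
    gold_key <- paste(gold$arg1, gold$arg2)
    for (si in seq_along(doc$sentences)) {
      pairs <- candidate_pairs(doc, si)
      if (!nrow(pairs)) next
      sent <- doc$sentences[[si]]
      for (pi in seq_len(nrow(pairs))) {
        e1 <- doc$entities[doc$entities$id == pairs$arg1[pi], ]
        e2 <- doc$entities[doc$entities$id == pairs$arg2[pi], ]
        idx <- build_relation_input(sent, e1, e2, cfg$input_mode,
                                    cfg$window_expand)
        toks <- sent$tokens$surface[idx]
        X <- embed_tokens(toks, table)
        V <- NULL
        if (cfg$use_kb && !is.null(store)) {
          rel <- unique(c(rel_of(e1$surface), rel_of(e2$surface)))
          rel <- rel[!duplicated(normalize_name(rel))]
          if (length(rel)) V <- kb_vectors(rel, table)$vectors
        }
        g <- match(paste(pairs$arg1[pi], pairs$arg2[pi]), gold_key)
        y <- if (is.na(g)) length(labels) else match(gold$rtype[g], labels)
        instances[[length(instances) + 1L]] <-
          list(doc = doc$id, arg1 = pairs$arg1[pi], arg2 = pairs$arg2[pi],
               X = X, V = V, y = y)
      }
    }
  }
  list(instances = instances, labels = labels)
}

# micro-F1 over instance predictions (NONE excluded); labels' last
# element is NONE
instance_micro_f1 <- function(pred, gold, n_labels) {
  none <- n_labels
  tp <- sum(pred == gold & gold != none)
  fp <- sum(pred != none & pred != gold)
  fn <- sum(gold != none & pred != gold)
  prf_from_counts(tp, fp, fn)["f1"]
}

prf_from_counts <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

# ---- relation training loop ------------------------------------------

#' Train the relation extraction model
#'
#' Cross-entropy training of the BiLSTM + KB-attention relation
#' classifier with AdaDelta, per-minibatch L2, and optional early
#' stopping on validation micro-F1. Deterministic for a fixed
#' `train_cfg$seed` on CPU.
#'
#' @param docs Training documents (with relation annotations).
#' @param store A [kb_store()] or `NULL`.
#' @param table An [embedding_table()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param labels Optional fixed label set (last must be `"NONE"`).
#' @return Object of class `kbx_checkpoint`: `params`, `model_cfg`,
#'   `labels`, and `log` (per-epoch loss and validation F1).
#' @export
train_relation_model <- function(docs, store, table, model_cfg, train_cfg,
                                 labels = NULL) {
  if (!length(docs)) stop("empty corpus")
  built <- build_relation_instances(docs, store, table, model_cfg, labels)
  inst <- built$instances
  labels <- built$labels
  if (!length(inst)) stop("corpus yields no candidate pairs")
  params <- init_relation_params(model_cfg, length(labels))
  # seed shuffling/subsampling after initialization so that two models
  # whose KB pathway never activates follow identical trajectories
  set.seed(train_cfg$seed)
  # cap the NONE:positive ratio if requested
  if (is.finite(train_cfg$negative_ratio)) {
    ys <- vapply(inst, function(i) i$y, 1L)
    neg <- which(ys == length(labels))
    npos <- sum(ys != length(labels))
    cap <- ceiling(train_cfg$negative_ratio * max(1L, npos))
    if (length(neg) > cap) {
      drop <- sample(neg, length(neg) - cap)
      inst <- inst[-drop]
    }
  }
  n <- length(inst)
  val_idx <- integer(0)
  if (train_cfg$val_fraction > 0 && n >= 10L) {
    val_idx <- sample(n, max(1L, round(train_cfg$val_fraction * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  st <- adadelta_state(params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_f1 = numeric(0))
  best_f1 <- -Inf; best_params <- params; wait <- 0L
  for (ep in seq_len(train_cfg$max_epochs)) {
    ord <- sample(tr_idx)
    total <- 0
    for (bs in seq(1L, length(ord), by = train_cfg$batch_size)) {
      batch <- ord[bs:min(bs + train_cfg$batch_size - 1L, length(ord))]
      acc <- NULL
      for (ii in batch) {
        it <- inst[[ii]]
        fw <- relation_forward(params, it$X, it$V, model_cfg, it$y,
                               training = TRUE)
        total <- total + fw$loss
        g <- relation_backward(params, fw, it$X, model_cfg, it$y)
        acc <- if (is.null(acc)) g else accumulate_grads(acc, g)
      }
      acc <- scale_grads(acc, 1 / length(batch))
      acc <- add_l2(acc, params, train_cfg$l2)
      upd <- adadelta_step(params, acc, st, train_cfg)
      params <- upd$params; st <- upd$state
    }
    vf <- NA_real_
    if (length(val_idx)) {
      vp <- vapply(val_idx, function(ii) {
        it <- inst[[ii]]
        relation_forward(params, it$X, it$V, model_cfg)$pred
      }, 1L)
      vg <- vapply(inst[val_idx], function(i) i$y, 1L)
      vf <- instance_micro_f1(vp, vg, length(labels))
      if (vf > best_f1 + 1e-9) {
        best_f1 <- vf; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    log <- rbind(log, data.frame(epoch = ep,
                                 train_loss = total / length(tr_idx),
                                 val_f1 = vf))
    if (length(val_idx) && wait >= train_cfg$patience) break
  }
  if (length(val_idx)) params <- best_params
  structure(list(params = params, model_cfg = model_cfg, labels = labels,
                 task = "relation", log = log),
            class = "kbx_checkpoint")
}

#' @export
print.kbx_checkpoint <- function(x, ...) {
  cat(sprintf("<kbx_checkpoint> %s model, %d labels, %d epochs trained\n",
              x$task, length(x$labels), nrow(x$log)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive of the configuration, label set
#' and named parameter tensors.
#'
#' @param ckpt A `kbx_checkpoint`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "kbx_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "kbx_checkpoint")) stop("not a kbrelex checkpoint")
  ckpt
}

# ---- entity training loop --------------------------------------------

#' Train the two-stage entity extraction model
#'
#' Stage 1 learns BIOE position tagging (token-level cross-entropy, or
#' the CRF negative log-likelihood when `model_cfg$use_crf`); stage 2
#' learns the Gene/Protein type classifier over gold span
#' representations.
#'
#' @inheritParams train_relation_model
#' @return Object of class `kbx_checkpoint` with `task = "entity"`.
#' @export
train_entity_model <- function(docs, store, table, model_cfg, train_cfg) {
  if (!length(docs)) stop("empty corpus")
  tag_idx <- stats::setNames(seq_along(bioe_tags()), bioe_tags())
  sents <- list()
  for (doc in docs) {
    for (si in seq_along(doc$sentences)) {
      sent <- doc$sentences[[si]]
      if (!nrow(sent$tokens)) next
      ents <- doc$entities[doc$entities$sentence == si, , drop = FALSE]
      gold <- unname(tag_idx[spans_to_bioe(sent, ents)])
      X <- embed_tokens(sent$tokens$surface, table)
      V <- if (model_cfg$use_kb && !is.null(store)) {
        sentence_kb_vectors(sent$tokens$surface, store, table)
      } else NULL
      sents[[length(sents) + 1L]] <- list(X = X, V = V, gold = gold,
                                          ents = ents)
    }
  }
  if (!length(sents)) stop("corpus yields no sentences")
  # stage-2 training items: gold spans with type labels
  types <- list()
  for (s in sents) {
    if (!nrow(s$ents)) next
    for (i in seq_len(nrow(s$ents))) {
      rep <- entity_representation(s$ents$surface[i], s$ents$etype[i],
                                   if (!is.null(store)) {
                                     lookup_records(s$ents$surface[i], store)
                                   } else list(), table)
      # stage 2 predicts the type, so the input omits the type component
      r <- rep$components$word + rep$components$annotation
      Ve <- NULL
      if (model_cfg$use_kb && !is.null(store)) {
        rel <- related_entities(s$ents$surface[i], store)
        if (length(rel)) Ve <- kb_vectors(rel, table)$vectors
      }
      types[[length(types) + 1L]] <-
        list(r = r, V = Ve, y = match(s$ents$etype[i], entity_types()))
    }
  }
  set.seed(train_cfg$seed)
  params <- init_entity_params(model_cfg)
  st <- adadelta_state(params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0))
  for (ep in seq_len(train_cfg$max_epochs)) {
    ord <- sample(seq_along(sents))
    total <- 0
    for (bs in seq(1L, length(ord), by = train_cfg$batch_size)) {
      batch <- ord[bs:min(bs + train_cfg$batch_size - 1L, length(ord))]
      acc <- NULL
      for (ii in batch) {
        s <- sents[[ii]]
        fw <- tagger_forward(params, s$X, s$V, model_cfg, s$gold,
                             training = TRUE)
        total <- total + fw$loss
        g <- tagger_backward(params, fw, s$X, model_cfg, s$gold)
        g$W_type <- zeros_like(params$W_type)
        g$b_type <- zeros_like(params$b_type)
        g$U_type <- zeros_like(params$U_type)
        acc <- if (is.null(acc)) g else accumulate_grads(acc, g)
      }
      acc <- scale_grads(acc, 1 / length(batch))
      acc <- add_l2(acc, params, train_cfg$l2)
      upd <- adadelta_step(params, acc, st, train_cfg)
      params <- upd$params; st <- upd$state
    }
    # stage 2 full-batch pass
    if (length(types)) {
      acc <- NULL
      for (it in types) {
        fb <- type_forward_backward(params, it$r, it$V, it$y)
        g <- zeros_like(params)
        g$W_type <- fb$grads$W_type
        g$b_type <- fb$grads$b_type
        g$U_type <- fb$grads$U_type
        acc <- if (is.null(acc)) g else accumulate_grads(acc, g)
      }
      acc <- scale_grads(acc, 1 / length(types))
      upd <- adadelta_step(params, acc, st, train_cfg)
      params <- upd$params; st <- upd$state
    }
    log <- rbind(log, data.frame(epoch = ep,
                                 train_loss = total / length(sents)))
  }
  structure(list(params = params, model_cfg = model_cfg,
                 labels = bioe_tags(), task = "entity", log = log),
            class = "kbx_checkpoint")
}

# ---- evaluation -------------------------------------------------------

#' Micro-averaged precision/recall/F1 over relation instances
#'
#' Matching is exact on `(rtype, arg1, arg2)` — relations are directed.
#' `NONE` predictions are abstentions: they are never counted as false
#' positives, and `NONE` is excluded from micro aggregation, following
#' shared-task convention. With empty denominators precision, recall and
#' F1 are 0 by convention.
#'
#' @param predicted,gold Data frames with columns `rtype`, `arg1`,
#'   `arg2` and optionally `doc` (document scoping of ids).
#' @return Object of class `prf_report`: per-label and micro counts with
#'   precision, recall, F1.
#' @export
evaluate_prf <- function(predicted, gold) {
  canon <- function(x) {
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (!nrow(x)) {
      return(data.frame(rtype = character(0), key = character(0)))
    }
    x <- x[x$rtype != "NONE", , drop = FALSE]
    doc <- if ("doc" %in% names(x)) x$doc else rep("", nrow(x))
    data.frame(rtype = x$rtype,
               key = paste(doc, x$rtype, x$arg1, x$arg2, sep = "\r"),
               stringsAsFactors = FALSE)
  }
  p <- canon(predicted); g <- canon(gold)
  p <- p[!duplicated(p$key), , drop = FALSE]
  g <- g[!duplicated(g$key), , drop = FALSE]
  labels <- sort(unique(c(p$rtype, g$rtype)))
  per <- data.frame(label = labels,
                    tp = integer(length(labels)),
                    fp = integer(length(labels)),
                    fn = integer(length(labels)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    pk <- p$key[p$rtype == labels[i]]
    gk <- g$key[g$rtype == labels[i]]
    per$tp[i] <- sum(pk %in% gk)
    per$fp[i] <- sum(!pk %in% gk)
    per$fn[i] <- sum(!gk %in% pk)
  }
  per$precision <- per$recall <- per$f1 <- numeric(length(labels))
  for (i in seq_along(labels)) {
    per[i, c("precision", "recall", "f1")] <-
      prf_from_counts(per$tp[i], per$fp[i], per$fn[i])
  }
  per <- per[, c("label", "tp", "fp", "fn", "precision", "recall", "f1")]
  micro <- prf_from_counts(sum(per$tp), sum(per$fp), sum(per$fn))
  structure(list(per_label = per,
                 micro = c(tp = sum(per$tp), fp = sum(per$fp),
                           fn = sum(per$fn), micro)),
            class = "prf_report")
}

#' @export
print.prf_report <- function(x, ...) {
  cat("micro: ", sprintf("P=%.4f R=%.4f F1=%.4f (tp=%d fp=%d fn=%d)\n",
                         x$micro["precision"], x$micro["recall"],
                         x$micro["f1"], x$micro["tp"], x$micro["fp"],
                         x$micro["fn"]))
  if (nrow(x$per_label)) print(x$per_label, row.names = FALSE)
  invisible(x)
}

# ---- prediction -------------------------------------------------------

#' Predict relations for a document
#'
#' For each ordered candidate pair in each sentence: build the input
#' window, embed, encode, attend over the pair's KB vectors per time
#' step, pool, classify. `NONE` predictions are suppressed from the
#' output. Deterministic in evaluation mode.
#'
#' @param doc A [standoff_document()] (entities present; gold relations
#'   ignored).
#' @param ckpt A relation `kbx_checkpoint`.
#' @param store A [kb_store()] or `NULL`.
#' @param table An [embedding_table()].
#' @return The document with `relations` replaced by predictions (ids
#'   `R1`, `R2`, ...).
#' @export
predict_document <- function(doc, ckpt, store, table) {
  stopifnot(inherits(ckpt, "kbx_checkpoint"), ckpt$task == "relation")
  bare <- doc
  bare$relations <- empty_relations()
  built <- build_relation_instances(list(bare), store, table,
                                    ckpt$model_cfg, ckpt$labels)
  out <- empty_relations()
  none <- length(ckpt$labels)
  rid <- 0L
  for (it in built$instances) {
    fw <- relation_forward(ckpt$params, it$X, it$V, ckpt$model_cfg)
    if (fw$pred != none) {
      rid <- rid + 1L
      out <- rbind(out, data.frame(id = paste0("R", rid),
                                   rtype = ckpt$labels[fw$pred],
                                   arg1 = it$arg1, arg2 = it$arg2,
                                   stringsAsFactors = FALSE))
    }
  }
  doc$relations <- out
  doc
}

#' Predict entity mentions for a document
#'
#' Stage 1 tags every sentence; decoded spans are typed by stage 2.
#'
#' @param doc A [standoff_document()] (annotations ignored).
#' @param ckpt An entity `kbx_checkpoint`.
#' @param store A [kb_store()] or `NULL`.
#' @param table An [embedding_table()].
#' @return The document with `entities` replaced by predictions (ids
#'   `T1`, `T2`, ...).
#' @export
predict_entities <- function(doc, ckpt, store, table) {
  stopifnot(inherits(ckpt, "kbx_checkpoint"), ckpt$task == "entity")
  ents <- empty_entities()
  tid <- 0L
  for (si in seq_along(doc$sentences)) {
    sent <- doc$sentences[[si]]
    if (!nrow(sent$tokens)) next
    tags <- tag_entities(sent, ckpt$params, ckpt$model_cfg, table, store)
    spans <- bioe_to_spans(tags, sent)
    if (!nrow(spans)) next
    for (i in seq_len(nrow(spans))) {
      surf <- substr(doc$text, spans$char_start[i] + 1L, spans$char_end[i])
      recs <- if (!is.null(store)) lookup_records(surf, store) else list()
      rep <- entity_representation(surf, "gene", recs, table)
      r <- rep$components$word + rep$components$annotation
      Ve <- NULL
      if (ckpt$model_cfg$use_kb && !is.null(store)) {
        rel <- related_entities(surf, store)
        if (length(rel)) Ve <- kb_vectors(rel, table)$vectors
      }
      ty <- type_entities(r, ckpt$params, Ve)
      tid <- tid + 1L
      ents <- rbind(ents, data.frame(id = paste0("T", tid),
                                     etype = ty$label,
                                     char_start = spans$char_start[i],
                                     char_end = spans$char_end[i],
                                     surface = surf, sentence = si,
                                     stringsAsFactors = FALSE))
    }
  }
  doc$entities <- ents
  doc
}
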