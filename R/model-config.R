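#' Model configuration
#'
#' Defaults follow the reference setting: 200-dimensional embeddings, a
#' BiLSTM state size of 200 per direction (so hidden states have 400
#' components), dropout 0.3 on the recurrent layer's inputs, four
#' position tags (BIOE), two entity types, and eight relation types plus
#' `NONE`.
#'
#' @param embed_dim Word embedding dimension.
#' @param lstm_state LSTM state size per direction.
#' @param dropout Dropout rate on BiLSTM inputs during training.
#' @param num_entity_tags Size of the position-tag alphabet.
#' @param num_entity_types Number of entity type labels.
#' @param num_relation_labels Relation labels including `NONE`.
#' @param input_mode `"whole_sentence"` or `"between_entities"` (the two
#'   input constructions for relation instances).
#' @param window_expand Words of context added on each side in
#'   `between_entities` mode (guards against degenerate inputs when the
#'   pair is adjacent).
#' @param use_kb Attend over KB-related entity vectors.
#' @param use_crf Use a linear-chain CRF output layer for tagging.
#' @param seed Parameter initialization seed.
#' @return Object of class `model_config`.
#' @export
model_config <- function(embed_dim = 200L, lstm_state = 200L, dropout = 0.3,
                         num_entity_tags = 4L, num_entity_types = 2L,
                         num_relation_labels = 9L,
                         input_mode = c("between_entities", "whole_sentence"),
                         window_expand = 2L, use_kb = TRUE, use_crf = FALSE,
                         seed = 1L) {
  input_mode <- match.arg(input_mode)
  stopifnot(embed_dim > 0, lstm_state > 0, dropout >= 0, dropout < 1,
            num_entity_tags > 0, num_entity_types > 0,
            num_relation_labels > 0, window_expand >= 0)
  structure(list(embed_dim = as.integer(embed_dim),
                 lstm_state = as.integer(lstm_state),
                 dropout = dropout,
                 num_entity_tags = as.integer(num_entity_tags),
                 num_entity_types = as.integer(num_entity_types),
                 num_relation_labels = as.integer(num_relation_labels),
                 input_mode = input_mode,
                 window_expand = as.integer(window_expand),
                 use_kb = isTRUE(use_kb), use_crf = isTRUE(use_crf),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Training configuration
#'
#' AdaDelta with learning-rate multiplier 1.0 (0.8 and 0.9 are the other
#' admitted values), per-minibatch L2 strength `1e-5`, minibatch size 10
#' (20 for large corpora). Early stopping monitors validation micro-F1.
#'
#' @param lr Learning-rate multiplier; one of 0.8, 0.9, 1.0.
#' @param l2 L2 regularization strength applied per minibatch.
#' @param batch_size Minibatch size.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   micro-F1 improvement); ignored when no validation split is used.
#' @param val_fraction Fraction of training instances held out for early
#'   stopping (0 disables early stopping).
#' @param rho,epsilon AdaDelta decay and stabilizer constants.
#' @param negative_ratio Cap on the NONE:positive instance ratio during
#'   training (`Inf` keeps every candidate pair).
#' @param seed Seed for shuffling and initialization.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1.0, l2 = 1e-5, batch_size = 10L,
                         max_epochs = 30L, patience = 10L,
                         val_fraction = 0, rho = 0.95, epsilon = 1e-6,
                         negative_ratio = Inf, seed = 1L) {
  if (!lr %in% c(0.8, 0.9, 1.0)) {
    stop("lr must be one of 0.8, 0.9, 1.0")
  }
  stopifnot(batch_size > 0, max_epochs >= 1, l2 >= 0,
            val_fraction >= 0, val_fraction < 1, negative_ratio > 0)
  structure(list(lr = lr, l2 = l2, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, rho = rho, epsilon = epsilon,
                 negative_ratio = negative_ratio, seed = as.integer(seed)),
            class = "train_config")
}

#' Emit a run configuration as YAML
#'
#' Serializes the model and training sections into one YAML document
#' (the run-config format also accepted by the command-line helper).
#'
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param path Optional file to write; otherwise the YAML string is
#'   returned.
#' @return The YAML string, invisibly when written to `path`.
#' @export
write_run_config <- function(model_cfg, train_cfg, path = NULL) {
  obj <- list(model = unclass(model_cfg), train = unclass(train_cfg))
  obj$train$negative_ratio <- if (is.infinite(obj$train$negative_ratio)) {
    ".inf"
  } else obj$train$negative_ratio
  txt <- yaml::as.yaml(obj)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @return List with elements `model` ([model_config()]) and `train`
#'   ([train_config()]).
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  m <- obj$model
  t <- obj$train
  nr <- t$negative_ratio
  if (is.null(nr) || identical(nr, ".inf")) nr <- Inf
  list(model = model_config(m$embed_dim, m$lstm_state, m$dropout,
                            m$num_entity_tags, m$num_entity_types,
                            m$num_relation_labels, m$input_mode,
                            m$window_expand, m$use_kb, m$use_crf, m$seed),
       train = train_config(t$lr, t$l2, t$batch_size, t$max_epochs,
                            t$patience, t$val_fraction, t$rho, t$epsilon,
                            nr, t$seed))
}
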