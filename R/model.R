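# Model container: configuration, vocabularies, parameter initialization and
# checkpointing for the six-layer character+token bi-LSTM-CRF network.
#
# Parameter groups (each individually addressable, so subsets can be
# transferred): token_embedding, char_embedding, char_lstm_fwd/bwd,
# token_lstm_fwd/bwd, projection_W/b, crf_transitions/start/end.

#' Model configuration
#'
#' Dimensions of the network. Defaults: 25-dimensional character embeddings
#' with a 25-unit-per-direction character bi-LSTM, and 100-dimensional token
#' embeddings with a 100-unit-per-direction token bi-LSTM.
#'
#' @param token_dim Token embedding dimension.
#' @param char_dim Character embedding dimension.
#' @param token_hidden Token LSTM hidden units per direction.
#' @param char_hidden Character LSTM hidden units per direction.
#' @param scheme Chunking scheme, `"BIO"` (default) or `"BIOES"`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(token_dim = 100L, char_dim = 25L,
                         token_hidden = 100L, char_hidden = 25L,
                         scheme = c("BIO", "BIOES")) {
  scheme <- match.arg(scheme)
  stopifnot(token_dim >= 1, char_dim >= 1, token_hidden >= 1, char_hidden >= 1)
  structure(list(token_dim = as.integer(token_dim),
                 char_dim = as.integer(char_dim),
                 token_hidden = as.integer(token_hidden),
                 char_hidden = as.integer(char_hidden),
                 scheme = scheme),
            class = "model_config")
}

UNK_TOKEN <- "<unk>"
UNK_CHAR <- "<unk>"

#' Build vocabularies from training documents
#'
#' Token and character inventories are collected from the tokenized training
#' corpus (row 1 is reserved for the unknown token/character); the label
#' inventory is derived from the entity types present and the chunking
#' scheme.
#'
#' @param docs List of [document()]s (the training partition).
#' @param scheme Chunking scheme used for the label inventory.
#' @return A list with `tokens`, `chars` and `labels` character vectors.
#' @export
build_vocab <- function(docs, scheme = c("BIO", "BIOES")) {
  scheme <- match.arg(scheme)
  surfs <- character(0)
  types <- character(0)
  for (doc in docs) {
    sents <- tokenize(doc$text)
    for (s in sents) surfs <- c(surfs, s$surface)
    types <- c(types, doc$annotations$entity_type)
  }
  tokens <- c(UNK_TOKEN, sort(unique(surfs)))
  chars <- c(UNK_CHAR, sort(unique(unlist(strsplit(surfs, "", fixed = TRUE)))))
  labels <- scheme_labels(unique(types), scheme)
  list(tokens = tokens, chars = chars, labels = labels)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

embed_init <- function(nr, nc) {
  lim <- sqrt(3 / nc)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

init_cell <- function(hidden, input) {
  list(W_xi = glorot(hidden, input), W_hi = glorot(hidden, hidden),
       W_ci = glorot(hidden, hidden), b_i = numeric(hidden),
       W_xc = glorot(hidden, input), W_hc = glorot(hidden, hidden),
       b_c = numeric(hidden),
       W_xo = glorot(hidden, input), W_ho = glorot(hidden, hidden),
       W_co = glorot(hidden, hidden), b_o = numeric(hidden))
}

init_params <- function(vocab, config) {
  L <- length(vocab$labels)
  E <- config$token_dim + 2L * config$char_hidden
  list(token_embedding = embed_init(length(vocab$tokens), config$token_dim),
       char_embedding = embed_init(length(vocab$chars), config$char_dim),
       char_lstm_fwd = init_cell(config$char_hidden, config$char_dim),
       char_lstm_bwd = init_cell(config$char_hidden, config$char_dim),
       token_lstm_fwd = init_cell(config$token_hidden, E),
       token_lstm_bwd = init_cell(config$token_hidden, E),
       projection_W = glorot(L, 2L * config$token_hidden),
       projection_b = numeric(L),
       crf_transitions = matrix(0, L, L),
       crf_start = numeric(L),
       crf_end = numeric(L))
}

#' Create a new (randomly initialized) model
#'
#' Embeddings are initialized uniformly on plus/minus `sqrt(3/dim)`, weight
#' matrices with Glorot-uniform draws; biases and all CRF parameters start at
#' zero. If pre-trained embeddings are supplied, matching vocabulary rows
#' (exact, then lowercase match) are overwritten with the pre-trained
#' vectors; they remain trainable.
#'
#' @param vocab Vocabularies from [build_vocab()].
#' @param config A [model_config()]; its `token_dim` must equal the
#'   embedding dimension when `embeddings` is given.
#' @param seed Integer seed for the initialization.
#' @param embeddings Optional result of [load_embeddings()].
#' @return An object of class `ner_model`.
#' @export
new_model <- function(vocab, config = model_config(), seed = 1L,
                      embeddings = NULL) {
  stopifnot(inherits(config, "model_config"))
  params <- withr::with_seed(as.integer(seed), init_params(vocab, config))
  if (!is.null(embeddings)) {
    if (ncol(embeddings$matrix) != config$token_dim)
      stopf("pre-trained embedding dimension %d does not match token_dim %d",
            ncol(embeddings$matrix), config$token_dim)
    for (k in seq_along(vocab$tokens)) {
      tok <- vocab$tokens[k]
      row <- embeddings$vocab[tok]
      if (is.na(row)) row <- embeddings$vocab[tolower(tok)]
      if (!is.na(row)) params$token_embedding[k, ] <- embeddings$matrix[row, ]
    }
  }
  structure(list(config = config, vocab = vocab, params = params,
                 init_seed = as.integer(seed)),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf(paste0("<ner_model: %d tokens, %d chars, %d labels (%s); ",
                     "token %d/%d, char %d/%d>\n"),
              length(x$vocab$tokens), length(x$vocab$chars),
              length(x$vocab$labels), x$config$scheme,
              x$config$token_dim, x$config$token_hidden,
              x$config$char_dim, x$config$char_hidden))
  invisible(x)
}

# Unknown handling: exact-match lookup, then lowercase fallback, then the
# reserved UNK row.
token_ids <- function(model, surfaces) {
  idx <- match(surfaces, model$vocab$tokens)
  miss <- is.na(idx)
  if (any(miss)) {
    low <- match(tolower(surfaces[miss]), model$vocab$tokens)
    idx[miss] <- low
  }
  idx[is.na(idx)] <- 1L
  idx
}

char_ids <- function(model, surface) {
  idx <- match(strsplit(surface, "", fixed = TRUE)[[1]], model$vocab$chars)
  idx[is.na(idx)] <- 1L
  idx
}

label_ids <- function(model, labels) {
  idx <- match(labels, model$vocab$labels)
  if (anyNA(idx))
    stopf("labels outside the model inventory: %s",
          paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

# Integer-id view of a tagged sentence, as consumed by the C++ core.
sentence_to_ids <- function(model, sent, with_labels = TRUE) {
  out <- list(tok = token_ids(model, sent$tokens$surface),
              chars = lapply(sent$tokens$surface, char_ids, model = model))
  if (with_labels && !is.null(sent$labels))
    out$labels <- label_ids(model, sent$labels)
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds every named parameter group, the vocabulary maps, the
#' label inventory, the chunking scheme and the configuration; parameters
#' round-trip bit-exactly.
#'
#' @param model A `ner_model`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ner_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ner_model")) stopf("'%s' is not a model checkpoint", path)
  model
}
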