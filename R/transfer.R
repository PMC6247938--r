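# Transfer learning: initialize a target-phase model from a source-trained
# model, whole-network by default or by named layer subsets, reconciling the
# two vocabularies, and run the two-phase experiment against the
# gold-corpus-only baseline.

#' Layer group names, in lower-to-higher order
#'
#' The six transferable parameter groups of the network, ordered from the
#' lowest (closest to the characters) to the highest (most task-specific)
#' layer: `char_embedding < char_lstm < token_embedding < token_lstm <
#' projection < crf`.
#'
#' @return Character vector of group names.
#' @export
layer_groups <- function() {
  c("char_embedding", "char_lstm", "token_embedding", "token_lstm",
    "projection", "crf")
}

group_members <- list(
  char_embedding = "char_embedding",
  char_lstm = c("char_lstm_fwd", "char_lstm_bwd"),
  token_embedding = "token_embedding",
  token_lstm = c("token_lstm_fwd", "token_lstm_bwd"),
  projection = c("projection_W", "projection_b"),
  crf = c("crf_transitions", "crf_start", "crf_end"))

#' Merge source and target-corpus vocabularies
#'
#' The target vocabulary is the union of the source vocabulary and the
#' vocabulary built from the target training documents, so that embedding
#' knowledge transferred from the source is retained for words absent from
#' the small target corpus. Source entries keep their relative order; new
#' entries follow.
#'
#' @param source_vocab Vocabulary list of the source model.
#' @param target_docs Target training documents.
#' @param scheme Chunking scheme for the label inventory.
#' @return A vocabulary list (`tokens`, `chars`, `labels`).
#' @export
build_vocab_union <- function(source_vocab, target_docs, scheme = "BIO") {
  tv <- build_vocab(target_docs, scheme)
  list(tokens = c(source_vocab$tokens,
                  setdiff(tv$tokens, source_vocab$tokens)),
       chars = c(source_vocab$chars, setdiff(tv$chars, source_vocab$chars)),
       labels = sort_labels(union(source_vocab$labels, tv$labels)))
}

sort_labels <- function(labels) {
  c("O", sort(setdiff(labels, "O")))
}

#' Initialize a target model from a source-trained model
#'
#' Parameters of the requested layer groups are copied from the source
#' model; embedding rows are copied for vocabulary items shared between
#' source and target, while rows for new items keep their fresh,
#' seed-determined initialization. Non-transferred groups are freshly
#' initialized. If the label inventories differ, the projection and CRF
#' groups are freshly initialized and a warning is raised.
#'
#' @param source_model A trained `ner_model`.
#' @param target_vocab Target vocabulary (typically [build_vocab_union()]).
#' @param layers `"all"` or a character subset of [layer_groups()].
#' @param seed Seed for the fresh initialization.
#' @param config Optional target [model_config()]; must match the source
#'   dimensions for transferred groups (an error otherwise). Defaults to the
#'   source configuration.
#' @return A new `ner_model`.
#' @export
transfer_parameters <- function(source_model, target_vocab, layers = "all",
                                seed = 1L, config = NULL) {
  if (identical(layers, "all")) layers <- layer_groups()
  bad <- setdiff(layers, layer_groups())
  if (length(bad))
    stopf("unknown layer group(s): %s", paste(bad, collapse = ", "))
  if (is.null(config)) config <- source_model$config
  dims_differ <- !identical(unclass(config)[c("token_dim", "char_dim",
                                              "token_hidden", "char_hidden")],
                            unclass(source_model$config)[c("token_dim", "char_dim",
                                                           "token_hidden", "char_hidden")])
  if (dims_differ)
    stopf("target configuration dimensions are incompatible with the source model")
  target <- new_model(target_vocab, config, seed = seed)
  labels_match <- identical(source_model$vocab$labels, target_vocab$labels)
  if (!labels_match && any(c("projection", "crf") %in% layers)) {
    warnf(paste("label inventories differ between source and target;",
                "projection and CRF layers are freshly initialized"))
    layers <- setdiff(layers, c("projection", "crf"))
  }
  for (grp in layers) {
    if (grp == "token_embedding") {
      shared <- intersect(target_vocab$tokens, source_model$vocab$tokens)
      ti <- match(shared, target_vocab$tokens)
      si <- match(shared, source_model$vocab$tokens)
      target$params$token_embedding[ti, ] <-
        source_model$params$token_embedding[si, ]
    } else if (grp == "char_embedding") {
      shared <- intersect(target_vocab$chars, source_model$vocab$chars)
      ti <- match(shared, target_vocab$chars)
      si <- match(shared, source_model$vocab$chars)
      target$params$char_embedding[ti, ] <-
        source_model$params$char_embedding[si, ]
    } else {
      for (member in group_members[[grp]])
        target$params[[member]] <- source_model$params[[member]]
    }
  }
  target
}

# Train the source-phase model on the silver corpus, carving a 10% dev split
# out of it for early stopping.
train_source_model <- function(ssc, config = model_config(), seed = 1L,
                               max_epochs = 100L, quiet = TRUE) {
  ssc_split <- split_corpus(ssc, fractions = c(0.9, 0.1, 0), seed = seed)
  vocab <- build_vocab(ssc_split$train, config$scheme)
  model <- new_model(vocab, config, seed = seed)
  fit <- train_model(model, ssc_split, source_profile(seed, max_epochs),
                     quiet = quiet)
  fit$model
}

# Train baseline and transfer arms on a fixed gold split and evaluate both
# on its test partition.
run_arms <- function(source_model, gsc_split, config, seed,
                     layers = "all", max_epochs = 100L, quiet = TRUE) {
  scheme <- config$scheme
  base_vocab <- build_vocab(gsc_split$train, scheme)
  base_model <- new_model(base_vocab, config, seed = seed)
  base_fit <- train_model(base_model, gsc_split, target_profile(seed, max_epochs),
                          quiet = quiet)
  tl_vocab <- build_vocab_union(source_model$vocab, gsc_split$train, scheme)
  tl_init <- transfer_parameters(source_model, tl_vocab, layers = layers,
                                 seed = seed)
  tl_fit <- train_model(tl_init, gsc_split, target_profile(seed, max_epochs),
                        quiet = quiet)
  test_sents <- docs_to_tagged(gsc_split$test, scheme)
  list(baseline = evaluate_tagged(base_fit$model, test_sents),
       transfer = evaluate_tagged(tl_fit$model, test_sents),
       baseline_log = base_fit$log, transfer_log = tl_fit$log,
       baseline_model = base_fit$model, transfer_model = tl_fit$model)
}

#' Run the two-phase transfer experiment against the baseline
#'
#' The baseline arm trains on the gold-corpus split only (target profile).
#' The transfer arm first trains on the silver corpus (source profile, with
#' a 10% dev carve-out of the silver corpus for early stopping), transfers
#' the requested parameter groups, and fine-tunes on the same gold split
#' (target profile). Both arms are evaluated on the same held-out gold test
#' partition. Overlapping document ids between the two corpora are an error
#' (circularity guard); deduplicate and blacklist-filter the silver corpus
#' first.
#'
#' @param ssc Silver-corpus documents (source), deduplicated against `gsc`.
#' @param gsc Gold-corpus documents (target).
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param layers Layer groups to transfer (`"all"` or subset of
#'   [layer_groups()]).
#' @param max_epochs Epoch limit for both phases.
#' @param quiet Suppress progress output.
#' @return A list with `baseline` and `transfer` (`ner_eval` objects),
#'   `reduction_in_error`, and the two training logs.
#' @export
run_transfer_experiment <- function(ssc, gsc, config = model_config(),
                                    seed = 1L, layers = "all",
                                    max_epochs = 100L, quiet = TRUE) {
  overlap <- intersect(doc_ids(ssc), doc_ids(gsc))
  if (length(overlap))
    stopf("silver and gold corpora share document ids (circularity): %s",
          paste(head(overlap, 5), collapse = ", "))
  gsc_split <- split_corpus(gsc, seed = seed)
  src <- train_source_model(ssc, config, seed = seed, max_epochs = max_epochs,
                            quiet = quiet)
  arms <- run_arms(src, gsc_split, config, seed = seed, layers = layers,
                   max_epochs = max_epochs, quiet = quiet)
  rie <- if (arms$baseline$f1 < 100)
    reduction_in_error(arms$transfer$f1, arms$baseline$f1) else NA_real_
  list(baseline = arms$baseline, transfer = arms$transfer,
       reduction_in_error = rie,
       baseline_log = arms$baseline_log, transfer_log = arms$transfer_log,
       source_model = src)
}
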