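# Training: per-example stochastic gradient descent with global-norm
# gradient clipping, dropout before the token bi-LSTM, and dev-set early
# stopping with patience, under named hyperparameter profiles for the
# source (silver-corpus) and target (gold-corpus) phases.

#' Training hyperparameter profile
#'
#' @param learning_rate Positive learning rate.
#' @param gradient_clip Positive global-norm clipping threshold.
#' @param dropout_rate Probability of dropping an embedding unit.
#' @param patience Consecutive non-improving dev epochs before stopping.
#' @param max_epochs Hard epoch limit.
#' @param seed Integer seed; per-epoch shuffling and dropout seeds are
#'   derived from it.
#' @return A list of class `training_profile`.
#' @export
training_profile <- function(learning_rate, gradient_clip = 5.0, dropout_rate = 0.5,
                             patience = 10L, max_epochs = 100L, seed = 1L) {
  stopifnot(learning_rate > 0, gradient_clip > 0,
            is_probability(dropout_rate), dropout_rate < 1,
            patience >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, gradient_clip = gradient_clip,
                 dropout_rate = dropout_rate, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
            class = "training_profile")
}

#' Source- and target-phase hyperparameter profiles
#'
#' The source phase (training on the large silver corpus) uses learning rate
#' 0.0005, gradient clipping 5.0 and dropout 0.8 — deliberately aggressive
#' regularization that discourages convergence on the source data so that
#' further learning can occur on the target data. The target phase
#' (fine-tuning on the gold corpus) uses learning rate 0.005 and dropout 0.5.
#' Both use early stopping with a patience of 10 epochs.
#'
#' @param seed Integer seed.
#' @param max_epochs Hard epoch limit (default 100).
#' @return A [training_profile()].
#' @export
source_profile <- function(seed = 1L, max_epochs = 100L) {
  training_profile(learning_rate = 0.0005, gradient_clip = 5.0,
                   dropout_rate = 0.8, patience = 10L,
                   max_epochs = max_epochs, seed = seed)
}

#' @rdname source_profile
#' @export
target_profile <- function(seed = 1L, max_epochs = 100L) {
  training_profile(learning_rate = 0.005, gradient_clip = 5.0,
                   dropout_rate = 0.5, patience = 10L,
                   max_epochs = max_epochs, seed = seed)
}

#' Gradients of the sentence negative log-likelihood
#'
#' Analytic back-propagation through the whole network (CRF, projection,
#' token bi-LSTM, dropout, character bi-LSTM, embeddings) for one sentence.
#'
#' @param model A `ner_model`.
#' @param sent A `tagged_sentence` with gold labels.
#' @param dropout_rate Dropout rate applied to the embeddings.
#' @param seed Optional seed for the dropout mask.
#' @return A list with `loss` and `gradients` (one entry per parameter
#'   group, shaped like the parameters).
#' @export
compute_gradients <- function(model, sent, dropout_rate = 0, seed = NULL) {
  if (!nrow(sent$tokens)) stopf("cannot compute gradients for an empty sentence")
  ids <- sentence_to_ids(model, sent)
  mask <- NULL
  if (dropout_rate > 0) {
    E <- model$config$token_dim + 2L * model$config$char_hidden
    gen <- function() dropout_mask(E, length(ids$tok), dropout_rate)
    mask <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  }
  cpp_sentence_grad(model$params, ids, mask, ids$labels)
}

flatten_group <- function(g) {
  if (is.list(g)) unlist(lapply(g, as.numeric), use.names = FALSE)
  else as.numeric(g)
}

global_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(flatten_group(g)^2), numeric(1))))
}

apply_update <- function(p, g, factor) {
  if (is.list(p)) return(Map(apply_update, p, g, MoreArgs = list(factor = factor)))
  p - factor * g
}

#' One stochastic gradient descent update with global-norm clipping
#'
#' If the global gradient norm `g` exceeds the clip threshold, all gradients
#' are scaled by `clip/g`; then every parameter moves by `-lr * grad`. No
#' momentum.
#'
#' @param params Model parameter list (as in `model$params`).
#' @param gradients Gradient list from [compute_gradients()]`$gradients`.
#' @param profile A [training_profile()].
#' @return The updated parameter list.
#' @export
sgd_step <- function(params, gradients, profile) {
  nrm <- global_grad_norm(gradients)
  scale <- if (nrm > profile$gradient_clip && nrm > 0)
    profile$gradient_clip / nrm else 1
  Map(apply_update, params, gradients,
      MoreArgs = list(factor = profile$learning_rate * scale))
}

# Early-stopping bookkeeping: strict improvement resets the patience
# counter; `patience` consecutive non-improving epochs stop training.
early_stop_state <- function(patience) {
  list(patience = patience, best_f1 = -Inf, best_epoch = 0L, n_bad = 0L,
       stop = FALSE, improved = FALSE)
}

# `active` implements the cold-start burn-in: until the tagger produces its
# first entity prediction on the dev set, non-improving epochs do not count
# against the patience (per-example SGD from a random initialization spends
# its first epochs in an all-O regime whose length depends on corpus size,
# not on model quality).
early_stop_update <- function(state, f1, epoch, active = TRUE) {
  if (f1 > state$best_f1) {
    state$best_f1 <- f1
    state$best_epoch <- epoch
    state$n_bad <- 0L
    state$improved <- TRUE
  } else {
    state$improved <- FALSE
    if (active) {
      state$n_bad <- state$n_bad + 1L
      if (state$n_bad >= state$patience) state$stop <- TRUE
    }
  }
  state
}

docs_to_tagged <- function(docs, scheme) {
  out <- list()
  for (doc in docs) {
    ts <- to_tagged(doc, scheme)
    keep <- vapply(ts, function(s) nrow(s$tokens) > 0L, logical(1))
    out <- c(out, ts[keep])
  }
  out
}

tagged_mentions <- function(sents, labels_list = NULL) {
  recs <- lapply(seq_along(sents), function(k) {
    s <- sents[[k]]
    if (!is.null(labels_list)) s$labels <- labels_list[[k]]
    ann <- from_tagged(s)
    if (!nrow(ann)) return(NULL)
    data.frame(doc_id = s$doc_id, start = ann$start, end = ann$end,
               entity_type = ann$entity_type, stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(empty_mentions())
  do.call(rbind, recs)
}

evaluate_tagged <- function(model, sents, ids = NULL) {
  if (is.null(ids))
    ids <- lapply(sents, sentence_to_ids, model = model, with_labels = FALSE)
  paths <- cpp_predict_corpus(model$params, ids)
  pred_labels <- lapply(paths, function(p) model$vocab$labels[p])
  score(tagged_mentions(sents), tagged_mentions(sents, pred_labels))
}

#' Train a model with per-sentence SGD and early stopping
#'
#' Each epoch shuffles the training sentences with an epoch-derived seed and
#' applies one clipped SGD update per sentence; entity-level F1 on the
#' development partition is evaluated after every epoch. Training stops after
#' `patience` consecutive epochs without dev-F1 improvement, or at
#' `max_epochs`; the returned model carries the parameters of the best dev-F1
#' epoch.
#'
#' @param model A `ner_model` (its vocabulary should be built from the
#'   training documents).
#' @param split A `corpus_split` with non-empty `train` and `dev`.
#' @param profile A [training_profile()].
#' @param quiet Suppress per-epoch progress lines.
#' @return A list with `model` (best parameters) and `log` (a
#'   `training_log`: per-epoch data frame with attributes `best_epoch` and
#'   `stop_reason`).
#' @export
train_model <- function(model, split, profile, quiet = TRUE) {
  if (!length(split$train) || !length(split$dev))
    stopf("training requires non-empty train and dev partitions")
  scheme <- model$config$scheme
  tr_sents <- docs_to_tagged(split$train, scheme)
  dv_sents <- docs_to_tagged(split$dev, scheme)
  if (!length(tr_sents)) stopf("no non-empty training sentences")
  tr_ids <- lapply(tr_sents, sentence_to_ids, model = model)
  dv_ids <- lapply(dv_sents, sentence_to_ids, model = model, with_labels = FALSE)
  dv_gold <- tagged_mentions(dv_sents)
  E <- model$config$token_dim + 2L * model$config$char_hidden

  params <- model$params
  best_params <- params
  state <- early_stop_state(profile$patience)
  engaged <- FALSE
  log_rows <- vector("list", profile$max_epochs)
  stop_reason <- "max_epochs"

  for (epoch in seq_len(profile$max_epochs)) {
    ep_seed <- derive_seed(profile$seed, epoch)
    shuffle_and_masks <- withr::with_seed(ep_seed, {
      ord <- sample.int(length(tr_ids))
      masks <- if (profile$dropout_rate > 0) {
        lapply(tr_ids, function(s) dropout_mask(E, length(s$tok), profile$dropout_rate))
      } else NULL
      list(ord = ord, masks = masks)
    })
    res <- cpp_train_epoch(params, tr_ids, shuffle_and_masks$ord,
                           shuffle_and_masks$masks,
                           profile$learning_rate, profile$gradient_clip)
    params <- res$params
    tmp_model <- model
    tmp_model$params <- params
    paths <- cpp_predict_corpus(params, dv_ids)
    dev_pred <- tagged_mentions(dv_sents,
                                lapply(paths, function(p) model$vocab$labels[p]))
    dev_eval <- score(dv_gold, dev_pred)
    if (!engaged && nrow(dev_pred) > 0L) engaged <- TRUE
    state <- early_stop_update(state, dev_eval$f1, epoch, active = engaged)
    if (state$improved) best_params <- params
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = res$mean_loss,
      dev_precision = dev_eval$precision, dev_recall = dev_eval$recall,
      dev_f1 = dev_eval$f1)
    if (!quiet)
      message(sprintf("epoch %3d  loss %8.4f  dev P %5.1f R %5.1f F1 %5.1f",
                      epoch, res$mean_loss, dev_eval$precision,
                      dev_eval$recall, dev_eval$f1))
    if (state$stop) { stop_reason <- "early_stopping"; break }
  }
  log_df <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  model$params <- best_params
  log <- structure(log_df, best_epoch = state$best_epoch,
                   stop_reason = stop_reason, class = c("training_log", "data.frame"))
  list(model = model, log = log)
}

#' @export
print.training_log <- function(x, ...) {
  cat(sprintf("<training_log: %d epochs, best dev F1 %.2f at epoch %d (%s)>\n",
              nrow(x), max(x$dev_f1), attr(x, "best_epoch"),
              attr(x, "stop_reason")))
  invisible(x)
}
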