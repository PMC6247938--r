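# Reference implementations of the network's forward computations, written
# in plain R so each layer can be inspected and tested in isolation. The
# training loop and batch prediction use the compiled core; the test-suite
# ties the two routes together numerically.

sigmoid <- function(x) 1 / (1 + exp(-x))

check_cell_shapes <- function(p, x) {
  h <- length(p$b_i)
  d <- length(x)
  ok <- nrow(p$W_xi) == h && ncol(p$W_xi) == d &&
    all(dim(p$W_hi) == c(h, h)) && all(dim(p$W_ci) == c(h, h)) &&
    nrow(p$W_xc) == h && ncol(p$W_xc) == d && all(dim(p$W_hc) == c(h, h)) &&
    nrow(p$W_xo) == h && ncol(p$W_xo) == d && all(dim(p$W_ho) == c(h, h)) &&
    all(dim(p$W_co) == c(h, h)) && length(p$b_c) == h && length(p$b_o) == h
  if (!ok) stopf("LSTM cell parameter shapes are inconsistent with input size %d", d)
  invisible(TRUE)
}

#' One step of the coupled-gate peephole LSTM cell
#'
#' Computes the recurrence
#' \deqn{i_t = \sigma(W_{xi} x_t + W_{hi} h_{t-1} + W_{ci} c_{t-1} + b_i)}
#' \deqn{c_t = (1 - i_t) \odot c_{t-1} + i_t \odot \tanh(W_{xc} x_t + W_{hc} h_{t-1} + b_c)}
#' \deqn{o_t = \sigma(W_{xo} x_t + W_{ho} h_{t-1} + W_{co} c_t + b_o)}
#' \deqn{h_t = o_t \odot \tanh(c_t)}
#' There is no separate forget gate (the forget weight is `1 - i_t`), the
#' peephole terms are full matrix products, and the output gate peeps at the
#' current cell state `c_t`.
#'
#' @param p LSTM cell parameter list (`W_xi`, `W_hi`, `W_ci`, `b_i`, `W_xc`,
#'   `W_hc`, `b_c`, `W_xo`, `W_ho`, `W_co`, `b_o`).
#' @param x_t Input vector.
#' @param h_prev,c_prev Previous hidden and cell state vectors.
#' @return A list with the new `h` and `c` vectors.
#' @export
lstm_cell_step <- function(p, x_t, h_prev, c_prev) {
  check_cell_shapes(p, x_t)
  if (length(h_prev) != length(p$b_i) || length(c_prev) != length(p$b_i))
    stopf("state vectors must have length %d", length(p$b_i))
  i <- sigmoid(drop(p$W_xi %*% x_t + p$W_hi %*% h_prev + p$W_ci %*% c_prev) + p$b_i)
  g <- tanh(drop(p$W_xc %*% x_t + p$W_hc %*% h_prev) + p$b_c)
  c_t <- (1 - i) * c_prev + i * g
  o <- sigmoid(drop(p$W_xo %*% x_t + p$W_ho %*% h_prev + p$W_co %*% c_t) + p$b_o)
  list(h = o * tanh(c_t), c = c_t)
}

run_lstm <- function(p, inputs) {
  h <- numeric(length(p$b_i))
  c <- numeric(length(p$b_i))
  out <- vector("list", length(inputs))
  for (t in seq_along(inputs)) {
    st <- lstm_cell_step(p, inputs[[t]], h, c)
    h <- st$h; c <- st$c
    out[[t]] <- h
  }
  out
}

#' Run a bi-directional LSTM over a sequence of vectors
#'
#' Output `t` is the concatenation of the forward hidden state at `t` and the
#' backward hidden state at `t` (the backward layer processes the reversed
#' sequence); initial hidden and cell states are zero.
#'
#' @param fwd,bwd LSTM cell parameter lists for the two directions.
#' @param inputs Non-empty list of input vectors.
#' @return A list of concatenated output vectors, one per input.
#' @export
bilstm_run <- function(fwd, bwd, inputs) {
  if (!length(inputs)) stopf("bilstm_run requires a non-empty input sequence")
  hf <- run_lstm(fwd, inputs)
  hb <- rev(run_lstm(bwd, rev(inputs)))
  Map(c, hf, hb)
}

#' Character-level representation of a token
#'
#' Runs the character bi-LSTM over the token's character embeddings and
#' concatenates the final forward state with the final backward state.
#'
#' @param model A `ner_model`.
#' @param token Token surface string (a single token).
#' @return A numeric vector of length `2 * char_hidden`.
#' @export
char_representation <- function(model, token) {
  if (!is.character(token) || length(token) != 1L || !nzchar(token))
    stopf("char_representation requires a non-empty token string")
  ids <- char_ids(model, token)
  emb <- lapply(ids, function(k) model$params$char_embedding[k, ])
  hf <- run_lstm(model$params$char_lstm_fwd, emb)
  hb <- run_lstm(model$params$char_lstm_bwd, rev(emb))
  c(hf[[length(hf)]], hb[[length(hb)]])
}

#' Character-enhanced token embeddings for a sentence
#'
#' Each token's embedding `e_i` concatenates its token-embedding row with its
#' character-level representation. During training, inverted dropout with the
#' given rate is applied to `e_i` (units are zeroed with probability
#' `dropout_rate` and survivors scaled by `1/(1-rate)`); at evaluation time
#' no dropout and no scaling are applied.
#'
#' @param model A `ner_model`.
#' @param sent A `tagged_sentence`.
#' @param dropout_rate Probability of dropping a unit.
#' @param training Logical; apply dropout?
#' @param seed Optional seed making the dropout mask reproducible.
#' @return A list of embedding vectors, one per token.
#' @export
embed_sentence <- function(model, sent, dropout_rate = 0, training = FALSE,
                           seed = NULL) {
  stopifnot(is_probability(dropout_rate))
  ids <- token_ids(model, sent$tokens$surface)
  e <- lapply(seq_along(ids), function(t) {
    c(model$params$token_embedding[ids[t], ],
      char_representation(model, sent$tokens$surface[t]))
  })
  if (training && dropout_rate > 0) {
    gen <- function() lapply(e, function(v) {
      if (dropout_rate >= 1) return(v * 0)
      keep <- runif(length(v)) >= dropout_rate
      v * keep / (1 - dropout_rate)
    })
    e <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  }
  e
}

dropout_mask <- function(n_units, n_tokens, rate) {
  if (rate >= 1) return(matrix(0, n_units, n_tokens))
  matrix((runif(n_units * n_tokens) >= rate) / (1 - rate), n_units, n_tokens)
}

#' Emission scores for an embedded sentence
#'
#' Runs the token bi-LSTM over the embedded sentence and projects each output
#' through the fully connected label-prediction layer. Scores are
#' unnormalized: global normalization happens in the CRF layer, no per-token
#' softmax is applied.
#'
#' @param model A `ner_model`.
#' @param embedded List of embedding vectors from [embed_sentence()].
#' @return A `T x L` matrix of label scores (one row per token).
#' @export
emission_scores <- function(model, embedded) {
  if (!length(embedded)) stopf("cannot score an empty sentence")
  h2 <- bilstm_run(model$params$token_lstm_fwd, model$params$token_lstm_bwd,
                   embedded)
  out <- t(vapply(h2, function(h)
    drop(model$params$projection_W %*% h) + model$params$projection_b,
    numeric(length(model$params$projection_b))))
  matrix(out, nrow = length(embedded),
         dimnames = list(NULL, model$vocab$labels))
}

crf_params <- function(model) {
  list(trans = model$params$crf_transitions,
       start = model$params$crf_start,
       end = model$params$crf_end)
}

log_sum_exp <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Log partition function of the linear-chain CRF
#'
#' Computes `log` of the sum over all label paths `y` of
#' `exp(start[y_1] + sum_t scores[t, y_t] + sum_t transitions[y_{t-1}, y_t] +
#' end[y_T])` by the forward algorithm in log space.
#'
#' @param scores `T x L` emission score matrix.
#' @param model A `ner_model` (source of the CRF transition parameters).
#' @return The log partition function (scalar).
#' @export
crf_log_partition <- function(scores, model) {
  p <- crf_params(model)
  T_ <- nrow(scores); L <- ncol(scores)
  stopifnot(T_ >= 1, all(dim(p$trans) == c(L, L)))
  alpha <- p$start + scores[1, ]
  if (T_ > 1) {
    for (t in 2:T_) {
      alpha <- vapply(seq_len(L), function(b)
        log_sum_exp(alpha + p$trans[, b]) + scores[t, b], numeric(1))
    }
  }
  log_sum_exp(alpha + p$end)
}

#' CRF negative log-likelihood of a gold label sequence
#'
#' `log_partition - gold path score`; non-negative for any input.
#'
#' @param scores `T x L` emission score matrix.
#' @param gold_labels Character labels or integer label ids, length `T`.
#' @param model A `ner_model`.
#' @return The negative log-likelihood (scalar).
#' @export
crf_neg_log_likelihood <- function(scores, gold_labels, model) {
  ids <- if (is.character(gold_labels)) label_ids(model, gold_labels)
         else as.integer(gold_labels)
  if (length(ids) != nrow(scores))
    stopf("gold label sequence length %d does not match %d tokens",
          length(ids), nrow(scores))
  p <- crf_params(model)
  gold <- p$start[ids[1]] + p$end[ids[length(ids)]] +
    sum(scores[cbind(seq_along(ids), ids)])
  if (length(ids) > 1)
    gold <- gold + sum(p$trans[cbind(ids[-length(ids)], ids[-1])])
  crf_log_partition(scores, model) - gold
}

#' Viterbi decoding of the maximum-scoring label path
#'
#' Dynamic program over emission and transition scores; ties are broken by
#' the lowest label index at each backtracking step.
#'
#' @param scores `T x L` emission score matrix.
#' @param model A `ner_model`.
#' @return A list with `path` (integer label ids), `labels` (characters) and
#'   `score`.
#' @export
viterbi_decode <- function(scores, model) {
  p <- crf_params(model)
  T_ <- nrow(scores); L <- ncol(scores)
  stopifnot(T_ >= 1)
  delta <- p$start + scores[1, ]
  bp <- matrix(0L, T_, L)
  if (T_ > 1) {
    for (t in 2:T_) {
      nxt <- numeric(L)
      for (b in seq_len(L)) {
        cand <- delta + p$trans[, b]
        bp[t, b] <- which.max(cand)
        nxt[b] <- cand[bp[t, b]] + scores[t, b]
      }
      delta <- nxt
    }
  }
  final <- delta + p$end
  path <- integer(T_)
  path[T_] <- which.max(final)
  if (T_ > 1) for (t in T_:2) path[t - 1] <- bp[t, path[t]]
  list(path = path, labels = model$vocab$labels[path],
       score = final[path[T_]])
}

#' Predict label sequences for tagged sentences
#'
#' Full pipeline: character-enhanced embeddings (no dropout), token bi-LSTM,
#' emission scores and Viterbi decoding, using the compiled fast path.
#' Deterministic.
#'
#' @param object A `ner_model`.
#' @param sentences A `tagged_sentence` or list of them.
#' @param ... Unused.
#' @return A list of character label vectors (one per sentence).
#' @export
predict.ner_model <- function(object, sentences, ...) {
  if (inherits(sentences, "tagged_sentence")) sentences <- list(sentences)
  ids <- lapply(sentences, sentence_to_ids, model = object, with_labels = FALSE)
  paths <- cpp_predict_corpus(object$params, ids)
  lapply(paths, function(p) object$vocab$labels[p])
}
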