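# Shared fixtures and independent oracles for the test suite.

zero_cell <- function(hidden, input) {
  z <- function(r, c) matrix(0, r, c)
  list(W_xi = z(hidden, input), W_hi = z(hidden, hidden),
       W_ci = z(hidden, hidden), b_i = numeric(hidden),
       W_xc = z(hidden, input), W_hc = z(hidden, hidden),
       b_c = numeric(hidden),
       W_xo = z(hidden, input), W_ho = z(hidden, hidden),
       W_co = z(hidden, hidden), b_o = numeric(hidden))
}

random_cell <- function(hidden, input, seed = 1) {
  withr::with_seed(seed, {
    r <- function(r_, c_) matrix(rnorm(r_ * c_, sd = 0.4), r_, c_)
    list(W_xi = r(hidden, input), W_hi = r(hidden, hidden),
         W_ci = r(hidden, hidden), b_i = rnorm(hidden, sd = 0.2),
         W_xc = r(hidden, input), W_hc = r(hidden, hidden),
         b_c = rnorm(hidden, sd = 0.2),
         W_xo = r(hidden, input), W_ho = r(hidden, hidden),
         W_co = r(hidden, hidden), b_o = rnorm(hidden, sd = 0.2))
  })
}

# Small document corpus built in code (no files).
tiny_docs <- function(n = 6, seed = 3, sentences = c(2L, 2L)) {
  generate_gsc(generator_config(n_documents = n, sentences_per_doc = sentences,
                                seed = seed))
}

tiny_model <- function(docs, seed = 42, scheme = "BIO",
                       config = model_config(token_dim = 4, char_dim = 3,
                                             token_hidden = 3, char_hidden = 2,
                                             scheme = scheme)) {
  new_model(build_vocab(docs, config$scheme), config, seed = seed)
}

# Attach random CRF parameters so partition/Viterbi tests are non-trivial.
randomize_crf <- function(model, seed = 7) {
  L <- length(model$vocab$labels)
  withr::with_seed(seed, {
    model$params$crf_transitions <- matrix(rnorm(L * L), L, L)
    model$params$crf_start <- rnorm(L)
    model$params$crf_end <- rnorm(L)
  })
  model
}

# Brute-force oracle: enumerate every label path of a linear-chain CRF.
enum_paths <- function(T_, L) {
  as.matrix(expand.grid(rep(list(seq_len(L)), T_)))
}

enum_path_scores <- function(scores, trans, start, end) {
  T_ <- nrow(scores)
  paths <- enum_paths(T_, ncol(scores))
  apply(paths, 1, function(y) {
    s <- start[y[1]] + end[y[T_]] + sum(scores[cbind(seq_len(T_), y)])
    if (T_ > 1) s <- s + sum(trans[cbind(y[-T_], y[-1])])
    s
  })
}

enum_log_partition <- function(scores, trans, start, end) {
  tot <- enum_path_scores(scores, trans, start, end)
  m <- max(tot)
  m + log(sum(exp(tot - m)))
}

enum_best_path <- function(scores, trans, start, end) {
  tot <- enum_path_scores(scores, trans, start, end)
  paths <- enum_paths(nrow(scores), ncol(scores))
  best <- which.max(tot)
  list(path = as.integer(paths[best, ]), score = tot[best])
}

mention_df <- function(doc_id, start, end, type = "Gene") {
  data.frame(doc_id = doc_id, start = start, end = end,
             entity_type = rep_len(type, length(doc_id)),
             stringsAsFactors = FALSE)
}

# A degenerate split where train, dev and test are the same documents
# (used for memorization-style checks).
self_split <- function(docs) {
  structure(list(train = docs, dev = docs, test = docs),
            class = "corpus_split")
}

docs_to_tagged_helper <- function(docs, scheme = "BIO") {
  bionertl:::docs_to_tagged(docs, scheme)
}

ann_key_set <- function(doc) {
  with(doc$annotations, sort(paste(entity_type, start, end, surface, sep = "|")))
}
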