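test_that("lstm_cell_step reproduces the coupled-gate peephole recurrence", {
  p <- zero_cell(1, 1)
  # all zeros: sigma(0)=0.5, tanh(0)=0
  r0 <- lstm_cell_step(p, 0, 0, 0)
  expect_equal(r0$h, 0)
  expect_equal(r0$c, 0)

  # c_prev = 2, everything else zero:
  # i = 0.5, c = (1-0.5)*2 = 1, o = 0.5, h = 0.5*tanh(1)
  r1 <- lstm_cell_step(p, 0, 0, 2)
  expect_equal(r1$c, 1.0, tolerance = 1e-9)
  expect_equal(r1$h, 0.5 * tanh(1), tolerance = 1e-9)
  expect_equal(round(r1$h, 6), 0.380797)

  # W_ci = 1, c_prev = 1: i = sigma(1), c = (1-i)*1, o = 0.5
  p2 <- zero_cell(1, 1)
  p2$W_ci <- matrix(1, 1, 1)
  r2 <- lstm_cell_step(p2, 0, 0, 1)
  i <- 1 / (1 + exp(-1))
  expect_equal(r2$c, 1 - i, tolerance = 1e-9)
  expect_equal(round(r2$c, 6), 0.268941)
  expect_equal(r2$h, 0.5 * tanh(1 - i), tolerance = 1e-9)

  # coupled-gate sanity limit: i forced to ~1 makes c the tanh candidate,
  # independent of c_prev
  p3 <- random_cell(3, 2, seed = 5)
  p3$b_i <- rep(50, 3)
  x <- c(0.3, -0.2)
  ra <- lstm_cell_step(p3, x, numeric(3), c(5, -5, 2))
  rb <- lstm_cell_step(p3, x, numeric(3), c(-1, 9, 0))
  cand <- tanh(drop(p3$W_xc %*% x) + p3$b_c)
  expect_equal(ra$c, cand, tolerance = 1e-8)
  expect_equal(rb$c, cand, tolerance = 1e-8)

  expect_error(lstm_cell_step(p3, c(1, 2, 3), numeric(3), numeric(3)),
               "shapes")
})

test_that("bilstm_run concatenates directional states with expected symmetries", {
  fwd <- zero_cell(2, 2)
  out <- bilstm_run(fwd, fwd, list(c(1, -1)))
  expect_length(out, 1L)
  expect_equal(out[[1]], numeric(4))

  expect_error(bilstm_run(fwd, fwd, list()), "non-empty")

  # palindromic input with fwd = bwd parameters: reversing the sequence and
  # swapping the two halves reproduces the output
  cell <- random_cell(3, 2, seed = 2)
  inputs <- list(c(0.5, -1), c(2, 0.25), c(0.5, -1))
  out2 <- bilstm_run(cell, cell, inputs)
  swapped <- lapply(rev(out2), function(v) c(v[4:6], v[1:3]))
  expect_equal(out2, swapped, tolerance = 1e-12)

  # output length always equals input length
  for (n in c(1, 4, 7)) {
    ins <- replicate(n, rnorm(2), simplify = FALSE)
    expect_length(bilstm_run(cell, cell, ins), n)
  }
})

test_that("char_representation summarizes token characters deterministically", {
  docs <- tiny_docs()
  m <- tiny_model(docs)
  v <- char_representation(m, "kinase")
  expect_length(v, 2L * m$config$char_hidden)
  expect_identical(v, char_representation(m, "kinase"))
  expect_false(isTRUE(all.equal(v, char_representation(m, "kinases"))))
  expect_error(char_representation(m, ""), "non-empty")

  # zero parameters give a zero vector for any single character
  m0 <- m
  for (nm in names(m0$params$char_lstm_fwd))
    m0$params$char_lstm_fwd[[nm]][] <- 0
  for (nm in names(m0$params$char_lstm_bwd))
    m0$params$char_lstm_bwd[[nm]][] <- 0
  expect_equal(char_representation(m0, "k"), numeric(2L * m$config$char_hidden))
})

test_that("embed_sentence applies inverted dropout only in training mode", {
  docs <- tiny_docs()
  m <- tiny_model(docs)
  s <- docs_to_tagged_helper(docs)[[1]]
  ev <- embed_sentence(m, s)
  expect_length(ev, nrow(s$tokens))
  expect_length(ev[[1]], m$config$token_dim + 2L * m$config$char_hidden)

  # rate 0 in training mode equals evaluation mode
  expect_equal(embed_sentence(m, s, dropout_rate = 0, training = TRUE), ev)
  # degenerate rate 1 zeroes everything
  z <- embed_sentence(m, s, dropout_rate = 1, training = TRUE, seed = 1)
  expect_true(all(vapply(z, function(v) all(v == 0), logical(1))))
  # fixed seed reproduces the mask; surviving units are scaled by 1/(1-p)
  a <- embed_sentence(m, s, dropout_rate = 0.5, training = TRUE, seed = 9)
  b <- embed_sentence(m, s, dropout_rate = 0.5, training = TRUE, seed = 9)
  expect_identical(a, b)
  kept <- unlist(a) != 0
  expect_equal(unlist(a)[kept], 2 * unlist(ev)[kept])
})

test_that("emission_scores projects bi-LSTM outputs and matches hand arithmetic", {
  docs <- tiny_docs()
  m <- tiny_model(docs)
  s <- docs_to_tagged_helper(docs)[[1]]
  e <- embed_sentence(m, s)
  sc <- emission_scores(m, e)
  expect_equal(dim(sc), c(length(e), length(m$vocab$labels)))

  # zero projection gives the zero lattice
  m0 <- m
  m0$params$projection_W[] <- 0
  m0$params$projection_b[] <- 0
  expect_true(all(emission_scores(m0, e) == 0))

  # independent matrix arithmetic on the bilstm outputs
  h2 <- bilstm_run(m$params$token_lstm_fwd, m$params$token_lstm_bwd, e)
  for (t in seq_along(e))
    expect_equal(unname(sc[t, ]),
                 drop(m$params$projection_W %*% h2[[t]]) + m$params$projection_b,
                 tolerance = 1e-12)
})

test_that("reference pipeline and compiled fast path agree on emissions and decoding", {
  docs <- tiny_docs(n = 8, seed = 13)
  m <- randomize_crf(tiny_model(docs, seed = 2))
  sents <- docs_to_tagged_helper(docs)
  for (s in sents[1:5]) {
    scR <- emission_scores(m, embed_sentence(m, s))
    ids <- bionertl:::sentence_to_ids(m, s, with_labels = FALSE)
    scC <- bionertl:::cpp_emissions(m$params, ids, NULL)
    expect_equal(unname(scR), scC, tolerance = 1e-10)
    vR <- viterbi_decode(scR, m)
    pC <- predict(m, s)[[1]]
    expect_identical(vR$labels, pC)
  }
})

test_that("crf_log_partition matches exhaustive enumeration", {
  docs <- tiny_docs()
  m <- randomize_crf(tiny_model(docs))
  L <- length(m$vocab$labels)

  # T=1, two labels, all zero -> log 2; T=2 -> log 4
  m2 <- m
  m2$vocab$labels <- c("O", "B-Gene")
  m2$params$crf_transitions <- matrix(0, 2, 2)
  m2$params$crf_start <- numeric(2)
  m2$params$crf_end <- numeric(2)
  expect_equal(crf_log_partition(matrix(0, 1, 2), m2), log(2))
  expect_equal(crf_log_partition(matrix(0, 2, 2), m2), log(4))

  withr::with_seed(31, {
    for (rep in 1:10) {
      T_ <- sample(1:5, 1)
      sc <- matrix(rnorm(T_ * L), T_, L)
      expect_equal(crf_log_partition(sc, m),
                   enum_log_partition(sc, m$params$crf_transitions,
                                      m$params$crf_start, m$params$crf_end),
                   tolerance = 1e-10)
    }
  })
})

test_that("crf_neg_log_likelihood equals the enumerated gold-path probability", {
  docs <- tiny_docs()
  m <- randomize_crf(tiny_model(docs))
  L <- length(m$vocab$labels)
  withr::with_seed(17, {
    for (rep in 1:5) {
      T_ <- sample(2:4, 1)
      sc <- matrix(rnorm(T_ * L), T_, L)
      gold <- sample(seq_len(L), T_, replace = TRUE)
      tot <- enum_path_scores(sc, m$params$crf_transitions,
                              m$params$crf_start, m$params$crf_end)
      paths <- enum_paths(T_, L)
      gold_row <- which(apply(paths, 1, function(y) all(y == gold)))
      prob <- exp(tot[gold_row]) / sum(exp(tot))
      expect_equal(crf_neg_log_likelihood(sc, gold, m), -log(prob),
                   tolerance = 1e-9)
    }
  })
  # all-zero parameters, T=1: loss is log L
  m0 <- m
  m0$params$crf_transitions[] <- 0
  m0$params$crf_start[] <- 0
  m0$params$crf_end[] <- 0
  expect_equal(crf_neg_log_likelihood(matrix(0, 1, L), 1L, m0), log(L))
  # dominant gold path: loss ~ 0
  sc_dom <- matrix(0, 3, L)
  sc_dom[, 2] <- 100
  expect_lt(crf_neg_log_likelihood(sc_dom, rep(2L, 3), m0), 1e-6)
  expect_error(crf_neg_log_likelihood(matrix(0, 2, L), 1L, m0),
               "does not match")
})

test_that("viterbi_decode finds the enumerated maximum with low-index ties", {
  docs <- tiny_docs()
  m <- randomize_crf(tiny_model(docs))
  L <- length(m$vocab$labels)

  # all-zero lattice and transitions: tie broken to label 1 throughout
  m0 <- m
  m0$params$crf_transitions[] <- 0
  m0$params$crf_start[] <- 0
  m0$params$crf_end[] <- 0
  v0 <- viterbi_decode(matrix(0, 4, L), m0)
  expect_equal(v0$path, rep(1L, 4))
  expect_equal(v0$score, 0)

  # zero transitions, distinct per-position maxima: per-position argmax
  sc <- matrix(c(5, 0, 0,
                 0, 0, 7,
                 0, 6, 0), 3, L, byrow = TRUE)
  expect_equal(viterbi_decode(sc, m0)$path, c(1L, 3L, 2L))

  withr::with_seed(23, {
    for (rep in 1:8) {
      T_ <- sample(1:5, 1)
      scr <- matrix(rnorm(T_ * L), T_, L)
      got <- viterbi_decode(scr, m)
      best <- enum_best_path(scr, m$params$crf_transitions,
                             m$params$crf_start, m$params$crf_end)
      expect_equal(got$score, best$score, tolerance = 1e-10)
      expect_equal(got$path, best$path)
    }
  })
})

test_that("viterbi score beats random paths and survives per-position shifts", {
  docs <- tiny_docs()
  m <- randomize_crf(tiny_model(docs, seed = 6), seed = 19)
  L <- length(m$vocab$labels)
  withr::with_seed(3, {
    sc <- matrix(rnorm(6 * L), 6, L)
    v <- viterbi_decode(sc, m)
    path_score <- function(y, scores) {
      s <- m$params$crf_start[y[1]] + m$params$crf_end[y[length(y)]] +
        sum(scores[cbind(seq_along(y), y)])
      s + sum(m$params$crf_transitions[cbind(y[-length(y)], y[-1])])
    }
    for (k in 1:1000) {
      y <- sample(seq_len(L), 6, replace = TRUE)
      expect_gte(v$score + 1e-9, path_score(y, sc))
    }
    # adding a constant to one position's emissions changes no decisions
    sc2 <- sc
    sc2[3, ] <- sc2[3, ] + 11.5
    v2 <- viterbi_decode(sc2, m)
    expect_equal(v2$path, v$path)
    expect_equal(v2$score, v$score + 11.5, tolerance = 1e-9)
    # posteriors are unchanged too
    lp1 <- crf_log_partition(sc, m)
    lp2 <- crf_log_partition(sc2, m)
    y <- v$path
    expect_equal(path_score(y, sc) - lp1, path_score(y, sc2) - lp2,
                 tolerance = 1e-9)
  })
})

test_that("predict is deterministic with one label per token", {
  docs <- tiny_docs(n = 5, seed = 10)
  m <- tiny_model(docs, seed = 3)
  sents <- docs_to_tagged_helper(docs)
  p1 <- predict(m, sents)
  p2 <- predict(m, sents)
  expect_identical(p1, p2)
  for (k in seq_along(sents))
    expect_length(p1[[k]], nrow(sents[[k]]$tokens))
  expect_true(all(unlist(p1) %in% m$vocab$labels))
})

test_that("checkpoints round-trip parameters bit-exactly", {
  docs <- tiny_docs()
  m <- randomize_crf(tiny_model(docs))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, m$params)
  expect_identical(back$vocab, m$vocab)
  expect_identical(unclass(back$config), unclass(m$config))
})
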