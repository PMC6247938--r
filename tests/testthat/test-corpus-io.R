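test_that("parse_brat maps text-bound annotations and enforces invariants", {
  doc <- parse_brat("cancer is bad", "T1\tDisease 0 6\tcancer")
  expect_s3_class(doc, "ner_document")
  expect_equal(nrow(doc$annotations), 1L)
  expect_equal(doc$annotations$entity_type, "Disease")
  expect_equal(doc$annotations$start, 0L)
  expect_equal(doc$annotations$end, 6L)
  expect_equal(doc$annotations$surface, "cancer")

  expect_error(parse_brat("cancer is bad", "T1\tDisease 0 99\tcancer"),
               "out of range")
  expect_error(parse_brat("cancer is bad", "T1\tDisease 0 5\tcancer"),
               "does not match")
  expect_error(parse_brat("cancer is bad", "T1\tDisease zero 6\tcancer"),
               "malformed")
  # discontinuous span: warning, annotation skipped, others kept
  expect_warning(
    doc2 <- parse_brat("cancer is bad",
                       c("T1\tDisease 0 6\tcancer",
                         "T2\tDisease 0 3;7 9\tcan is")),
    "discontinuous")
  expect_equal(nrow(doc2$annotations), 1L)
  # non-text-bound lines are ignored
  doc3 <- parse_brat("cancer is bad",
                     c("T1\tDisease 0 6\tcancer", "R1\tRel Arg1:T1 Arg2:T1"))
  expect_equal(nrow(doc3$annotations), 1L)
})

test_that("write_brat round-trips parse_brat up to id renumbering", {
  doc <- parse_brat("cancer is bad", "T1\tDisease 0 6\tcancer")
  out <- write_brat(doc)
  rt <- parse_brat(out$text, out$ann_lines, doc$doc_id)
  expect_equal(ann_key_set(rt), ann_key_set(doc))
  # empty annotation list -> empty ann lines
  empty <- document("d", "no entities here")
  expect_length(write_brat(empty)$ann_lines, 0L)
})

test_that("Brat round-trip is the identity on generator output", {
  docs <- generate_gsc(generator_config(n_documents = 25, seed = 8))
  dir <- withr::local_tempdir()
  write_brat_dir(docs, dir)
  back <- read_brat_dir(dir)
  expect_length(back, length(docs))
  for (k in seq_along(docs)) {
    expect_identical(back[[k]]$doc_id, docs[[k]]$doc_id)
    expect_identical(back[[k]]$text, docs[[k]]$text)
    expect_identical(ann_key_set(back[[k]]), ann_key_set(docs[[k]]))
  }
})

test_that("tokenize splits punctuation, keeps offsets, guards abbreviations", {
  sents <- tokenize("BRCA1 is mutated.")
  expect_length(sents, 1L)
  toks <- sents[[1]]
  expect_equal(toks$surface, c("BRCA1", "is", "mutated", "."))
  expect_equal(toks$start, c(0L, 6L, 9L, 16L))
  expect_equal(toks$end, c(5L, 8L, 16L, 17L))

  expect_identical(tokenize(""), list())

  # single-capital abbreviation does not end the sentence
  expect_length(tokenize("A. thaliana grows. B. subtilis too."), 2L)
  # ordinary boundary: period + whitespace + uppercase
  expect_length(tokenize("It ends here. Next starts."), 2L)
  # hyphens and internal slashes stay inside the token
  toks2 <- tokenize("N-acetyl-cysteine and AKT/mTOR act.")[[1]]
  expect_true("N-acetyl-cysteine" %in% toks2$surface)
  expect_true("AKT/mTOR" %in% toks2$surface)
  # surrounding punctuation split off
  toks3 <- tokenize("(BRCA1), done.")[[1]]
  expect_equal(toks3$surface, c("(", "BRCA1", ")", ",", "done", "."))
  # offsets always index the original text
  txt <- "Alpha (beta). Gamma delta."
  for (s in tokenize(txt))
    expect_equal(substring(txt, s$start + 1L, s$end), s$surface)
})

test_that("to_tagged produces scheme-correct labels and snaps misaligned spans", {
  doc <- document("d", "cancer is bad",
                  data.frame(id = "T1", entity_type = "Disease",
                             start = 0L, end = 6L, surface = "cancer"))
  tg <- to_tagged(doc, "BIO")
  expect_equal(tg[[1]]$labels, c("B-Disease", "O", "O"))
  expect_equal(attr(tg, "n_snapped"), 0L)

  doc2 <- document("d", "breast cancer hurts",
                   data.frame(id = "T1", entity_type = "Disease",
                              start = 0L, end = 13L,
                              surface = "breast cancer"))
  expect_equal(to_tagged(doc2, "BIOES")[[1]]$labels,
               c("B-Disease", "E-Disease", "O"))
  expect_equal(to_tagged(doc2, "BIO")[[1]]$labels,
               c("B-Disease", "I-Disease", "O"))

  # annotation starting mid-token snaps outward to the token start
  doc3 <- document("d", "cancer is bad",
                   data.frame(id = "T1", entity_type = "Disease",
                              start = 3L, end = 6L, surface = "cer"))
  tg3 <- to_tagged(doc3, "BIO")
  expect_equal(tg3[[1]]$labels, c("B-Disease", "O", "O"))
  expect_equal(attr(tg3, "n_snapped"), 1L)
})

test_that("from_tagged inverts to_tagged and applies the conlleval repair", {
  toks <- data.frame(surface = c("breast", "cancer", "hurts"),
                     start = c(0L, 7L, 14L), end = c(6L, 13L, 19L))
  sent <- structure(list(doc_id = "d", tokens = toks,
                         labels = c("B-Disease", "I-Disease", "O")),
                    class = "tagged_sentence")
  ann <- from_tagged(sent)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$start, 0L)
  expect_equal(ann$end, 13L)
  expect_equal(ann$surface, "breast cancer")

  # orphan I- opens a new entity
  sent$labels <- c("O", "I-Disease", "O")
  rep_ann <- from_tagged(sent)
  expect_equal(nrow(rep_ann), 1L)
  expect_equal(rep_ann$start, 7L)
  expect_equal(rep_ann$end, 13L)

  # type change inside a run opens a new entity
  sent$labels <- c("B-Disease", "I-Gene", "O")
  expect_equal(nrow(from_tagged(sent)), 2L)

  sent$labels <- c("O", "O", "O")
  expect_equal(nrow(from_tagged(sent)), 0L)

  sent$labels <- c("O", "X-Disease", "O")
  expect_error(from_tagged(sent), "unknown label")
})

test_that("tagging round-trip is the identity on token-aligned documents", {
  docs <- generate_gsc(generator_config(n_documents = 15, seed = 21))
  for (doc in docs) {
    for (scheme in c("BIO", "BIOES")) {
      sents <- to_tagged(doc, scheme)
      got <- do.call(rbind, lapply(sents, from_tagged))
      got <- got[order(got$start), , drop = FALSE]
      ann <- doc$annotations[order(doc$annotations$start), , drop = FALSE]
      expect_equal(got$start, ann$start)
      expect_equal(got$end, ann$end)
      expect_equal(got$surface, ann$surface)
      expect_equal(got$entity_type, ann$entity_type)
    }
  }
})

test_that("normalize_annotations keeps longest-then-earliest and drops overlap", {
  doc <- document("d", "breast cancer hurts",
                  data.frame(id = c("T1", "T2"),
                             entity_type = "Disease",
                             start = c(0L, 7L), end = c(13L, 13L),
                             surface = c("breast cancer", "cancer")))
  expect_warning(norm <- normalize_annotations(doc), "overlap")
  expect_equal(norm$annotations$surface, "breast cancer")
})

test_that("split_corpus floors train/dev and remainders to test, deterministically", {
  docs <- generate_gsc(generator_config(n_documents = 100, seed = 4,
                                        sentences_per_doc = c(1L, 1L)))
  sp <- split_corpus(docs, seed = 2)
  expect_length(sp$train, 60L)
  expect_length(sp$dev, 10L)
  expect_length(sp$test, 30L)

  sp10 <- split_corpus(docs[1:10], seed = 2)
  expect_length(sp10$train, 6L)
  expect_length(sp10$dev, 1L)
  expect_length(sp10$test, 3L)

  again <- split_corpus(docs, seed = 2)
  expect_identical(vapply(sp$train, `[[`, "", "doc_id"),
                   vapply(again$train, `[[`, "", "doc_id"))

  expect_error(split_corpus(docs[1:2], seed = 1), "cannot split")
  expect_error(split_corpus(docs, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("split partitions are disjoint and exhaustive for varying n", {
  for (n in c(3L, 7L, 12L, 31L)) {
    docs <- generate_gsc(generator_config(n_documents = n, seed = n,
                                          sentences_per_doc = c(1L, 1L)))
    sp <- split_corpus(docs, seed = n)
    ids <- c(vapply(sp$train, `[[`, "", "doc_id"),
             vapply(sp$dev, `[[`, "", "doc_id"),
             vapply(sp$test, `[[`, "", "doc_id"))
    expect_length(ids, n)
    expect_false(anyDuplicated(ids) > 0)
    expect_setequal(ids, vapply(docs, `[[`, "", "doc_id"))
  }
})

test_that("deduplicate_against removes exactly the matching doc ids", {
  docs <- lapply(c("a", "b", "c"), function(id) document(id, "text here"))
  expect_equal(vapply(deduplicate_against(docs, "b"), `[[`, "", "doc_id"),
               c("a", "c"))
  expect_length(deduplicate_against(docs, character()), 3L)
  expect_length(deduplicate_against(docs, c("a", "b", "c", "d")), 0L)
  expect_equal(attr(deduplicate_against(docs, "b"), "n_removed"), 1L)
})

test_that("filter_blacklist removes case-insensitive full-surface matches only", {
  doc <- document("d", "BRCA1 and Proteins and proteinase",
                  data.frame(id = c("T1", "T2", "T3"),
                             entity_type = "Gene",
                             start = c(0L, 10L, 23L), end = c(5L, 18L, 33L),
                             surface = c("BRCA1", "Proteins", "proteinase")))
  out <- filter_blacklist(list(doc), c("genes", "proteins", "animals"))
  expect_equal(out[[1]]$annotations$surface, c("BRCA1", "proteinase"))
  expect_identical(out[[1]]$text, doc$text)
  expect_equal(attr(out, "n_removed"), 1L)
  # empty blacklist is the identity
  same <- filter_blacklist(list(doc), character())
  expect_equal(nrow(same[[1]]$annotations), 3L)
})

test_that("load_embeddings reads word2vec text format with its edge rules", {
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("2 3", "brca1 0.1 0.2 0.3", "kinase -1 0 1"), path)
  emb <- load_embeddings(path)
  expect_equal(dim(emb$matrix), c(2L, 3L))
  expect_equal(emb$matrix[emb$vocab[["kinase"]], ], c(-1, 0, 1))
  expect_equal(emb$matrix[emb$vocab[["brca1"]], ], c(0.1, 0.2, 0.3))

  writeLines(c("3 3", "brca1 0.1 0.2 0.3", "kinase -1 0 1"), path)
  expect_warning(emb2 <- load_embeddings(path), "declares 3")
  expect_equal(nrow(emb2$matrix), 2L)

  writeLines(c("2 3", "brca1 0.1 0.2 0.3", "brca1 9 9 9"), path)
  expect_warning(emb3 <- load_embeddings(path), "repeated")
  expect_equal(emb3$matrix[emb3$vocab[["brca1"]], ], c(0.1, 0.2, 0.3))

  writeLines(c("2 3", "brca1 0.1 0.2", "kinase -1 0 1"), path)
  expect_error(load_embeddings(path), "expected 3")
})

test_that("CoNLL export/import round-trips tagged sentences", {
  docs <- tiny_docs(n = 3, seed = 9)
  sents <- unlist(lapply(docs, to_tagged), recursive = FALSE)
  class(sents) <- NULL
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(sents, path)
  back <- read_conll(path)
  expect_length(back, length(sents))
  for (k in seq_along(sents)) {
    expect_equal(back[[k]]$doc_id, sents[[k]]$doc_id)
    expect_equal(back[[k]]$tokens$surface, sents[[k]]$tokens$surface)
    expect_equal(back[[k]]$tokens$start, sents[[k]]$tokens$start)
    expect_equal(back[[k]]$labels, sents[[k]]$labels)
  }
})
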