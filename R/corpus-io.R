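# Corpus input/output: Brat standoff and CoNLL-style formats, tokenization,
# conversion between character-offset annotations and per-token label
# sequences, corpus splitting and silver-corpus filtering.
#
# Offsets are 0-based, half-open [start, end) throughout (the Brat standoff
# convention).

#' Construct a document
#'
#' A document is the unit of corpora, splits and deduplication: an identifier,
#' the raw text, and a table of character-offset entity annotations.
#'
#' @param doc_id Unique document identifier (string).
#' @param text Document text.
#' @param annotations Data frame with columns `id`, `entity_type`, `start`,
#'   `end`, `surface`. Offsets are 0-based half-open. May be `NULL` for an
#'   unannotated document.
#' @return An object of class `ner_document`.
#' @export
document <- function(doc_id, text, annotations = NULL) {
  if (is.null(annotations)) annotations <- empty_annotations()
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  validate_annotations(annotations, text, doc_id)
  structure(list(doc_id = doc_id, text = text, annotations = annotations),
            class = "ner_document")
}

empty_annotations <- function() {
  data.frame(id = character(), entity_type = character(),
             start = integer(), end = integer(), surface = character(),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, text, doc_id) {
  need <- c("id", "entity_type", "start", "end", "surface")
  if (!all(need %in% names(ann)))
    stopf("annotations of '%s' must have columns %s", doc_id,
          paste(need, collapse = ", "))
  if (nrow(ann) == 0L) return(invisible(TRUE))
  n <- nchar(text)
  bad <- ann$start < 0 | ann$end > n | ann$start >= ann$end
  if (any(bad))
    stopf("document '%s': annotation offsets out of range [0, %d): %s",
          doc_id, n, paste(ann$id[bad], collapse = ", "))
  slice <- substring(text, ann$start + 1L, ann$end)
  mism <- slice != ann$surface
  if (any(mism))
    stopf("document '%s': annotation surface does not match text slice for %s",
          doc_id, paste(ann$id[mism], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.ner_document <- function(x, ...) {
  cat(sprintf("<ner_document '%s': %d chars, %d annotations>\n",
              x$doc_id, nchar(x$text), nrow(x$annotations)))
  invisible(x)
}

doc_ids <- function(docs) vapply(docs, function(d) d$doc_id, character(1))

#' Parse a Brat standoff annotation file
#'
#' Reads text-bound ("T") annotation lines of the Brat standoff format,
#' `T<id>\\t<type> <start> <end>\\t<surface>`. Non-"T" lines (relations,
#' events, notes) are ignored. Discontinuous spans (`start end;start end`)
#' are rejected with a warning and skipped. A surface string that does not
#' match the corresponding text slice is an error, as are out-of-range
#' offsets.
#'
#' @param text Document text.
#' @param ann_lines Character vector of annotation lines (or a single string
#'   containing newlines).
#' @param doc_id Document identifier to attach.
#' @return A [document()].
#' @export
parse_brat <- function(text, ann_lines, doc_id = "doc") {
  if (length(ann_lines) == 1L && grepl("\n", ann_lines))
    ann_lines <- strsplit(ann_lines, "\n", fixed = TRUE)[[1]]
  ann_lines <- ann_lines[nzchar(ann_lines)]
  recs <- list()
  for (ln in ann_lines) {
    if (!startsWith(ln, "T")) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stopf("malformed Brat annotation line: '%s'", ln)
    id <- parts[[1]]
    mid <- strsplit(parts[[2]], " ", fixed = TRUE)[[1]]
    if (any(grepl(";", parts[[2]], fixed = TRUE))) {
      warnf("discontinuous span rejected in '%s': '%s'", doc_id, ln)
      next
    }
    if (length(mid) != 3L)
      stopf("malformed Brat annotation line: '%s'", ln)
    start <- suppressWarnings(as.integer(mid[[2]]))
    end <- suppressWarnings(as.integer(mid[[3]]))
    if (is.na(start) || is.na(end))
      stopf("malformed Brat annotation line: '%s'", ln)
    surface <- paste(parts[3:length(parts)], collapse = "\t")
    recs[[length(recs) + 1L]] <-
      data.frame(id = id, entity_type = mid[[1]], start = start, end = end,
                 surface = surface, stringsAsFactors = FALSE)
  }
  ann <- if (length(recs)) do.call(rbind, recs) else empty_annotations()
  document(doc_id, text, ann)
}

#' Serialize a document to Brat standoff
#'
#' Inverse of [parse_brat()] up to annotation id renumbering: annotations are
#' written as text-bound lines `T1`, `T2`, ... in order of start offset.
#'
#' @param doc A [document()].
#' @return A list with elements `text` and `ann_lines`.
#' @export
write_brat <- function(doc) {
  ann <- doc$annotations
  if (nrow(ann)) {
    ann <- ann[order(ann$start, ann$end), , drop = FALSE]
    lines <- sprintf("T%d\t%s %d %d\t%s", seq_len(nrow(ann)),
                     ann$entity_type, ann$start, ann$end, ann$surface)
  } else {
    lines <- character()
  }
  list(text = doc$text, ann_lines = lines)
}

#' Read a directory of paired Brat .txt/.ann files
#'
#' @param dir Directory containing `<id>.txt` / `<id>.ann` pairs.
#' @return A list of [document()]s, ordered by file name.
#' @export
read_brat_dir <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(tf) {
    base <- sub("\\.txt$", "", basename(tf))
    af <- file.path(dir, paste0(base, ".ann"))
    text <- paste(readLines(tf, warn = FALSE), collapse = "\n")
    ann <- if (file.exists(af)) readLines(af, warn = FALSE) else character()
    tryCatch(parse_brat(text, ann, doc_id = base),
             error = function(e) stopf("while reading '%s': %s", af, conditionMessage(e)))
  })
}

#' Write documents as a Brat standoff directory
#'
#' @param docs List of [document()]s.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_brat_dir <- function(docs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (doc in docs) {
    out <- write_brat(doc)
    writeLines(out$text, file.path(dir, paste0(doc$doc_id, ".txt")))
    writeLines(out$ann_lines, file.path(dir, paste0(doc$doc_id, ".ann")))
  }
  invisible(dir)
}

# --------------------------------------------------------------- tokenizer

PUNCT_RE <- "[][!\"#$%&'()*+,./:;<=>?@\\^_`{|}~-]"

#' Tokenize text into sentences of offset tokens
#'
#' Deterministic, dependency-free tokenizer: text is split on whitespace,
#' then leading and trailing punctuation characters are split off as separate
#' tokens; hyphens and slashes inside a token are kept (so biomedical names
#' like "N-acetyl-cysteine" stay whole). A sentence boundary is a `.`, `!` or
#' `?` token followed by whitespace and an uppercase letter, except when the
#' `.` follows a single capital letter (abbreviation guard, "A. thaliana").
#'
#' @param text Character scalar.
#' @return A list of sentences; each sentence is a data frame with columns
#'   `surface`, `start`, `end` (0-based half-open offsets into `text`).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(list())
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) return(list())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  surf <- character(0); tok_s <- integer(0); tok_e <- integer(0)
  for (k in seq_along(starts)) {
    s <- starts[k]                       # 1-based position of chunk start
    e <- s + lens[k] - 1L                # 1-based inclusive end
    chars <- strsplit(substr(text, s, e), "", fixed = TRUE)[[1]]
    i <- 1L; j <- length(chars)
    lead <- integer(0); trail <- integer(0)
    while (i < j && grepl(PUNCT_RE, chars[i])) { lead <- c(lead, i); i <- i + 1L }
    while (j > i && grepl(PUNCT_RE, chars[j])) { trail <- c(j, trail); j <- j - 1L }
    pieces <- c(lapply(lead, function(p) c(p, p)),
                list(c(i, j)),
                lapply(trail, function(p) c(p, p)))
    for (p in pieces) {
      a <- s + p[1] - 1L; b <- s + p[2] - 1L
      surf <- c(surf, substr(text, a, b))
      tok_s <- c(tok_s, a - 1L)          # to 0-based
      tok_e <- c(tok_e, b)               # half-open end
    }
  }
  toks <- data.frame(surface = surf, start = tok_s, end = tok_e,
                     stringsAsFactors = FALSE)
  # sentence boundaries over the token stream
  n <- nrow(toks)
  is_break <- logical(n)
  for (k in seq_len(n)) {
    if (!toks$surface[k] %in% c(".", "!", "?")) next
    if (k == n) { is_break[k] <- TRUE; next }
    gap <- substr(text, toks$end[k] + 1L, toks$start[k + 1])
    if (!grepl("^\\s+$", gap)) next
    if (!grepl("^[A-Z]", toks$surface[k + 1])) next
    if (toks$surface[k] == "." && k > 1L &&
        grepl("^[A-Z]$", toks$surface[k - 1]) &&
        toks$end[k - 1] == toks$start[k]) next   # single-capital abbreviation
    is_break[k] <- TRUE
  }
  sent_id <- cumsum(c(0L, is_break[-n])) + 1L
  split(toks, factor(sent_id, levels = unique(sent_id))) |>
    unname() |> lapply(function(d) {
    rownames(d) <- NULL
    d
  })
}

# ------------------------------------------------- annotation normalization

#' Resolve overlapping annotations
#'
#' Keeps the longest annotation among overlapping ones; among equal lengths
#' the earliest start wins; the rest are dropped with a warning.
#'
#' @param doc A [document()].
#' @return The document with non-overlapping annotations.
#' @export
normalize_annotations <- function(doc) {
  ann <- doc$annotations
  if (nrow(ann) < 2L) return(doc)
  len <- ann$end - ann$start
  ord <- order(-len, ann$start)
  keep <- logical(nrow(ann))
  kept_s <- integer(0); kept_e <- integer(0)
  for (k in ord) {
    if (!any(ann$start[k] < kept_e & ann$end[k] > kept_s)) {
      keep[k] <- TRUE
      kept_s <- c(kept_s, ann$start[k]); kept_e <- c(kept_e, ann$end[k])
    }
  }
  if (!all(keep)) {
    warnf("document '%s': dropped %d overlapping annotation(s)",
          doc$doc_id, sum(!keep))
    doc$annotations <- ann[keep, , drop = FALSE]
    rownames(doc$annotations) <- NULL
  }
  doc
}

# ------------------------------------------------------- tagging conversion

scheme_labels <- function(types, scheme = c("BIO", "BIOES")) {
  scheme <- match.arg(scheme)
  pre <- if (scheme == "BIO") c("B", "I") else c("B", "I", "E", "S")
  c("O", as.vector(t(outer(sort(unique(types)), pre,
                           function(ty, p) paste0(p, "-", ty)))))
}

#' Convert a document to per-token label sequences
#'
#' Tokenizes the text and maps each (normalized, non-overlapping) annotation
#' to a maximal run of entity labels in the chosen chunking scheme. An
#' annotation whose boundaries fall inside tokens is snapped outward to the
#' minimal covering token span; the number of snaps is recorded in the
#' `n_snapped` attribute of the result (and logged when
#' `options(bionertl.verbose = TRUE)`).
#'
#' @param doc A [document()].
#' @param scheme `"BIO"` (IOB2, default) or `"BIOES"`.
#' @return A list of tagged sentences (class `tagged_sentence`), each a list
#'   with `doc_id`, `tokens` (data frame) and `labels` (character); the list
#'   carries attribute `n_snapped`.
#' @export
to_tagged <- function(doc, scheme = c("BIO", "BIOES")) {
  scheme <- match.arg(scheme)
  doc <- suppressWarnings(normalize_annotations(doc))
  sents <- tokenize(doc$text)
  ann <- doc$annotations
  n_snapped <- 0L
  out <- lapply(sents, function(toks) {
    labels <- rep("O", nrow(toks))
    if (nrow(ann)) {
      for (k in seq_len(nrow(ann))) {
        cov <- which(toks$end > ann$start[k] & toks$start < ann$end[k])
        if (!length(cov)) next
        if (toks$start[cov[1]] != ann$start[k] ||
            toks$end[cov[length(cov)]] != ann$end[k])
          n_snapped <<- n_snapped + 1L
        ty <- ann$entity_type[k]
        if (scheme == "BIO") {
          labels[cov] <- paste0("I-", ty)
          labels[cov[1]] <- paste0("B-", ty)
        } else {
          if (length(cov) == 1L) {
            labels[cov] <- paste0("S-", ty)
          } else {
            labels[cov] <- paste0("I-", ty)
            labels[cov[1]] <- paste0("B-", ty)
            labels[cov[length(cov)]] <- paste0("E-", ty)
          }
        }
      }
    }
    structure(list(doc_id = doc$doc_id, tokens = toks, labels = labels),
              class = "tagged_sentence")
  })
  if (n_snapped > 0L)
    log_msg("document '%s': snapped %d annotation boundary(ies) to tokens",
            doc$doc_id, n_snapped)
  structure(out, n_snapped = n_snapped)
}

#' Recover annotations from a tagged sentence
#'
#' Inverse of [to_tagged()], with the conlleval repair convention: an `I-`
#' label following `O`, the sentence start, or a different entity type opens
#' a new entity. Surfaces are reconstructed from token surfaces and their
#' offset gaps.
#'
#' @param sent A `tagged_sentence`.
#' @return A data frame with columns `entity_type`, `start`, `end`, `surface`.
#' @export
from_tagged <- function(sent) {
  labels <- sent$labels
  toks <- sent$tokens
  ok <- grepl("^O$|^[BIES]-.+$", labels)
  if (!all(ok))
    stopf("unknown label string(s): %s", paste(unique(labels[!ok]), collapse = ", "))
  n <- length(labels)
  ents <- list()
  cur_start <- NA_integer_; cur_type <- NA_character_
  close_ent <- function(last) {
    if (!is.na(cur_start))
      ents[[length(ents) + 1L]] <<- c(cur_start, last, cur_type)
    cur_start <<- NA_integer_; cur_type <<- NA_character_
  }
  for (k in seq_len(n)) {
    lab <- labels[k]
    if (lab == "O") { close_ent(k - 1L); next }
    pre <- substr(lab, 1, 1)
    ty <- substring(lab, 3)
    if (pre %in% c("B", "S") || is.na(cur_type) || ty != cur_type) {
      close_ent(k - 1L)
      cur_start <- k; cur_type <- ty
    }
    if (pre %in% c("E", "S")) close_ent(k)
  }
  close_ent(n)
  if (!length(ents)) {
    return(data.frame(entity_type = character(), start = integer(),
                      end = integer(), surface = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(ents, function(e) {
    i <- as.integer(e[1]); j <- as.integer(e[2])
    surf <- toks$surface[i]
    if (j > i) {
      for (k in (i + 1L):j) {
        gap <- toks$start[k] - toks$end[k - 1L]
        surf <- paste0(surf, strrep(" ", gap), toks$surface[k])
      }
    }
    data.frame(entity_type = e[3], start = toks$start[i], end = toks$end[j],
               surface = surf, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

# ----------------------------------------------------------------- splits

#' Split a corpus into train/dev/test partitions at the document level
#'
#' Default fractions are 60% train, 10% development and 30% test. Sizes are
#' `floor(n * f_train)` and `floor(n * f_dev)`, with the remainder going to
#' the test partition. Deterministic for a fixed seed.
#'
#' @param docs List of [document()]s.
#' @param fractions Numeric vector of three fractions summing to 1.
#' @param seed Integer seed.
#' @return A list with elements `train`, `dev`, `test` (class `corpus_split`).
#' @export
split_corpus <- function(docs, fractions = c(0.6, 0.1, 0.3), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  n <- length(docs)
  n_parts <- sum(fractions > 0)
  if (n < n_parts)
    stopf("cannot split %d document(s) into %d parts", n, n_parts)
  ids <- doc_ids(docs)
  if (anyDuplicated(ids)) stopf("duplicated doc_ids in corpus")
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(n * fractions[1])
  n_dev <- floor(n * fractions[2])
  structure(list(train = docs[perm[seq_len(n_train)]],
                 dev = docs[perm[n_train + seq_len(n_dev)]],
                 test = docs[perm[setdiff(seq_len(n), seq_len(n_train + n_dev))]]),
            class = "corpus_split")
}

#' @export
print.corpus_split <- function(x, ...) {
  cat(sprintf("<corpus_split: %d train / %d dev / %d test>\n",
              length(x$train), length(x$dev), length(x$test)))
  invisible(x)
}

#' Exclude silver-corpus documents that appear in gold corpora
#'
#' Removes every silver-standard document whose `doc_id` is present in the
#' given set of gold-standard document ids, guarding against circularity in
#' performance testing. The number of removals is recorded in the
#' `n_removed` attribute.
#'
#' @param ssc List of [document()]s (silver corpus).
#' @param gsc_ids Character vector of gold-corpus doc ids.
#' @return The filtered list of documents.
#' @export
deduplicate_against <- function(ssc, gsc_ids) {
  keep <- !(doc_ids(ssc) %in% gsc_ids)
  log_msg("deduplication removed %d of %d silver documents", sum(!keep), length(ssc))
  structure(ssc[keep], n_removed = sum(!keep))
}

#' Remove blacklisted annotation surfaces
#'
#' Removes annotations whose surface form matches a blacklist entry
#' case-insensitively (exact full-surface match, not substring). Documents
#' and text are unchanged. The total number of removed annotations is in the
#' `n_removed` attribute.
#'
#' @param docs List of [document()]s.
#' @param blacklist Character vector of surface forms, e.g.
#'   `c("genes", "proteins", "animals")`.
#' @return The list of documents with filtered annotations.
#' @export
filter_blacklist <- function(docs, blacklist) {
  stopifnot(is.character(blacklist))
  bl <- tolower(blacklist)
  removed <- 0L
  out <- lapply(docs, function(doc) {
    drop <- tolower(doc$annotations$surface) %in% bl
    removed <<- removed + sum(drop)
    doc$annotations <- doc$annotations[!drop, , drop = FALSE]
    rownames(doc$annotations) <- NULL
    doc
  })
  log_msg("blacklist filtering removed %d annotation(s)", removed)
  structure(out, n_removed = removed)
}

# -------------------------------------------------------------- embeddings

#' Load pre-trained word embeddings in word2vec text format
#'
#' The first line must be `<count> <dim>`; each following line holds a token
#' and `dim` floats. A repeated token keeps its first occurrence (with a
#' warning); a header count that disagrees with the actual number of vectors
#' produces a warning, and the actual count is used. A dimension mismatch on
#' any line is an error.
#'
#' @param path Path to the embeddings file.
#' @return A list with `vocab` (named integer vector, token to row index) and
#'   `matrix` (numeric matrix, one row per token).
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty embeddings file: %s", path)
  hdr <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(hdr) != 2L) stopf("malformed word2vec header: '%s'", lines[[1]])
  count <- as.integer(hdr[[1]]); dim <- as.integer(hdr[[2]])
  body <- lines[-1]
  if (length(body) != count)
    warnf("embeddings header declares %d vectors but file has %d; using %d",
          count, length(body), length(body))
  toks <- character(length(body))
  mat <- matrix(NA_real_, length(body), dim)
  for (k in seq_along(body)) {
    parts <- strsplit(trimws(body[[k]]), "\\s+")[[1]]
    if (length(parts) != dim + 1L)
      stopf("embedding line %d has %d values, expected %d",
            k + 1L, length(parts) - 1L, dim)
    toks[k] <- parts[[1]]
    mat[k, ] <- as.numeric(parts[-1])
  }
  dup <- duplicated(toks)
  if (any(dup)) {
    warnf("embeddings contain %d repeated token(s); keeping first occurrences",
          sum(dup))
    toks <- toks[!dup]
    mat <- mat[!dup, , drop = FALSE]
  }
  list(vocab = setNames(seq_along(toks), toks), matrix = mat)
}

# ------------------------------------------------------------ CoNLL export

#' Write tagged sentences in CoNLL-style columns
#'
#' One token per line with tab-separated columns token/start/end/label, a
#' blank line between sentences, and `-DOCSTART- <doc_id>` separators.
#'
#' @param sents List of `tagged_sentence` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_conll <- function(sents, path) {
  con <- file(path, "w")
  on.exit(close(con))
  last_doc <- NA_character_
  for (s in sents) {
    if (is.na(last_doc) || s$doc_id != last_doc) {
      writeLines(paste0("-DOCSTART- ", s$doc_id), con)
      last_doc <- s$doc_id
    }
    writeLines(sprintf("%s\t%d\t%d\t%s", s$tokens$surface, s$tokens$start,
                       s$tokens$end, s$labels), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read tagged sentences from a CoNLL-style file written by [write_conll()]
#'
#' @param path Input file path.
#' @return A list of `tagged_sentence` objects.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sents <- list()
  cur <- list()
  doc <- "doc"
  flush_sent <- function() {
    if (!length(cur)) return()
    df <- do.call(rbind, cur)
    sents[[length(sents) + 1L]] <<- structure(
      list(doc_id = doc,
           tokens = data.frame(surface = df$surface,
                               start = as.integer(df$start),
                               end = as.integer(df$end),
                               stringsAsFactors = FALSE),
           labels = df$label),
      class = "tagged_sentence")
    cur <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, "-DOCSTART-")) {
      flush_sent()
      doc <- trimws(sub("^-DOCSTART-", "", ln))
      next
    }
    if (!nzchar(trimws(ln))) { flush_sent(); next }
    p <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(p) != 4L) stopf("malformed CoNLL line: '%s'", ln)
    cur[[length(cur) + 1L]] <- data.frame(surface = p[1], start = p[2],
                                          end = p[3], label = p[4],
                                          stringsAsFactors = FALSE)
  }
  flush_sent()
  sents
}
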