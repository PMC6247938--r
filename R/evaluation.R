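# Entity-level exact-match evaluation: precision/recall/F1 over mention
# sets, macro-averaging across corpora, reduction-in-error, learning curves
# with trial variability, error-set overlap and a paired approximate
# randomization test.
#
# A mention is the tuple (doc_id, start, end, entity_type); a prediction
# counts as correct if and only if it exactly equals a gold mention.

empty_mentions <- function() {
  data.frame(doc_id = character(), start = integer(), end = integer(),
             entity_type = character(), stringsAsFactors = FALSE)
}

as_mentions <- function(x) {
  if (is.null(x) || !nrow(as.data.frame(x))) return(empty_mentions())
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("doc_id", "start", "end", "entity_type")
  if (!all(need %in% names(x)))
    stopf("mentions need columns %s", paste(need, collapse = ", "))
  x[, need]
}

mention_keys <- function(m) {
  if (!nrow(m)) return(character())
  paste(m$doc_id, m$start, m$end, m$entity_type, sep = "\r")
}

#' Gold entity mentions of a corpus
#'
#' Extracts the mention set (doc_id, start, end, entity_type) of a list of
#' documents, after token-boundary snapping, for use with [score()].
#'
#' @param docs List of [document()]s.
#' @param scheme Chunking scheme used for the round-trip.
#' @return A mention data frame.
#' @export
gold_mentions <- function(docs, scheme = "BIO") {
  tagged_mentions(docs_to_tagged(docs, scheme))
}

#' Entity-level exact-match scoring
#'
#' True positives are the intersection of gold and predicted mention sets,
#' false positives the predictions outside gold, false negatives the gold
#' mentions not predicted. Precision, recall and F1 are percentages; each is
#' defined as 0 when its denominator is 0.
#'
#' @param gold,pred Mention data frames (columns `doc_id`, `start`, `end`,
#'   `entity_type`).
#' @return An object of class `ner_eval` with elements `tp`, `fp`, `fn`
#'   (mention data frames) and `precision`, `recall`, `f1` (percent).
#' @export
score <- function(gold, pred) {
  gold <- as_mentions(gold)
  pred <- as_mentions(pred)
  gold <- gold[!duplicated(mention_keys(gold)), , drop = FALSE]
  pred <- pred[!duplicated(mention_keys(pred)), , drop = FALSE]
  gk <- mention_keys(gold)
  pk <- mention_keys(pred)
  tp <- pred[pk %in% gk, , drop = FALSE]
  fp <- pred[!(pk %in% gk), , drop = FALSE]
  fn <- gold[!(gk %in% pk), , drop = FALSE]
  ntp <- nrow(tp); nfp <- nrow(fp); nfn <- nrow(fn)
  precision <- if (ntp + nfp > 0) 100 * ntp / (ntp + nfp) else 0
  recall <- if (ntp + nfn > 0) 100 * ntp / (ntp + nfn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1),
            class = "ner_eval")
}

#' @export
print.ner_eval <- function(x, ...) {
  cat(sprintf("<ner_eval: TP %d FP %d FN %d | P %.2f%% R %.2f%% F1 %.2f%%>\n",
              nrow(x$tp), nrow(x$fp), nrow(x$fn),
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Reduction in error
#'
#' The fraction of the baseline's F1 shortfall eliminated by transfer
#' learning: `(F1_TL - F1_baseline) / (100 - F1_baseline) * 100`. Negative
#' when transfer hurts.
#'
#' @param f1_tl,f1_baseline F1 scores in percent, both in `[0, 100]` with
#'   `f1_baseline < 100`.
#' @return The reduction in error, in percent.
#' @export
reduction_in_error <- function(f1_tl, f1_baseline) {
  stopifnot(f1_tl >= 0, f1_tl <= 100, f1_baseline >= 0, f1_baseline <= 100)
  if (f1_baseline == 100)
    stopf("reduction in error is undefined for a perfect baseline (F1 = 100)")
  (f1_tl - f1_baseline) / (100 - f1_baseline) * 100
}

#' Macro-average evaluation results across corpora
#'
#' Unweighted arithmetic mean of precision, recall and F1 across results
#' (not recomputed from pooled counts).
#'
#' @param results Non-empty list of `ner_eval` objects.
#' @return A list with `precision`, `recall` and `f1` averages.
#' @export
macro_average <- function(results) {
  if (!length(results)) stopf("macro_average requires a non-empty list")
  list(precision = mean(vapply(results, function(r) r$precision, numeric(1))),
       recall = mean(vapply(results, function(r) r$recall, numeric(1))),
       f1 = mean(vapply(results, function(r) r$f1, numeric(1))))
}

#' Error-set overlap between two systems
#'
#' Intersections of the true-positive, false-negative and false-positive
#' mention sets of two systems evaluated against the same gold standard —
#' the counts behind a two-set Venn diagram.
#'
#' @param a,b `ner_eval` results computed against the same gold mentions.
#' @return A list with elements `tp`, `fp`, `fn`, each a named numeric
#'   vector `c(a_only, both, b_only)`.
#' @export
error_overlap <- function(a, b) {
  gold_a <- sort(c(mention_keys(a$tp), mention_keys(a$fn)))
  gold_b <- sort(c(mention_keys(b$tp), mention_keys(b$fn)))
  if (!identical(gold_a, gold_b))
    stopf("error_overlap requires results computed against the same gold set")
  pair <- function(ka, kb) {
    c(a_only = length(setdiff(ka, kb)),
      both = length(intersect(ka, kb)),
      b_only = length(setdiff(kb, ka)))
  }
  list(tp = pair(mention_keys(a$tp), mention_keys(b$tp)),
       fp = pair(mention_keys(a$fp), mention_keys(b$fp)),
       fn = pair(mention_keys(a$fn), mention_keys(b$fn)))
}

#' Paired approximate randomization test on F1
#'
#' Two-sided document-level randomization: in each shuffle the predictions of
#' the two systems are swapped per document with probability 1/2 and the
#' absolute F1 difference recomputed;
#' `p = (#\{|dF1_shuffled| >= |dF1_observed|\} + 1) / (n_shuffles + 1)`.
#' With `exhaustive = TRUE` all `2^D` swap patterns are enumerated and the
#' exact proportion is returned.
#'
#' @param gold Gold mention data frame.
#' @param pred_a,pred_b Prediction mention data frames of the two systems
#'   over the same documents.
#' @param n_shuffles Number of random shuffles (default 9999).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all swap patterns instead of sampling.
#' @return The p-value.
#' @export
paired_significance <- function(gold, pred_a, pred_b, n_shuffles = 9999L,
                                seed = 1L, exhaustive = FALSE) {
  gold <- as_mentions(gold); pred_a <- as_mentions(pred_a); pred_b <- as_mentions(pred_b)
  docs <- sort(unique(c(gold$doc_id, pred_a$doc_id, pred_b$doc_id)))
  split_by_doc <- function(m) lapply(docs, function(d) m[m$doc_id == d, , drop = FALSE])
  g <- split_by_doc(gold); pa <- split_by_doc(pred_a); pb <- split_by_doc(pred_b)
  f1_of <- function(pred_list) {
    score(do.call(rbind, g), do.call(rbind, pred_list))$f1
  }
  delta <- function(swap) {
    a <- pa; b <- pb
    a[swap] <- pb[swap]
    b[swap] <- pa[swap]
    abs(f1_of(a) - f1_of(b))
  }
  d_obs <- abs(f1_of(pa) - f1_of(pb))
  D <- length(docs)
  if (exhaustive) {
    if (D > 20L) stopf("exhaustive enumeration limited to 20 documents")
    hits <- 0L
    for (pattern in 0:(2^D - 1)) {
      swap <- as.logical(bitwAnd(bitwShiftR(pattern, 0:(D - 1)), 1L))
      if (delta(swap) >= d_obs - 1e-12) hits <- hits + 1L
    }
    return(hits / 2^D)
  }
  hits <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_shuffles), function(i) {
      delta(runif(D) < 0.5) >= d_obs - 1e-12
    }, logical(1)))
  })
  (hits + 1) / (n_shuffles + 1)
}

#' Learning curves for baseline and transfer arms
#'
#' For each target-train-set fraction (a percent of the overall gold-corpus
#' size), subsamples that many documents from the fixed train partition,
#' trains the baseline arm (gold only) and the transfer arm (initialized
#' from a silver-trained source model) `n_trials` times with distinct
#' derived seeds, and reports the mean and sample standard deviation
#' (`n - 1` denominator) of the test-set F1. The dev and test partitions
#' stay fixed across fractions and trials; the source model is trained once
#' per trial and reused across fractions.
#'
#' @param gsc Gold-corpus document list.
#' @param ssc Silver-corpus document list (deduplicated and filtered).
#' @param fractions Percents in `(0, 60]`.
#' @param n_trials Trials per fraction (default 3).
#' @param base_seed Integer seed.
#' @param config A [model_config()].
#' @param max_epochs Epoch limit passed to both training phases.
#' @return A list with `summary` (fraction, arm, mean_f1, sd_f1) and
#'   `trials` (per-trial F1 table) data frames.
#' @export
learning_curve <- function(gsc, ssc, fractions = c(10, 20, 40, 60),
                           n_trials = 3L, base_seed = 1L,
                           config = model_config(), max_epochs = 100L) {
  stopifnot(all(fractions > 0), all(fractions <= 60))
  n <- length(gsc)
  gsc_split <- split_corpus(gsc, seed = base_seed)
  rows <- list()
  for (trial in seq_len(n_trials)) {
    tseed <- derive_seed(base_seed, trial)
    src <- train_source_model(ssc, config, seed = tseed, max_epochs = max_epochs)
    for (f in fractions) {
      n_take <- floor(f / 100 * n)
      if (n_take < 1L)
        stopf("fraction %g%% of %d documents yields no training documents", f, n)
      n_take <- min(n_take, length(gsc_split$train))
      sub_idx <- withr::with_seed(derive_seed(tseed, round(f * 100)),
                                  sample.int(length(gsc_split$train), n_take))
      sub_split <- gsc_split
      sub_split$train <- gsc_split$train[sub_idx]
      arms <- run_arms(src, sub_split, config, seed = tseed,
                       max_epochs = max_epochs)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, trial = trial,
        baseline_f1 = arms$baseline$f1, transfer_f1 = arms$transfer$f1)
    }
  }
  trials <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(sort(unique(trials$fraction)), function(f) {
    sub <- trials[trials$fraction == f, ]
    data.frame(fraction = f,
               arm = c("baseline", "transfer"),
               mean_f1 = c(mean(sub$baseline_f1), mean(sub$transfer_f1)),
               sd_f1 = c(sd0(sub$baseline_f1), sd0(sub$transfer_f1)))
  }))
  list(summary = summ, trials = trials)
}

sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)

#' Bin corpora by annotation count
#'
#' Groups per-corpus F1 improvements by total-annotation-count bins and marks
#' statistically significant entries (p <= 0.05).
#'
#' @param summaries Data frame with columns `name`, `annotations`,
#'   `delta_f1`, `p_value`.
#' @param bin_edges Numeric vector of interior bin edges.
#' @return A list with `entries` (the input plus `bin` and `significant`
#'   columns) and `summary` (per-bin count and mean improvement; empty bins
#'   are present with zero members).
#' @export
bin_by_annotations <- function(summaries, bin_edges) {
  stopifnot(all(c("name", "annotations", "delta_f1", "p_value") %in%
                  names(summaries)),
            all(summaries$annotations >= 0))
  breaks <- unique(sort(c(-Inf, bin_edges, Inf)))
  bins <- cut(summaries$annotations, breaks = breaks, right = TRUE)
  entries <- summaries
  entries$bin <- bins
  entries$significant <- entries$p_value <= 0.05
  summary <- data.frame(bin = levels(bins))
  summary$n <- as.integer(table(bins)[summary$bin])
  summary$mean_delta_f1 <- vapply(summary$bin, function(b) {
    v <- entries$delta_f1[as.character(entries$bin) == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  list(entries = entries, summary = summary)
}
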