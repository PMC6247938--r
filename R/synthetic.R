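# Synthetic corpus generation: a small, clean gold-standard-like corpus and
# a much larger silver-standard-like corpus over the same entity class,
# degraded by missing annotations, spurious annotations of generic
# distractor terms, and boundary errors.
#
# Entity surfaces are composed from morpheme pools, so held-out documents
# contain surface forms never seen in training and the character-level
# layers have something to generalize over; fixed context templates provide
# learnable lexical cues around the entity slot.

default_morpheme_pools <- function() {
  list(prefix = c("brc", "abl", "erb", "myc", "raf", "grb", "jak", "src",
                  "akt", "fak", "pik", "plk", "cdk", "mapk", "stat", "smad",
                  "wnt", "tgf", "egf", "notch"),
       stem = c("a", "o", "in", "er", "il", "ex"),
       suffix = c("1", "2", "3", "ase", "or", "x", "b", "r"))
}

default_context_templates <- function() {
  list(c("Expression", "of", "<E>", "was", "elevated", "in", "tumor",
         "cells", "."),
       c("We", "observed", "that", "<E>", "phosphorylates", "its",
         "substrate", "."),
       c("The", "<E>", "pathway", "regulates", "apoptosis", "in", "human",
         "tissue", "."),
       c("Mutations", "in", "<E>", "are", "associated", "with", "disease",
         "."),
       c("Inhibition", "of", "<E>", "reduced", "cell", "proliferation", "."),
       c("Knockdown", "of", "<E>", "impaired", "growth", "of", "the",
         "cultures", "."),
       c("Treatment", "increased", "<E>", "activity", "in", "a", "dose",
         "dependent", "manner", "."),
       c("Binding", "of", "<E>", "to", "the", "promoter", "was", "confirmed",
         "."))
}

default_distractor_templates <- function() {
  list(c("Many", "<D>", "were", "analysed", "in", "this", "study", "."),
       c("Several", "<D>", "remain", "poorly", "characterized", "."),
       c("The", "<D>", "were", "obtained", "from", "healthy", "donors", "."),
       c("A", "panel", "of", "<D>", "was", "screened", "."))
}

#' Synthetic corpus generator configuration
#'
#' Defaults produce a 100-document gold-standard-like corpus with one entity
#' class, a 60-surface entity lexicon composed from morpheme pools, and
#' contextual cue templates flanking the entity slot. The distractor terms
#' include the generic surfaces ("proteins", "genes", "animals") that
#' silver-corpus blacklist filtering targets.
#'
#' @param entity_type Entity class name.
#' @param n_documents Number of documents.
#' @param sentences_per_doc Integer range `c(min, max)`.
#' @param entity_lexicon_size Number of distinct entity surfaces.
#' @param morpheme_pools List of `prefix`, `stem`, `suffix` fragment pools.
#' @param context_templates List of token vectors with an `"<E>"` slot.
#' @param distractor_terms Generic, never-gold surface forms.
#' @param entity_sentence_prob Probability a sentence carries an entity.
#' @param two_token_prob Probability an entity gets a head-noun second token.
#' @param seed Integer seed; fixed seed implies fixed output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(entity_type = "Gene",
                             n_documents = 100L,
                             sentences_per_doc = c(2L, 4L),
                             entity_lexicon_size = 60L,
                             morpheme_pools = default_morpheme_pools(),
                             context_templates = default_context_templates(),
                             distractor_terms = c("proteins", "genes",
                                                  "animals", "cells",
                                                  "samples"),
                             entity_sentence_prob = 0.75,
                             two_token_prob = 0.25,
                             seed = 1L) {
  stopifnot(entity_lexicon_size >= 1, length(context_templates) >= 1,
            length(morpheme_pools$prefix) >= 1, n_documents >= 1,
            length(sentences_per_doc) == 2L,
            sentences_per_doc[1] >= 1,
            sentences_per_doc[2] >= sentences_per_doc[1])
  structure(list(entity_type = entity_type,
                 n_documents = as.integer(n_documents),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 entity_lexicon_size = as.integer(entity_lexicon_size),
                 morpheme_pools = morpheme_pools,
                 context_templates = context_templates,
                 distractor_terms = distractor_terms,
                 entity_sentence_prob = entity_sentence_prob,
                 two_token_prob = two_token_prob,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Silver-corpus noise configuration
#'
#' Noise is modeled directly at the annotation level: each gold annotation
#' is dropped with probability `fn_rate`, has one boundary moved by one
#' token with probability `boundary_shift_rate`, and each occurrence of a
#' distractor term is spuriously annotated with probability `fp_rate`. The
#' silver corpus is `size_multiplier` times the gold corpus size.
#'
#' @param fn_rate Probability of dropping a gold annotation.
#' @param fp_rate Probability of annotating a distractor occurrence.
#' @param boundary_shift_rate Probability of moving one boundary by one token.
#' @param size_multiplier Integer >= 1.
#' @param seed Integer seed for the noise process.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(fn_rate = 0.3, fp_rate = 0.1,
                         boundary_shift_rate = 0.05,
                         size_multiplier = 10L, seed = 1L) {
  stopifnot(is_probability(fn_rate), is_probability(fp_rate),
            is_probability(boundary_shift_rate), size_multiplier >= 1)
  structure(list(fn_rate = fn_rate, fp_rate = fp_rate,
                 boundary_shift_rate = boundary_shift_rate,
                 size_multiplier = as.integer(size_multiplier),
                 seed = as.integer(seed)),
            class = "noise_config")
}

# The entity lexicon is a function of the generator seed only, so the gold
# and silver corpora draw from the same surface inventory.
make_lexicon <- function(cfg) {
  pools <- cfg$morpheme_pools
  combos <- as.vector(outer(as.vector(outer(pools$prefix, pools$stem, paste0)),
                            pools$suffix, paste0))
  n <- min(cfg$entity_lexicon_size, length(combos))
  withr::with_seed(derive_seed(cfg$seed, 101L),
                   sample(combos, n))
}

entity_heads <- c("kinase", "receptor", "homolog")

sample_template <- function(templates) templates[[sample.int(length(templates), 1L)]]

generate_documents <- function(cfg, n_documents, id_prefix, gen_seed) {
  lexicon <- make_lexicon(cfg)
  distractor_templates <- default_distractor_templates()
  withr::with_seed(gen_seed, {
    lapply(seq_len(n_documents), function(k) {
      doc_id <- sprintf("%s-%05d", id_prefix, k)
      n_sent <- cfg$sentences_per_doc[1] +
        sample.int(cfg$sentences_per_doc[2] - cfg$sentences_per_doc[1] + 1L, 1L) - 1L
      text <- character(0)
      pos <- 0L
      ann <- list()
      for (si in seq_len(n_sent)) {
        if (runif(1) < cfg$entity_sentence_prob) {
          tmpl <- sample_template(cfg$context_templates)
          ent <- lexicon[sample.int(length(lexicon), 1L)]
          if (runif(1) < cfg$two_token_prob)
            ent <- paste(ent, entity_heads[sample.int(length(entity_heads), 1L)])
          ent_toks <- strsplit(ent, " ", fixed = TRUE)[[1]]
          slot <- which(tmpl == "<E>")
          tokens <- append(tmpl[-slot], ent_toks, after = slot - 1L)
          ent_range <- c(slot, slot + length(ent_toks) - 1L)
        } else {
          tmpl <- sample_template(distractor_templates)
          slot <- which(tmpl == "<D>")
          term <- cfg$distractor_terms[sample.int(length(cfg$distractor_terms), 1L)]
          tokens <- tmpl
          tokens[slot] <- term
          ent_range <- NULL
        }
        for (ti in seq_along(tokens)) {
          sep <- if (pos > 0L) 1L else 0L
          start <- pos + sep
          end <- start + nchar(tokens[ti])
          if (!is.null(ent_range) && ti == ent_range[1]) e_start <- start
          if (!is.null(ent_range) && ti == ent_range[2]) e_end <- end
          text <- c(text, if (sep) " " else NULL, tokens[ti])
          pos <- end
        }
        if (!is.null(ent_range)) {
          ann[[length(ann) + 1L]] <- data.frame(
            id = sprintf("T%d", length(ann) + 1L),
            entity_type = cfg$entity_type, start = e_start, end = e_end,
            surface = paste(tokens[ent_range[1]:ent_range[2]], collapse = " "),
            stringsAsFactors = FALSE)
        }
      }
      ann_df <- if (length(ann)) do.call(rbind, ann) else empty_annotations()
      document(doc_id, paste(text, collapse = ""), ann_df)
    })
  })
}

#' Generate a clean gold-standard-like corpus
#'
#' Documents have unique ids (`gsc-00001`, ...); every entity occurrence is
#' annotated exactly once at token-aligned offsets; entity surfaces are
#' morpheme recombinations so held-out splits contain unseen surface forms.
#'
#' @param cfg A [generator_config()].
#' @return A list of [document()]s.
#' @export
generate_gsc <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  generate_documents(cfg, cfg$n_documents, "gsc", derive_seed(cfg$seed, 1L))
}

#' Generate a noise-degraded silver-standard-like corpus
#'
#' Generates `size_multiplier * n_documents` fresh documents from the same
#' configuration (ids `ssc-00001`, ..., disjoint from the gold corpus for
#' every seed), then independently drops each gold annotation with
#' `fn_rate`, moves one annotation boundary by one token with
#' `boundary_shift_rate`, and spuriously annotates each distractor-term
#' occurrence with `fp_rate`. Document text is never altered, only the
#' annotations.
#'
#' @param gsc_template The [generator_config()] used for the gold corpus.
#' @param noise A [noise_config()].
#' @return A list of [document()]s.
#' @export
degrade_to_ssc <- function(gsc_template, noise) {
  stopifnot(inherits(gsc_template, "generator_config"),
            inherits(noise, "noise_config"))
  n <- gsc_template$n_documents * noise$size_multiplier
  docs <- generate_documents(gsc_template, n, "ssc",
                             derive_seed(gsc_template$seed, 2L))
  withr::with_seed(derive_seed(noise$seed, 3L), {
    lapply(docs, function(doc) apply_noise(doc, gsc_template, noise))
  })
}

apply_noise <- function(doc, cfg, noise) {
  ann <- doc$annotations
  toks <- do.call(rbind, tokenize(doc$text))
  if (nrow(ann)) {
    # missing annotations
    keep <- runif(nrow(ann)) >= noise$fn_rate
    ann <- ann[keep, , drop = FALSE]
  }
  if (nrow(ann) && noise$boundary_shift_rate > 0) {
    for (k in seq_len(nrow(ann))) {
      if (runif(1) >= noise$boundary_shift_rate) next
      shifted <- shift_boundary(ann[k, ], toks, doc$text)
      if (!is.null(shifted)) ann[k, ] <- shifted
    }
  }
  if (noise$fp_rate > 0 && nrow(toks)) {
    hits <- which(toks$surface %in% cfg$distractor_terms)
    for (h in hits) {
      if (runif(1) >= noise$fp_rate) next
      covered <- nrow(ann) &&
        any(ann$start < toks$end[h] & ann$end > toks$start[h])
      if (covered) next
      ann <- rbind(ann, data.frame(
        id = sprintf("T%d", nrow(ann) + 1L),
        entity_type = cfg$entity_type,
        start = toks$start[h], end = toks$end[h],
        surface = toks$surface[h], stringsAsFactors = FALSE))
    }
  }
  if (nrow(ann)) {
    ann <- ann[order(ann$start), , drop = FALSE]
    ann$id <- sprintf("T%d", seq_len(nrow(ann)))
    rownames(ann) <- NULL
  }
  doc$annotations <- ann
  suppressWarnings(normalize_annotations(doc))
}

# Move one boundary of an annotation by one token, staying token-aligned and
# non-empty; returns NULL when no valid move exists.
shift_boundary <- function(a, toks, text) {
  cov <- which(toks$end > a$start & toks$start < a$end)
  if (!length(cov)) return(NULL)
  first <- cov[1]; last <- cov[length(cov)]
  moves <- list()
  if (first > 1L && !toks$surface[first - 1L] %in% c(".", "!", "?"))
    moves <- c(moves, list(c(first - 1L, last)))          # extend left
  if (last < nrow(toks) && !toks$surface[last + 1L] %in% c(".", "!", "?"))
    moves <- c(moves, list(c(first, last + 1L)))          # extend right
  if (last > first) {
    moves <- c(moves, list(c(first + 1L, last)))          # shrink left
    moves <- c(moves, list(c(first, last - 1L)))          # shrink right
  }
  if (!length(moves)) return(NULL)
  mv <- moves[[sample.int(length(moves), 1L)]]
  a$start <- toks$start[mv[1]]
  a$end <- toks$end[mv[2]]
  a$surface <- substring(text, a$start + 1L, a$end)
  a
}

#' Corpus summary statistics
#'
#' Counts computed after the package's own tokenization: sentences, tokens,
#' unique token surfaces, annotations, and unique (case-sensitive)
#' annotation surfaces.
#'
#' @param docs List of [document()]s.
#' @return A named list of five counts.
#' @export
corpus_stats <- function(docs) {
  n_sent <- 0L; n_tok <- 0L
  tok_surf <- character(0); ann_surf <- character(0); n_ann <- 0L
  for (doc in docs) {
    sents <- tokenize(doc$text)
    n_sent <- n_sent + length(sents)
    for (s in sents) {
      n_tok <- n_tok + nrow(s)
      tok_surf <- c(tok_surf, s$surface)
    }
    n_ann <- n_ann + nrow(doc$annotations)
    ann_surf <- c(ann_surf, doc$annotations$surface)
  }
  list(n_sentences = n_sent, n_tokens = n_tok,
       n_unique_tokens = length(unique(tok_surf)),
       n_annotations = n_ann,
       n_unique_annotations = length(unique(ann_surf)))
}
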