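# Synthetic annotated-corpus generator. Emits corpora in the unified XML
# dialect whose class structure is controllable, so the whole pipeline is
# testable without any external download. Each positive class is signalled
# by a multi-token trigger phrase placed between (or, when the gap is too
# short, just before) the two candidate mentions, so that filter widths in
# the 2-6 range can span it; the inter-entity token distance is drawn from
# a configurable distribution whose default concentrates on 2, 4 and 6
# with a long tail, mirroring the distance profile of real DDI sentences.

#' Default per-class trigger templates
#'
#' Multi-token trigger phrases; every template of a class contains at
#' least one keyword unique to that class, so with zero noise the class
#' of a pair is decidable from its sentence's trigger phrase.
#'
#' @return Named list (class -> list of token vectors).
#' @export
default_templates <- function() {
  list(
    advice = list(
      c("should", "not", "be", "used", "in", "combination", "with"),
      c("caution", "should", "be", "observed", "when", "given", "with")),
    effect = list(
      c("may", "enhance", "the", "sedative", "effect", "of"),
      c("increases", "the", "risk", "of", "bleeding", "with")),
    int = list(
      c("interacts", "with"),
      c("is", "reported", "to", "interact", "with")),
    mechanism = list(
      c("significantly", "decreases", "clearance", "of"),
      c("inhibits", "the", "metabolism", "of"))
  )
}

# Closed filler lexicon, free of every trigger keyword so lexical
# decidability of the class is exact at zero noise.
filler_lexicon <- function() {
  c("the", "a", "of", "in", "patients", "plasma", "concentration",
    "concentrations", "therapy", "treatment", "administration", "dose",
    "doses", "daily", "oral", "renal", "hepatic", "serum", "studies",
    "study", "healthy", "subjects", "volunteers", "single", "repeated",
    "coadministration", "exposure", "response", "baseline", "group")
}

#' Synthetic drug-name lexicon
#'
#' Deterministic pseudo-drug names assembled from pharmacological-looking
#' syllables; a small fraction are two-word names (`"... acid"`) so the
#' multi-word-mention path of entity blinding is exercised.
#'
#' @param size Number of names.
#' @return Character vector of length `size`.
#' @export
drug_lexicon <- function(size = 60) {
  pre <- c("ami", "carbo", "dexa", "eto", "flu", "keto", "levo", "meto",
           "nifedi", "oxy", "pheno", "quina", "rifa", "sulfa", "terbi",
           "vera", "zido", "lora", "cime", "propra")
  suf <- c("pril", "mycin", "zole", "dine", "statin", "barbital", "pine",
           "olol", "micin", "vudine", "floxacin", "mab")
  base <- as.vector(outer(pre, suf, paste0))
  names_out <- base[seq_len(min(size, length(base)))]
  # every sixth entry becomes a two-token name
  k <- seq(6, length(names_out), by = 6)
  names_out[k] <- paste(sub("...$", "", names_out[k]), "acid")
  names_out
}

#' Default inter-entity distance distribution
#'
#' Probability mass over token distances `p2 - p1`: spikes at 2, 4 and 6
#' (the most common distances in real DDI sentences) over a geometric
#' long tail up to 40, giving a mean around 12-14 tokens.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_distance_probs <- function() {
  d <- 2:40
  p <- 0.93^(d - 2)
  names(p) <- d
  p <- 0.45 * p / sum(p)
  p["2"] <- p["2"] + 0.16
  p["3"] <- p["3"] + 0.05
  p["4"] <- p["4"] + 0.10
  p["5"] <- p["5"] + 0.05
  p["6"] <- p["6"] + 0.09
  p["7"] <- p["7"] + 0.10
  p / sum(p)
}

#' Generator configuration
#'
#' Defaults emulate the structure of the real annotated corpus at desk
#' scale: the positive-class mix follows the corpus shares (advice 20.9,
#' effect 41.1, int 5.6, mechanism 32.3 percent of positives), a 40
#' percent non-interacting share keeps class counts usable at small
#' corpus sizes, documents are drawn roughly 3:1 from drugbank-like vs
#' medline-like provenance, and a quarter of sentences carry a third
#' (bystander) mention so the `drug0` and multi-pair paths are always
#' exercised.
#'
#' @param n_documents Number of documents.
#' @param sentences_per_document Sentences in each document.
#' @param class_proportions Named probabilities over [DDI_CLASSES]
#'   (normalized internally; an error if they do not sum to 1 within
#'   tolerance before normalization).
#' @param templates Per-class trigger templates ([default_templates()]).
#' @param distance_probs Named probability vector over inter-entity token
#'   distances.
#' @param lexicon_size Number of synthetic drug names.
#' @param extra_mention_rate Probability that a sentence carries a third
#'   drug mention (a `drug0` bystander, adding two `other` pairs).
#' @param noise_rate Probability in `[0, 1)` that a sentence's trigger
#'   phrase is swapped for another class's trigger while the label is
#'   kept.
#' @param provenance_mix Named probabilities over document provenance.
#' @param discontinuous_rate Probability that a positive sentence's
#'   second mention is made discontinuous (a minimal fixture for the
#'   preprocessing drop filter; 0 by default).
#' @param seed Integer seed.
#' @return An object of class `ddi_generator_config`.
#' @export
generator_config <- function(n_documents = 30,
                             sentences_per_document = 4,
                             class_proportions = c(
                               advice = 0.125, effect = 0.247,
                               int = 0.034, mechanism = 0.194,
                               other = 0.400),
                             templates = default_templates(),
                             distance_probs = default_distance_probs(),
                             lexicon_size = 60,
                             extra_mention_rate = 0.25,
                             noise_rate = 0.05,
                             provenance_mix = c(drugbank = 0.77,
                                                medline = 0.23),
                             discontinuous_rate = 0,
                             seed = 1) {
  stopifnot(n_documents >= 1, sentences_per_document >= 1)
  if (!setequal(names(class_proportions), DDI_CLASSES)) {
    stop("class_proportions must be named over the five DDI classes")
  }
  if (abs(sum(class_proportions) - 1) > 1e-6) {
    stop("class_proportions must sum to 1")
  }
  if (noise_rate < 0 || noise_rate >= 1) stop("noise_rate must be in [0, 1)")
  stopifnot(extra_mention_rate >= 0, extra_mention_rate <= 1,
            discontinuous_rate >= 0, discontinuous_rate < 1,
            abs(sum(distance_probs) - 1) < 1e-6)
  for (cl in names(templates)) {
    if (!all(vapply(templates[[cl]], length, integer(1)) >= 1)) {
      stop("templates for class '", cl, "' must be non-empty")
    }
  }
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 class_proportions = class_proportions[DDI_CLASSES] /
                   sum(class_proportions),
                 templates = templates,
                 distance_probs = distance_probs,
                 lexicon_size = as.integer(lexicon_size),
                 extra_mention_rate = extra_mention_rate,
                 noise_rate = noise_rate,
                 provenance_mix = provenance_mix /
                   sum(provenance_mix),
                 discontinuous_rate = discontinuous_rate,
                 seed = as.integer(seed)),
            class = "ddi_generator_config")
}

# Build one sentence: token vector plus entity records. Entities are
# tracked by token slots, then character offsets are derived when the
# tokens are pasted into the sentence text.
build_sentence_tokens <- function(cl, dist, trigger_class, cfg, lexicon) {
  fillers <- filler_lexicon()
  drugs <- sample(lexicon, 3)
  trigger <- if (trigger_class %in% names(cfg$templates)) {
    tpl <- cfg$templates[[trigger_class]]
    tpl[[sample.int(length(tpl), 1)]]
  } else character(0)
  gap <- dist - 1L  # tokens strictly between the two mentions
  prefix <- sample(fillers, sample(1:4, 1), replace = TRUE)
  if (length(trigger) > 0 && length(trigger) <= gap) {
    between <- c(trigger,
                 sample(fillers, gap - length(trigger), replace = TRUE))
  } else {
    # trigger does not fit between the mentions: put it before them
    prefix <- c(prefix, trigger)
    between <- if (gap > 0) sample(fillers, gap, replace = TRUE) else character(0)
  }
  suffix <- sample(fillers, sample(0:3, 1), replace = TRUE)
  list(prefix = prefix, between = between, suffix = suffix, drugs = drugs)
}

# Token slots -> sentence text + 0-based inclusive character spans for a
# set of (possibly multi-token) mention slots.
tokens_to_text <- function(tokens) {
  starts <- integer(length(tokens))
  pos <- 0L
  for (i in seq_along(tokens)) {
    starts[i] <- pos
    pos <- pos + nchar(tokens[i]) + 1L
  }
  list(text = paste(tokens, collapse = " "), starts = starts,
       ends = starts + nchar(tokens) - 1L)
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic under the config seed (the same configuration always
#' yields a structurally identical corpus and byte-identical XML when
#' written). With zero noise the class of every positive pair is
#' decidable from its sentence's trigger phrase.
#'
#' @param cfg A [generator_config()].
#' @return A [ddi_corpus()].
#' @export
generate_corpus <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  lexicon <- drug_lexicon(cfg$lexicon_size)
  classes <- names(cfg$class_proportions)
  docs <- vector("list", cfg$n_documents)
  for (di in seq_len(cfg$n_documents)) {
    prov <- sample(names(cfg$provenance_mix), 1,
                   prob = cfg$provenance_mix)
    sents <- vector("list", cfg$sentences_per_document)
    for (si in seq_len(cfg$sentences_per_document)) {
      cl <- sample(classes, 1, prob = cfg$class_proportions)
      dist <- as.integer(sample(names(cfg$distance_probs), 1,
                                prob = cfg$distance_probs))
      trigger_class <- cl
      if (cfg$noise_rate > 0 && runif(1) < cfg$noise_rate) {
        trigger_class <- sample(setdiff(DDI_CLASSES, cl), 1)
      }
      parts <- build_sentence_tokens(cl, dist, trigger_class, cfg, lexicon)
      sid <- sprintf("s%d.%d", di, si)
      make_disc <- cl != "other" && cfg$discontinuous_rate > 0 &&
        runif(1) < cfg$discontinuous_rate
      extra <- runif(1) < cfg$extra_mention_rate

      d1 <- strsplit(parts$drugs[1], " ", fixed = TRUE)[[1]]
      tokens <- c(parts$prefix, d1)
      e1_slots <- seq(length(parts$prefix) + 1L, length.out = length(d1))
      tokens <- c(tokens, parts$between)
      if (make_disc) {
        # coordinated noun phrase: "<mod1> or <mod2> blocking agents";
        # the first mention (<mod1> ... blocking agents) is discontinuous
        mods <- sample(c("ganglionic", "peripheral", "central", "adrenergic"), 2)
        start2 <- length(tokens) + 1L
        tokens <- c(tokens, mods[1], "or", mods[2], "blocking", "agents")
        e2_slots <- list(c(start2, start2), c(start2 + 3L, start2 + 4L))
      } else {
        d2 <- strsplit(parts$drugs[2], " ", fixed = TRUE)[[1]]
        start2 <- length(tokens) + 1L
        tokens <- c(tokens, d2)
        e2_slots <- list(c(start2, start2 + length(d2) - 1L))
      }
      e3_slots <- NULL
      if (extra) {
        d3 <- strsplit(parts$drugs[3], " ", fixed = TRUE)[[1]]
        start3 <- length(tokens) + 2L
        tokens <- c(tokens, "and", d3)
        e3_slots <- c(start3, start3 + length(d3) - 1L)
      }
      tokens <- c(tokens, parts$suffix, ".")

      tt <- tokens_to_text(tokens)
      span_of <- function(slots) {
        matrix(c(tt$starts[slots[1]], tt$ends[slots[2]]), ncol = 2,
               dimnames = list(NULL, c("start", "end")))
      }
      text_of <- function(slots) {
        substr(tt$text, tt$starts[slots[1]] + 1, tt$ends[slots[2]] + 1)
      }
      ents <- list(entity_mention(
        paste0(sid, ".e1"),
        text_of(c(e1_slots[1], e1_slots[length(e1_slots)])),
        span_of(c(e1_slots[1], e1_slots[length(e1_slots)]))))
      e2_spans <- do.call(rbind, lapply(e2_slots, span_of))
      ents[[2]] <- entity_mention(
        paste0(sid, ".e2"),
        paste(vapply(e2_slots, text_of, character(1)), collapse = " "),
        e2_spans,
        type = if (make_disc) "group" else "drug")
      if (!is.null(e3_slots)) {
        ents[[3]] <- entity_mention(paste0(sid, ".e3"),
                                    text_of(e3_slots), span_of(e3_slots))
      }
      pairs <- list(candidate_pair(paste0(sid, ".p1"),
                                   paste0(sid, ".e1"), paste0(sid, ".e2"),
                                   cl))
      if (!is.null(e3_slots)) {
        pairs[[2]] <- candidate_pair(paste0(sid, ".p2"),
                                     paste0(sid, ".e1"),
                                     paste0(sid, ".e3"), "other")
        pairs[[3]] <- candidate_pair(paste0(sid, ".p3"),
                                     paste0(sid, ".e2"),
                                     paste0(sid, ".e3"), "other")
      }
      sents[[si]] <- ddi_sentence(sid, tt$text, ents, pairs)
    }
    docs[[di]] <- ddi_document(sprintf("d%d", di), prov, sents)
  }
  ddi_corpus(docs)
}

#' Generate a distance-only classification task
#'
#' A corpus in which the label of every pair depends ONLY on which band
#' the inter-entity token distance falls into: every sentence uses one
#' constant filler token, one shared sentence length and no trigger
#' phrase, so no lexical feature is informative and the relative
#' position of the two mentions is the only signal. This isolates what
#' the position embeddings contribute: a model with `md > 0` can
#' separate the bands while a word-only model (`md = 0`) cannot beat the
#' class prior.
#'
#' @param n_sentences Number of sentences (one labelled pair each).
#' @param bands Named list (class -> `c(min, max)` distance range);
#'   at least two non-overlapping bands.
#' @param sentences_per_document Document granularity.
#' @param filler The single filler token.
#' @param lexicon_size Drug-name lexicon size.
#' @param seed Integer seed.
#' @return A [ddi_corpus()] with provenance `synthetic`.
#' @export
generate_position_task <- function(n_sentences = 400,
                                   bands = list(effect = c(7, 9),
                                                mechanism = c(14, 16)),
                                   sentences_per_document = 5,
                                   filler = "tissue",
                                   lexicon_size = 60,
                                   seed = 1) {
  if (length(bands) < 2) stop("need at least 2 distance bands")
  bad <- setdiff(names(bands), DDI_CLASSES)
  if (length(bad) > 0) stop("bands must be named by DDI classes")
  bm <- do.call(rbind, bands)
  ord <- order(bm[, 1])
  if (any(bm[ord, 1][-1] <= bm[ord, 2][-nrow(bm)])) {
    stop("distance bands overlap")
  }
  set.seed(seed)
  lexicon <- drug_lexicon(lexicon_size)
  lexicon <- lexicon[!grepl(" ", lexicon)]  # single-token names only
  # exactly balanced class assignment (shuffled), so the class prior of
  # the task is 1/#bands up to integer rounding rather than binomial
  class_seq <- sample(rep(names(bands), length.out = n_sentences))
  max_d <- max(bm[, 2])
  # the trailing filler run must always exceed the widest plausible
  # convolution window, otherwise a window spanning drug2 and the final
  # period would leak the distance into the word channel
  n_pre <- 3L; n_post <- 6L
  docs <- list()
  si_all <- 0L
  n_docs <- ceiling(n_sentences / sentences_per_document)
  for (di in seq_len(n_docs)) {
    sents <- list()
    for (sj in seq_len(min(sentences_per_document,
                           n_sentences - si_all))) {
      si_all <- si_all + 1L
      cl <- class_seq[si_all]
      dist <- sample(seq(bands[[cl]][1], bands[[cl]][2]), 1)
      drugs <- sample(lexicon, 2)
      # constant total length: trailing fillers absorb the distance
      tokens <- c(rep(filler, n_pre), drugs[1],
                  rep(filler, dist - 1L), drugs[2],
                  rep(filler, (max_d - dist) + n_post), ".")
      tt <- tokens_to_text(tokens)
      sid <- sprintf("p%d.%d", di, sj)
      p1_slot <- n_pre + 1L
      p2_slot <- p1_slot + dist
      ents <- list(
        entity_mention(paste0(sid, ".e1"), drugs[1],
                       matrix(c(tt$starts[p1_slot], tt$ends[p1_slot]),
                              ncol = 2)),
        entity_mention(paste0(sid, ".e2"), drugs[2],
                       matrix(c(tt$starts[p2_slot], tt$ends[p2_slot]),
                              ncol = 2)))
      pairs <- list(candidate_pair(paste0(sid, ".p1"),
                                   paste0(sid, ".e1"),
                                   paste0(sid, ".e2"), cl))
      sents[[length(sents) + 1L]] <- ddi_sentence(sid, tt$text, ents, pairs)
    }
    docs[[length(docs) + 1L]] <- ddi_document(sprintf("pd%d", di),
                                              "synthetic", sents)
  }
  ddi_corpus(docs)
}
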