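# Turning candidate pairs into blinded, tokenized, fixed-length instances.
#
# The padding token is the literal string "0"; the blinding labels are
# "drug1"/"drug2" for the candidate mentions and "drug0" for bystanders.

PAD_TOKEN <- "0"

#' Tokenizer configuration
#'
#' Cleaning is an ordered list of regular-expression rules applied before
#' (optional) lowercasing and whitespace splitting. The default rule set
#' separates punctuation and special characters into their own tokens
#' while leaving word-internal hyphens, underscores and digits intact, so
#' blinding labels like `drug1` survive as single tokens. Rules are
#' deterministic and order-stable, and the configuration is plain data so
#' it can be audited or swapped.
#'
#' @param lowercase Convert the text to lower case (default `TRUE`).
#' @param rules Data frame with character columns `pattern` and
#'   `replacement`, applied in row order via `gsub(..., perl = TRUE)`.
#' @return An object of class `ddi_tokenizer`.
#' @export
tokenizer_config <- function(lowercase = TRUE, rules = default_token_rules()) {
  stopifnot(is.data.frame(rules),
            all(c("pattern", "replacement") %in% names(rules)))
  structure(list(lowercase = isTRUE(lowercase), rules = rules),
            class = "ddi_tokenizer")
}

#' Default special-character separation rules
#' @return Data frame of `(pattern, replacement)` rules.
#' @export
default_token_rules <- function() {
  data.frame(
    pattern = c(
      # punctuation and special characters become stand-alone tokens
      "([\\(\\)\\[\\]\\{\\},!?;:\"'`%/=+<>&*#~|$^\\\\\u2018\u2019\u201c\u201d])",
      "\\.",
      # collapse runs of whitespace
      "\\s+"
    ),
    replacement = c(" \\1 ", " . ", " "),
    stringsAsFactors = FALSE
  )
}

#' Clean and tokenize text
#'
#' Applies the configured rules, lowercases (by default) and splits on
#' whitespace. The procedure is idempotent: tokenizing already-clean text
#' splits it unchanged.
#'
#' @param text A character scalar.
#' @param cfg A [tokenizer_config()].
#' @return Character vector of tokens.
#' @examples
#' clean_and_tokenize("Drug1 (oral) inhibits drug2.")
#' @export
clean_and_tokenize <- function(text, cfg = tokenizer_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- text
  for (i in seq_len(nrow(cfg$rules))) {
    out <- gsub(cfg$rules$pattern[i], cfg$rules$replacement[i], out,
                perl = TRUE)
  }
  if (cfg$lowercase) out <- tolower(out)
  out <- trimws(out)
  if (!nzchar(out)) return(character(0))
  strsplit(out, " ", fixed = TRUE)[[1]]
}

# ---- entity blinding ------------------------------------------------------

#' Blind the drug mentions of a candidate pair
#'
#' Replaces the full character span of the pair's first mention with
#' `drug1`, of its second with `drug2`, and of every other entity mention
#' in the sentence with `drug0`. Replacement happens on the raw sentence
#' text, before tokenization, so multi-word drug names collapse into
#' single blinded tokens.
#'
#' Overlap resolution: the two pair mentions claim their spans first; the
#' remaining mentions are replaced longest-span-first, and any span
#' overlapping an already-claimed region is skipped. The two pair
#' mentions themselves must be continuous and must not overlap each other
#' (such pairs are dropped upstream by [generate_instances()]).
#'
#' @param sentence A [ddi_sentence()].
#' @param pair A [candidate_pair()] belonging to `sentence`.
#' @return The blinded sentence text (character scalar).
#' @export
blind_entities <- function(sentence, pair) {
  ents <- sentence$entities
  names(ents) <- vapply(ents, function(e) e$id, character(1))
  e1 <- ents[[pair$e1]]; e2 <- ents[[pair$e2]]
  if (is.null(e1) || is.null(e2)) {
    stop("pair '", pair$id, "' references a missing entity id")
  }
  if (is_discontinuous(e1) || is_discontinuous(e2)) {
    stop("pair '", pair$id, "': cannot blind a discontinuous mention")
  }
  s1 <- e1$spans[1, ]; s2 <- e2$spans[1, ]
  if (s1["start"] <= s2["end"] && s2["start"] <= s1["end"]) {
    stop("pair '", pair$id, "': the two mentions overlap")
  }
  repl <- data.frame(start = c(s1["start"], s2["start"]),
                     end = c(s1["end"], s2["end"]),
                     label = c("drug1", "drug2"))
  bystanders <- ents[setdiff(names(ents), c(pair$e1, pair$e2))]
  if (length(bystanders) > 0) {
    spans <- do.call(rbind, lapply(bystanders, function(e) e$spans))
    spans <- spans[order(spans[, "end"] - spans[, "start"],
                         decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(spans))) {
      st <- spans[i, "start"]; en <- spans[i, "end"]
      overlaps <- any(st <= repl$end & repl$start <= en)
      if (!overlaps) {
        repl <- rbind(repl, data.frame(start = st, end = en,
                                       label = "drug0"))
      }
    }
  }
  # splice right-to-left so earlier offsets stay valid
  repl <- repl[order(repl$start, decreasing = TRUE), , drop = FALSE]
  text <- sentence$text
  for (i in seq_len(nrow(repl))) {
    before <- if (repl$start[i] > 0) substr(text, 1, repl$start[i]) else ""
    after <- substr(text, repl$end[i] + 2, nchar(text))
    text <- paste0(before, repl$label[i], after)
  }
  text
}

# ---- padding / truncation -------------------------------------------------

#' Pad (or truncate) a token sequence to a fixed length
#'
#' Shorter sequences are extended with the auxiliary padding token `"0"`.
#' Sequences longer than `n` are truncated from the tail; if entity
#' positions are supplied and tail truncation would lose either blinded
#' entity, the window is centred on the two entities instead.
#'
#' @param tokens Character vector of tokens.
#' @param n Target length (`n >= 1`).
#' @param p1,p2 Optional 1-based token positions of `drug1` and `drug2`.
#' @return If `p1`/`p2` are `NULL`, the padded character vector. Otherwise
#'   a list with `tokens`, adjusted `p1`, `p2`, `true_length` (pre-padding
#'   token count inside the window) and a `truncated` flag. If both
#'   entities cannot fit in one window of length `n`, `NULL` is returned.
#' @export
pad_to_length <- function(tokens, n, p1 = NULL, p2 = NULL) {
  stopifnot(n >= 1)
  len <- length(tokens)
  simple <- is.null(p1) || is.null(p2)
  if (len > n) {
    if (simple) {
      tokens <- tokens[seq_len(n)]
    } else {
      if (p2 - p1 + 1 > n) return(NULL)  # entities cannot share a window
      start <- 1L
      if (p2 > n) {  # centre the window on the two entities
        start <- max(1L, min(floor((p1 + p2) / 2) - floor(n / 2) + 1L,
                             len - n + 1L))
        if (start > p1) start <- p1
        if (start + n - 1L < p2) start <- p2 - n + 1L
      }
      tokens <- tokens[start:(start + n - 1L)]
      p1 <- p1 - start + 1L
      p2 <- p2 - start + 1L
    }
    true_len <- n
    truncated <- TRUE
  } else {
    tokens <- c(tokens, rep(PAD_TOKEN, n - len))
    true_len <- len
    truncated <- FALSE
  }
  if (simple) return(tokens)
  list(tokens = tokens, p1 = as.integer(p1), p2 = as.integer(p2),
       true_length = as.integer(true_len), truncated = truncated)
}

# ---- instance generation --------------------------------------------------

new_instance <- function(tokens, p1, p2, label, sentence_id, pair_id,
                         provenance, true_length) {
  structure(list(tokens = tokens, p1 = p1, p2 = p2,
                 label = label, sentence_id = sentence_id,
                 pair_id = pair_id, provenance = provenance,
                 true_length = true_length),
            class = "ddi_instance")
}

#' Generate blinded instances from one document
#'
#' Produces exactly one instance per candidate pair, except pairs where
#' either mention is discontinuous (removed, mirroring the corpus-level
#' filter that discards the small fraction of such pairs), pairs whose
#' two mentions overlap in the text, and pairs whose blinded tokens
#' cannot be resolved to exactly one `drug1` and one `drug2`. Filtering
#' is silent but counted.
#'
#' @param doc A [ddi_document()].
#' @param cfg A [tokenizer_config()].
#' @param n Fixed instance length (default 128, the corpus maximum the
#'   model was designed around).
#' @param drop_identical_surface Also drop pairs whose two mentions share
#'   the same surface text (off by default; kept as a comparison switch).
#' @return List with `instances` (list of `ddi_instance`) and `dropped`,
#'   a named integer vector of drop counters
#'   (`discontinuous`, `overlap`, `identical_surface`, `ambiguous`,
#'   `window`) plus a `truncated` counter.
#' @export
generate_instances <- function(doc, cfg = tokenizer_config(), n = 128,
                               drop_identical_surface = FALSE) {
  dropped <- c(discontinuous = 0L, overlap = 0L, identical_surface = 0L,
               ambiguous = 0L, window = 0L)
  truncated <- 0L
  out <- list()
  for (s in doc$sentences) {
    ents <- s$entities
    names(ents) <- vapply(ents, function(e) e$id, character(1))
    for (p in s$pairs) {
      e1 <- ents[[p$e1]]; e2 <- ents[[p$e2]]
      if (is_discontinuous(e1) || is_discontinuous(e2)) {
        dropped["discontinuous"] <- dropped["discontinuous"] + 1L
        next
      }
      if (drop_identical_surface && identical(e1$text, e2$text)) {
        dropped["identical_surface"] <- dropped["identical_surface"] + 1L
        next
      }
      blinded <- tryCatch(blind_entities(s, p), error = function(e) NULL)
      if (is.null(blinded)) {
        dropped["overlap"] <- dropped["overlap"] + 1L
        next
      }
      tokens <- clean_and_tokenize(blinded, cfg)
      p1 <- which(tokens == "drug1")
      p2 <- which(tokens == "drug2")
      if (length(p1) != 1L || length(p2) != 1L || p1 >= p2) {
        dropped["ambiguous"] <- dropped["ambiguous"] + 1L
        next
      }
      fit <- pad_to_length(tokens, n, p1, p2)
      if (is.null(fit)) {
        dropped["window"] <- dropped["window"] + 1L
        next
      }
      if (fit$truncated) truncated <- truncated + 1L
      out[[length(out) + 1L]] <- new_instance(
        fit$tokens, fit$p1, fit$p2, p$label, s$id, p$id,
        doc$provenance, fit$true_length)
    }
  }
  list(instances = out, dropped = dropped, truncated = truncated)
}

#' Preprocess a whole corpus into blinded instances
#'
#' Runs [generate_instances()] over every document and aggregates the
#' drop counters.
#'
#' @inheritParams generate_instances
#' @param docs A [ddi_corpus()].
#' @return An object of class `ddi_instances`: list with `instances`,
#'   `dropped` and `truncated`.
#' @export
preprocess_corpus <- function(docs, cfg = tokenizer_config(), n = 128,
                              drop_identical_surface = FALSE) {
  per_doc <- lapply(docs, generate_instances, cfg = cfg, n = n,
                    drop_identical_surface = drop_identical_surface)
  structure(list(
    instances = do.call(c, c(lapply(per_doc, `[[`, "instances"),
                             list(list()))),
    dropped = Reduce(`+`, lapply(per_doc, `[[`, "dropped"),
                     accumulate = FALSE,
                     init = c(discontinuous = 0L, overlap = 0L,
                              identical_surface = 0L, ambiguous = 0L,
                              window = 0L)),
    truncated = sum(vapply(per_doc, `[[`, integer(1), "truncated"))),
    class = "ddi_instances")
}

#' @export
print.ddi_instances <- function(x, ...) {
  cat("ddi_instances:", length(x$instances), "instances;",
      sum(x$dropped), "dropped (",
      paste(names(x$dropped), x$dropped, sep = "=", collapse = ", "),
      ");", x$truncated, "truncated\n")
  invisible(x)
}

#' Instance metadata as a data frame
#' @param x A `ddi_instances` object or plain list of instances.
#' @return Data frame with one row per instance (without the tokens).
#' @export
instances_meta <- function(x) {
  inst <- if (inherits(x, "ddi_instances")) x$instances else x
  data.frame(
    pair_id = vapply(inst, `[[`, character(1), "pair_id"),
    sentence_id = vapply(inst, `[[`, character(1), "sentence_id"),
    provenance = vapply(inst, `[[`, character(1), "provenance"),
    label = vapply(inst, `[[`, character(1), "label"),
    p1 = vapply(inst, `[[`, integer(1), "p1"),
    p2 = vapply(inst, `[[`, integer(1), "p2"),
    true_length = vapply(inst, `[[`, integer(1), "true_length"),
    stringsAsFactors = FALSE)
}
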