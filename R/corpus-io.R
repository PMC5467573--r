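# Reading and writing annotated corpora in the unified PPI/DDI XML dialect.
#
# The on-disk layout is <corpus><document><sentence><entity/><pair/>...
# Character offsets are 0-based inclusive "start-end" ranges; a
# discontinuous mention joins several ranges with ";".

#' Create an entity mention
#'
#' @param id Mention identifier, unique within its sentence.
#' @param text Surface string of the mention.
#' @param spans Two-column integer matrix of `(start, end)` character
#'   ranges, 0-based inclusive, in reading order. A mention with more than
#'   one range is *discontinuous* (e.g. "ganglionic ... blocking drugs"
#'   inside a coordinated noun phrase).
#' @param type Entity type (`drug`, `brand`, `group`, `drug_n`, ...).
#'   Unknown types are accepted and passed through; entity blinding erases
#'   them anyway.
#' @return An object of class `ddi_entity`.
#' @export
entity_mention <- function(id, text, spans, type = "drug") {
  spans <- matrix(as.integer(spans), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(spans) < 1) stop("entity '", id, "': spans must be non-empty")
  if (any(spans[, "start"] > spans[, "end"])) {
    stop("entity '", id, "': each span must have start <= end")
  }
  structure(list(id = as.character(id), text = as.character(text),
                 spans = spans, type = as.character(type)),
            class = "ddi_entity")
}

#' Is an entity mention discontinuous?
#' @param entity A `ddi_entity`.
#' @return Logical scalar.
#' @export
is_discontinuous <- function(entity) nrow(entity$spans) > 1L

#' Create a candidate pair
#'
#' One ordered pair of drug mentions in one sentence: the unit that the
#' classifier labels. `other` means the pair is annotated as
#' non-interacting.
#'
#' @param id Pair identifier.
#' @param e1,e2 Entity ids of the two mentions; `e1` must start at or
#'   before `e2` in the sentence.
#' @param label One of [DDI_CLASSES].
#' @return An object of class `ddi_pair`.
#' @export
candidate_pair <- function(id, e1, e2, label) {
  structure(list(id = as.character(id), e1 = as.character(e1),
                 e2 = as.character(e2),
                 label = as.character(as_ddi_label(label))),
            class = "ddi_pair")
}

#' Create a sentence
#' @param id Sentence identifier.
#' @param text Sentence text.
#' @param entities List of [entity_mention()] objects.
#' @param pairs List of [candidate_pair()] objects.
#' @return An object of class `ddi_sentence`.
#' @export
ddi_sentence <- function(id, text, entities = list(), pairs = list()) {
  structure(list(id = as.character(id), text = as.character(text),
                 entities = entities, pairs = pairs),
            class = "ddi_sentence")
}

#' Create a document
#' @param id Document identifier.
#' @param provenance Subcorpus tag, one of [DDI_PROVENANCES]; drives the
#'   per-subcorpus evaluation breakdown.
#' @param sentences List of [ddi_sentence()] objects.
#' @return An object of class `ddi_document`.
#' @export
ddi_document <- function(id, provenance, sentences = list()) {
  provenance <- match.arg(provenance, DDI_PROVENANCES)
  structure(list(id = as.character(id), provenance = provenance,
                 sentences = sentences),
            class = "ddi_document")
}

#' Create a corpus
#' @param documents List of [ddi_document()] objects.
#' @return An object of class `ddi_corpus` (a list of documents).
#' @export
ddi_corpus <- function(documents = list()) {
  structure(documents, class = "ddi_corpus")
}

# ---- validation -----------------------------------------------------------

validate_sentence <- function(sent, doc_id = "?") {
  where <- sprintf("document '%s', sentence '%s'", doc_id, sent$id)
  eids <- vapply(sent$entities, function(e) e$id, character(1))
  if (anyDuplicated(eids)) {
    stop(where, ": duplicated entity ids within sentence")
  }
  nchr <- nchar(sent$text)
  for (e in sent$entities) {
    if (any(e$spans[, "start"] < 0) || any(e$spans[, "end"] >= nchr)) {
      stop(where, ": entity '", e$id, "' span outside sentence text")
    }
  }
  ent_start <- setNames(
    vapply(sent$entities, function(e) e$spans[1, "start"], integer(1)), eids)
  for (p in sent$pairs) {
    if (!(p$e1 %in% eids) || !(p$e2 %in% eids)) {
      stop(where, ": pair '", p$id, "' references a missing entity id")
    }
    if (ent_start[[p$e1]] > ent_start[[p$e2]]) {
      stop(where, ": pair '", p$id, "' has e1 starting after e2")
    }
  }
  invisible(TRUE)
}

validate_document <- function(doc) {
  if (!doc$provenance %in% DDI_PROVENANCES) {
    stop("document '", doc$id, "': provenance must be one of ",
         paste(DDI_PROVENANCES, collapse = ", "))
  }
  for (s in doc$sentences) validate_sentence(s, doc$id)
  invisible(TRUE)
}

# ---- reading --------------------------------------------------------------

parse_char_offset <- function(offset, id = "?") {
  parts <- strsplit(offset, ";", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    se <- strsplit(trimws(p), "-", fixed = TRUE)[[1]]
    if (length(se) != 2 || anyNA(suppressWarnings(as.integer(se)))) {
      stop("entity '", id, "': malformed charOffset '", offset, "'")
    }
    as.integer(se)
  })
  matrix(unlist(rows), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("start", "end")))
}

infer_provenance <- function(attr_origin, doc_id) {
  if (!is.na(attr_origin) && nzchar(attr_origin)) {
    ori <- tolower(attr_origin)
    if (ori %in% DDI_PROVENANCES) return(ori)
    stop("document '", doc_id, "': unknown origin '", attr_origin, "'")
  }
  if (grepl("drugbank", doc_id, ignore.case = TRUE)) return("drugbank")
  if (grepl("medline", doc_id, ignore.case = TRUE)) return("medline")
  stop("document '", doc_id, "': provenance cannot be determined; set an ",
       "'origin' attribute (drugbank / medline / synthetic) or use a ",
       "DDI-DrugBank / DDI-MedLine style id")
}

parse_sentence_node <- function(snode, doc_id) {
  sid <- xml2::xml_attr(snode, "id")
  text <- xml2::xml_attr(snode, "text")
  entities <- lapply(xml2::xml_find_all(snode, "./entity"), function(en) {
    eid <- xml2::xml_attr(en, "id")
    entity_mention(
      id = eid,
      text = xml2::xml_attr(en, "text"),
      spans = parse_char_offset(xml2::xml_attr(en, "charOffset"), eid),
      type = xml2::xml_attr(en, "type"))
  })
  eids <- vapply(entities, function(e) e$id, character(1))
  pairs <- lapply(xml2::xml_find_all(snode, "./pair"), function(pn) {
    pid <- xml2::xml_attr(pn, "id")
    e1 <- xml2::xml_attr(pn, "e1")
    e2 <- xml2::xml_attr(pn, "e2")
    if (!(e1 %in% eids) || !(e2 %in% eids)) {
      stop("sentence '", sid, "': pair '", pid,
           "' references a missing entity id")
    }
    ddi <- tolower(xml2::xml_attr(pn, "ddi"))
    if (identical(ddi, "true")) {
      type <- xml2::xml_attr(pn, "type")
      if (is.na(type) || !(type %in% DDI_POSITIVE_CLASSES)) {
        stop("sentence '", sid, "': pair '", pid,
             "' has ddi=\"true\" with missing/unknown type")
      }
      label <- type
    } else if (identical(ddi, "false")) {
      label <- "other"
    } else {
      stop("sentence '", sid, "': pair '", pid, "' has invalid ddi attribute")
    }
    candidate_pair(pid, e1, e2, label)
  })
  ddi_sentence(sid, text, entities, pairs)
}

#' Read a corpus from unified-format XML
#'
#' Parses documents, sentences, entity mentions (splitting multi-range
#' `charOffset` attributes on `";"` into discontinuous spans) and candidate
#' pairs. Pairs with `ddi="false"` are labelled `other`; pairs with
#' `ddi="true"` take their `type` attribute as label. Document provenance
#' is read from the `origin` attribute, falling back to the
#' DDI-DrugBank / DDI-MedLine document-id convention.
#'
#' @param path Path to an XML file whose root is `<corpus>` (or a single
#'   `<document>`).
#' @return A [ddi_corpus()].
#' @seealso [write_corpus()], [corpus_stats()]
#' @export
read_corpus <- function(path) {
  xml <- xml2::read_xml(path)
  root <- xml2::xml_name(xml)
  doc_nodes <- if (root == "document") list(xml) else {
    xml2::xml_find_all(xml, "./document")
  }
  docs <- lapply(doc_nodes, function(dn) {
    did <- xml2::xml_attr(dn, "id")
    prov <- infer_provenance(xml2::xml_attr(dn, "origin"), did)
    sents <- lapply(xml2::xml_find_all(dn, "./sentence"),
                    parse_sentence_node, doc_id = did)
    ddi_document(did, prov, sents)
  })
  corpus <- ddi_corpus(docs)
  for (d in corpus) validate_document(d)
  corpus
}

# ---- writing --------------------------------------------------------------

format_char_offset <- function(spans) {
  paste(paste0(spans[, "start"], "-", spans[, "end"]), collapse = ";")
}

#' Write a corpus as unified-format XML
#'
#' The emitted file round-trips: `read_corpus(write_corpus(docs, path))`
#' is structurally identical to `docs`. All type invariants are checked
#' first and a violation aborts the write with the violated invariant
#' named.
#'
#' @param docs A [ddi_corpus()] or plain list of [ddi_document()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(docs, path) {
  for (d in docs) validate_document(d)
  root <- xml2::xml_new_root("corpus")
  for (d in docs) {
    dn <- xml2::xml_add_child(root, "document", id = d$id,
                              origin = d$provenance)
    for (s in d$sentences) {
      sn <- xml2::xml_add_child(dn, "sentence", id = s$id, text = s$text)
      for (e in s$entities) {
        xml2::xml_add_child(sn, "entity", id = e$id,
                            charOffset = format_char_offset(e$spans),
                            type = e$type, text = e$text)
      }
      for (p in s$pairs) {
        if (p$label == "other") {
          xml2::xml_add_child(sn, "pair", id = p$id, e1 = p$e1, e2 = p$e2,
                              ddi = "false")
        } else {
          xml2::xml_add_child(sn, "pair", id = p$id, e1 = p$e1, e2 = p$e2,
                              ddi = "true", type = p$label)
        }
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

# ---- summaries ------------------------------------------------------------

#' Summary statistics of a corpus
#'
#' Class distribution of candidate pairs (per subcorpus and total, the
#' shape of the corpus description tables) plus the number of
#' discontinuous entity mentions.
#'
#' @param docs A [ddi_corpus()].
#' @return A list with elements `class_counts` (classes x provenance
#'   matrix), `n_documents`, `n_sentences`, `n_entities`, `n_pairs`,
#'   `n_discontinuous_mentions`, `n_pairs_with_discontinuous`.
#' @export
corpus_stats <- function(docs) {
  provs <- vapply(docs, function(d) d$provenance, character(1))
  counts <- matrix(0L, nrow = length(DDI_CLASSES),
                   ncol = length(DDI_PROVENANCES),
                   dimnames = list(DDI_CLASSES, DDI_PROVENANCES))
  n_sent <- 0L; n_ent <- 0L; n_disc <- 0L; n_pair_disc <- 0L
  for (d in docs) {
    for (s in d$sentences) {
      n_sent <- n_sent + 1L
      n_ent <- n_ent + length(s$entities)
      disc <- vapply(s$entities, is_discontinuous, logical(1))
      names(disc) <- vapply(s$entities, function(e) e$id, character(1))
      n_disc <- n_disc + sum(disc)
      for (p in s$pairs) {
        counts[p$label, d$provenance] <- counts[p$label, d$provenance] + 1L
        if (isTRUE(disc[[p$e1]]) || isTRUE(disc[[p$e2]])) {
          n_pair_disc <- n_pair_disc + 1L
        }
      }
    }
  }
  structure(list(class_counts = counts,
                 n_documents = length(docs),
                 n_sentences = n_sent,
                 n_entities = n_ent,
                 n_pairs = sum(counts),
                 n_discontinuous_mentions = n_disc,
                 n_pairs_with_discontinuous = n_pair_disc),
            class = "ddi_corpus_stats")
}

#' @export
print.ddi_corpus_stats <- function(x, ...) {
  cat("DDI corpus:", x$n_documents, "documents,", x$n_sentences,
      "sentences,", x$n_entities, "entities,", x$n_pairs, "pairs\n")
  cat("Discontinuous mentions:", x$n_discontinuous_mentions,
      sprintf("(%d pairs involve one)\n", x$n_pairs_with_discontinuous))
  tab <- cbind(x$class_counts, total = rowSums(x$class_counts))
  print(tab[, colSums(tab) > 0 | colnames(tab) == "total", drop = FALSE])
  invisible(x)
}
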