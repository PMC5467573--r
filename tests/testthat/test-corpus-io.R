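# Reading and writing the unified annotated-corpus XML dialect.

sample_corpus_xml <- function() {
  paste0(
    '<corpus>',
    '<document id="DDI-DrugBank.d1">',
    '<sentence id="d1.s1" text="Aspirin blocks heparin and warfarin here.">',
    '<entity id="d1.s1.e1" charOffset="0-6" type="drug" text="Aspirin"/>',
    '<entity id="d1.s1.e2" charOffset="15-21" type="drug" text="heparin"/>',
    '<entity id="d1.s1.e3" charOffset="27-34" type="drug" text="warfarin"/>',
    '<pair id="d1.s1.p1" e1="d1.s1.e1" e2="d1.s1.e2" ddi="true" type="mechanism"/>',
    '<pair id="d1.s1.p2" e1="d1.s1.e1" e2="d1.s1.e3" ddi="false"/>',
    '</sentence>',
    '</document>',
    '<document id="DDI-MedLine.d2" origin="medline">',
    '<sentence id="d2.s1" text="ganglionic or peripheral adrenergic blocking drugs">',
    '<entity id="d2.s1.e1" charOffset="0-9;25-49" type="group"',
    ' text="ganglionic adrenergic blocking drugs"/>',
    '<entity id="d2.s1.e2" charOffset="14-49" type="group"',
    ' text="peripheral adrenergic blocking drugs"/>',
    '<pair id="d2.s1.p1" e1="d2.s1.e1" e2="d2.s1.e2" ddi="false"/>',
    '</sentence>',
    '</document>',
    '</corpus>')
}

write_tmp_xml <- function(text) {
  path <- withr::local_tempfile(fileext = ".xml",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

test_that("read_corpus materializes documents, entities, pairs and labels", {
  docs <- read_corpus(write_tmp_xml(sample_corpus_xml()))
  expect_length(docs, 2)
  s <- docs[[1]]$sentences[[1]]
  expect_length(s$entities, 3)
  expect_length(s$pairs, 2)
  expect_equal(s$pairs[[1]]$label, "mechanism")
  expect_equal(s$pairs[[2]]$label, "other")
  # provenance from id convention and from the origin attribute
  expect_equal(docs[[1]]$provenance, "drugbank")
  expect_equal(docs[[2]]$provenance, "medline")
})

test_that("multi-range charOffset becomes a discontinuous mention", {
  docs <- read_corpus(write_tmp_xml(sample_corpus_xml()))
  e <- docs[[2]]$sentences[[1]]$entities[[1]]
  expect_equal(nrow(e$spans), 2)
  expect_equal(unname(e$spans[1, ]), c(0L, 9L))
  expect_equal(unname(e$spans[2, ]), c(25L, 49L))
  expect_true(is_discontinuous(e))
  expect_false(is_discontinuous(docs[[1]]$sentences[[1]]$entities[[1]]))
})

test_that("empty corpus file yields an empty corpus without error", {
  docs <- read_corpus(write_tmp_xml("<corpus></corpus>"))
  expect_length(docs, 0)
})

test_that("reader rejects malformed or inconsistent files", {
  expect_error(read_corpus(write_tmp_xml("<corpus><document id=")),
               class = "error")
  bad_pair <- sub('e2="d1.s1.e2"', 'e2="d1.s1.e99"', sample_corpus_xml())
  expect_error(read_corpus(write_tmp_xml(bad_pair)), "missing entity")
  no_type <- sub(' type="mechanism"', "", sample_corpus_xml())
  expect_error(read_corpus(write_tmp_xml(no_type)), "missing/unknown type")
})

test_that("round-trip preserves generator corpora across seeds", {
  for (seed in c(1, 12, 303)) {
    cfg <- generator_config(n_documents = 6, seed = seed,
                            discontinuous_rate = 0.1)
    docs <- generate_corpus(cfg)
    path <- withr::local_tempfile(fileext = ".xml")
    write_corpus(docs, path)
    back <- read_corpus(path)
    expect_equal(back, docs, ignore_attr = FALSE)
    # count conservation against the raw XML
    n_pair_nodes <- length(xml2::xml_find_all(xml2::read_xml(path),
                                              "//pair"))
    expect_equal(corpus_stats(back)$n_pairs, n_pair_nodes)
  }
})

test_that("provenance and mixed subcorpora survive a round-trip", {
  docs <- ddi_corpus(list(
    ddi_document("a1", "drugbank", list(ddi_sentence("a1.s1", "x y."))),
    ddi_document("b1", "medline", list(ddi_sentence("b1.s1", "x y.")))))
  path <- withr::local_tempfile(fileext = ".xml")
  write_corpus(docs, path)
  back <- read_corpus(path)
  expect_equal(vapply(back, `[[`, character(1), "provenance"),
               c("drugbank", "medline"))
})

test_that("write_corpus refuses invariant violations, naming them", {
  doc <- ddi_document("d1", "synthetic", list(ddi_sentence(
    "s1", "alpha beta.",
    entities = list(entity_mention("e1", "alpha", matrix(c(0, 4), 1))),
    pairs = list(candidate_pair("p1", "e1", "eX", "other")))))
  path <- withr::local_tempfile(fileext = ".xml")
  expect_error(write_corpus(ddi_corpus(list(doc)), path),
               "missing entity id")
  bad_span <- ddi_document("d2", "synthetic", list(ddi_sentence(
    "s2", "ab.",
    entities = list(entity_mention("e1", "abcdef", matrix(c(0, 5), 1))))))
  expect_error(write_corpus(ddi_corpus(list(bad_span)), path),
               "span outside sentence")
})

test_that("corpus_stats reports class distribution and discontinuity", {
  cfg <- generator_config(n_documents = 12, seed = 4,
                          discontinuous_rate = 0.3)
  docs <- generate_corpus(cfg)
  st <- corpus_stats(docs)
  expect_equal(sum(st$class_counts), st$n_pairs)
  expect_gt(st$n_discontinuous_mentions, 0)
  expect_gte(st$n_pairs_with_discontinuous, st$n_discontinuous_mentions)
  expect_output(print(st), "Discontinuous mentions")
})

test_that("cli corpus-stats and preprocess commands run end to end", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_corpus(generate_corpus(generator_config(n_documents = 4)), path)
  out <- capture.output(st <- cli_main(c("corpus-stats", path)))
  expect_true(any(grepl("DDI corpus", out)))
  jsonl <- withr::local_tempfile(fileext = ".jsonl")
  suppressMessages(cli_main(c("preprocess", path, "--out", jsonl)))
  lines <- readLines(jsonl)
  expect_equal(length(lines), corpus_stats(read_corpus(path))$n_pairs)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("tokens", "p1", "p2", "label") %in% names(rec)))
})
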