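# Shared-task scoring: confusion counting, metric arithmetic, chi-square
# model comparison, per-corpus breakdown and distance statistics.

test_that("confusion counting follows the shared-task conventions", {
  # single hit
  cc <- count_confusions("effect", "effect")
  expect_equal(cc$tp[cc$class == "effect"], 1)
  expect_equal(sum(cc$tp) + sum(cc$fp) + sum(cc$fn), 1)
  # positive-to-positive confusion counts as FN of gold AND FP of pred
  cc2 <- count_confusions("mechanism", "effect")
  expect_equal(cc2$fn[cc2$class == "mechanism"], 1)
  expect_equal(cc2$fp[cc2$class == "effect"], 1)
  # true negatives are not counted anywhere
  cc3 <- count_confusions("other", "other")
  expect_true(all(cc3[, c("tp", "fp", "fn", "total")] == 0))
  expect_error(count_confusions(c("other", "effect"), "other"),
               "same length")
  expect_error(count_confusions("other", "banana"), "unknown DDI class")
})

test_that("count identities hold on random label vectors", {
  set.seed(42)
  for (rep in 1:10) {
    gold <- sample(DDI_CLASSES, 200, replace = TRUE)
    pred <- sample(DDI_CLASSES, 200, replace = TRUE)
    cc <- count_confusions(gold, pred)
    expect_equal(cc$tp + cc$fn, cc$total)
    expect_equal(sum(cc$total), sum(gold != "other"))
    rep_tab <- metrics_report(gold, pred)
    ov <- rep_tab[rep_tab$class == "Overall", ]
    expect_equal(ov$tp, sum(cc$tp))
    expect_equal(ov$fp, sum(cc$fp))
    expect_equal(ov$fn, sum(cc$fn))
  }
})

test_that("metric arithmetic reproduces every reference score triple", {
  for (card in reference_scorecards()) {
    per <- card[card$class != "Overall", ]
    got <- precision_recall_f1(per$tp, per$fp, per$fn)
    expect_equal(got$P, per$P, tolerance = 0.011)
    expect_equal(got$R, per$R, tolerance = 0.011)
    expect_equal(got$F1, per$F1, tolerance = 0.011)
    ov <- card[card$class == "Overall", ]
    cc <- structure(data.frame(class = per$class, tp = per$tp,
                               fp = per$fp, fn = per$fn,
                               total = per$total),
                    class = c("ddi_confusion", "data.frame"))
    mo <- micro_overall(cc)
    expect_equal(unname(mo), c(ov$P, ov$R, ov$F1), tolerance = 0.011)
  }
})

test_that("zero-denominator conventions give all-zero scores", {
  expect_equal(unname(precision_recall_f1(0, 1, 2)), c(0, 0, 0))
  expect_equal(unname(precision_recall_f1(0, 0, 0)), c(0, 0, 0))
})

test_that("chi-square matches the brute-force oracle on random tables", {
  set.seed(7)
  for (rep in 1:25) {
    gold <- sample(DDI_CLASSES, 120, replace = TRUE)
    pa <- ifelse(runif(120) < 0.6, gold,
                 sample(DDI_CLASSES, 120, replace = TRUE))
    pb <- ifelse(runif(120) < 0.4, gold,
                 sample(DDI_CLASSES, 120, replace = TRUE))
    cmp <- chi_square_compare(gold, pa, pb)
    expect_equal(cmp$chi_square, chisq_oracle(cmp$table),
                 tolerance = 1e-10)
    expect_equal(cmp$p_value,
                 stats::pchisq(cmp$chi_square, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_identical(cmp$significant,
                     cmp$chi_square > 3.84 && cmp$p_value < 0.05)
  }
})

test_that("chi-square worked example: [[60,40],[40,60]] gives 8.0", {
  gold <- rep("effect", 100)
  pa <- rep(c("effect", "other"), c(60, 40))
  pb <- rep(c("effect", "other"), c(40, 60))
  cmp <- chi_square_compare(gold, pa, pb)
  expect_equal(unname(cmp$table), matrix(c(60, 40, 40, 60), 2,
                                         byrow = TRUE))
  expect_equal(cmp$chi_square, 8.0)
  expect_equal(cmp$p_value, 0.00468, tolerance = 1e-3)
  expect_true(cmp$significant)
})

test_that("identical prediction sets give chi-square 0, not significant", {
  gold <- sample(DDI_CLASSES, 50, replace = TRUE)
  pred <- sample(DDI_CLASSES, 50, replace = TRUE)
  cmp <- chi_square_compare(gold, pred, pred)
  expect_equal(cmp$chi_square, 0)
  expect_false(cmp$significant)
  expect_error(chi_square_compare(gold, pred[-1], pred), "same gold")
})

test_that("per-corpus reports partition and add up to the global counts", {
  set.seed(3)
  prov <- sample(c("drugbank", "medline"), 150, replace = TRUE)
  gold <- sample(DDI_CLASSES, 150, replace = TRUE)
  pred <- sample(DDI_CLASSES, 150, replace = TRUE)
  rep_all <- per_corpus_report(prov, gold, pred)
  expect_setequal(names(rep_all$by_corpus), c("drugbank", "medline"))
  for (col in c("tp", "fp", "fn", "total")) {
    expect_equal(rep_all$by_corpus$drugbank[[col]] +
                   rep_all$by_corpus$medline[[col]],
                 rep_all$overall[[col]])
  }
  # a single-provenance corpus yields a single sub-report
  rep_db <- per_corpus_report(rep("drugbank", 10), gold[1:10], pred[1:10])
  expect_named(rep_db$by_corpus, "drugbank")
})

test_that("entity distance statistics: histogram, mean, modes", {
  inst <- list(toy_instance(c("drug1", "a", "drug2", "0"), 1, 3, "effect"),
               toy_instance(c("drug1", "a", "drug2", "0"), 1, 3, "effect"),
               toy_instance(c("drug1", "a", "b", "c", "drug2"), 1, 5,
                            "effect"))
  st <- entity_distance_stats(inst)
  expect_equal(st$modes, 2L)
  expect_equal(st$mean, mean(c(2, 2, 4)))
  one <- entity_distance_stats(inst[3])
  expect_equal(one$mean, 4)
})

test_that("prediction files round-trip through the tab-separated format", {
  pp <- preprocess_corpus(generate_corpus(generator_config(
    n_documents = 5, seed = 6)))
  meta <- instances_meta(pp)
  pred <- sample(DDI_CLASSES, nrow(meta), replace = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(meta, pred, path)
  back <- read_predictions(path)
  expect_equal(back$predicted, pred)
  expect_equal(back$gold, meta$label)
  expect_equal(back$provenance, meta$provenance)
})
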