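# Shared fixtures: a hand-built mechanism sentence with three mentions,
# frozen reference score tables, tiny handcrafted instances for the CNN
# unit tests, and a central-difference gradient oracle.

# "Amprenavir significantly decreases clearance of rifabutin and
# 25-O-desacetylrifabutin" with exact 0-based inclusive offsets.
amprenavir_sentence <- function() {
  txt <- paste("Amprenavir significantly decreases clearance of",
               "rifabutin and 25-O-desacetylrifabutin")
  ddi_sentence(
    "amp.s1", txt,
    entities = list(
      entity_mention("amp.e1", "Amprenavir", matrix(c(0, 9), 1)),
      entity_mention("amp.e2", "rifabutin", matrix(c(48, 56), 1)),
      entity_mention("amp.e3", "25-O-desacetylrifabutin",
                     matrix(c(62, 84), 1))),
    pairs = list(
      candidate_pair("amp.p1", "amp.e1", "amp.e2", "mechanism"),
      candidate_pair("amp.p2", "amp.e1", "amp.e3", "mechanism"),
      candidate_pair("amp.p3", "amp.e2", "amp.e3", "mechanism")))
}

# Frozen reference score tables: per-class TP/FP/FN/total counts with the
# published-style percentage triples they must reproduce (classes in
# order advice, effect, int, mechanism, then the micro-averaged Overall).
reference_scorecards <- function() {
  card <- function(mat) {
    df <- as.data.frame(mat)
    names(df) <- c("tp", "fp", "fn", "total", "P", "R", "F1")
    df$class <- c("advice", "effect", "int", "mechanism", "Overall")
    df
  }
  list(
    baseline_whole = card(rbind(
      c(131, 43, 90, 221, 75.29, 59.28, 66.33),
      c(239, 220, 121, 360, 52.07, 66.39, 58.36),
      c(27, 3, 69, 96, 90.00, 28.12, 42.86),
      c(176, 84, 122, 298, 67.69, 59.06, 63.08),
      c(573, 350, 402, 975, 62.08, 58.77, 60.38))),
    baseline_drugbank = card(rbind(
      c(130, 43, 84, 214, 75.14, 60.75, 67.18),
      c(212, 190, 86, 298, 52.74, 71.14, 60.57),
      c(27, 2, 67, 94, 93.10, 28.72, 43.90),
      c(169, 79, 109, 278, 68.15, 60.79, 64.26),
      c(538, 314, 346, 884, 63.15, 60.86, 61.98))),
    baseline_medline = card(rbind(
      c(1, 0, 6, 7, 100.00, 14.29, 25.00),
      c(27, 30, 35, 62, 47.37, 43.55, 45.38),
      c(0, 1, 2, 2, 0.00, 0.00, 0.00),
      c(7, 5, 13, 20, 58.33, 35.00, 43.75),
      c(35, 36, 56, 91, 49.30, 38.46, 43.21))),
    best_whole = card(rbind(
      c(145, 41, 76, 221, 77.96, 65.61, 71.25),
      c(183, 81, 177, 360, 69.32, 50.83, 58.65),
      c(27, 8, 69, 96, 77.14, 28.12, 41.22),
      c(192, 106, 106, 298, 64.43, 64.43, 64.43),
      c(547, 236, 428, 975, 69.86, 56.10, 62.23))))
}

# Handcrafted padded instance (plain structure; only the documented
# fields are needed downstream).
toy_instance <- function(tokens, p1, p2, label, sid = "t.s1",
                         pid = "t.p1", provenance = "synthetic") {
  structure(list(tokens = tokens, p1 = as.integer(p1),
                 p2 = as.integer(p2), label = label,
                 sentence_id = sid, pair_id = pid,
                 provenance = provenance,
                 true_length = as.integer(sum(tokens != "0"))),
            class = "ddi_instance")
}

# A small labelled instance set padded to length n, two instances per
# positive class plus two negatives, with word cues tied to the labels.
toy_instances <- function(n = 8) {
  mk <- function(i, cue, label, p2) {
    toks <- c("drug1", cue, "drug2", "x", "y", "z")[seq_len(min(6, n))]
    toks[3] <- "w"; toks[p2] <- "drug2"
    toy_instance(c(toks, rep("0", n - length(toks))), 1, p2, label,
                 sid = paste0("t.s", i), pid = paste0("t.p", i))
  }
  list(mk(1, "combination", "advice", 3),
       mk(2, "combination", "advice", 4),
       mk(3, "enhance", "effect", 3),
       mk(4, "enhance", "effect", 4),
       mk(5, "interacts", "int", 3),
       mk(6, "interacts", "int", 4),
       mk(7, "clearance", "mechanism", 3),
       mk(8, "clearance", "mechanism", 4),
       mk(9, "and", "other", 3),
       mk(10, "and", "other", 4))
}

# Tiny model setup shared by the CNN unit tests.
tiny_setup <- function(n = 8, me = 4, md = 2, filter_sizes = c(2, 3),
                       m = 3, seed = 5, ...) {
  inst <- toy_instances(n)
  vocab <- build_vocabulary(inst)
  hyper <- hyperparams(n = n, me = me, md = md,
                       filter_sizes = filter_sizes, m = m,
                       batch_size = 4, seed = seed, ...)
  list(inst = inst, vocab = vocab, hyper = hyper,
       enc = encode_instances(inst, vocab))
}

# Central-difference gradient oracle, independent of the analytic
# backward pass.
numeric_gradient <- function(model, name, enc, rows, mask, h = 1e-5) {
  p <- model$params[[name]]
  out <- p * 0
  for (i in seq_along(p)) {
    up <- model; up$params[[name]][i] <- p[i] + h
    dn <- model; dn$params[[name]][i] <- p[i] - h
    out[i] <- (cnn_loss(up, enc, rows, dropout_mask = mask) -
                 cnn_loss(dn, enc, rows, dropout_mask = mask)) / (2 * h)
  }
  out
}

# Brute-force chi-square oracle on a 2x2 table.
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
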