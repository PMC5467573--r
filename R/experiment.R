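# Study protocol: sentence-level validation split, learning curves, and
# named hyper-parameter sweeps with all-pairs chi-square significance
# matrices. The test set is never used for any selection decision.

#' Split instances into train and validation at the sentence level
#'
#' Sentences are assigned whole, so no sentence contributes instances to
#' both sides. Shuffled sentences are accumulated into the validation
#' side until its instance count is as close as possible to the target
#' fraction; with realistically many sentences the achieved fraction is
#' within a couple of percentage points of the target.
#'
#' @param instances A `ddi_instances` object or list of `ddi_instance`.
#' @param fraction Target validation fraction of instances (default
#'   0.10).
#' @param seed Integer seed; the split is deterministic given
#'   `(instances, fraction, seed)`.
#' @return List with `train` and `validation` (lists of instances) and
#'   `achieved_fraction`.
#' @export
split_train_validation <- function(instances, fraction = 0.10, seed = 1) {
  inst <- if (inherits(instances, "ddi_instances")) instances$instances else instances
  sids <- vapply(inst, `[[`, character(1), "sentence_id")
  usent <- unique(sids)
  if (length(usent) < 2) stop("need at least 2 sentences to split")
  set.seed(seed)
  shuffled <- sample(usent)
  counts <- table(sids)[shuffled]
  target <- fraction * length(inst)
  cum <- cumsum(as.integer(counts))
  # take the prefix whose instance count is closest to the target
  k <- which.min(abs(cum - target))
  if (cum[k] > length(inst) - 1) k <- k - 1  # keep train non-empty
  val_sent <- if (k >= 1) shuffled[seq_len(k)] else character(0)
  in_val <- sids %in% val_sent
  list(train = inst[!in_val], validation = inst[in_val],
       achieved_fraction = mean(in_val))
}

#' Run a named hyper-parameter sweep
#'
#' Trains one model per configuration on a shared train/validation
#' split, scores each on the validation set (and optionally a test
#' set), and computes the all-pairs chi-square significance matrix of
#' the validation predictions. A failing run is recorded with its error
#' message and does not abort the sweep.
#'
#' @param grid Named list of [hyperparams()] configurations.
#' @param train,validation Instance sets from
#'   [split_train_validation()].
#' @param test Optional held-out instances, scored but never used for
#'   selection.
#' @param vocab Optional shared vocabulary (built from `train` when
#'   `NULL`).
#' @param verbose Print progress.
#' @return An object of class `ddi_sweep`: list with `records` (per
#'   config: `name`, `model`, `validation_metrics`, `test_metrics`,
#'   `validation_pred`, or `error`), `results` (data frame of name /
#'   P / R / F1 on validation), `chi_square` and `p_value` matrices,
#'   `significant` logical matrix, and `ranking` (config names by
#'   decreasing validation F1).
#' @export
run_sweep <- function(grid, train, validation, test = NULL,
                      vocab = NULL, verbose = FALSE) {
  if (length(grid) == 0) stop("empty sweep grid")
  if (is.null(names(grid)) || anyDuplicated(names(grid))) {
    stop("grid configurations must have unique names")
  }
  tr <- if (inherits(train, "ddi_instances")) train$instances else train
  va <- if (inherits(validation, "ddi_instances")) validation$instances else validation
  if (is.null(vocab)) vocab <- build_vocabulary(tr)
  tenc <- encode_instances(tr, vocab)
  venc <- encode_instances(va, vocab)
  xenc <- if (is.null(test)) NULL else {
    te <- if (inherits(test, "ddi_instances")) test$instances else test
    encode_instances(te, vocab)
  }
  gold_val <- DDI_CLASSES[venc$label]
  records <- lapply(names(grid), function(nm) {
    if (verbose) message("sweep: training '", nm, "'")
    tryCatch({
      model <- train_cnn(tenc, grid[[nm]], validation = venc,
                         vocab = vocab)
      vpred <- as.character(predict_cnn(model, venc))
      rec <- list(name = nm, model = model,
                  validation_pred = vpred,
                  validation_metrics = metrics_report(gold_val, vpred))
      if (!is.null(xenc)) {
        xpred <- as.character(predict_cnn(model, xenc))
        rec$test_pred <- xpred
        rec$test_metrics <- metrics_report(DDI_CLASSES[xenc$label], xpred)
      }
      rec
    }, error = function(e) {
      list(name = nm, error = conditionMessage(e))
    })
  })
  names(records) <- names(grid)
  ok <- !vapply(records, function(r) is.null(r$validation_pred), logical(1))
  nms <- names(grid)
  chi <- pval <- matrix(NA_real_, length(nms), length(nms),
                        dimnames = list(nms, nms))
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (i != j && ok[i] && ok[j]) {
        cmp <- chi_square_compare(gold_val,
                                  records[[i]]$validation_pred,
                                  records[[j]]$validation_pred)
        chi[i, j] <- cmp$chi_square
        pval[i, j] <- cmp$p_value
      }
    }
  }
  results <- do.call(rbind, lapply(records[ok], function(r) {
    ov <- r$validation_metrics[r$validation_metrics$class == "Overall", ]
    data.frame(name = r$name, P = ov$P, R = ov$R, F1 = ov$F1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(results)) {
    results <- data.frame(name = character(0), P = numeric(0),
                          R = numeric(0), F1 = numeric(0))
  }
  rownames(results) <- NULL
  ranking <- results$name[order(results$F1, decreasing = TRUE)]
  structure(list(records = records, results = results,
                 chi_square = chi, p_value = pval,
                 significant = (chi > 3.84) & (pval < 0.05),
                 ranking = ranking),
            class = "ddi_sweep")
}

#' @export
print.ddi_sweep <- function(x, ...) {
  cat("ddi_sweep:", length(x$records), "configurations\n")
  shown <- x$results
  if (nrow(shown) > 0) {
    shown$P <- sprintf("%.2f%%", shown$P)
    shown$R <- sprintf("%.2f%%", shown$R)
    shown$F1 <- sprintf("%.2f%%", shown$F1)
    print(shown, row.names = FALSE)
    cat("ranking:", paste(x$ranking, collapse = " > "), "\n")
  }
  invisible(x)
}

#' Learning curve of a trained model
#'
#' One row per epoch with summed training loss and micro-averaged F1 on
#' the training (and, if supplied at training time, validation) sets.
#' The epoch maximizing validation F1 (training F1 when no validation
#' data was given) is reported as attribute `best_epoch`.
#'
#' @param model A [train_cnn()] result.
#' @return The curve data frame with attribute `best_epoch`.
#' @export
learning_curve <- function(model) {
  stopifnot(inherits(model, "ddi_cnn"))
  curve <- model$curve
  if (nrow(curve) > 0) {
    crit <- if (all(is.na(curve$validation_f1))) curve$train_f1 else {
      curve$validation_f1
    }
    attr(curve, "best_epoch") <- curve$epoch[which.max(crit)]
  }
  curve
}
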