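# The network: convolution over the embedded instance matrix with a
# multi-size filter bank, ReLU, max-over-time pooling, dropout, and a
# fully connected softmax layer. Trained by minimizing the summed
# negative log-likelihood (cross entropy) plus an l2 penalty on the
# softmax weights, with Adam over shuffled mini-batches.
#
# Backpropagation is hand-derived. The convolution is computed as an
# im2col gather followed by one dense matrix product per filter size;
# the max-pool backward pass is a sparse scatter (one surviving window
# per instance and filter), routed through Matrix::sparseMatrix.

#' CNN hyper-parameters
#'
#' Defaults follow the fixed settings of the reference configuration:
#' instance length `n = 128`, word dimension `me = 300`, `m = 200`
#' filters per window size, dropout rate 0.5, l2 coefficient 3 on the
#' softmax weights, mini-batch size 50, 25 epochs, ReLU nonlinearity and
#' `k = 5` classes. The position dimension `md` takes values 0 (position
#' features disabled), 5 or 10 in the embedding study; the default is 5,
#' the best-performing setting. Adam step size and moment decays are not
#' part of the published settings; the standard 1e-3 / 0.9 / 0.999 /
#' 1e-8 defaults are used. Filters and softmax weights are initialized
#' uniform on (-`init_range`, +`init_range`); embedding tables uniform
#' on (-1, +1).
#'
#' @param n Fixed instance length.
#' @param me Word-embedding dimension.
#' @param md Position-embedding dimension (0 disables position features).
#' @param filter_sizes Integer vector of distinct window widths.
#' @param m Number of filters per window size.
#' @param dropout Dropout probability `p` on the pooled vector, `0 <= p < 1`.
#' @param l2 Coefficient of the squared-norm penalty on the softmax weights.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param lr,beta1,beta2,eps Adam step size, moment decays and epsilon.
#' @param init_range Half-width of the uniform init for filters and `Ws`.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return An object of class `ddi_hyperparams`.
#' @export
hyperparams <- function(n = 128, me = 300, md = 5,
                        filter_sizes = c(3, 4, 5), m = 200,
                        dropout = 0.5, l2 = 3, batch_size = 50,
                        epochs = 25, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8, init_range = 0.1,
                        seed = 1) {
  filter_sizes <- as.integer(filter_sizes)
  stopifnot(n >= 1, me >= 1, md >= 0, m >= 1,
            length(filter_sizes) >= 1,
            all(filter_sizes >= 1), all(filter_sizes <= n),
            !anyDuplicated(filter_sizes),
            dropout >= 0, dropout < 1, l2 >= 0,
            batch_size >= 1, epochs >= 0)
  structure(list(n = as.integer(n), me = as.integer(me),
                 md = as.integer(md), filter_sizes = filter_sizes,
                 m = as.integer(m), dropout = dropout, l2 = l2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, eps = eps, init_range = init_range,
                 k = length(DDI_CLASSES), seed = as.integer(seed)),
            class = "ddi_hyperparams")
}

input_dim <- function(hyper) hyper$me + 2L * hyper$md
total_filters <- function(hyper) hyper$m * length(hyper$filter_sizes)

# Draw all trainable tensors from the current RNG state. Draw order is
# fixed (We, Wd1, Wd2, filters by size, Ws) so a seed fully determines
# the initialization.
init_params <- function(vocab, hyper, We = NULL) {
  d <- input_dim(hyper)
  if (is.null(We)) {
    We <- init_random_embeddings(vocab, hyper$me)
  } else {
    stopifnot(nrow(We) == vocab$size, ncol(We) == hyper$me)
  }
  Wd1 <- Wd2 <- NULL
  if (hyper$md > 0) {
    npos <- 2L * hyper$n - 1L
    Wd1 <- matrix(runif(npos * hyper$md, -1, 1), npos, hyper$md)
    Wd2 <- matrix(runif(npos * hyper$md, -1, 1), npos, hyper$md)
  }
  r <- hyper$init_range
  params <- list(We = We, Wd1 = Wd1, Wd2 = Wd2)
  for (w in hyper$filter_sizes) {
    params[[paste0("F_", w)]] <-
      matrix(runif(hyper$m * w * d, -r, r), hyper$m, w * d)
    params[[paste0("b_", w)]] <- numeric(hyper$m)
  }
  params$Ws <- matrix(runif(total_filters(hyper) * hyper$k, -r, r),
                      total_filters(hyper), hyper$k)
  params$d <- numeric(hyper$k)
  params
}

#' Initialize an untrained CNN model
#'
#' @param vocab A `ddi_vocabulary`.
#' @param hyper A [hyperparams()] object.
#' @param We Optional pre-built `|V| x me` word-embedding matrix (e.g.
#'   from [load_pretrained()]); randomly initialized when `NULL`.
#' @return An object of class `ddi_cnn` with fields `params`, `hyper`,
#'   `vocab`, `curve` (empty) and `updates` (0).
#' @export
init_cnn <- function(vocab, hyper = hyperparams(), We = NULL) {
  set.seed(hyper$seed)
  structure(list(params = init_params(vocab, hyper, We),
                 hyper = hyper, vocab = vocab,
                 curve = empty_curve(), updates = 0L),
            class = "ddi_cnn")
}

empty_curve <- function() {
  data.frame(epoch = integer(0), loss = numeric(0),
             train_f1 = numeric(0), validation_f1 = numeric(0),
             ws_norm = numeric(0))
}

#' @export
print.ddi_cnn <- function(x, ...) {
  h <- x$hyper
  cat(sprintf(
    "ddi_cnn: n=%d, me=%d, md=%d, filters m=%d x sizes (%s), |V|=%d, %d updates\n",
    h$n, h$me, h$md, h$m, paste(h$filter_sizes, collapse = ", "),
    x$vocab$size, x$updates))
  if (nrow(x$curve) > 0) {
    last <- x$curve[nrow(x$curve), ]
    cat(sprintf("  after epoch %d: train F1 = %.2f%%%s\n", last$epoch,
                last$train_f1,
                if (is.na(last$validation_f1)) "" else
                  sprintf(", validation F1 = %.2f%%", last$validation_f1)))
  }
  invisible(x)
}

# ---- reference single-filter convolution ----------------------------------

#' Convolve one filter over an input matrix
#'
#' Reference implementation of the convolutional layer for a single
#' filter: `s_i = g(sum_j <f_j, x_{i+j-1}> + b)` for window positions
#' `i = 1 .. n-w+1`. The batched training path is an im2col
#' reformulation of this same map.
#'
#' @param X `n x d` input matrix (one row per token).
#' @param f `w x d` filter matrix (row `j` applies to the j-th token of
#'   the window).
#' @param b Bias term.
#' @param g Nonlinearity (default ReLU).
#' @return Numeric score sequence of length `n - w + 1`.
#' @export
convolve_filter <- function(X, f, b = 0, g = function(v) pmax(v, 0)) {
  w <- nrow(f); n <- nrow(X)
  if (w > n) stop("filter width w = ", w, " exceeds n = ", n)
  vapply(seq_len(n - w + 1L), function(i) {
    g(sum(f * X[i:(i + w - 1L), , drop = FALSE]) + b)
  }, numeric(1))
}

#' Max-over-time pooling
#'
#' Collapses a filter's score sequence to its maximum; invariant to any
#' permutation of the sequence.
#'
#' @param s Non-empty numeric vector.
#' @return The maximum score.
#' @export
pool_max <- function(s) {
  if (length(s) == 0) stop("cannot pool an empty score sequence")
  max(s)
}

# ---- batched forward / backward -------------------------------------------

# Gather the stacked input matrix for a set of instances: row
# (b-1)*n + i is the embedded token i of the b-th requested instance.
gather_X <- function(params, hyper, enc, rows) {
  widx <- as.vector(t(enc$word[rows, , drop = FALSE]))
  X <- params$We[widx, , drop = FALSE]
  p1v <- p2v <- NULL
  if (hyper$md > 0) {
    p1v <- as.vector(t(enc$pos1[rows, , drop = FALSE]))
    p2v <- as.vector(t(enc$pos2[rows, , drop = FALSE]))
    X <- cbind(X, params$Wd1[p1v, , drop = FALSE],
               params$Wd2[p2v, , drop = FALSE])
  }
  list(X = X, widx = widx, p1v = p1v, p2v = p2v)
}

# Restack a filter matrix F (m x w*d, one row per filter with the w
# per-token slices side by side) into the d x (m*w) kernel used by the
# shifted-GEMM convolution: column block j holds t(F_j).
stack_filters <- function(Fw, w, d, m) {
  K <- matrix(0, d, m * w)
  for (j in seq_len(w)) {
    K[, ((j - 1L) * m + 1L):(j * m)] <- t(Fw[, ((j - 1L) * d + 1L):(j * d),
                                             drop = FALSE])
  }
  K
}

# Forward pass up to the pooled vector z. The convolution is computed as
# one GEMM per filter size on the full token matrix (every token against
# every per-position filter slice) followed by shifted row-gathers, which
# avoids materializing an im2col copy of the input. Returns per-size
# caches needed for backprop (window starts, argmax positions, scores).
forward_pool <- function(params, hyper, Xall, nb, keep_scores = FALSE) {
  n <- hyper$n; m <- hyper$m; d <- input_dim(hyper)
  z <- matrix(0, nb, total_filters(hyper))
  caches <- vector("list", length(hyper$filter_sizes))
  for (si in seq_along(hyper$filter_sizes)) {
    w <- hyper$filter_sizes[si]
    L <- n - w + 1L
    starts <- rep.int((seq_len(nb) - 1L) * n, rep.int(L, nb)) + seq_len(L)
    B <- Xall %*% stack_filters(params[[paste0("F_", w)]], w, d, m)
    A <- matrix(params[[paste0("b_", w)]], nb * L, m, byrow = TRUE)
    for (j in 0:(w - 1L)) {
      A <- A + B[starts + j, (j * m + 1L):(j * m + m), drop = FALSE]
    }
    S <- A
    S[S < 0] <- 0
    # reshape so each (instance, filter) pair is a row of length L,
    # then take the first maximal window position
    M <- matrix(aperm(array(S, c(L, nb, m)), c(2, 3, 1)), nb * m, L)
    amax <- matrix(max.col(M, ties.method = "first"), nb, m)
    rmat <- (seq_len(nb) - 1L) * L + amax
    # flatten the index: a two-column index matrix would otherwise be
    # taken as (row, col) coordinate pairs
    lin <- as.vector(rmat + (col(rmat) - 1L) * (nb * L))
    zw <- matrix(S[lin], nb, m)
    z[, ((si - 1L) * m + 1L):(si * m)] <- zw
    caches[[si]] <- list(w = w, L = L, starts = starts,
                         amax = amax, rmat = rmat, zw = zw,
                         S = if (keep_scores) array(S, c(L, nb, m)) else NULL)
  }
  list(z = z, caches = caches)
}

softmax_head <- function(params, z_d) {
  o <- z_d %*% params$Ws
  o <- o + matrix(params$d, nrow(o), length(params$d), byrow = TRUE)
  mo <- apply(o, 1, max)
  lse <- mo + log(rowSums(exp(o - mo)))
  logp <- o - lse
  list(o = o, logp = logp, prob = exp(logp))
}

make_dropout_mask <- function(nb, mtot, p) {
  if (p <= 0) return(matrix(1, nb, mtot))
  matrix((runif(nb * mtot) >= p) / (1 - p), nb, mtot)
}

#' Forward pass with full trace
#'
#' Runs the network on a set of encoded instances and returns every
#' intermediate quantity: per-filter score sequences, the pooled vector
#' `z`, its (possibly) dropped version `z_d`, output scores `o` and class
#' probabilities. In `train` mode elements of `z` are zeroed with
#' probability `p` and survivors are rescaled by `1/(1-p)` (inverted
#' dropout), so in `eval` mode nothing is dropped and no rescaling is
#' needed.
#'
#' @param model A `ddi_cnn`.
#' @param enc A [encode_instances()] result.
#' @param rows Instance rows to run (default all).
#' @param mode `"eval"` or `"train"`.
#' @param dropout_mask Optional fixed mask matrix (already scaled), used
#'   for deterministic replay; only meaningful in train mode.
#' @return List with `s` (one `L x nb x m` array per filter size), `z`,
#'   `z_d`, `o`, `prob` and `mask`.
#' @export
cnn_forward <- function(model, enc, rows = NULL,
                        mode = c("eval", "train"), dropout_mask = NULL) {
  mode <- match.arg(mode)
  hyper <- model$hyper; params <- model$params
  if (is.null(rows)) rows <- seq_len(nrow(enc$word))
  nb <- length(rows)
  g <- gather_X(params, hyper, enc, rows)
  fp <- forward_pool(params, hyper, g$X, nb, keep_scores = TRUE)
  if (mode == "train") {
    mask <- if (is.null(dropout_mask)) {
      make_dropout_mask(nb, total_filters(hyper), hyper$dropout)
    } else dropout_mask
    z_d <- fp$z * mask
  } else {
    mask <- NULL
    z_d <- fp$z
  }
  head <- softmax_head(params, z_d)
  list(s = setNames(lapply(fp$caches, `[[`, "S"),
                    paste0("w", hyper$filter_sizes)),
       z = fp$z, z_d = z_d, o = head$o, prob = head$prob, mask = mask)
}

#' Training loss on a batch
#'
#' `J = -sum_i log p(y_i | x_i, theta) + l2 * ||Ws||^2`, the summed
#' cross entropy of the batch plus the squared-norm penalty on the
#' softmax weights. Computed with the log-sum-exp guard.
#'
#' @param model A `ddi_cnn`.
#' @param enc Encoded instances with labels.
#' @param rows Instance rows (default all).
#' @param dropout_mask Optional fixed dropout mask; `NULL` means no
#'   dropout is applied (the deterministic limit used for gradient
#'   checking).
#' @return Scalar loss.
#' @export
cnn_loss <- function(model, enc, rows = NULL, dropout_mask = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(enc$word))
  if (length(rows) == 0) stop("empty batch")
  pass <- batch_pass(model$params, model$hyper, enc, rows,
                     mask = dropout_mask, grad = FALSE)
  pass$loss
}

#' Analytic gradients on a batch
#'
#' Backpropagation through the softmax head, dropout, max-pooling,
#' ReLU convolution and the embedding lookups. Returns one gradient per
#' trainable tensor, matching the layout of `model$params`.
#'
#' @inheritParams cnn_loss
#' @return Named list of gradients.
#' @export
cnn_gradients <- function(model, enc, rows = NULL, dropout_mask = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(enc$word))
  batch_pass(model$params, model$hyper, enc, rows,
             mask = dropout_mask, grad = TRUE)$grads
}

# One combined forward (+ optional backward) pass over a batch.
batch_pass <- function(params, hyper, enc, rows, mask = NULL,
                       grad = TRUE) {
  nb <- length(rows)
  y <- enc$label[rows]
  g <- gather_X(params, hyper, enc, rows)
  fp <- forward_pool(params, hyper, g$X, nb)
  z_d <- if (is.null(mask)) fp$z else fp$z * mask
  head <- softmax_head(params, z_d)
  loss <- -sum(head$logp[cbind(seq_len(nb), y)]) +
    hyper$l2 * sum(params$Ws^2)
  if (!grad) return(list(loss = loss, prob = head$prob))

  m <- hyper$m; d <- input_dim(hyper)
  dO <- head$prob
  dO[cbind(seq_len(nb), y)] <- dO[cbind(seq_len(nb), y)] - 1
  grads <- list()
  grads$Ws <- crossprod(z_d, dO) + 2 * hyper$l2 * params$Ws
  grads$d <- colSums(dO)
  dz <- dO %*% t(params$Ws)
  if (!is.null(mask)) dz <- dz * mask

  # One global sparse scatter for every (size, window-slice, filter)
  # column: dT has a nonzero at (token row, stacked column) for each
  # surviving pooled window, so both the filter gradients and the input
  # gradient come from a single sparse-dense product each.
  sizes <- hyper$filter_sizes
  stack_rows <- m * sizes                     # rows per size in F_stack
  offs <- cumsum(c(0L, head(stack_rows, -1)))
  F_stack <- matrix(0, sum(stack_rows), d)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  dvals <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    cache <- fp$caches[[si]]
    w <- cache$w
    Fw <- params[[paste0("F_", w)]]
    for (j in seq_len(w)) {
      F_stack[offs[si] + (j - 1L) * m + seq_len(m), ] <-
        Fw[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
    }
    dzw <- dz[, ((si - 1L) * m + 1L):(si * m), drop = FALSE]
    dval <- dzw * (cache$zw > 0)  # ReLU: no gradient through flat maxima
    dvals[[si]] <- dval
    nz <- which(dval != 0)
    if (length(nz) > 0) {
      fcol <- ((nz - 1L) %/% nb) + 1L
      tok0 <- cache$starts[cache$rmat[nz]]  # first token row of the window
      for (j in seq_len(w)) {
        ti <- c(ti, tok0 + (j - 1L))
        tj <- c(tj, offs[si] + (j - 1L) * m + fcol)
        tx <- c(tx, dval[nz])
      }
    }
    grads[[paste0("b_", w)]] <- colSums(dval)
  }
  if (length(ti) > 0) {
    dT <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                               dims = c(nb * hyper$n, nrow(F_stack)))
    dF_stack <- as.matrix(Matrix::crossprod(dT, g$X))
    dXall <- as.matrix(dT %*% F_stack)
  } else {
    dF_stack <- matrix(0, nrow(F_stack), d)
    dXall <- matrix(0, nb * hyper$n, d)
  }
  for (si in seq_along(sizes)) {
    w <- sizes[si]
    dFw <- matrix(0, m, w * d)
    for (j in seq_len(w)) {
      dFw[, ((j - 1L) * d + 1L):(j * d)] <-
        dF_stack[offs[si] + (j - 1L) * m + seq_len(m), , drop = FALSE]
    }
    grads[[paste0("F_", w)]] <- dFw
  }

  me <- hyper$me
  grads$We <- matrix(0, nrow(params$We), me)
  rs <- rowsum(dXall[, seq_len(me), drop = FALSE], g$widx)
  grads$We[as.integer(rownames(rs)), ] <- rs
  if (hyper$md > 0) {
    md <- hyper$md
    grads$Wd1 <- matrix(0, nrow(params$Wd1), md)
    rs1 <- rowsum(dXall[, me + seq_len(md), drop = FALSE], g$p1v)
    grads$Wd1[as.integer(rownames(rs1)), ] <- rs1
    grads$Wd2 <- matrix(0, nrow(params$Wd2), md)
    rs2 <- rowsum(dXall[, me + md + seq_len(md), drop = FALSE], g$p2v)
    grads$Wd2[as.integer(rownames(rs2)), ] <- rs2
  }
  list(loss = loss, prob = head$prob, grads = grads)
}

# ---- training -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) if (is.null(p)) NULL else p * 0),
       v = lapply(params, function(p) if (is.null(p)) NULL else p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, hyper) {
  state$t <- state$t + 1L
  corr1 <- 1 - hyper$beta1^state$t
  corr2 <- 1 - hyper$beta2^state$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- hyper$beta1 * state$m[[nm]] + (1 - hyper$beta1) * gmat
    state$v[[nm]] <- hyper$beta2 * state$v[[nm]] + (1 - hyper$beta2) * gmat^2
    params[[nm]] <- params[[nm]] - hyper$lr *
      (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + hyper$eps)
  }
  list(params = params, state = state)
}

micro_f1_idx <- function(gold, pred) {
  pos <- length(DDI_POSITIVE_CLASSES)
  tp <- sum(gold == pred & gold <= pos)
  fp <- sum(pred <= pos & pred != gold)
  fn <- sum(gold <= pos & pred != gold)
  unname(precision_recall_f1(tp, fp, fn)["F1"])
}

predict_idx <- function(params, hyper, enc, rows = NULL,
                        batch_size = 256L) {
  if (is.null(rows)) rows <- seq_len(nrow(enc$word))
  out <- integer(length(rows))
  prob <- matrix(0, length(rows), hyper$k)
  for (chunk in split(seq_along(rows),
                      ceiling(seq_along(rows) / batch_size))) {
    g <- gather_X(params, hyper, enc, rows[chunk])
    fp <- forward_pool(params, hyper, g$X, length(chunk))
    head <- softmax_head(params, fp$z)
    prob[chunk, ] <- head$prob
    out[chunk] <- max.col(head$prob, ties.method = "first")
  }
  list(index = out, prob = prob)
}

#' Train the CNN
#'
#' Performs `epochs x ceiling(N / batch_size)` Adam updates over
#' per-epoch reshuffled mini-batches, minimizing the summed cross
#' entropy plus the l2 penalty on the softmax weights. Fully
#' reproducible: the seed in `hyper` determines initialization,
#' shuffling and dropout, so two runs with the same inputs and seed
#' yield identical parameters.
#'
#' @param instances Training data: a `ddi_instances` object, a list of
#'   `ddi_instance`, or a pre-built `ddi_encoded` (in which case `vocab`
#'   must be the vocabulary it was encoded with).
#' @param hyper A [hyperparams()] object.
#' @param validation Optional held-out data in any of the same forms
#'   (encoded data must share `vocab`); scored once per epoch.
#' @param vocab Optional vocabulary; built from the training instances
#'   when `NULL`.
#' @param We Optional initial word-embedding matrix (e.g. from
#'   [load_pretrained()]).
#' @param verbose Print per-epoch progress.
#' @return A `ddi_cnn` whose `curve` has one row per epoch: `epoch`,
#'   summed training `loss`, `train_f1` and `validation_f1`
#'   (micro-averaged, in percent; `NA` without validation data) and
#'   `ws_norm`, the Frobenius norm of the softmax weights.
#' @export
train_cnn <- function(instances, hyper = hyperparams(),
                      validation = NULL, vocab = NULL, We = NULL,
                      verbose = FALSE) {
  if (inherits(instances, "ddi_encoded")) {
    if (is.null(vocab)) stop("encoded training data needs its vocabulary")
    enc <- instances
  } else {
    inst <- if (inherits(instances, "ddi_instances")) instances$instances else instances
    if (length(inst) == 0) stop("empty training set")
    if (is.null(vocab)) vocab <- build_vocabulary(inst)
    enc <- encode_instances(inst, vocab)
  }
  if (enc$n != hyper$n) {
    stop("instances are padded to n = ", enc$n,
         " but the model expects n = ", hyper$n)
  }
  venc <- NULL
  if (!is.null(validation)) {
    venc <- if (inherits(validation, "ddi_encoded")) validation else {
      vin <- if (inherits(validation, "ddi_instances")) validation$instances else validation
      encode_instances(vin, vocab)
    }
  }
  N <- nrow(enc$word)
  set.seed(hyper$seed)
  params <- init_params(vocab, hyper, We)
  state <- adam_init(params)
  curve <- empty_curve()
  for (epoch in seq_len(hyper$epochs)) {
    ord <- sample.int(N)
    epoch_loss <- 0
    for (batch in split(ord, ceiling(seq_along(ord) / hyper$batch_size))) {
      mask <- make_dropout_mask(length(batch), total_filters(hyper),
                                hyper$dropout)
      pass <- batch_pass(params, hyper, enc, batch, mask = mask,
                         grad = TRUE)
      epoch_loss <- epoch_loss + pass$loss
      upd <- adam_step(params, pass$grads, state, hyper)
      params <- upd$params
      state <- upd$state
    }
    train_f1 <- micro_f1_idx(enc$label,
                             predict_idx(params, hyper, enc)$index)
    val_f1 <- if (is.null(venc)) NA_real_ else {
      micro_f1_idx(venc$label, predict_idx(params, hyper, venc)$index)
    }
    curve <- rbind(curve, data.frame(
      epoch = epoch, loss = epoch_loss, train_f1 = train_f1,
      validation_f1 = val_f1,
      ws_norm = sqrt(sum(params$Ws^2))))
    if (verbose) {
      message(sprintf("epoch %d: loss %.2f, train F1 %.2f%%%s", epoch,
                      epoch_loss, train_f1,
                      if (is.na(val_f1)) "" else
                        sprintf(", val F1 %.2f%%", val_f1)))
    }
  }
  structure(list(params = params, hyper = hyper, vocab = vocab,
                 curve = curve, updates = state$t),
            class = "ddi_cnn")
}

#' Predict class labels
#'
#' Runs the network in eval mode (no dropout) and takes the class with
#' the highest probability; ties are broken toward the lowest class
#' index. Prediction is stateless, so results do not depend on how the
#' input is partitioned into batches.
#'
#' @param model A `ddi_cnn`.
#' @param newdata Instances (`ddi_instances`, list, or `ddi_encoded`
#'   built with the model's vocabulary).
#' @param type `"class"` (factor over [DDI_CLASSES]), `"index"` or
#'   `"prob"` (N x 5 probability matrix).
#' @param batch_size Internal batch size.
#' @return Predictions in the requested form.
#' @export
predict_cnn <- function(model, newdata, type = c("class", "index", "prob"),
                        batch_size = 256L) {
  type <- match.arg(type)
  enc <- if (inherits(newdata, "ddi_encoded")) newdata else {
    inst <- if (inherits(newdata, "ddi_instances")) newdata$instances else newdata
    encode_instances(inst, model$vocab)
  }
  res <- predict_idx(model$params, model$hyper, enc,
                     batch_size = batch_size)
  switch(type,
         class = factor(DDI_CLASSES[res$index], levels = DDI_CLASSES),
         index = res$index,
         prob = structure(res$prob, dimnames = list(NULL, DDI_CLASSES)))
}

# ---- checkpointing --------------------------------------------------------

#' Save a model checkpoint
#'
#' One archive holding every trainable tensor, the hyper-parameters, the
#' vocabulary and the learning curve; [load_cnn()] restores it
#' bit-identically.
#'
#' @param model A `ddi_cnn`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "ddi_cnn"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' Restore a model checkpoint
#' @param path A file written by [save_cnn()].
#' @return The restored `ddi_cnn`.
#' @export
load_cnn <- function(path) {
  obj <- readRDS(path)
  stopifnot(is.list(obj), all(c("params", "hyper", "vocab") %in% names(obj)))
  structure(obj, class = "ddi_cnn")
}
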