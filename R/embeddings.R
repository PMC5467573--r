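# Word table and position-embedding tables; encoding instances into the
# CNN input matrix X (one row per token: word vector concatenated with the
# two relative-position vectors).

UNK_TOKEN <- "<unk>"

#' Build a vocabulary from training instances
#'
#' Index 1 is reserved for the padding token `"0"` and index 2 for the
#' unknown token; the remaining tokens are sorted so construction is
#' order-independent.
#'
#' @param instances A `ddi_instances` object or list of `ddi_instance`.
#' @return An object of class `ddi_vocabulary` with fields `tokens`
#'   (index to token), `index` (token to index), `pad_index`,
#'   `unk_index`, `size`.
#' @export
build_vocabulary <- function(instances) {
  inst <- if (inherits(instances, "ddi_instances")) instances$instances else instances
  if (length(inst) == 0) stop("cannot build a vocabulary from no instances")
  toks <- sort(unique(unlist(lapply(inst, `[[`, "tokens"))))
  toks <- setdiff(toks, c(PAD_TOKEN, UNK_TOKEN))
  tokens <- c(PAD_TOKEN, UNK_TOKEN, toks)
  structure(list(tokens = tokens,
                 index = setNames(seq_along(tokens), tokens),
                 pad_index = 1L, unk_index = 2L,
                 size = length(tokens)),
            class = "ddi_vocabulary")
}

#' @export
print.ddi_vocabulary <- function(x, ...) {
  cat("ddi_vocabulary: |V| =", x$size,
      "(incl. padding and unknown entries)\n")
  invisible(x)
}

#' Map tokens to vocabulary indices
#' @param vocab A [build_vocabulary()] result.
#' @param tokens Character vector.
#' @return Integer vector; out-of-vocabulary tokens get the unknown index.
#' @export
token_indices <- function(vocab, tokens) {
  idx <- unname(vocab$index[tokens])
  idx[is.na(idx)] <- vocab$unk_index
  as.integer(idx)
}

#' Randomly initialized word embeddings
#'
#' Entries are i.i.d. uniform on (-1, +1), the initialization used when
#' no pre-trained vectors are supplied.
#'
#' @param vocab A `ddi_vocabulary` (or an integer row count).
#' @param me Embedding dimension (default 300).
#' @param seed Integer RNG seed; if `NULL` the current RNG state is used.
#' @return `|V| x me` numeric matrix.
#' @export
init_random_embeddings <- function(vocab, me = 300, seed = NULL) {
  stopifnot(me >= 1)
  nv <- if (inherits(vocab, "ddi_vocabulary")) vocab$size else as.integer(vocab)
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(nv * me, -1, 1), nrow = nv, ncol = me)
}

# ---- word2vec formats -----------------------------------------------------

#' Write word vectors in word2vec format
#'
#' Supports both the plain-text dialect (`"count dim"` header, one
#' `word v1 ... vd` line per word) and the binary dialect (same header,
#' then for each word its name, a space, `dim` little-endian float32
#' values and a newline). Binary storage is single precision, so vectors
#' written and re-read through the binary dialect are rounded to float32.
#'
#' @param mat Numeric matrix, one row per word.
#' @param words Character vector of row names.
#' @param path Output path.
#' @param binary Write the binary dialect (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(mat, words, path, binary = FALSE) {
  stopifnot(nrow(mat) == length(words))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(sprintf("%d %d\n", nrow(mat), ncol(mat))), con)
    for (i in seq_len(nrow(mat))) {
      writeBin(charToRaw(paste0(words[i], " ")), con)
      writeBin(as.numeric(mat[i, ]), con, size = 4, endian = "little")
      writeBin(charToRaw("\n"), con)
    }
  } else {
    lines <- c(sprintf("%d %d", nrow(mat), ncol(mat)),
               vapply(seq_len(nrow(mat)), function(i) {
                 paste(words[i], paste(formatC(mat[i, ], format = "g",
                                               digits = 17),
                                       collapse = " "))
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}

read_word2vec_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("word2vec file '", path, "': empty file")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr)) {
    stop("word2vec file '", path, "': unreadable header")
  }
  nw <- hdr[1]; dim <- hdr[2]
  words <- character(nw)
  mat <- matrix(0, nrow = nw, ncol = dim)
  for (i in seq_len(nw)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != dim + 1) {
      stop("word2vec file '", path, "': bad record at line ", i + 1)
    }
    words[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  list(words = words, vectors = mat)
}

read_word2vec_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    chars <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (length(b) == 0) return(NULL)
      if (b == charToRaw(" ")) break
      if (b != charToRaw("\n")) chars <- c(chars, b)
    }
    rawToChar(chars)
  }
  hdr_line <- character(0)
  repeat {
    b <- readBin(con, "raw", n = 1)
    if (length(b) == 0 || b == charToRaw("\n")) break
    hdr_line <- c(hdr_line, rawToChar(b))
  }
  hdr <- suppressWarnings(as.integer(strsplit(trimws(paste(hdr_line,
                                                           collapse = "")),
                                              "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr)) {
    stop("word2vec file '", path, "': unreadable header")
  }
  nw <- hdr[1]; dim <- hdr[2]
  words <- character(nw)
  mat <- matrix(0, nrow = nw, ncol = dim)
  for (i in seq_len(nw)) {
    w <- read_token()
    if (is.null(w)) stop("word2vec file '", path, "': truncated at word ", i)
    words[i] <- w
    v <- readBin(con, "numeric", n = dim, size = 4, endian = "little")
    if (length(v) != dim) {
      stop("word2vec file '", path, "': truncated vector for '", w, "'")
    }
    mat[i, ] <- v
  }
  list(words = words, vectors = mat)
}

#' Load pre-trained word vectors for a vocabulary
#'
#' Vocabulary tokens found in the file take their pre-trained vector;
#' tokens not found -- including the blinding labels `drug1`/`drug2`/
#' `drug0` and the reserved padding/unknown entries -- are randomly
#' initialized uniform on (-1, +1). All rows remain trainable: the word
#' vectors are fine-tuned during training.
#'
#' @param path A word2vec text or binary vector file.
#' @param vocab A `ddi_vocabulary`.
#' @param me Expected embedding dimension; a file with a different
#'   dimension is an error. `NULL` accepts the file's dimension.
#' @param format `"auto"` (by file extension/content), `"text"` or
#'   `"binary"`.
#' @param seed Seed for the random rows.
#' @return `|V| x me` matrix with attribute `coverage`, the fraction of
#'   vocabulary tokens found in the file.
#' @export
load_pretrained <- function(path, vocab, me = NULL,
                            format = c("auto", "text", "binary"),
                            seed = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bin$", path)) "binary" else "text"
  }
  vec <- switch(format,
                text = read_word2vec_text(path),
                binary = read_word2vec_binary(path))
  dim_file <- ncol(vec$vectors)
  if (!is.null(me) && dim_file != me) {
    stop("word2vec file '", path, "' has dimension ", dim_file,
         " but ", me, " was configured")
  }
  me <- dim_file
  We <- init_random_embeddings(vocab, me, seed = seed)
  hit <- match(vocab$tokens, vec$words)
  found <- which(!is.na(hit))
  if (length(found) > 0) We[found, ] <- vec$vectors[hit[found], ]
  attr(We, "coverage") <- length(found) / vocab$size
  We
}

# ---- position indices and instance encoding -------------------------------

#' Shifted relative-position index
#'
#' The raw relative position of token `i` with respect to an entity at
#' position `p` is `i - p`, which ranges over `(-n+1, n-1)`. To index an
#' embedding table it is shifted affinely into `(1, 2n-1)`:
#' `index = (i - p) + n`, so the endpoint `-n+1` maps to 1, distance 0
#' maps to the centre `n`, and `n-1` maps to `2n-1`.
#'
#' @param i,p Token positions in `1..n` (vectorized).
#' @param n Fixed instance length.
#' @return Integer index/indices in `[1, 2n-1]`.
#' @export
relative_position_index <- function(i, p, n) {
  if (any(i < 1 | i > n) || any(p < 1 | p > n)) {
    stop("positions must lie in [1, n]")
  }
  as.integer((i - p) + n)
}

#' Encode instances as index matrices
#'
#' Produces, for each instance, its `n` word indices and the two shifted
#' relative-position index sequences (distances to `drug1` and `drug2`).
#' Padding positions are indexed by the same formula: their distances to
#' the entities simply keep growing, which the shifted range already
#' accommodates.
#'
#' @param instances A `ddi_instances` object or list of `ddi_instance`,
#'   all padded to one common length.
#' @param vocab A `ddi_vocabulary`.
#' @return An object of class `ddi_encoded`: list with `word`, `pos1`,
#'   `pos2` (N x n integer matrices), `label` (integer vector, class
#'   indices into [DDI_CLASSES]), `n`, and `meta` (see
#'   [instances_meta()]).
#' @export
encode_instances <- function(instances, vocab) {
  inst <- if (inherits(instances, "ddi_instances")) instances$instances else instances
  if (length(inst) == 0) stop("no instances to encode")
  lens <- vapply(inst, function(x) length(x$tokens), integer(1))
  n <- lens[1]
  if (any(lens != n)) stop("instances are not padded to a common length")
  N <- length(inst)
  word <- matrix(0L, N, n)
  pos1 <- matrix(0L, N, n)
  pos2 <- matrix(0L, N, n)
  for (b in seq_len(N)) {
    word[b, ] <- token_indices(vocab, inst[[b]]$tokens)
    pos1[b, ] <- relative_position_index(seq_len(n), inst[[b]]$p1, n)
    pos2[b, ] <- relative_position_index(seq_len(n), inst[[b]]$p2, n)
  }
  labels <- match(vapply(inst, `[[`, character(1), "label"), DDI_CLASSES)
  structure(list(word = word, pos1 = pos1, pos2 = pos2,
                 label = as.integer(labels), n = as.integer(n),
                 meta = instances_meta(inst)),
            class = "ddi_encoded")
}

#' @export
print.ddi_encoded <- function(x, ...) {
  cat("ddi_encoded:", nrow(x$word), "instances, n =", x$n, "\n")
  invisible(x)
}

#' Materialize the input matrix X of one encoded instance
#'
#' Row `i` of X is the concatenation of the word embedding of token `i`
#' with the two position embeddings of its shifted distances to the two
#' entities; with `md = 0` the position blocks are absent and X is
#' `n x me`.
#'
#' @param enc A [encode_instances()] result.
#' @param i Instance row.
#' @param params Model parameter list (fields `We`, and optionally `Wd1`,
#'   `Wd2`), e.g. `model$params` from [train_cnn()] or [init_cnn()].
#' @return `n x (me + 2 md)` numeric matrix.
#' @export
input_matrix <- function(enc, i, params) {
  X <- params$We[enc$word[i, ], , drop = FALSE]
  if (!is.null(params$Wd1)) {
    X <- cbind(X, params$Wd1[enc$pos1[i, ], , drop = FALSE],
               params$Wd2[enc$pos2[i, ], , drop = FALSE])
  }
  unname(X)
}
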