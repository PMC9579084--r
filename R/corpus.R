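#' @importFrom Matrix sparseMatrix rowSums colSums t Diagonal
#' @importFrom stats cor rnorm runif optim nlminb quantile sd var lm pt pf pchisq qnorm uniroot setNames aggregate
#' @importFrom utils head read.csv write.csv
NULL

# -- tolerances used across the package ---------------------------------------
#' Numerical tolerances and defaults
#'
#' Named constants governing the numerical behaviour of the package:
#' `rotation_tol` (1e-8) for cosine preservation under change of basis,
#' `gs_tol` (1e-10) for Gram-Schmidt orthonormality and degeneracy detection,
#' `collinear_tol` (0.999) absolute cosine above which a general-factor vector
#' is rejected as collinear with a concept vector, and `fidelity_default`
#' (0.80) the reliability gate on pre/post orthogonalization correlation.
#'
#' @format A named list.
#' @export
ir_tolerances <- list(
  rotation_tol  = 1e-8,
  gs_tol        = 1e-10,
  collinear_tol = 0.999,
  fidelity_default = 0.80
)

#' Construct a corpus of tokenized documents
#'
#' A corpus is an ordered list of token sequences (pre-lemmatized, lowercase)
#' with unique document identifiers. Tokenization elsewhere in the package is
#' whitespace splitting only: corpora are assumed already lemmatized, as is
#' standard when training LSA spaces for automated assessment.
#'
#' @param documents list of character vectors (tokens), or a character vector
#'   of raw document strings which will be whitespace-tokenized.
#' @param doc_ids character vector of unique labels; defaults to `doc1..docN`.
#' @return An object of class `ir_corpus`: list with `documents`, `doc_ids`,
#'   and `empty` (logical flag per document).
#' @export
ir_corpus <- function(documents, doc_ids = NULL) {
  if (is.character(documents)) {
    documents <- lapply(documents, tokenize_text)
  }
  if (!is.list(documents)) stop("`documents` must be a list of token vectors")
  n <- length(documents)
  if (n == 0L) stop("empty corpus")
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_len(n))
  if (anyDuplicated(doc_ids)) stop("doc_ids must be unique")
  if (length(doc_ids) != n) stop("doc_ids length must match documents")
  documents <- lapply(documents, as.character)
  structure(
    list(documents = documents, doc_ids = as.character(doc_ids),
         empty = vapply(documents, function(d) length(d) == 0L, logical(1))),
    class = "ir_corpus"
  )
}

#' @export
print.ir_corpus <- function(x, ...) {
  cat(sprintf("<ir_corpus> %d documents (%d empty), %d tokens total\n",
              length(x$documents), sum(x$empty),
              sum(lengths(x$documents))))
  invisible(x)
}

#' @export
length.ir_corpus <- function(x) length(x$documents)

#' Whitespace tokenizer for pre-lemmatized text
#'
#' @param text character scalar or vector; each element is one document.
#' @return character vector of tokens (single input) or list of such vectors.
#' @export
tokenize_text <- function(text) {
  out <- lapply(text, function(s) {
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    toks[nzchar(toks)]
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Read a corpus from disk
#'
#' Either a single UTF-8 text file with one document per line, or a directory
#' of `.txt` files (one document per file, file name stem used as doc_id).
#'
#' @param path file or directory path.
#' @return An [ir_corpus()].
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) stop("no .txt files in ", path)
    docs <- lapply(files, function(f)
      tokenize_text(paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                          collapse = " ")))
    ir_corpus(docs, doc_ids = sub("\\.txt$", "", basename(files)))
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    ir_corpus(lapply(lines, tokenize_text))
  }
}

#' Build a term-document count matrix
#'
#' Counts term frequencies per document and drops terms appearing in fewer
#' than `min_doc_freq` documents. The default of 2 excludes single-document
#' terms, whose log-entropy global weight is exactly 1 and which can therefore
#' dominate concept vectors; set `min_doc_freq = 1` to admit them.
#'
#' @param corpus an [ir_corpus()].
#' @param min_doc_freq minimum number of documents a term must occur in.
#' @return An object of class `ir_tdm`: list with `counts` (sparse
#'   term x document `dgCMatrix`), `vocabulary`, `doc_ids`, and
#'   `dropped_terms` (terms removed by the document-frequency filter).
#' @export
build_term_doc_matrix <- function(corpus, min_doc_freq = 2L) {
  stopifnot(inherits(corpus, "ir_corpus"))
  if (all(corpus$empty)) stop("empty corpus")
  docs <- corpus$documents
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  if (length(vocab) == 0L) stop("empty corpus")
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (d in seq_along(docs)) {
    if (length(docs[[d]]) == 0L) next
    tab <- table(docs[[d]])
    ii <- c(ii, match(names(tab), vocab))
    jj <- c(jj, rep.int(d, length(tab)))
    xx <- c(xx, as.integer(tab))
  }
  counts <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(length(vocab), length(docs)),
                                 dimnames = list(vocab, corpus$doc_ids))
  df <- Matrix::rowSums(counts > 0)
  keep <- df >= min_doc_freq
  dropped <- vocab[!keep]
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L)
    warning("all terms dropped by min_doc_freq = ", min_doc_freq)
  structure(
    list(counts = counts, vocabulary = rownames(counts),
         doc_ids = corpus$doc_ids, dropped_terms = dropped,
         min_doc_freq = as.integer(min_doc_freq)),
    class = "ir_tdm"
  )
}

#' @export
print.ir_tdm <- function(x, ...) {
  cat(sprintf("<ir_tdm> %d terms x %d documents (%d terms dropped, min_doc_freq = %d)\n",
              nrow(x$counts), ncol(x$counts), length(x$dropped_terms),
              x$min_doc_freq))
  invisible(x)
}

#' Log-entropy weighting of a term-document matrix
#'
#' The standard LSA weighting: entry `(t, d)` becomes
#' `log(1 + f_td) * g_t` where the global weight
#' `g_t = 1 + sum_d p_td log(p_td) / log(n_docs)` with
#' `p_td = f_td / sum_d f_td`. A term concentrated in a single document gets
#' weight 1; a term spread uniformly over all documents gets weight 0. The
#' entropy ratio is invariant to logarithm base; natural logarithms are used.
#'
#' @param tdm an `ir_tdm`.
#' @return list with `weighted` (sparse term x document matrix) and
#'   `global_weights` (named numeric in `[0, 1]`).
#' @export
log_entropy_weight <- function(tdm) {
  stopifnot(inherits(tdm, "ir_tdm"))
  counts <- tdm$counts
  n_docs <- ncol(counts)
  if (n_docs < 2L)
    stop("log-entropy weighting needs at least 2 documents (log(n) = 0 otherwise)")
  if (nrow(counts) == 0L) stop("no terms in matrix")
  row_tot <- Matrix::rowSums(counts)
  trip <- Matrix::summary(counts)         # i, j, x triplets
  p <- trip$x / row_tot[trip$i]
  plogp <- p * log(p)                     # p > 0 always on stored entries
  ent <- rep(0, nrow(counts))
  agg <- tapply(plogp, trip$i, sum)
  ent[as.integer(names(agg))] <- agg
  gw <- 1 + ent / log(n_docs)
  gw <- pmin(pmax(gw, 0), 1)              # clamp fp dust at the boundaries
  names(gw) <- rownames(counts)
  local <- counts
  local@x <- log1p(local@x)
  weighted <- Matrix::Diagonal(x = gw) %*% local
  dimnames(weighted) <- dimnames(counts)
  list(weighted = weighted, global_weights = gw)
}

#' Train a latent semantic space by truncated SVD
#'
#' Computes the rank-`k` truncated singular value decomposition of the
#' weighted term-document matrix `X ~ U_k S_k V_k'` and stores term vectors as
#' the rows of `U_k S_k` (the "US" matrix); `V` is discarded. New documents
#' are represented by fold-in, i.e. sums of term vectors ([fold_in()]).
#'
#' @param weighted term x document matrix (sparse or dense) from
#'   [log_entropy_weight()], or the list that function returns.
#' @param k number of retained dimensions; must not exceed
#'   `min(n_terms, n_docs)`.
#' @param global_weights optional named per-term weights carried into the
#'   space for weighted fold-in (taken automatically when `weighted` is the
#'   list returned by [log_entropy_weight()]).
#' @return An object of class `semantic_space`: `term_vectors`
#'   (term x k dense matrix), `singular_values`, `vocabulary`, `k`,
#'   `global_weights`.
#' @export
train_space <- function(weighted, k, global_weights = NULL) {
  if (is.list(weighted) && !is.null(weighted$weighted)) {
    if (is.null(global_weights)) global_weights <- weighted$global_weights
    weighted <- weighted$weighted
  }
  X <- as.matrix(weighted)
  if (!all(is.finite(X))) stop("weighted matrix must be finite")
  if (k < 1L || k > min(dim(X)))
    stop("k must satisfy 1 <= k <= min(#terms, #docs); got k = ", k)
  sv <- svd(X, nu = k, nv = 0)
  d <- sv$d[seq_len(k)]
  if (any(d < 0)) stop("negative singular value (numerical failure)")
  term_vectors <- sv$u %*% diag(d, nrow = k)
  rownames(term_vectors) <- rownames(X)
  colnames(term_vectors) <- paste0("dim", seq_len(k))
  if (is.null(global_weights)) {
    global_weights <- rep(1, nrow(X)); names(global_weights) <- rownames(X)
  }
  structure(
    list(term_vectors = term_vectors, singular_values = d,
         vocabulary = rownames(X), k = as.integer(k),
         global_weights = global_weights),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("<semantic_space> %d terms, k = %d (sigma_1 = %.3g, sigma_k = %.3g)\n",
              length(x$vocabulary), x$k,
              x$singular_values[1], x$singular_values[x$k]))
  invisible(x)
}

#' Project a document into a semantic space (fold-in)
#'
#' A document vector is the sum of its in-vocabulary tokens' term vectors, the
#' usual bag-of-words fold-in. Out-of-vocabulary tokens are skipped and
#' counted. With `weight_terms = TRUE` each term vector is multiplied by its
#' log-entropy global weight before summation; the unweighted sum is the
#' default.
#'
#' @param tokens character vector of tokens (or a string, tokenized on
#'   whitespace).
#' @param space a `semantic_space` or `meaningful_space`.
#' @param weight_terms multiply each term vector by its global weight.
#' @return numeric k-vector with attributes `n_oov` (count of skipped tokens)
#'   and `n_tokens`.
#' @export
fold_in <- function(tokens, space, weight_terms = FALSE) {
  if (length(tokens) == 1L && is.character(tokens) && grepl("\\s", tokens))
    tokens <- tokenize_text(tokens)
  tv <- space$term_vectors
  idx <- match(tokens, rownames(tv))
  oov <- is.na(idx)
  v <- numeric(ncol(tv))
  if (any(!oov)) {
    hit <- idx[!oov]
    if (weight_terms) {
      w <- space$global_weights[hit]
      v <- as.numeric(crossprod(tv[hit, , drop = FALSE], w))
    } else {
      v <- colSums(tv[hit, , drop = FALSE])
    }
  } else if (length(tokens) > 0L) {
    warning("all tokens out of vocabulary; returning zero vector")
  }
  names(v) <- colnames(tv)
  attr(v, "n_oov") <- sum(oov)
  attr(v, "n_tokens") <- length(tokens)
  v
}

#' Cosine similarity
#'
#' @param v1,v2 numeric vectors of equal length; both must be nonzero.
#' @return cosine similarity in `[-1, 1]`.
#' @export
cosine <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("undefined cosine: zero vector")
  min(max(sum(v1 * v2) / (n1 * n2), -1), 1)
}

#' Persist a semantic space as plain text
#'
#' Writes `vocabulary.txt`, `term_vectors.mtx` (MatrixMarket) and a
#' `space.json` sidecar (k, singular values, global weights).
#'
#' @param space a `semantic_space`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_space <- function(space, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(space$vocabulary, file.path(dir, "vocabulary.txt"))
  Matrix::writeMM(Matrix::Matrix(space$term_vectors, sparse = TRUE),
                  file.path(dir, "term_vectors.mtx"))
  jsonlite::write_json(
    list(k = space$k, singular_values = space$singular_values,
         global_weights = as.list(space$global_weights)),
    file.path(dir, "space.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Load a semantic space written by [write_space()]
#' @param dir directory containing `vocabulary.txt`, `term_vectors.mtx`,
#'   `space.json`.
#' @return a `semantic_space`.
#' @export
read_space <- function(dir) {
  vocab <- readLines(file.path(dir, "vocabulary.txt"))
  tv <- as.matrix(Matrix::readMM(file.path(dir, "term_vectors.mtx")))
  meta <- jsonlite::read_json(file.path(dir, "space.json"),
                              simplifyVector = TRUE)
  rownames(tv) <- vocab
  colnames(tv) <- paste0("dim", seq_len(ncol(tv)))
  gw <- unlist(meta$global_weights)
  structure(
    list(term_vectors = tv, singular_values = as.numeric(meta$singular_values),
         vocabulary = vocab, k = as.integer(meta$k), global_weights = gw),
    class = "semantic_space"
  )
}
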