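# Projection scoring: a constructed response folded into the meaningful
# space yields, in its leading coordinates, the extent to which it covers
# each rubric concept (plus the general dimension in the bifactor variant).

#' Score one document by projection
#'
#' Folds the document into the meaningful space and reads the leading
#' meaningful coordinates as concept (and general) scores. Raw coordinates
#' may be negative and are not floored or rescaled: downstream validity
#' analyses consume them as-is. With `normalize = "unit"` the document vector
#' is scaled to unit length before reading coordinates, removing the
#' correlation of raw scores with document length.
#'
#' @param mspace a `meaningful_space`.
#' @param tokens character vector of tokens (or a whitespace-joined string).
#' @param normalize `"none"` (default) or `"unit"`.
#' @param weight_terms weight tokens by their global entropy weight during
#'   fold-in.
#' @return named numeric vector over the meaningful labels, with attributes
#'   `n_oov`, `n_tokens`, and `flagged` (TRUE when the document is empty or
#'   all tokens are out of vocabulary).
#' @export
score_document <- function(mspace, tokens, normalize = c("none", "unit"),
                           weight_terms = FALSE) {
  normalize <- match.arg(normalize)
  v <- suppressWarnings(fold_in(tokens, mspace, weight_terms = weight_terms))
  nv <- sqrt(sum(v^2))
  flagged <- nv == 0
  if (normalize == "unit" && nv > 0) v <- v / nv
  s <- v[seq_along(mspace$meaningful_labels)]
  names(s) <- mspace$meaningful_labels
  attr(s, "n_oov") <- attr(v, "n_oov")
  attr(s, "n_tokens") <- attr(v, "n_tokens")
  attr(s, "flagged") <- flagged
  s
}

#' Score a corpus of constructed responses
#'
#' Row-wise [score_document()] over a corpus, preserving document order.
#' Rows whose out-of-vocabulary rate exceeds `oov_threshold` are flagged as
#' unreliable but kept.
#'
#' @param mspace a `meaningful_space`.
#' @param corpus an [ir_corpus()] (unique doc_ids required).
#' @param normalize `"none"` or `"unit"`.
#' @param weight_terms weight tokens by global entropy weight.
#' @param oov_threshold OOV rate above which a row is flagged (default 0.5).
#' @return An object of class `score_table`: a data.frame with `doc_id`,
#'   one `score__<label>` column per meaningful dimension, `oov_rate`, and
#'   `flagged`; attributes record variant metadata.
#' @export
score_corpus <- function(mspace, corpus, normalize = c("none", "unit"),
                         weight_terms = FALSE, oov_threshold = 0.5) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(corpus, "ir_corpus"))
  if (anyDuplicated(corpus$doc_ids)) stop("duplicate doc_ids")
  labs <- mspace$meaningful_labels
  n <- length(corpus$documents)
  scores <- matrix(0, n, length(labs),
                   dimnames = list(NULL, paste0("score__", labs)))
  oov_rate <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    s <- score_document(mspace, corpus$documents[[i]], normalize = normalize,
                        weight_terms = weight_terms)
    scores[i, ] <- as.numeric(s)
    nt <- attr(s, "n_tokens")
    oov_rate[i] <- if (nt > 0) attr(s, "n_oov") / nt else 1
    flagged[i] <- attr(s, "flagged") || oov_rate[i] > oov_threshold
  }
  out <- data.frame(doc_id = corpus$doc_ids, scores, oov_rate = oov_rate,
                    flagged = flagged, stringsAsFactors = FALSE,
                    check.names = FALSE)
  structure(out,
            class = c("score_table", "data.frame"),
            meaningful_labels = labs,
            variant = if (isTRUE(mspace$has_general)) "bifactor" else "classic",
            normalize = normalize)
}

#' Extract the score matrix from a score table
#' @param st a `score_table`.
#' @param general include the general column if present (default TRUE).
#' @return numeric matrix (documents x meaningful dimensions) with doc_ids
#'   as rownames and plain concept labels as colnames.
#' @export
score_matrix <- function(st, general = TRUE) {
  labs <- attr(st, "meaningful_labels")
  cols <- paste0("score__", labs)
  m <- as.matrix(st[, cols, drop = FALSE])
  colnames(m) <- labs
  rownames(m) <- st$doc_id
  if (!general && identical(attr(st, "variant"), "bifactor"))
    m <- m[, colnames(m) != "G", drop = FALSE]
  m
}

#' Write / read score tables as CSV
#'
#' UTF-8, header row, `.` decimal separator; one row per document.
#'
#' @param st a `score_table`.
#' @param path output file.
#' @return `path` (write) or a `score_table` (read), invisibly for write.
#' @export
write_score_table <- function(st, path) {
  utils::write.csv(as.data.frame(st), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  labs <- sub("^score__", "", grep("^score__", names(df), value = TRUE))
  structure(df, class = c("score_table", "data.frame"),
            meaningful_labels = labs,
            variant = if ("score__G" %in% names(df)) "bifactor" else "classic")
}

#' Run the full pipeline from a configuration list
#'
#' End-to-end driver: read/accept a corpus, train the space, build the rubric
#' concept vectors, assemble and orthogonalize the basis, rotate, score the
#' response documents, and (when ratings are supplied) run the validation
#' battery. Deterministic given the seeds in the config; artifacts carry
#' provenance metadata (config hash, seeds, package version).
#'
#' @param config named list (or YAML file path) with fields:
#'   `corpus` (path or `ir_corpus`), `responses` (path or `ir_corpus`),
#'   `rubric` (path or `ir_rubric`), `k` (space dimensions),
#'   `min_doc_freq` (default 2), `variant` (`"classic"`/`"bifactor"`),
#'   `source` (`"descriptors"`/`"fragments"`), `general_position`,
#'   `normalize` (`"none"`/`"unit"`), `seed`, optional `ratings`
#'   (path or `rating_table`) and `out_dir` for artifact writing.
#' @return list with `space`, `mspace`, `scores` (a `score_table`),
#'   optional `validation`, and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  req <- c("corpus", "responses", "rubric", "k")
  missing_f <- setdiff(req, names(config))
  if (length(missing_f))
    stop("config missing field(s): ", paste(missing_f, collapse = ", "))
  variant <- match.arg(config$variant %||% "classic",
                       c("classic", "bifactor"))
  source <- match.arg(config$source %||% "descriptors",
                      c("descriptors", "fragments"))
  normalize <- match.arg(config$normalize %||% "none", c("none", "unit"))
  seed <- as.integer(config$seed %||% 1L)

  corpus <- if (inherits(config$corpus, "ir_corpus")) config$corpus
            else read_corpus(config$corpus)
  responses <- if (inherits(config$responses, "ir_corpus")) config$responses
               else read_corpus(config$responses)
  rubric <- if (inherits(config$rubric, "ir_rubric")) config$rubric
            else read_rubric(config$rubric)

  tdm <- build_term_doc_matrix(corpus,
                               min_doc_freq = config$min_doc_freq %||% 2L)
  lw <- log_entropy_weight(tdm)
  space <- train_space(lw, k = as.integer(config$k))
  mspace <- build_meaningful_space(
    space, rubric, variant = variant, source = source,
    general_position = config$general_position %||% "after_concepts",
    seed = seed,
    strict_fidelity = isTRUE(config$strict_fidelity))
  scores <- score_corpus(mspace, responses, normalize = normalize)

  validation <- NULL
  if (!is.null(config$ratings)) {
    ratings <- if (inherits(config$ratings, "rating_table")) config$ratings
               else read_rating_table(config$ratings)
    validation <- validation_report(scores, ratings)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("inbuiltr")),
    seed = seed, variant = variant, source = source, normalize = normalize,
    k = as.integer(config$k),
    config_hash = config_hash(config),
    fidelity = as.list(mspace$fidelity))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_score_table(scores, file.path(config$out_dir, "scores.csv"))
    jsonlite::write_json(provenance,
                         file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(validation))
      jsonlite::write_json(validation,
                           file.path(config$out_dir, "validation.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(space = space, mspace = mspace, scores = scores,
       validation = validation, provenance = provenance)
}

# stable hash of the scientific config for provenance (no external digest
# dependency); purely I/O fields are excluded so the hash identifies the
# analysis, not where its artifacts land
config_hash <- function(config) {
  config$out_dir <- NULL
  canon <- function(x) {
    if (inherits(x, c("ir_corpus", "ir_rubric", "rating_table")))
      return(paste0("<object:", class(x)[1], ">"))
    if (is.list(x)) {
      x <- x[order(names(x))]
      return(lapply(x, canon))
    }
    x
  }
  s <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  # polynomial rolling hash over the serialized config (mod 2^31 - 1)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
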