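# Human rating tables: document x rater x concept scores on the rubric
# scale (0..max_score per concept), stored long, one row per
# (doc, rater, concept).

#' Construct a rating table
#'
#' @param df data.frame with columns `doc_id`, `rater_id`, `concept`,
#'   `score`.
#' @param scale_max named numeric vector of per-concept maxima (default 2
#'   for every concept present).
#' @return An object of class `rating_table` (a long data.frame) with
#'   attributes `concepts`, `raters`, `scale_max`.
#' @export
rating_table <- function(df, scale_max = NULL) {
  req <- c("doc_id", "rater_id", "concept", "score")
  if (!all(req %in% names(df)))
    stop("rating table needs columns: ", paste(req, collapse = ", "))
  df <- df[, req]
  df$doc_id <- as.character(df$doc_id)
  df$rater_id <- as.character(df$rater_id)
  df$concept <- as.character(df$concept)
  concepts <- unique(df$concept)
  raters <- sort(unique(df$rater_id))
  # every rater must score the same concept set
  tab <- table(df$rater_id, df$concept)
  if (any(tab == 0)) stop("every rater must score every concept")
  if (is.null(scale_max))
    scale_max <- stats::setNames(rep(2, length(concepts)), concepts)
  for (cc in concepts) {
    s <- df$score[df$concept == cc]
    if (any(s < 0 | s > scale_max[[cc]]))
      stop("scores for concept '", cc, "' outside [0, ", scale_max[[cc]], "]")
  }
  structure(df, class = c("rating_table", "data.frame"),
            concepts = concepts, raters = raters, scale_max = scale_max)
}

#' Read / write rating tables (long CSV)
#'
#' Long format: `doc_id, rater_id, concept, score`; UTF-8, `.` decimal.
#'
#' @param path CSV file.
#' @return A [rating_table()].
#' @export
read_rating_table <- function(path) {
  rating_table(utils::read.csv(path, fileEncoding = "UTF-8"))
}

#' @rdname read_rating_table
#' @param rt a `rating_table`.
#' @export
write_rating_table <- function(rt, path) {
  utils::write.csv(as.data.frame(rt), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Targets x raters matrix for one concept
#'
#' The slice consumed by [icc_two_way_mixed()]; use `concept = "total"` for
#' per-rater total scores (sum over concepts).
#'
#' @param rt a `rating_table`.
#' @param concept concept name or `"total"`.
#' @return numeric matrix, documents x raters.
#' @export
ratings_matrix <- function(rt, concept) {
  raters <- attr(rt, "raters")
  docs <- unique(rt$doc_id)
  out <- matrix(NA_real_, length(docs), length(raters),
                dimnames = list(docs, raters))
  if (identical(concept, "total")) {
    agg <- stats::aggregate(score ~ doc_id + rater_id, data = rt, FUN = sum)
    for (r in seq_len(nrow(agg)))
      out[agg$doc_id[r], agg$rater_id[r]] <- agg$score[r]
  } else {
    sub <- rt[rt$concept == concept, ]
    if (nrow(sub) == 0L) stop("unknown concept: ", concept)
    out[cbind(sub$doc_id, sub$rater_id)] <- sub$score
  }
  out
}

#' Wide documents x (rater, concept) matrix
#'
#' Column names are `<rater>_<concept>` (concept names made syntactic), the
#' variable layout used for parallel analysis, EFA, and the SEM human side.
#'
#' @param rt a `rating_table`.
#' @return numeric matrix with doc_ids as rownames.
#' @export
ratings_wide <- function(rt) {
  raters <- attr(rt, "raters")
  concepts <- attr(rt, "concepts")
  docs <- unique(rt$doc_id)
  cols <- as.vector(outer(raters, make.names(concepts), paste, sep = "_"))
  out <- matrix(NA_real_, length(docs), length(cols),
                dimnames = list(docs, cols))
  for (r in seq_len(nrow(rt))) {
    out[rt$doc_id[r], paste0(rt$rater_id[r], "_",
                             make.names(rt$concept[r]))] <- rt$score[r]
  }
  out
}

#' Mean rating per document and concept
#' @param rt a `rating_table`.
#' @return numeric matrix, documents x concepts (mean across raters).
#' @export
mean_ratings <- function(rt) {
  concepts <- attr(rt, "concepts")
  docs <- unique(rt$doc_id)
  out <- matrix(NA_real_, length(docs), length(concepts),
                dimnames = list(docs, concepts))
  agg <- stats::aggregate(score ~ doc_id + concept, data = rt, FUN = mean)
  out[cbind(agg$doc_id, agg$concept)] <- agg$score
  out
}

#' Validation battery for computational scores against human ratings
#'
#' Runs, in order: inter-rater ICCs per concept and for the total score;
#' parallel analysis of the wide human rating matrix; an EFA with as many
#' factors as concepts (oblimin, factor scores retained); and one
#' standardized-beta regression per concept of the human factor score on all
#' computational concept scores. Factors are matched to concepts by their
#' largest mean loading. Optionally fits the cross-loading SEM.
#'
#' @param scores a `score_table`.
#' @param ratings a `rating_table` covering the same doc_ids.
#' @param icc_type,icc_definition passed to [icc_two_way_mixed()].
#' @param include_sem also fit the cross-loading structural model (slower).
#' @param pa_seed seed for the parallel-analysis simulation.
#' @return list with `icc` (data.frame), `parallel` (a `pa_result`),
#'   `efa` (an `efa_result`), `regressions` (data.frame of standardized
#'   betas, one row per human concept), and optionally `sem` (a `sem_fit`).
#' @export
validation_report <- function(scores, ratings, icc_type = "single",
                              icc_definition = "consistency",
                              include_sem = FALSE, pa_seed = 1L) {
  concepts <- attr(ratings, "concepts")
  icc_rows <- lapply(c(concepts, "total"), function(cc) {
    res <- tryCatch(
      icc_two_way_mixed(ratings_matrix(ratings, cc), type = icc_type,
                        definition = icc_definition),
      error = function(e) NULL)
    data.frame(concept = cc,
               icc = if (is.null(res)) NA_real_ else res$icc,
               F = if (is.null(res)) NA_real_ else res$F,
               p = if (is.null(res)) NA_real_ else res$p)
  })
  icc_df <- do.call(rbind, icc_rows)

  hw <- ratings_wide(ratings)
  pa <- parallel_analysis(hw, seed = pa_seed)
  ef <- efa(hw, n_factors = length(concepts), rotation = "oblimin",
            estimator = "ml")

  # match EFA factors to concepts by mean loading of the concept's
  # rater variables
  fmatch <- integer(length(concepts))
  avail <- rep(TRUE, length(concepts))
  for (ci in seq_along(concepts)) {
    rows <- grepl(paste0("_", make.names(concepts[ci]), "$"),
                  rownames(ef$loadings))
    ml <- colMeans(abs(ef$loadings[rows, , drop = FALSE]))
    ml[!avail] <- -Inf
    fmatch[ci] <- which.max(ml)
    avail[fmatch[ci]] <- FALSE
  }

  sm <- score_matrix(scores, general = FALSE)
  sm <- sm[match(rownames(hw), rownames(sm)), , drop = FALSE]
  reg_rows <- lapply(seq_along(concepts), function(ci) {
    res <- standardized_regression(ef$scores[, fmatch[ci]], sm)
    out <- data.frame(concept = concepts[ci], r_squared = res$r_squared)
    for (j in seq_along(res$beta)) {
      out[[paste0("beta_", colnames(sm)[j])]] <- res$beta[j]
    }
    out
  })
  regs <- do.call(rbind, reg_rows)

  out <- list(icc = icc_df, parallel = pa, efa = ef, regressions = regs)
  if (include_sem)
    out$sem <- fit_sem_crossloading(
      scores, ratings,
      structure = if (identical(attr(scores, "variant"), "bifactor"))
        "bifactor" else "classic")
  out
}
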