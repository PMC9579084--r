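# Rubric representation and concept-vector construction.
#
# A rubric concept is defined either by a handful of expert-chosen lexical
# descriptors (classic variant; about three per concept is usually enough) or
# by the nouns embedded in a fragment of the instructional text (automatic
# variant). Either way the concept vector is the sum of the corresponding
# term vectors, normalized once after summation.

#' Construct a rubric
#'
#' @param concepts list of concepts created by [ir_concept()].
#' @param text_id label for the instructional text the rubric belongs to.
#' @return An object of class `ir_rubric`.
#' @export
ir_rubric <- function(concepts, text_id = "text1") {
  if (length(concepts) < 1L) stop("a rubric needs at least one concept")
  nms <- vapply(concepts, function(cc) cc$name, character(1))
  if (anyDuplicated(nms)) stop("concept names must be unique")
  structure(list(concepts = concepts, text_id = text_id,
                 concept_names = nms),
            class = "ir_rubric")
}

#' Construct a rubric concept
#'
#' @param name concept label.
#' @param descriptors character vector of lemmas (classic variant).
#' @param fragment_nouns character vector of lemmas extracted from an
#'   instructional-text fragment (automatic variant); duplicates are allowed
#'   and, by default, each occurrence contributes to the concept vector.
#' @param max_score maximum rubric score for the concept (default 2, the
#'   usual 0-2 conceptual-axis scale).
#' @return An object of class `ir_concept`.
#' @export
ir_concept <- function(name, descriptors = character(0),
                       fragment_nouns = character(0), max_score = 2) {
  descriptors <- tolower(as.character(descriptors))
  fragment_nouns <- tolower(as.character(fragment_nouns))
  if (length(descriptors) == 0L && length(fragment_nouns) == 0L)
    stop("concept '", name, "' needs descriptors or fragment_nouns")
  if (max_score < 0) stop("max_score must be nonnegative")
  if (length(descriptors) > 0L && length(descriptors) != 3L)
    # three descriptors per concept is the usual working recipe; more or
    # fewer is legal but worth flagging to the rubric designer
    message("note: concept '", name, "' has ", length(descriptors),
            " descriptors (3 is typical)")
  structure(list(name = name, descriptors = descriptors,
                 fragment_nouns = fragment_nouns, max_score = max_score),
            class = "ir_concept")
}

#' @export
print.ir_rubric <- function(x, ...) {
  cat(sprintf("<ir_rubric> '%s': %d concepts\n", x$text_id,
              length(x$concepts)))
  for (cc in x$concepts)
    cat(sprintf("  %s (max %g): %d descriptors, %d fragment nouns\n",
                cc$name, cc$max_score, length(cc$descriptors),
                length(cc$fragment_nouns)))
  invisible(x)
}

#' Read a rubric from YAML or JSON
#'
#' Expected shape: `text_id`, and `concepts`, a list of entries each with
#' `name`, optional `max_score`, `descriptors` and/or `fragment_nouns`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return An [ir_rubric()].
#' @export
read_rubric <- function(path) {
  spec <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  concepts <- lapply(spec$concepts, function(cc) {
    suppressMessages(ir_concept(
      name = cc$name,
      descriptors = unlist(cc$descriptors %||% character(0)),
      fragment_nouns = unlist(cc$fragment_nouns %||% character(0)),
      max_score = cc$max_score %||% 2))
  })
  ir_rubric(concepts, text_id = spec$text_id %||% "text1")
}

#' Write a rubric to YAML
#' @param rubric an [ir_rubric()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rubric <- function(rubric, path) {
  spec <- list(
    text_id = rubric$text_id,
    concepts = lapply(rubric$concepts, function(cc) {
      out <- list(name = cc$name, max_score = cc$max_score)
      if (length(cc$descriptors)) out$descriptors <- as.list(cc$descriptors)
      if (length(cc$fragment_nouns))
        out$fragment_nouns <- as.list(cc$fragment_nouns)
      out
    }))
  yaml::write_yaml(spec, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared worker: unit-normalized multiset sum of term vectors
concept_vector_from_terms <- function(space, terms, concept_name, source,
                                      prenormalize_terms = FALSE,
                                      unique_terms = FALSE, strict = FALSE) {
  if (unique_terms) terms <- unique(terms)
  idx <- match(terms, space$vocabulary)
  oov <- terms[is.na(idx)]
  used <- idx[!is.na(idx)]
  if (length(used) == 0L)
    stop("concept '", concept_name, "': all terms out of vocabulary (",
         paste(oov, collapse = ", "), ")")
  if (length(oov) > 0L) {
    msg <- paste0("concept '", concept_name, "': dropping OOV terms: ",
                  paste(unique(oov), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  tv <- space$term_vectors[used, , drop = FALSE]
  if (prenormalize_terms) {
    nr <- sqrt(rowSums(tv^2))
    tv <- tv / nr
  }
  v <- colSums(tv)
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12)
    stop("concept '", concept_name, "': term vectors cancel to zero")
  structure(
    list(concept_name = concept_name, vector = v / nv, source = source,
         n_terms_used = length(used), oov_terms = unique(oov)),
    class = "concept_vector"
  )
}

#' Concept vector from lexical descriptors
#'
#' Sums the term vectors of the concept's lexical descriptors and normalizes
#' the sum to unit length (normalization happens once, after summation;
#' component vectors are left at their natural U*S magnitudes unless
#' `prenormalize_terms` is set, so frequent and strongly represented terms
#' carry more weight).
#'
#' @param space a `semantic_space`.
#' @param concept an [ir_concept()] with non-empty `descriptors`.
#' @param prenormalize_terms normalize each term vector before summation.
#' @param strict error (rather than warn) on out-of-vocabulary descriptors.
#' @return An object of class `concept_vector`: `concept_name`, unit-norm
#'   `vector`, `source = "descriptors"`, `n_terms_used`, `oov_terms`.
#' @export
concept_vector_from_descriptors <- function(space, concept,
                                            prenormalize_terms = FALSE,
                                            strict = FALSE) {
  if (length(concept$descriptors) == 0L)
    stop("concept '", concept$name, "' has no descriptors")
  concept_vector_from_terms(space, concept$descriptors, concept$name,
                            "descriptors",
                            prenormalize_terms = prenormalize_terms,
                            strict = strict)
}

#' Concept vector from instructional-text fragment nouns
#'
#' Identical construction to [concept_vector_from_descriptors()] but over the
#' (typically longer) list of nouns embedded in a fragment of the
#' instructional text. By default a noun repeated in the fragment contributes
#' once per occurrence (multiset sum); `unique_terms = TRUE` collapses to a
#' set.
#'
#' @inheritParams concept_vector_from_descriptors
#' @param unique_terms collapse repeated nouns before summation.
#' @return A `concept_vector` with `source = "fragment_nouns"`.
#' @export
concept_vector_from_fragment <- function(space, concept,
                                         prenormalize_terms = FALSE,
                                         unique_terms = FALSE,
                                         strict = FALSE) {
  if (length(concept$fragment_nouns) == 0L)
    stop("concept '", concept$name, "' has no fragment_nouns")
  concept_vector_from_terms(space, concept$fragment_nouns, concept$name,
                            "fragment_nouns",
                            prenormalize_terms = prenormalize_terms,
                            unique_terms = unique_terms, strict = strict)
}

#' Build all concept vectors of a rubric
#'
#' @param space a `semantic_space`.
#' @param rubric an [ir_rubric()].
#' @param source `"descriptors"` or `"fragments"`.
#' @param ... passed to the per-concept constructors.
#' @return list of `concept_vector` objects, one per rubric concept, in
#'   rubric order.
#' @export
concept_vectors <- function(space, rubric,
                            source = c("descriptors", "fragments"), ...) {
  source <- match.arg(source)
  lapply(rubric$concepts, function(cc) {
    if (source == "descriptors") {
      concept_vector_from_descriptors(space, cc, ...)
    } else {
      concept_vector_from_fragment(space, cc, ...)
    }
  })
}

#' Semantic neighborhood of a concept vector
#'
#' Ranks vocabulary terms by cosine to the concept vector, the standard check
#' that a concept's descriptors mean what the designer intends in the trained
#' space. Ties are broken lexicographically.
#'
#' @param space a `semantic_space`.
#' @param cv a `concept_vector` (or any numeric k-vector).
#' @param n number of neighbors to return; `n >=` vocabulary size returns the
#'   full ranking.
#' @return data.frame with columns `term` and `cosine`, sorted descending.
#' @export
neighborhood_check <- function(space, cv, n = 10L) {
  v <- if (inherits(cv, "concept_vector")) cv$vector else as.numeric(cv)
  tv <- space$term_vectors
  norms <- sqrt(rowSums(tv^2))
  ok <- norms > 0
  cosines <- as.numeric(tv[ok, , drop = FALSE] %*% v) /
    (norms[ok] * sqrt(sum(v^2)))
  terms <- rownames(tv)[ok]
  ord <- order(-cosines, terms)
  n <- min(n, length(terms))
  data.frame(term = terms[ord][seq_len(n)],
             cosine = cosines[ord][seq_len(n)],
             stringsAsFactors = FALSE)
}
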