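# Assembly and orthogonalization of the change-of-basis matrix ("beta"):
# the leading columns hold unit concept vectors (plus, in the bifactor
# variant, a general-knowledge vector), the remaining columns are standard
# basis vectors drawn at random, and the whole matrix is orthonormalized by
# modified Gram-Schmidt before rotating the space.

#' Assemble the change-of-basis matrix (classic form)
#'
#' Places the `k` unit concept vectors in the leading columns and completes
#' the basis up to the space dimensionality `p` with `p - k` standard-basis
#' vectors drawn uniformly at random without replacement. The draw is
#' deterministic given `seed`.
#'
#' @param space a `semantic_space` (its `k` is the dimensionality `p` here).
#' @param concept_vectors list of `concept_vector` objects (unit norm).
#' @param seed integer seed for the standard-basis fill draw.
#' @return An object of class `beta_matrix`: `columns` (p x p),
#'   `meaningful_labels`, `k` (number of concept columns), `has_general`,
#'   `fill_indices`, `seed`, `orthonormal = FALSE`.
#' @export
assemble_beta <- function(space, concept_vectors, seed = 1L) {
  p <- space$k
  k <- length(concept_vectors)
  if (k < 1L) stop("need at least one concept vector")
  if (k >= p) stop("number of concepts (", k, ") must be < space dimension (", p, ")")
  V <- vapply(concept_vectors, function(cv) {
    v <- cv$vector
    if (length(v) != p) stop("concept vector has wrong dimension")
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) stop("zero concept vector: ", cv$concept_name)
    if (abs(nv - 1) > 1e-8) v <- v / nv
    v
  }, numeric(p))
  labels <- vapply(concept_vectors, function(cv) cv$concept_name, character(1))
  fill_indices <- draw_fill(p, p - k, seed)
  cols <- cbind(V, diag(p)[, fill_indices, drop = FALSE])
  colnames(cols) <- c(labels, paste0("L", fill_indices))
  structure(
    list(columns = cols, meaningful_labels = labels, k = k,
         has_general = FALSE, general_position = NA_character_,
         fill_indices = fill_indices, seed = as.integer(seed),
         orthonormal = FALSE, fidelity = NULL),
    class = "beta_matrix"
  )
}

# seeded uniform draw of fill coordinates, isolated from the caller's RNG
draw_fill <- function(p, n_fill, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sort(sample.int(p, n_fill))
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> p = %d, %d meaningful column(s) [%s]%s, %d fill, %s\n",
              nrow(x$columns), length(x$meaningful_labels),
              paste(x$meaningful_labels, collapse = ", "),
              if (x$has_general) " (incl. general)" else "",
              length(x$fill_indices),
              if (x$orthonormal) "orthonormalized" else "raw"))
  invisible(x)
}

#' Estimate the general-knowledge vector from split descriptors
#'
#' Builds the general factor of the bifactor variant. Each concept's lemma
#' list (descriptors or fragment nouns) is split at random into two balanced
#' subsets; each subset is represented as a unit vector (normalized sum of
#' term vectors); a one-factor exploratory factor analysis treats the
#' `2k` subset vectors as variables and the `p` space coordinates as
#' observations; and the general vector is the loadings-weighted sum of the
#' subset vectors, normalized to unit length. Raw loadings are used as
#' weights; only the final vector is normalized.
#'
#' @param space a `semantic_space`.
#' @param rubric an [ir_rubric()].
#' @param source `"descriptors"` or `"fragments"`.
#' @param split_seed seed for the balanced random split.
#' @param n_splits subsets per concept (default 2).
#' @param strict error when a concept has a single usable lexeme; otherwise
#'   the lexeme is duplicated across subsets with a warning.
#' @return An object of class `general_factor_model`: `subset_vectors`
#'   (p x 2k matrix), `loadings`, `general_vector` (unit p-vector),
#'   `subset_terms`.
#' @export
estimate_general_vector <- function(space, rubric,
                                    source = c("descriptors", "fragments"),
                                    split_seed = 1L, n_splits = 2L,
                                    strict = FALSE) {
  source <- match.arg(source)
  p <- space$k
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(split_seed)
  subset_vectors <- NULL
  subset_terms <- list()
  labels <- character(0)
  for (cc in rubric$concepts) {
    terms <- if (source == "descriptors") cc$descriptors else cc$fragment_nouns
    terms <- terms[terms %in% space$vocabulary]
    if (length(terms) == 0L)
      stop("concept '", cc$name, "': no usable lexemes in vocabulary")
    if (length(terms) < n_splits) {
      if (strict)
        stop("concept '", cc$name, "' has a single usable lexeme; cannot split")
      warning("concept '", cc$name,
              "': fewer lexemes than splits; duplicating")
      terms <- rep(terms, length.out = n_splits)
    }
    perm <- sample(terms)
    groups <- split(perm, rep(seq_len(n_splits), length.out = length(perm)))
    for (g in seq_along(groups)) {
      v <- colSums(space$term_vectors[match(groups[[g]], space$vocabulary),
                                      , drop = FALSE])
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) stop("subset vector cancels to zero for '", cc$name, "'")
      subset_vectors <- cbind(subset_vectors, v / nv)
      labels <- c(labels, paste0(cc$name, "_s", g))
      subset_terms[[paste0(cc$name, "_s", g)]] <- groups[[g]]
    }
  }
  colnames(subset_vectors) <- labels
  # one-factor minres EFA: variables = subset vectors, observations = the
  # p space coordinates; extraction called directly so that degenerate
  # (rank-1) subset configurations remain solvable
  R <- stats::cor(subset_vectors)
  mr <- extract_minres(R, 1L)
  lam <- as.numeric(mr$loadings)
  if (sum(lam) < 0) lam <- -lam
  if (any(!is.finite(lam)))
    stop("degenerate one-factor solution (non-finite loadings)")
  if (any(abs(lam) > 1.02))
    stop("Heywood case in one-factor solution; loadings: ",
         paste(round(lam, 3), collapse = ", "))
  lam <- pmin(pmax(lam, -1), 1)   # absorb numerical overshoot at the bound
  g <- as.numeric(subset_vectors %*% lam)
  ng <- sqrt(sum(g^2))
  if (ng < 1e-10) stop("general vector cancels to zero (loadings sum to ~0)")
  g <- g / ng
  # sign convention: align with the mean subset vector so G points toward
  # shared content rather than away from it
  if (sum(g * rowMeans(subset_vectors)) < 0) g <- -g
  structure(
    list(subset_vectors = subset_vectors, loadings = lam,
         general_vector = g, subset_terms = subset_terms,
         source = source, split_seed = as.integer(split_seed)),
    class = "general_factor_model"
  )
}

#' Assemble the change-of-basis matrix (bifactor form)
#'
#' As [assemble_beta()], but the meaningful block additionally contains the
#' general-knowledge vector, so only `p - k - 1` standard-basis fill columns
#' remain. The general column is placed after the concept columns by default
#' (`after_concepts`); `general_first` puts it before them, which — because
#' Gram-Schmidt proceeds in column order — residualizes every concept
#' dimension against the general dimension, the usual bifactor reading.
#'
#' @inheritParams assemble_beta
#' @param general a `general_factor_model` from [estimate_general_vector()].
#' @param position `"after_concepts"` or `"general_first"`.
#' @param general_label label for the general column (default `"G"`).
#' @return A `beta_matrix` with `has_general = TRUE`.
#' @export
assemble_beta_bifactor <- function(space, concept_vectors, general,
                                   position = c("after_concepts",
                                                "general_first"),
                                   seed = 1L, general_label = "G") {
  position <- match.arg(position)
  p <- space$k
  k <- length(concept_vectors)
  if (k + 1L >= p) stop("k + 1 must be < space dimension")
  g <- general$general_vector
  for (cv in concept_vectors) {
    cs <- abs(sum(g * cv$vector))
    if (cs > ir_tolerances$collinear_tol)
      stop("general vector nearly collinear with concept '",
           cv$concept_name, "' (|cos| = ", round(cs, 4), ")")
  }
  base <- assemble_beta(space, concept_vectors, seed = seed)
  fill_indices <- draw_fill(p, p - k - 1L, seed)
  concept_cols <- base$columns[, seq_len(k), drop = FALSE]
  if (position == "after_concepts") {
    meaningful <- cbind(concept_cols, g)
    labels <- c(base$meaningful_labels, general_label)
  } else {
    meaningful <- cbind(g, concept_cols)
    labels <- c(general_label, base$meaningful_labels)
  }
  cols <- cbind(meaningful, diag(p)[, fill_indices, drop = FALSE])
  colnames(cols) <- c(labels, paste0("L", fill_indices))
  structure(
    list(columns = cols, meaningful_labels = labels, k = k,
         has_general = TRUE, general_position = position,
         fill_indices = fill_indices, seed = as.integer(seed),
         orthonormal = FALSE, fidelity = NULL),
    class = "beta_matrix"
  )
}

#' Orthonormalize a basis by modified Gram-Schmidt with a fidelity gate
#'
#' Orthogonalizes the columns strictly in order (meaningful block first, fill
#' last) so the meaningful vectors retain maximal fidelity, then checks for
#' each meaningful column the Pearson correlation between its coordinates
#' before and after orthogonalization. A fidelity of 0.80 or more is
#' considered reliable; below the threshold the function warns, or errors in
#' strict mode. Modified (rather than classical) Gram-Schmidt is used for
#' numerical stability; the two coincide in exact arithmetic.
#'
#' @param beta a `beta_matrix`.
#' @param fidelity_threshold reliability gate on the pre/post correlation.
#' @param strict error (rather than warn) when any meaningful fidelity falls
#'   below the threshold.
#' @return The orthonormalized `beta_matrix`, with `orthonormal = TRUE` and a
#'   `fidelity` named vector over the meaningful columns.
#' @export
gram_schmidt <- function(beta, fidelity_threshold = ir_tolerances$fidelity_default,
                         strict = FALSE) {
  B <- beta$columns
  p <- ncol(B)
  Q <- B
  for (j in seq_len(p)) {
    v <- Q[, j]
    if (j > 1L) {
      for (i in seq_len(j - 1L)) v <- v - sum(Q[, i] * v) * Q[, i]
    }
    nv <- sqrt(sum(v^2))
    if (nv < ir_tolerances$gs_tol)
      stop("degenerate basis: column ", j, " ('", colnames(B)[j],
           "') has near-zero residual norm; re-seed the fill")
    Q[, j] <- v / nv
  }
  n_meaningful <- length(beta$meaningful_labels)
  # Pearson correlation between pre- and post-orthogonalization columns;
  # when a column has zero coordinate variance (possible only in very low
  # dimension) the uncentered correlation, i.e. the cosine, is used instead
  fidelity <- vapply(seq_len(n_meaningful), function(j) {
    b <- B[, j]; q <- Q[, j]
    if (stats::sd(b) < 1e-14 || stats::sd(q) < 1e-14) {
      sum(b * q) / sqrt(sum(b^2) * sum(q^2))
    } else {
      stats::cor(b, q)
    }
  }, numeric(1))
  names(fidelity) <- beta$meaningful_labels
  low <- fidelity < fidelity_threshold
  if (any(low)) {
    msg <- paste0("fidelity below ", fidelity_threshold, " for: ",
                  paste(sprintf("%s (%.3f)", names(fidelity)[low],
                                fidelity[low]), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  out <- beta
  out$columns <- Q
  out$orthonormal <- TRUE
  out$fidelity <- fidelity
  out
}

#' Rotate a semantic space into the meaningful basis
#'
#' Expresses every term vector in the orthonormalized basis: coordinate `j`
#' of a vector `v` becomes the inner product of `v` with basis column `j`.
#' This is a pure rotation, so all norms and pairwise cosines are preserved;
#' the leading coordinates of any projected document now read as concept
#' (and, in the bifactor variant, general-knowledge) coverage scores.
#'
#' @param space a `semantic_space`.
#' @param ortho_beta an orthonormalized `beta_matrix` (checked to
#'   `gs_tol`).
#' @return An object of class `meaningful_space`: `term_vectors` (term x p,
#'   meaningful columns first and named), `meaningful_labels`, `k`,
#'   `has_general`, `fidelity`, `vocabulary`, `global_weights`.
#' @export
change_basis <- function(space, ortho_beta) {
  Q <- ortho_beta$columns
  dev <- max(abs(crossprod(Q) - diag(ncol(Q))))
  if (dev > 1e-8)
    stop("basis is not orthonormal (max |Q'Q - I| = ", format(dev), "); ",
         "run gram_schmidt() first")
  rotated <- space$term_vectors %*% Q
  nm <- ortho_beta$meaningful_labels
  colnames(rotated) <- c(nm, paste0("lat", seq_len(ncol(Q) - length(nm))))
  rownames(rotated) <- space$vocabulary
  structure(
    list(term_vectors = rotated, meaningful_labels = nm,
         k = ortho_beta$k, has_general = ortho_beta$has_general,
         general_position = ortho_beta$general_position,
         fidelity = ortho_beta$fidelity, vocabulary = space$vocabulary,
         global_weights = space$global_weights,
         seed = ortho_beta$seed),
    class = "meaningful_space"
  )
}

#' @export
print.meaningful_space <- function(x, ...) {
  cat(sprintf("<meaningful_space> %d terms, p = %d, meaningful: %s\n",
              nrow(x$term_vectors), ncol(x$term_vectors),
              paste(x$meaningful_labels, collapse = ", ")))
  if (!is.null(x$fidelity))
    cat("  fidelity:", paste(sprintf("%s %.3f", names(x$fidelity),
                                     x$fidelity), collapse = ", "), "\n")
  invisible(x)
}

#' Build a meaningful space end to end
#'
#' Convenience wrapper: concept vectors from the rubric, (optionally) the
#' general vector, beta assembly, Gram-Schmidt, change of basis. On a
#' degenerate fill draw the fill is re-seeded (seed + 1, up to 10 retries).
#'
#' @param space a `semantic_space`.
#' @param rubric an [ir_rubric()].
#' @param variant `"classic"` or `"bifactor"`.
#' @param source `"descriptors"` or `"fragments"`.
#' @param general_position passed to [assemble_beta_bifactor()].
#' @param seed fill-draw seed (also the split seed for the general factor).
#' @param strict_fidelity error when any meaningful fidelity < threshold.
#' @param fidelity_threshold reliability gate (default 0.80).
#' @return A `meaningful_space`.
#' @export
build_meaningful_space <- function(space, rubric,
                                   variant = c("classic", "bifactor"),
                                   source = c("descriptors", "fragments"),
                                   general_position = "after_concepts",
                                   seed = 1L, strict_fidelity = FALSE,
                                   fidelity_threshold = ir_tolerances$fidelity_default) {
  variant <- match.arg(variant)
  source <- match.arg(source)
  cvs <- concept_vectors(space, rubric, source = source)
  try_seed <- seed
  for (attempt in 1:10) {
    beta <- if (variant == "classic") {
      assemble_beta(space, cvs, seed = try_seed)
    } else {
      gen <- estimate_general_vector(space, rubric, source = source,
                                     split_seed = seed)
      assemble_beta_bifactor(space, cvs, gen, position = general_position,
                             seed = try_seed)
    }
    ob <- tryCatch(gram_schmidt(beta, fidelity_threshold = fidelity_threshold,
                                strict = strict_fidelity),
                   error = function(e) {
                     if (grepl("degenerate basis", conditionMessage(e)))
                       NULL else stop(e)
                   })
    if (!is.null(ob)) return(change_basis(space, ob))
    try_seed <- try_seed + 1L
  }
  stop("could not find a non-degenerate standard-basis fill in 10 attempts")
}
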