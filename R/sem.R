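# Unweighted least squares confirmatory factor and structural equation
# models. Models are expressed in RAM form (directed-path matrix A,
# symmetric covariance matrix S, observed filter) and the ULS discrepancy
# F = 1/2 * ||S_sample - Sigma(theta)||_F^2 is minimized with nlminb.
#
# ULS has no native chi-square; the reported test statistic is
# (N - 1) * 2 * F_min, the common software convention, and the usual
# incremental/absolute indices (CFI, TLI, RMSEA, SRMR) are computed from it
# against the independence baseline fitted under the same estimator. This is
# a convention, not a distributional claim.

#' Declare a CFA/SEM model
#'
#' A small declarative schema: latent factors with their observed indicators,
#' regressions (latent or observed outcomes on latent or observed
#' predictors), and free covariances. Identification: the first loading of
#' every factor is fixed to 1; all variances (or residual variances) are
#' free. Exogenous observed predictors get a saturated
#' variance/covariance block; latent residual covariances default to zero.
#'
#' @param factors named list: factor name -> character vector of indicator
#'   column names. May be empty for observed-only models.
#' @param regressions named list: outcome -> character vector of predictors.
#' @param covariances list of length-2 character vectors naming free
#'   covariances, or the string `"saturated"` to free every pairwise
#'   covariance among the observed variables.
#' @param observed extra observed variables not otherwise mentioned (for
#'   saturated or independence models).
#' @param exo_latent_cov free covariances among exogenous latent factors
#'   (default TRUE).
#' @return An object of class `sem_model`.
#' @export
sem_model <- function(factors = list(), regressions = list(),
                      covariances = list(), observed = character(0),
                      exo_latent_cov = TRUE) {
  structure(list(factors = factors, regressions = regressions,
                 covariances = covariances, observed = observed,
                 exo_latent_cov = exo_latent_cov),
            class = "sem_model")
}

#' Read a CFA/SEM model from YAML
#'
#' Expected keys: `factors` (map of factor -> indicator list), `regressions`
#' (map of outcome -> predictor list), `covariances` (list of 2-element
#' lists or `saturated`), `observed`.
#'
#' @param path YAML file.
#' @return A [sem_model()].
#' @export
read_sem_model <- function(path) {
  y <- yaml::read_yaml(path)
  covs <- y$covariances %||% list()
  if (!identical(covs, "saturated") && length(covs))
    covs <- lapply(covs, unlist)
  sem_model(factors = lapply(y$factors %||% list(), unlist),
            regressions = lapply(y$regressions %||% list(), unlist),
            covariances = covs,
            observed = unlist(y$observed %||% character(0)),
            exo_latent_cov = y$exo_latent_cov %||% TRUE)
}

# build the parameter table for a model given the sample covariance
build_partable <- function(model, S_sample) {
  obs <- colnames(S_sample)
  latents <- names(model$factors)
  all_ind <- unlist(model$factors, use.names = FALSE)
  bad <- setdiff(all_ind, obs)
  if (length(bad)) stop("indicators not in data: ", paste(bad, collapse = ", "))
  vars <- c(obs, latents)
  nv <- length(vars)
  idx <- stats::setNames(seq_len(nv), vars)

  rows <- list()
  add <- function(mat, i, j, free, value, label, lower = -Inf) {
    rows[[length(rows) + 1L]] <<- data.frame(
      mat = mat, i = i, j = j, free = free, value = value, label = label,
      lower = lower, stringsAsFactors = FALSE)
  }

  reg_lhs <- names(model$regressions)
  bad_lhs <- setdiff(reg_lhs, vars)
  if (length(bad_lhs)) stop("regression outcomes unknown: ",
                            paste(bad_lhs, collapse = ", "))
  cov_vars <- if (identical(model$covariances, "saturated")) character(0)
              else unlist(model$covariances, use.names = FALSE)
  endo_obs <- unique(c(all_ind, intersect(reg_lhs, obs)))
  exo_obs <- setdiff(
    intersect(unique(c(unlist(model$regressions), model$observed, cov_vars)),
              obs),
    endo_obs)
  endo_lat <- intersect(reg_lhs, latents)
  exo_lat <- setdiff(latents, endo_lat)

  # loadings: first fixed to 1, rest free
  for (f in latents) {
    ind <- model$factors[[f]]
    add("A", idx[ind[1]], idx[f], FALSE, 1, paste0(f, "=~", ind[1]))
    for (v in ind[-1])
      add("A", idx[v], idx[f], TRUE, 0.8, paste0(f, "=~", v))
  }
  # regressions
  for (lhs in reg_lhs) for (rhs in model$regressions[[lhs]]) {
    if (!rhs %in% vars) stop("unknown predictor: ", rhs)
    add("A", idx[lhs], idx[rhs], TRUE, 0.05, paste0(lhs, "~", rhs))
  }
  # observed (residual) variances
  for (v in obs) {
    start <- if (v %in% endo_obs) 0.5 * S_sample[v, v] else S_sample[v, v]
    add("S", idx[v], idx[v], TRUE, max(start, 0.05),
        paste0(v, "~~", v), lower = 1e-8)
  }
  # latent (residual) variances
  for (f in latents)
    add("S", idx[f], idx[f], TRUE, 0.4, paste0(f, "~~", f), lower = 1e-8)
  # requested covariances
  if (identical(model$covariances, "saturated")) {
    if (length(latents) || length(reg_lhs))
      stop("'saturated' covariances only for observed-only models")
    cmb <- utils::combn(obs, 2, simplify = FALSE)
    for (pr in cmb)
      add("S", idx[pr[1]], idx[pr[2]], TRUE, S_sample[pr[1], pr[2]],
          paste0(pr[1], "~~", pr[2]))
  } else {
    for (pr in model$covariances) {
      if (length(pr) != 2L) stop("covariances must be pairs")
      st <- if (all(pr %in% obs)) S_sample[pr[1], pr[2]] else 0
      add("S", idx[pr[1]], idx[pr[2]], TRUE, st,
          paste0(pr[1], "~~", pr[2]))
    }
  }
  # saturate exogenous observed block
  if (length(exo_obs) > 1L) {
    cmb <- utils::combn(exo_obs, 2, simplify = FALSE)
    for (pr in cmb)
      add("S", idx[pr[1]], idx[pr[2]], TRUE, S_sample[pr[1], pr[2]],
          paste0(pr[1], "~~", pr[2]))
  }
  # covariances among exogenous latents
  if (isTRUE(model$exo_latent_cov) && length(exo_lat) > 1L) {
    cmb <- utils::combn(exo_lat, 2, simplify = FALSE)
    for (pr in cmb)
      add("S", idx[pr[1]], idx[pr[2]], TRUE, 0.1,
          paste0(pr[1], "~~", pr[2]))
  }
  pt <- do.call(rbind, rows)
  pt <- pt[!duplicated(pt$label), ]
  list(partable = pt, vars = vars, obs = obs, latents = latents, idx = idx)
}

# evaluate Sigma(theta) for the observed block
sigma_of_theta <- function(theta, tmpl) {
  A <- tmpl$A0; Smat <- tmpl$S0
  fr <- tmpl$pt$free
  A[tmpl$linA[fr & tmpl$pt$mat == "A"]] <- theta[tmpl$par_of[fr & tmpl$pt$mat == "A"]]
  sidx <- fr & tmpl$pt$mat == "S"
  Smat[tmpl$linS1[sidx]] <- theta[tmpl$par_of[sidx]]
  Smat[tmpl$linS2[sidx]] <- theta[tmpl$par_of[sidx]]
  B <- tryCatch(solve(diag(nrow(A)) - A), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  Sig_all <- B %*% Smat %*% t(B)
  list(obs = Sig_all[tmpl$obs_ix, tmpl$obs_ix, drop = FALSE], all = Sig_all)
}

make_template <- function(bp) {
  pt <- bp$partable
  nv <- length(bp$vars)
  A0 <- matrix(0, nv, nv); S0 <- matrix(0, nv, nv)
  # prefill fixed values
  for (r in which(!pt$free)) {
    if (pt$mat[r] == "A") A0[pt$i[r], pt$j[r]] <- pt$value[r]
    else { S0[pt$i[r], pt$j[r]] <- pt$value[r]; S0[pt$j[r], pt$i[r]] <- pt$value[r] }
  }
  par_of <- integer(nrow(pt)); par_of[pt$free] <- seq_len(sum(pt$free))
  list(pt = pt, A0 = A0, S0 = S0,
       linA = (pt$j - 1L) * nv + pt$i,
       linS1 = (pt$j - 1L) * nv + pt$i,
       linS2 = (pt$i - 1L) * nv + pt$j,
       par_of = par_of,
       obs_ix = match(bp$obs, bp$vars),
       nv = nv)
}

#' Fit a model by unweighted least squares
#'
#' Minimizes half the squared Frobenius discrepancy between the sample and
#' model-implied covariance matrices. By default the data are standardized
#' first (so the fit is to the correlation matrix), which puts indicators
#' and computational scores of very different natural scales on an equal
#' footing in the ULS discrepancy.
#'
#' @param model a [sem_model()].
#' @param data observations x variables data.frame/matrix containing every
#'   observed variable of the model, or a covariance matrix when `n_obs` is
#'   given.
#' @param n_obs number of observations when `data` is a covariance matrix.
#' @param std_data standardize variables before fitting (default TRUE;
#'   ignored when `data` is a covariance matrix).
#' @param se compute approximate standard errors from the numerical Hessian
#'   of the scaled discrepancy (normal-theory convention carried over to
#'   ULS; default TRUE).
#' @return An object of class `sem_fit`: `partable` (estimates, SEs, z,
#'   standardized estimates), `fit` (a `fit_indices` list: `chi2`, `df`,
#'   `CFI`, `TLI`, `RMSEA`, `RMSEA_ci`, `SRMR`, `estimator`), `Sigma`,
#'   `S`, `converged`, `n_obs`.
#' @export
fit_uls <- function(model, data, n_obs = NULL, std_data = TRUE, se = TRUE) {
  if (is.matrix(data) && nrow(data) == ncol(data) && !is.null(n_obs) &&
      isSymmetric(unname(data), tol = 1e-8)) {
    S <- as.matrix(data); N <- n_obs
  } else {
    X <- as.matrix(data)
    cov_vars <- if (identical(model$covariances, "saturated")) character(0)
                else unlist(model$covariances, use.names = FALSE)
    need <- unique(c(unlist(model$factors), unlist(model$regressions),
                     names(model$regressions), model$observed, cov_vars))
    need <- intersect(need, colnames(X))
    if (length(need) == 0L) stop("no model variables found in data")
    X <- X[, need, drop = FALSE]
    if (std_data) X <- scale(X)
    S <- stats::cov(X)
    N <- nrow(X)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("sample covariance not positive semi-definite")

  bp <- build_partable(model, S)
  tmpl <- make_template(bp)
  pt <- bp$partable
  q <- sum(pt$free)
  p <- length(bp$obs)
  n_moments <- p * (p + 1) / 2
  if (q > n_moments)
    stop("model not identified: ", q, " free parameters for ",
         n_moments, " moments")

  fobj <- function(theta) {
    sg <- sigma_of_theta(theta, tmpl)
    if (is.null(sg)) return(1e10)
    0.5 * sum((S - sg$obs)^2)
  }
  start <- pt$value[pt$free]
  lower <- pt$lower[pt$free]
  opt <- stats::nlminb(start, fobj, lower = lower,
                       control = list(iter.max = 5000, eval.max = 10000))
  if (!is.finite(opt$objective))
    stop("ULS optimization failed (non-finite discrepancy); ",
         "check identification and starting values")
  converged <- opt$convergence == 0
  if (!converged)
    warning("nlminb convergence code ", opt$convergence, ": ", opt$message)
  theta <- opt$par
  sg <- sigma_of_theta(theta, tmpl)
  Sigma <- sg$obs

  # fill estimates
  pt$est <- pt$value
  pt$est[pt$free] <- theta

  # fit indices
  Tstat <- (N - 1) * 2 * opt$objective
  df <- n_moments - q
  offd <- S; diag(offd) <- 0
  Tb <- (N - 1) * sum(offd^2)
  dfb <- p * (p - 1) / 2
  fit <- fit_indices_from_T(Tstat, df, Tb, dfb, N, S, Sigma)

  # approximate SEs
  pt$se <- NA_real_
  if (se && q > 0) {
    H <- tryCatch(stats::optimHess(theta, function(th) (N - 1) * 2 * fobj(th)),
                  error = function(e) NULL)
    if (!is.null(H)) {
      Hi <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Hi)) {
        v <- 2 * diag(Hi)
        v[v < 0] <- NA_real_
        pt$se[pt$free] <- sqrt(v)
      }
    }
  }
  pt$z <- pt$est / pt$se

  # standardized solution from model-implied variances
  sd_all <- sqrt(pmax(diag(sg$all), 0))
  pt$std <- NA_real_
  for (r in seq_len(nrow(pt))) {
    i <- pt$i[r]; j <- pt$j[r]
    if (pt$mat[r] == "A") {
      pt$std[r] <- if (sd_all[i] > 0) pt$est[r] * sd_all[j] / sd_all[i] else NA
    } else if (i == j) {
      pt$std[r] <- if (sd_all[i] > 0) pt$est[r] / sd_all[i]^2 else NA
    } else {
      pt$std[r] <- if (sd_all[i] > 0 && sd_all[j] > 0)
        pt$est[r] / (sd_all[i] * sd_all[j]) else NA
    }
  }
  pt$lhs_var <- bp$vars[pt$i]
  pt$rhs_var <- bp$vars[pt$j]

  structure(
    list(partable = pt[, c("label", "mat", "lhs_var", "rhs_var", "free",
                           "est", "se", "z", "std")],
         fit = fit, Sigma = Sigma, S = S, converged = converged,
         n_obs = N, model = model, discrepancy = opt$objective),
    class = "sem_fit")
}

fit_indices_from_T <- function(Tstat, df, Tb, dfb, N, S, Sigma) {
  num <- max(Tstat - df, 0)
  den <- max(Tb - dfb, Tstat - df, 0)
  CFI <- if (den == 0) 1 else 1 - num / den
  TLI <- if (df == 0 || dfb == 0) 1 else {
    d <- Tb / dfb - 1
    if (abs(d) < 1e-12) 1 else (Tb / dfb - Tstat / df) / d
  }
  RMSEA <- if (df == 0) 0 else sqrt(max(Tstat - df, 0) / (df * (N - 1)))
  ci <- if (df == 0) c(0, 0) else rmsea_ci(Tstat, df, N)
  p <- ncol(S)
  sds <- sqrt(diag(S))
  resid_std <- (S - Sigma) / tcrossprod(sds)
  SRMR <- sqrt(sum(resid_std[lower.tri(resid_std, diag = TRUE)]^2) /
                 (p * (p + 1) / 2))
  list(chi2 = Tstat, df = df, CFI = CFI, TLI = TLI, RMSEA = RMSEA,
       RMSEA_ci = ci, SRMR = SRMR, estimator = "ULS",
       baseline_chi2 = Tb, baseline_df = dfb)
}

#' @export
print.sem_fit <- function(x, ...) {
  f <- x$fit
  cat(sprintf("ULS fit: chi2(%d) = %.3f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f [%.3f-%.3f], SRMR = %.3f\n",
              f$df, f$chi2, f$CFI, f$TLI, f$RMSEA, f$RMSEA_ci[1],
              f$RMSEA_ci[2], f$SRMR))
  cat(sprintf("%d free parameters, n = %d%s\n", sum(x$partable$free),
              x$n_obs, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Confirmatory factor analysis by ULS
#'
#' Thin wrapper over [fit_uls()] for pure measurement models.
#'
#' @inheritParams fit_uls
#' @return A `sem_fit`.
#' @export
fit_cfa <- function(model, data, n_obs = NULL, std_data = TRUE, se = TRUE) {
  fit_uls(model, data, n_obs = n_obs, std_data = std_data, se = se)
}

#' Cross-loading structural model of computational vs human scores
#'
#' The convergent/discriminant validity model: human concept factors
#' (each measured by the raters' scores for that concept) are regressed on
#' every computational concept score with full cross-loadings. In the
#' `classic` structure the human side is a correlated-factor measurement
#' model (residual covariances among human factors free). In the `bifactor`
#' structure every rating additionally loads on a human general factor,
#' specific factors are mutually orthogonal (their residual covariances are
#' fixed to zero), the human general factor is regressed on the observed
#' general score(s) of the bifactor computational variant, and when two
#' general scores are supplied their covariance is estimated.
#'
#' @param ir_scores a `score_table` (bifactor variant required for
#'   `structure = "bifactor"`), or a named list of two score tables (e.g.
#'   descriptor- and fragment-based) whose general columns both predict the
#'   human general factor.
#' @param human a `rating_table`.
#' @param structure `"classic"` or `"bifactor"`.
#' @param ... passed to [fit_uls()].
#' @return A `sem_fit` with an extra element `structural`: data.frame of the
#'   structural paths (outcome, predictor, est, se, z, std, convergent flag
#'   marking the largest |std| path per outcome).
#' @export
fit_sem_crossloading <- function(ir_scores, human,
                                 structure = c("classic", "bifactor"), ...) {
  structure_type <- match.arg(structure)
  tables <- if (inherits(ir_scores, "score_table")) list(ir = ir_scores)
            else ir_scores
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("ir", seq_along(tables))
  hw <- ratings_wide(human)
  doc_ids <- rownames(hw)
  for (nm in names(tables)) {
    st <- tables[[nm]]
    if (!all(doc_ids %in% st$doc_id))
      stop("unmatched doc_ids between ratings and score table '", nm, "'")
  }
  concepts <- attr(human, "concepts")
  raters <- attr(human, "raters")

  dat <- as.data.frame(hw)
  ir_concept_cols <- character(0)
  g_cols <- character(0)
  for (nm in names(tables)) {
    st <- tables[[nm]]
    sm <- score_matrix(st)
    sm <- sm[match(doc_ids, rownames(sm)), , drop = FALSE]
    for (cn in colnames(sm)) {
      col <- paste0(nm, "_", make.names(cn))
      dat[[col]] <- sm[, cn]
      if (cn == "G") g_cols <- c(g_cols, col)
      else ir_concept_cols <- c(ir_concept_cols, col)
    }
  }
  if (structure_type == "bifactor" && length(g_cols) == 0L)
    stop("bifactor structure needs a general score column (score__G)")

  hr_factors <- list()
  for (cc in concepts)
    hr_factors[[paste0("HR_", make.names(cc))]] <-
      paste0(raters, "_", make.names(cc))

  # one latent per table-concept pair when >1 table; observed otherwise
  predictors <- ir_concept_cols
  ir_factors <- list()
  if (length(tables) > 1L) {
    by_concept <- split(ir_concept_cols,
                        sub("^[^_]+_", "", ir_concept_cols))
    ir_factors <- stats::setNames(by_concept,
                                  paste0("IRF_", names(by_concept)))
    predictors <- names(ir_factors)
  }

  regressions <- stats::setNames(
    rep(list(predictors), length(hr_factors)), names(hr_factors))
  covariances <- list()
  if (structure_type == "bifactor") {
    hr_factors[["HRG"]] <- unlist(unname(hr_factors[seq_along(concepts)]))
    regressions[["HRG"]] <- g_cols
    if (length(g_cols) == 2L)
      covariances <- c(covariances, list(g_cols))
  } else {
    # correlated human factors: free residual covariances
    hf <- names(hr_factors)
    if (length(hf) > 1L)
      covariances <- c(covariances,
                       utils::combn(hf, 2, simplify = FALSE))
  }
  model <- sem_model(factors = c(hr_factors, ir_factors),
                     regressions = regressions,
                     covariances = covariances)
  fit <- fit_uls(model, dat, ...)

  pt <- fit$partable
  struct <- pt[pt$mat == "A" & pt$free &
                 grepl("^HR", pt$lhs_var) &
                 pt$rhs_var %in% c(predictors, g_cols), ]
  struct <- data.frame(outcome = struct$lhs_var, predictor = struct$rhs_var,
                       est = struct$est, se = struct$se, z = struct$z,
                       std = struct$std, stringsAsFactors = FALSE)
  struct$convergent <- FALSE
  for (o in unique(struct$outcome)) {
    ix <- which(struct$outcome == o)
    struct$convergent[ix[which.max(abs(struct$std[ix]))]] <- TRUE
  }
  fit$structural <- struct
  fit$structure <- structure_type
  fit
}
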