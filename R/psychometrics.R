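# Validation battery: inter-rater reliability, descriptive contrasts,
# factor-retention and factor-analysis tools, and standardized-beta
# regression. Confirmatory models live in sem.R.

#' Two-way mixed-effects intraclass correlation
#'
#' Shrout-Fleiss intraclass correlations from the two-way ANOVA mean squares
#' of a targets x raters matrix. The two-way mixed model treats raters as
#' fixed and targets as random; `consistency` ignores rater mean differences,
#' `agreement` penalizes them; `single` is the reliability of one rater,
#' `average` of the mean across raters.
#'
#' @param ratings numeric matrix, targets in rows, raters in columns (a
#'   `rating_table` slice via [ratings_matrix()] works).
#' @param type `"single"` or `"average"`.
#' @param definition `"consistency"` or `"agreement"`.
#' @return An object of class `icc_result`: `icc`, `variant`, `F`, `df1`,
#'   `df2`, `p`, `n_targets`, `n_raters`.
#' @export
icc_two_way_mixed <- function(ratings, type = c("single", "average"),
                              definition = c("consistency", "agreement")) {
  type <- match.arg(type)
  definition <- match.arg(definition)
  X <- as.matrix(ratings)
  if (anyNA(X)) {
    drop <- rowSums(is.na(X)) > 0
    warning("listwise deletion of ", sum(drop), " incomplete target(s)")
    X <- X[!drop, , drop = FALSE]
  }
  n <- nrow(X); k <- ncol(X)
  if (n < 2L || k < 2L) stop("need at least 2 targets and 2 raters")
  grand <- mean(X)
  row_m <- rowMeans(X); col_m <- colMeans(X)
  msr <- k * sum((row_m - grand)^2) / (n - 1)          # between targets
  msc <- n * sum((col_m - grand)^2) / (k - 1)          # between raters
  sse <- sum((X - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))                      # residual
  if (msr < 1e-14)
    stop("zero between-target variance: ICC undefined")
  icc <- if (definition == "consistency") {
    if (type == "single") (msr - mse) / (msr + (k - 1) * mse)
    else (msr - mse) / msr
  } else {
    if (type == "single")
      (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    else (msr - mse) / (msr + (msc - mse) / n)
  }
  Fval <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  structure(
    list(icc = icc, variant = paste(type, definition, sep = "-"),
         F = Fval, df1 = df1, df2 = df2,
         p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
         n_targets = n, n_raters = k,
         ms = c(msr = msr, msc = msc, mse = mse)),
    class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f, F(%d, %d) = %.2f, p = %.3g (n = %d, raters = %d)\n",
              x$variant, x$icc, x$df1, x$df2, x$F, x$p, x$n_targets,
              x$n_raters))
  invisible(x)
}

#' Paired t contrast with Cohen's d
#'
#' Paired t test plus an effect size. The default `d` is the mean difference
#' divided by the standard deviation of the differences (d_z); `"pooled"`
#' divides by the pooled within-condition SD instead.
#'
#' @param x,y equal-length paired numeric samples.
#' @param d_method `"dz"` or `"pooled"`.
#' @return list with `t`, `df`, `p`, `cohens_d`, `means`, `sds`.
#' @export
paired_contrast <- function(x, y, d_method = c("dz", "pooled")) {
  d_method <- match.arg(d_method)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 2L) stop("need n >= 2 pairs")
  diffs <- x - y
  sdd <- stats::sd(diffs)
  if (sdd < 1e-14) {
    if (mean(diffs) == 0) {
      # identical samples: define t = d = 0 rather than 0/0
      return(list(t = 0, df = n - 1, p = 1, cohens_d = 0,
                  means = c(mean(x), mean(y)),
                  sds = c(stats::sd(x), stats::sd(y))))
    }
    stop("zero variance of differences with nonzero mean difference")
  }
  tval <- mean(diffs) / (sdd / sqrt(n))
  denom <- if (d_method == "dz") sdd
           else sqrt((stats::var(x) + stats::var(y)) / 2)
  list(t = tval, df = n - 1,
       p = 2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE),
       cohens_d = mean(diffs) / denom,
       means = c(mean(x), mean(y)),
       sds = c(stats::sd(x), stats::sd(y)))
}

# squared multiple correlations from the inverse correlation matrix
smc <- function(R) {
  Ri <- tryCatch(solve(R), error = function(e) solve(R + diag(1e-8, nrow(R))))
  1 - 1 / diag(Ri)
}

#' Horn's parallel analysis
#'
#' Compares the empirical eigenvalues of the correlation matrix (principal
#' components) and of the reduced correlation matrix with squared multiple
#' correlations on the diagonal (common factors) against eigenvalues of
#' standard-normal data of identical shape. A component/factor is retained
#' while its empirical eigenvalue exceeds the chosen percentile of the
#' simulated ones; retention stops at the first failure.
#'
#' @param data observations x variables numeric matrix or data.frame.
#' @param n_sims number of Monte Carlo datasets (default 100).
#' @param percentile percentile of simulated eigenvalues (default 95, the
#'   PA95 criterion).
#' @param seed RNG seed for the simulation.
#' @return An object of class `pa_result`: `n_factors_retained`,
#'   `n_components_retained`, `pc_eigenvalues`, `fa_eigenvalues`,
#'   `pc_simulated`, `fa_simulated` (percentile curves), `percentile`,
#'   `n_sims`.
#' @export
parallel_analysis <- function(data, n_sims = 100L, percentile = 95,
                              seed = 1L) {
  X <- as.matrix(data)
  n <- nrow(X); p <- ncol(X)
  if (any(apply(X, 2, stats::sd) < 1e-12))
    stop("constant variable: degenerate correlation matrix")
  if (n <= p) warning("fewer observations than variables + 1; ",
                      "parallel analysis may be unstable")
  R <- stats::cor(X)
  pc_emp <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  fa_emp <- eigen(reduced_cor(R), symmetric = TRUE, only.values = TRUE)$values
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pc_sim <- matrix(0, n_sims, p); fa_sim <- matrix(0, n_sims, p)
  for (s in seq_len(n_sims)) {
    Rs <- stats::cor(matrix(stats::rnorm(n * p), n, p))
    pc_sim[s, ] <- eigen(Rs, symmetric = TRUE, only.values = TRUE)$values
    fa_sim[s, ] <- eigen(reduced_cor(Rs), symmetric = TRUE,
                         only.values = TRUE)$values
  }
  q <- percentile / 100
  pc_q <- apply(pc_sim, 2, stats::quantile, probs = q)
  fa_q <- apply(fa_sim, 2, stats::quantile, probs = q)
  retained <- function(emp, simq) {
    keep <- emp > simq
    if (!keep[1]) 0L else (which(c(!keep, TRUE))[1] - 1L)
  }
  structure(
    list(n_factors_retained = retained(fa_emp, fa_q),
         n_components_retained = retained(pc_emp, pc_q),
         pc_eigenvalues = pc_emp, fa_eigenvalues = fa_emp,
         pc_simulated = pc_q, fa_simulated = fa_q,
         percentile = percentile, n_sims = n_sims),
    class = "pa_result")
}

reduced_cor <- function(R) {
  Rr <- R
  diag(Rr) <- smc(R)
  Rr
}

#' @export
print.pa_result <- function(x, ...) {
  cat(sprintf("Parallel analysis (PA%g, %d sims): retain %d factor(s), %d component(s)\n",
              x$percentile, x$n_sims, x$n_factors_retained,
              x$n_components_retained))
  invisible(x)
}

# ---- oblimin rotation via gradient projection --------------------------------

# oblimin criterion and gradient (gamma = 0 is direct quartimin)
vg_oblimin <- function(L, gamma = 0) {
  p <- nrow(L); m <- ncol(L)
  L2 <- L^2
  N <- matrix(1, m, m) - diag(m)
  C <- if (gamma == 0) L2 %*% N
       else (diag(p) - matrix(gamma / p, p, p)) %*% L2 %*% N
  list(f = sum(L2 * C) / 4, Gq = L * C)
}

# oblique gradient-projection rotation (Jennrich 2002 family)
gpa_oblique <- function(A, gamma = 0, maxit = 1000L, eps = 1e-6) {
  m <- ncol(A)
  Tmat <- diag(m)
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- vg_oblimin(L, gamma)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), m)
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    improved <- FALSE
    for (i in 1:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), m)
      Tit <- tryCatch(solve(Tt), error = function(e) NULL)
      if (!is.null(Tit)) {
        Lt <- A %*% t(Tit)
        vgt <- vg_oblimin(Lt, gamma)
        if (vgt$f < f - 0.5 * s^2 * al) {
          Tmat <- Tt; Ti <- Tit; L <- Lt; f <- vgt$f
          G <- -t(t(L) %*% vgt$Gq %*% Ti)
          improved <- TRUE
          break
        }
      }
      al <- al / 2
    }
    if (!improved) break
  }
  Phi <- crossprod(Tmat)
  list(loadings = L, Phi = Phi, Tmat = Tmat, criterion = f, iterations = iter)
}

# minimum-residual extraction: optimize uniquenesses, loadings from the
# eigen-decomposition of the reduced correlation matrix
extract_minres <- function(R, m) {
  p <- nrow(R)
  loadings_from_psi <- function(psi) {
    Rr <- R
    diag(Rr) <- 1 - psi
    e <- eigen(Rr, symmetric = TRUE)
    d <- pmax(e$values[seq_len(m)], 0)
    e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(d), m)
  }
  obj <- function(psi) {
    L <- loadings_from_psi(psi)
    res <- R - tcrossprod(L)
    diag(res) <- 0
    sum(res^2)
  }
  start <- pmin(pmax(1 - smc(R), 0.005), 1)
  fit <- stats::nlminb(start, obj, lower = 5e-4, upper = 1)
  if (!fit$convergence %in% c(0, 1))
    warning("minres extraction: nlminb convergence code ", fit$convergence)
  L <- loadings_from_psi(fit$par)
  list(loadings = L, uniquenesses = fit$par, criterion = fit$objective)
}

#' Exploratory factor analysis with oblimin rotation
#'
#' Extraction by maximum likelihood (via [stats::factanal()]) or minimum
#' residual, followed by direct oblimin rotation (gradient projection) when
#' more than one factor is requested. Returns the rotated pattern matrix,
#' factor correlation matrix, fit statistics (RMSEA with 90% CI, TLI, RMSR),
#' and regression-method (Thomson) factor scores.
#'
#' @param data observations x variables matrix/data.frame, or a correlation
#'   matrix when `n_obs` is supplied (no factor scores in that case).
#' @param n_factors number of factors, `< n_vars`.
#' @param rotation `"oblimin"` or `"none"`.
#' @param estimator `"ml"` or `"minres"`.
#' @param n_obs number of observations when `data` is a correlation matrix.
#' @param oblimin_gamma oblimin family parameter (0 = direct quartimin).
#' @return An object of class `efa_result`: `loadings` (pattern),
#'   `Phi` (factor correlations), `uniquenesses`, `fit` (list: `chi2`, `df`,
#'   `p`, `RMSEA`, `RMSEA_ci`, `TLI`, `RMSR`), `scores`, `estimator`,
#'   `rotation`, `heywood`.
#' @export
efa <- function(data, n_factors, rotation = c("oblimin", "none"),
                estimator = c("ml", "minres"), n_obs = NULL,
                oblimin_gamma = 0) {
  rotation <- match.arg(rotation)
  estimator <- match.arg(estimator)
  is_cor <- is.matrix(data) && nrow(data) == ncol(data) &&
    max(abs(diag(as.matrix(data)) - 1)) < 1e-10 && !is.null(n_obs)
  if (is_cor) {
    R <- as.matrix(data); X <- NULL; n <- n_obs
  } else {
    X <- as.matrix(data)
    n <- nrow(X)
    if (any(apply(X, 2, stats::sd) < 1e-12)) stop("constant variable")
    R <- stats::cor(X)
  }
  p <- ncol(R)
  m <- as.integer(n_factors)
  if (m >= p) stop("n_factors must be < number of variables")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) stop("correlation matrix not positive definite")

  if (estimator == "ml") {
    fa <- tryCatch(
      stats::factanal(covmat = R, factors = m, n.obs = n, rotation = "none"),
      error = function(e) stop("ML factor analysis failed to converge: ",
                               conditionMessage(e)))
    L <- matrix(fa$loadings, p, m)
    psi <- fa$uniquenesses
    chi2 <- if (!is.null(fa$STATISTIC)) as.numeric(fa$STATISTIC) else NA_real_
    df <- if (!is.null(fa$dof)) as.numeric(fa$dof) else
      ((p - m)^2 - p - m) / 2
  } else {
    mr <- extract_minres(R, m)
    L <- mr$loadings
    psi <- mr$uniquenesses
    df <- ((p - m)^2 - p - m) / 2
    # ML discrepancy evaluated at the minres solution, Bartlett-corrected
    Sigma <- tcrossprod(L) + diag(psi, p)
    Fml <- log(det(Sigma)) - log(det(R)) +
      sum(diag(R %*% solve(Sigma))) - p
    chi2 <- max((n - 1 - (2 * p + 5) / 6 - 2 * m / 3) * Fml, 0)
  }
  heywood <- any(psi < 1e-3)
  if (heywood) warning("Heywood case: near-zero uniqueness")

  Phi <- diag(m)
  if (rotation == "oblimin" && m > 1L) {
    rot <- gpa_oblique(L, gamma = oblimin_gamma)
    L <- rot$loadings
    Phi <- rot$Phi
    # canonical presentation: order by SS loadings, positive column sums
    ss <- colSums(L^2)
    ord <- order(-ss)
    L <- L[, ord, drop = FALSE]; Phi <- Phi[ord, ord, drop = FALSE]
    sgn <- ifelse(colSums(L) < 0, -1, 1)
    L <- sweep(L, 2, sgn, "*")
    Phi <- diag(sgn, m) %*% Phi %*% diag(sgn, m)
  } else if (m == 1L && sum(L) < 0) {
    L <- -L
  }
  rownames(L) <- colnames(R)
  colnames(L) <- paste0("F", seq_len(m))
  dimnames(Phi) <- list(colnames(L), colnames(L))

  # residual-based and chi-square-based fit
  Sigma_rot <- L %*% Phi %*% t(L) + diag(psi, p)
  resid <- R - Sigma_rot
  rmsr <- sqrt(sum(resid[lower.tri(resid)]^2) / (p * (p - 1) / 2))
  fitstats <- list(chi2 = chi2, df = df, p = NA_real_, RMSEA = NA_real_,
                   RMSEA_ci = c(NA_real_, NA_real_), TLI = NA_real_,
                   RMSR = rmsr)
  if (is.finite(chi2) && df > 0) {
    fitstats$p <- stats::pchisq(chi2, df, lower.tail = FALSE)
    fitstats$RMSEA <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
    fitstats$RMSEA_ci <- rmsea_ci(chi2, df, n)
    null_chi2 <- (n - 1 - (2 * p + 5) / 6) * (-log(det(R)))
    null_df <- p * (p - 1) / 2
    num <- null_chi2 / null_df - chi2 / df
    den <- null_chi2 / null_df - 1
    fitstats$TLI <- if (abs(den) < 1e-12) 1 else num / den
  }

  scores <- NULL
  if (!is.null(X)) {
    # Thomson regression scores: weights R^{-1} * structure
    S_mat <- L %*% Phi
    W <- solve(R, S_mat)
    scores <- scale(X) %*% W
    colnames(scores) <- colnames(L)
  }
  structure(
    list(loadings = L, Phi = Phi, uniquenesses = psi, fit = fitstats,
         scores = scores, estimator = estimator, rotation = rotation,
         heywood = heywood, n_obs = n),
    class = "efa_result")
}

#' @export
print.efa_result <- function(x, ...) {
  cat(sprintf("EFA (%s, %s): %d factors, RMSR = %.3f",
              x$estimator, x$rotation, ncol(x$loadings), x$fit$RMSR))
  if (is.finite(x$fit$RMSEA)) cat(sprintf(", RMSEA = %.3f", x$fit$RMSEA))
  cat("\n")
  print(round(x$loadings, 3))
  invisible(x)
}

# 90% CI for RMSEA by inverting the noncentral chi-square
rmsea_ci <- function(chi2, df, n, level = 0.90) {
  a <- (1 - level) / 2
  upper_p <- function(ncp) stats::pchisq(chi2, df, ncp = ncp)
  lo <- 0
  if (upper_p(0) > 1 - a) {
    f <- function(ncp) upper_p(ncp) - (1 - a)
    lo <- stats::uniroot(f, c(0, max(chi2 * 2, 1)), extendInt = "downX")$root
  }
  hi <- 0
  if (upper_p(0) > a) {
    f <- function(ncp) upper_p(ncp) - a
    hi <- stats::uniroot(f, c(0, max(chi2 * 3, 1)), extendInt = "downX")$root
  }
  c(sqrt(lo / (df * (n - 1))), sqrt(hi / (df * (n - 1))))
}

#' Tucker congruence between two loading matrices
#'
#' Congruence is computed after greedily matching columns and aligning signs,
#' so it is invariant to column permutation and reflection.
#'
#' @param A,B loading matrices with the same dimensions.
#' @return numeric vector of per-factor congruence coefficients (of the
#'   matched columns of `B`, in `A`'s column order).
#' @export
tucker_congruence <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  m <- ncol(A)
  cong <- abs(crossprod(A, B) /
                outer(sqrt(colSums(A^2)), sqrt(colSums(B^2))))
  out <- numeric(m)
  usedB <- logical(m)
  for (i in seq_len(m)) {
    j <- which.max(ifelse(usedB, -Inf, cong[i, ]))
    out[i] <- cong[i, j]
    usedB[j] <- TRUE
  }
  out
}

#' Standardized-beta multiple regression
#'
#' Ordinary least squares on z-scored outcome and predictors; the
#' coefficients are the standardized betas used to judge convergent and
#' discriminant validity of concept scores against human criteria.
#'
#' @param outcome numeric vector (e.g. an EFA factor score for one human
#'   concept).
#' @param predictors numeric matrix or data.frame (e.g. the concept columns
#'   of a score table).
#' @return list with `beta` (named), `p` (named), `r_squared`, `n`.
#' @export
standardized_regression <- function(outcome, predictors) {
  Xp <- as.matrix(predictors)
  if (is.null(colnames(Xp))) colnames(Xp) <- paste0("x", seq_len(ncol(Xp)))
  n <- length(outcome)
  if (nrow(Xp) != n) stop("outcome and predictors must have matching rows")
  if (n <= ncol(Xp) + 1L) stop("need n > number of predictors + 1")
  qrx <- qr(cbind(1, Xp))
  if (qrx$rank < ncol(Xp) + 1L) {
    bad <- colnames(Xp)[qrx$pivot[seq(qrx$rank + 1L, ncol(Xp) + 1L)] - 1L]
    stop("exact collinearity among predictors: ",
         paste(bad, collapse = ", "))
  }
  kap <- kappa(scale(Xp), exact = TRUE)
  if (kap > 1e8)
    warning("predictors nearly collinear (condition number ",
            format(kap, digits = 3), ")")
  zy <- as.numeric(scale(outcome))
  zX <- scale(Xp)
  fit <- stats::lm(zy ~ zX)
  sm <- summary(fit)
  beta <- stats::coef(fit)[-1]
  names(beta) <- colnames(Xp)
  pvals <- sm$coefficients[-1, 4]
  names(pvals) <- colnames(Xp)
  list(beta = beta, p = pvals, r_squared = sm$r.squared, n = n)
}
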