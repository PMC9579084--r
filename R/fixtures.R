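# Seeded synthetic-data generators: a topic-structured training corpus with
# an optional planted shared (general) component, rubrics derived from the
# topic ground truth, summaries with known concept-coverage weights, and
# simulated raters with a controllable reliability target. These stand in
# for an instructional-text corpus, its assessment rubric, student
# summaries, and human raters, giving every other module a deterministic,
# download-free test surface.
#
# The generative model is a plain seeded multinomial topic mixture
# (generation only, no inference): each document draws tokens from its own
# topic's exclusive word list, or from a shared pool with probability
# shared_vocab_fraction. The shared pool is the planted general factor.

#' Specification of a synthetic topic corpus
#'
#' The defaults define the standard desk-scale fixture: 5 topics of 200
#' exclusive words each, 200 documents per topic, mean document length 60
#' tokens (Poisson), no shared pool. They emulate, at a size a laptop can
#' train in seconds, an instructional-domain corpus with clearly separated
#' conceptual topics.
#'
#' @param n_topics number of topics.
#' @param words_per_topic exclusive vocabulary size per topic.
#' @param shared_pool_size size of the shared (general-knowledge) pool.
#' @param shared_vocab_fraction probability that a token is drawn from the
#'   shared pool instead of the document's own topic.
#' @param topic_leak probability that a token is drawn from one of the
#'   *other* topics' word lists (uniformly), emulating the cross-topic
#'   contamination real paragraphs have. Without any cross-topic
#'   co-occurrence the trained topic centroids are exactly orthogonal and no
#'   common (general) variance exists between concepts, so the default is a
#'   small positive value.
#' @param docs_per_topic training documents per topic.
#' @param doc_length_mean mean Poisson document length (tokens).
#' @param burstiness document-level word-choice concentration: each
#'   document's within-topic word distribution is a Dirichlet perturbation
#'   of the topic's Zipf profile with concentration
#'   `burstiness * words_per_topic * zipf`. Small values emulate the word
#'   burstiness of real text (a writer reuses idiosyncratic vocabulary),
#'   which spreads within-topic term vectors and keeps the trained space
#'   from collapsing onto one dimension per topic.
#' @param seed RNG seed.
#' @return list of class `topic_spec`.
#' @export
topic_spec <- function(n_topics = 5L, words_per_topic = 200L,
                       shared_pool_size = 100L, shared_vocab_fraction = 0,
                       topic_leak = 0.05, docs_per_topic = 200L,
                       doc_length_mean = 60, burstiness = 0.2, seed = 1L) {
  stopifnot(n_topics >= 1, words_per_topic >= 1, docs_per_topic >= 1,
            doc_length_mean > 0, burstiness > 0,
            shared_vocab_fraction >= 0, shared_vocab_fraction <= 1,
            topic_leak >= 0, shared_vocab_fraction + topic_leak <= 1)
  if (shared_vocab_fraction > 0 && shared_pool_size < 1L)
    stop("infeasible spec: shared_vocab_fraction > 0 needs a shared pool")
  structure(list(n_topics = as.integer(n_topics),
                 words_per_topic = as.integer(words_per_topic),
                 shared_pool_size = as.integer(shared_pool_size),
                 shared_vocab_fraction = shared_vocab_fraction,
                 topic_leak = topic_leak,
                 docs_per_topic = as.integer(docs_per_topic),
                 doc_length_mean = doc_length_mean,
                 burstiness = burstiness,
                 seed = as.integer(seed)),
            class = "topic_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

topic_words <- function(spec) {
  lapply(seq_len(spec$n_topics), function(tj)
    sprintf("t%d_w%03d", tj, seq_len(spec$words_per_topic)))
}

shared_words <- function(spec) {
  if (spec$shared_pool_size > 0L)
    sprintf("sh_w%03d", seq_len(spec$shared_pool_size))
  else character(0)
}

#' Generate a topic-structured training corpus
#'
#' Documents are sampled as multinomial mixtures dominated by one topic:
#' each token comes from the shared pool with probability
#' `shared_vocab_fraction`, else from the document's own topic's exclusive
#' word list. Within-list draws follow a Zipf-like 1/rank profile so that
#' each topic has clearly most-frequent words (which the rubric generator
#' picks as descriptors). Deterministic given `spec$seed`.
#'
#' @param spec a [topic_spec()].
#' @return list with `corpus` (an [ir_corpus()]), `doc_topics` (integer
#'   topic per document), `topic_words` (list of per-topic exclusive word
#'   vectors), `shared_words`, `spec`.
#' @export
generate_topic_corpus <- function(spec) {
  tw <- topic_words(spec)
  sw <- shared_words(spec)
  with_seed(spec$seed, {
    n_docs <- spec$n_topics * spec$docs_per_topic
    doc_topics <- rep(seq_len(spec$n_topics), each = spec$docs_per_topic)
    zipf <- function(n) { w <- 1 / seq_len(n); w / sum(w) }
    pt <- zipf(spec$words_per_topic)
    ps <- if (length(sw)) zipf(length(sw)) else NULL
    leak <- if (spec$n_topics > 1L) spec$topic_leak else 0
    docs <- vector("list", n_docs)
    for (d in seq_len(n_docs)) {
      len <- max(1L, stats::rpois(1, spec$doc_length_mean))
      # bursty per-document word preferences around the Zipf profile
      pd <- stats::rgamma(spec$words_per_topic,
                          shape = spec$burstiness * spec$words_per_topic * pt)
      pd <- pd / sum(pd)
      # token sources: own topic, shared pool, or a uniformly drawn other
      # topic (cross-topic contamination)
      src <- sample(c("own", "shared", "leak"), len, replace = TRUE,
                    prob = c(1 - spec$shared_vocab_fraction - leak,
                             spec$shared_vocab_fraction, leak))
      toks <- character(len)
      n_own <- sum(src == "own")
      if (n_own > 0L)
        toks[src == "own"] <- sample(tw[[doc_topics[d]]], n_own,
                                     replace = TRUE, prob = pd)
      n_sh <- sum(src == "shared")
      if (n_sh > 0L) {
        psd <- stats::rgamma(length(sw),
                             shape = spec$burstiness * length(sw) * ps)
        toks[src == "shared"] <- sample(sw, n_sh, replace = TRUE,
                                        prob = psd / sum(psd))
      }
      n_lk <- sum(src == "leak")
      if (n_lk > 0L) {
        others <- setdiff(seq_len(spec$n_topics), doc_topics[d])
        lk_topics <- sample(others, n_lk, replace = TRUE)
        toks[src == "leak"] <- vapply(lk_topics, function(tj)
          sample(tw[[tj]], 1, prob = pt), character(1))
      }
      docs[[d]] <- toks
    }
    list(corpus = ir_corpus(docs),
         doc_topics = doc_topics, topic_words = tw, shared_words = sw,
         spec = spec)
  })
}

#' Derive a rubric from topic ground truth
#'
#' Descriptors are the `n_descriptors` most frequent topic-exclusive words
#' of each topic in the generated corpus (three by default, the usual
#' working recipe); `fragment_nouns` are the `fragment_length` most frequent
#' topic words, standing in for the nouns of an instructional-text fragment.
#'
#' @param truth output of [generate_topic_corpus()].
#' @param n_descriptors descriptors per concept.
#' @param fragment_length fragment noun count per concept (capped at the
#'   topic vocabulary).
#' @return An [ir_rubric()] with concepts `concept1..conceptK`.
#' @export
generate_rubric_from_topics <- function(truth, n_descriptors = 3L,
                                        fragment_length = 25L) {
  counts <- table(unlist(truth$corpus$documents, use.names = FALSE))
  concepts <- lapply(seq_along(truth$topic_words), function(tj) {
    words <- truth$topic_words[[tj]]
    freq <- as.numeric(counts[words])
    freq[is.na(freq)] <- 0
    ord <- order(-freq, words)
    present <- sum(freq > 0)
    if (present < n_descriptors)
      stop("topic ", tj, " has only ", present,
           " exclusive words present in the corpus (need ", n_descriptors, ")")
    suppressMessages(ir_concept(
      name = paste0("concept", tj),
      descriptors = words[ord][seq_len(n_descriptors)],
      fragment_nouns = words[ord][seq_len(min(fragment_length, present))],
      max_score = 2))
  })
  ir_rubric(concepts, text_id = "synthetic")
}

#' Specification of synthetic summaries
#'
#' Coverage weights per summary are drawn from a symmetric Dirichlet over
#' the concepts and scaled by `1 - noise_word_rate`; the remainder of each
#' summary is off-topic noise drawn uniformly from the whole corpus
#' vocabulary. Defaults: 200 summaries, gamma-distributed lengths of mean
#' 80 tokens (SD 25, mirroring the length variability of real student
#' summaries), 20% noise, Dirichlet concentration 2 so every summary covers
#' most concepts to varying degree — which, combined with length variance,
#' produces the positive manifold of concept scores seen in real summary
#' data.
#'
#' @param n_summaries number of summaries.
#' @param length_mean mean summary length in tokens.
#' @param length_sd between-summary SD of length (gamma distributed), a
#'   proxy for writer productivity/ability; real summary corpora show a
#'   coefficient of variation around 0.2-0.25.
#' @param noise_word_rate expected fraction of off-topic tokens, in `[0,1)`.
#' @param alpha Dirichlet concentration for the coverage weights.
#' @param seed RNG seed.
#' @return list of class `summary_spec`.
#' @export
summary_spec <- function(n_summaries = 200L, length_mean = 80,
                         length_sd = 25, noise_word_rate = 0.2,
                         alpha = 2, seed = 1L) {
  stopifnot(n_summaries >= 1, length_mean > 0, length_sd >= 0,
            noise_word_rate >= 0, noise_word_rate < 1, alpha > 0)
  structure(list(n_summaries = as.integer(n_summaries),
                 length_mean = length_mean, length_sd = length_sd,
                 noise_word_rate = noise_word_rate, alpha = alpha,
                 seed = as.integer(seed)),
            class = "summary_spec")
}

#' Generate summaries with known concept coverage
#'
#' Each summary's tokens are drawn from the topic word lists in proportion
#' to its coverage weights, with shared-pool tokens folded in at the corpus'
#' `shared_vocab_fraction` and uniform off-topic noise at `noise_word_rate`.
#' The true coverage matrix is returned for recovery tests.
#'
#' @param spec a [summary_spec()].
#' @param truth output of [generate_topic_corpus()].
#' @param coverage optional n_summaries x n_topics matrix of coverage
#'   weights (rows summing to at most 1) overriding the Dirichlet draw; the
#'   per-row remainder up to 1 is off-topic noise.
#' @return list with `corpus` (an [ir_corpus()] of summaries, ids
#'   `sum1..sumN`), `coverage` (n_summaries x n_topics matrix of true
#'   weights, rows summing to `1 - noise_word_rate`), `counts` (realized
#'   topical token counts per summary and concept, the natural criterion for
#'   simulated raters since raw projection scores also grow with length),
#'   and `lengths`.
#' @export
generate_summaries <- function(spec, truth, coverage = NULL) {
  k <- truth$spec$n_topics
  tw <- truth$topic_words
  sw <- truth$shared_words
  shared_frac <- truth$spec$shared_vocab_fraction
  vocab_all <- c(unlist(tw), sw)
  zipf <- function(n) { w <- 1 / seq_len(n); w / sum(w) }
  pt <- zipf(truth$spec$words_per_topic)
  with_seed(spec$seed, {
    if (is.null(coverage)) {
      W <- matrix(stats::rgamma(spec$n_summaries * k, shape = spec$alpha),
                  spec$n_summaries, k)
      W <- W / rowSums(W) * (1 - spec$noise_word_rate)
    } else {
      W <- as.matrix(coverage)
      if (nrow(W) != spec$n_summaries || ncol(W) != k)
        stop("coverage must be n_summaries x n_topics")
      if (any(W < 0) || any(rowSums(W) > 1 + 1e-12))
        stop("coverage rows must be nonnegative and sum to at most 1")
    }
    lens <- if (spec$length_sd > 0) {
      sh <- (spec$length_mean / spec$length_sd)^2
      pmax(3L, as.integer(round(stats::rgamma(spec$n_summaries, shape = sh,
                                              rate = sh / spec$length_mean))))
    } else rep(max(3L, as.integer(round(spec$length_mean))),
               spec$n_summaries)
    cnt <- matrix(0L, spec$n_summaries, k)
    docs <- vector("list", spec$n_summaries)
    for (i in seq_len(spec$n_summaries)) {
      len <- lens[i]
      kind <- sample(c(seq_len(k), 0L), len, replace = TRUE,
                     prob = c(W[i, ], max(1 - sum(W[i, ]), 0)))
      toks <- character(len)
      for (tj in seq_len(k)) {
        nij <- sum(kind == tj)
        cnt[i, tj] <- nij
        if (nij == 0L) next
        # respect the corpus' shared-vocabulary mixture inside topical tokens
        nsh <- stats::rbinom(1, nij, shared_frac)
        tt <- sample(tw[[tj]], nij - nsh, replace = TRUE, prob = pt)
        if (nsh > 0L) tt <- c(tt, sample(sw, nsh, replace = TRUE))
        toks[kind == tj] <- sample(tt)
      }
      nnoise <- sum(kind == 0L)
      if (nnoise > 0L)
        toks[kind == 0L] <- sample(vocab_all, nnoise, replace = TRUE)
      docs[[i]] <- toks
    }
    colnames(W) <- paste0("concept", seq_len(k))
    colnames(cnt) <- colnames(W)
    ids <- paste0("sum", seq_len(spec$n_summaries))
    rownames(W) <- rownames(cnt) <- ids
    list(corpus = ir_corpus(docs, doc_ids = ids),
         coverage = W, counts = cnt, lengths = lens)
  })
}

#' Specification of simulated raters
#'
#' @param n_raters number of raters (default 2, the usual blind double
#'   rating).
#' @param reliability target single-rater reliability (ICC-like), in
#'   `(0, 1]`.
#' @param scale_max maximum rubric score (default 2, the 0-2 conceptual-axis
#'   scale).
#' @param seed RNG seed.
#' @return list of class `rater_spec`.
#' @export
rater_spec <- function(n_raters = 2L, reliability = 0.8, scale_max = 2L,
                       seed = 1L) {
  if (reliability <= 0 || reliability > 1)
    stop("reliability must be in (0, 1]")
  stopifnot(n_raters >= 1, scale_max > 0)
  structure(list(n_raters = as.integer(n_raters), reliability = reliability,
                 scale_max = as.integer(scale_max), seed = as.integer(seed)),
            class = "rater_spec")
}

# latent correlation needed so that, after discretization to
# scale_max + 1 levels, the between-rater correlation hits the target.
# First-order closed form: categorization attenuates a bivariate-normal
# correlation by a^2 where a = cor(X, cat(X)); refined by a
# common-random-numbers simulation because the approximation degrades as
# rho -> 1.
calibrate_latent_rho <- function(target, scale_max) {
  cuts <- stats::qnorm(seq_len(scale_max) / (scale_max + 1))
  a_cov <- sum(stats::dnorm(cuts))
  p_lev <- diff(c(0, stats::pnorm(cuts), 1))
  lev <- 0:scale_max
  a_var <- sum(p_lev * lev^2) - sum(p_lev * lev)^2
  a2 <- a_cov^2 / a_var
  rho0 <- min(target / a2, 0.999)
  if (target >= 0.999) return(1)
  n <- 20000L
  z1 <- with_seed(991L, stats::rnorm(n))
  e2 <- with_seed(992L, stats::rnorm(n))
  catg <- function(x) findInterval(x, cuts)
  f <- function(rho) {
    x2 <- rho * z1 + sqrt(1 - rho^2) * e2
    stats::cor(catg(z1), catg(x2)) - target
  }
  out <- tryCatch(stats::uniroot(f, c(max(rho0 - 0.2, 0.01),
                                      min(rho0 + 0.15, 0.9999)),
                                 extendInt = "upX", tol = 1e-4)$root,
                  error = function(e) rho0)
  min(out, 1)
}

#' Generate simulated human ratings from true coverage
#'
#' Each rater's score for a concept is a discretized monotone transform of
#' the true coverage plus rater-specific Gaussian noise. The coverage column
#' is first mapped to normal scores; each rater observes
#' `sqrt(rho) * z + sqrt(1 - rho) * noise` with the latent correlation `rho`
#' calibrated (closed-form approximation refined by a common-random-numbers
#' simulation) so that the between-rater correlation of the discretized
#' 0..scale_max scores matches the reliability target; scores are cut at
#' equal-probability thresholds.
#'
#' @param coverage n_docs x n_concepts matrix of true coverage weights
#'   (column names become concept names).
#' @param spec a [rater_spec()].
#' @param doc_ids optional document ids (default rownames or `sum1..sumN`).
#' @return A [rating_table()] with attribute `latent` (the noise-free
#'   normal-score matrix) for recovery tests.
#' @export
generate_ratings <- function(coverage, spec, doc_ids = NULL) {
  W <- as.matrix(coverage)
  n <- nrow(W); k <- ncol(W)
  if (is.null(colnames(W))) colnames(W) <- paste0("concept", seq_len(k))
  if (is.null(doc_ids))
    doc_ids <- rownames(W) %||% paste0("sum", seq_len(n))
  rho <- if (spec$reliability >= 1) 1
         else calibrate_latent_rho(spec$reliability, spec$scale_max)
  cuts <- stats::qnorm(seq_len(spec$scale_max) / (spec$scale_max + 1))
  with_seed(spec$seed, {
    latent <- apply(W, 2, function(col)
      stats::qnorm((rank(col, ties.method = "average") - 0.5) / n))
    rows <- vector("list", spec$n_raters * k)
    ri <- 0L
    for (r in seq_len(spec$n_raters)) {
      for (cj in seq_len(k)) {
        eps <- stats::rnorm(n)
        obs <- sqrt(rho) * latent[, cj] + sqrt(1 - rho) * eps
        sc <- findInterval(obs, cuts)   # 0..scale_max by construction
        ri <- ri + 1L
        rows[[ri]] <- data.frame(doc_id = doc_ids,
                                 rater_id = paste0("r", r),
                                 concept = colnames(W)[cj],
                                 score = sc, stringsAsFactors = FALSE)
      }
    }
    rt <- rating_table(do.call(rbind, rows),
                       scale_max = stats::setNames(rep(spec$scale_max, k),
                                                   colnames(W)))
    attr(rt, "latent") <- latent
    rt
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Generates corpus, rubric, summaries, ratings, and their ground truth, and
#' writes them as plain-text artifacts (`corpus.txt`, `rubric.yaml`,
#' `summaries.txt`, `coverage.csv`, `ratings.csv`, `doc_topics.csv`).
#'
#' @param dir target directory.
#' @param tspec,sspec,rspec specifications ([topic_spec()],
#'   [summary_spec()], [rater_spec()]).
#' @return `dir`, invisibly.
#' @export
write_fixture_dataset <- function(dir, tspec = topic_spec(),
                                  sspec = summary_spec(),
                                  rspec = rater_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_topic_corpus(tspec)
  rubric <- generate_rubric_from_topics(truth)
  sums <- generate_summaries(sspec, truth)
  ratings <- generate_ratings(sums$counts, rspec)
  writeLines(vapply(truth$corpus$documents, paste, character(1),
                    collapse = " "),
             file.path(dir, "corpus.txt"))
  write_rubric(rubric, file.path(dir, "rubric.yaml"))
  writeLines(vapply(sums$corpus$documents, paste, character(1),
                    collapse = " "),
             file.path(dir, "summaries.txt"))
  utils::write.csv(data.frame(doc_id = sums$corpus$doc_ids, sums$coverage),
                   file.path(dir, "coverage.csv"), row.names = FALSE)
  write_rating_table(ratings, file.path(dir, "ratings.csv"))
  utils::write.csv(data.frame(doc_id = truth$corpus$doc_ids,
                              topic = truth$doc_topics),
                   file.path(dir, "doc_topics.csv"), row.names = FALSE)
  invisible(dir)
}
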