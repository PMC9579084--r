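test_that("topic corpus generation is seeded and structurally sound", {
  spec <- topic_spec(n_topics = 3, words_per_topic = 30, docs_per_topic = 20,
                     doc_length_mean = 25, seed = 5)
  g1 <- generate_topic_corpus(spec)
  g2 <- generate_topic_corpus(spec)
  expect_identical(g1$corpus$documents, g2$corpus$documents)
  expect_identical(g1$doc_topics, g2$doc_topics)
  expect_length(g1$corpus, 60)
  # topic word lists are disjoint
  expect_equal(anyDuplicated(unlist(g1$topic_words)), 0)
  # single topic: every document shares the label
  g_one <- generate_topic_corpus(topic_spec(n_topics = 1,
                                            words_per_topic = 20,
                                            docs_per_topic = 10,
                                            doc_length_mean = 15, seed = 2))
  expect_true(all(g_one$doc_topics == 1L))
  expect_error(topic_spec(shared_vocab_fraction = 0.3,
                          shared_pool_size = 0), "infeasible")
})

test_that("trained fixture spaces separate topics: intra >> inter cosine", {
  fx <- small_fixture(seed = 29, shared = 0, k = 15)
  # with no shared pool and default leak, documents of the same topic are
  # far more similar than documents of different topics
  dv <- t(vapply(fx$truth$corpus$documents[c(1:6, 41:46, 81:86)],
                 function(d) as.numeric(fold_in(d, fx$space)),
                 numeric(15)))
  grp <- rep(1:3, each = 6)
  intra <- c(); inter <- c()
  for (i in 1:17) for (j in (i + 1):18) {
    cs <- cosine(dv[i, ], dv[j, ])
    if (grp[i] == grp[j]) intra <- c(intra, cs) else inter <- c(inter, cs)
  }
  expect_gt(mean(intra), mean(inter) + 0.5)
})

test_that("rubric generation takes top-frequency exclusive words and respects caps", {
  fx <- small_fixture(seed = 3)
  rub <- generate_rubric_from_topics(fx$truth, n_descriptors = 3,
                                     fragment_length = 10)
  counts <- table(unlist(fx$truth$corpus$documents))
  for (tj in seq_along(rub$concepts)) {
    cc <- rub$concepts[[tj]]
    expect_length(cc$descriptors, 3)
    expect_true(all(cc$descriptors %in% fx$truth$topic_words[[tj]]))
    # descriptors are the most frequent exclusive words
    freqs <- as.numeric(counts[fx$truth$topic_words[[tj]]])
    freqs[is.na(freqs)] <- 0
    top3 <- sort(freqs, decreasing = TRUE)[3]
    expect_true(all(as.numeric(counts[cc$descriptors]) >= top3))
  }
  # descriptors disjoint across concepts (exclusive word lists)
  all_desc <- unlist(lapply(rub$concepts, `[[`, "descriptors"))
  expect_equal(anyDuplicated(all_desc), 0)
  # fragment_length >= topic vocabulary returns all present topic words
  rub_full <- generate_rubric_from_topics(fx$truth, fragment_length = 10000)
  present <- sum(fx$truth$topic_words[[1]] %in%
                   unlist(fx$truth$corpus$documents))
  expect_length(rub_full$concepts[[1]]$fragment_nouns, present)
})

test_that("summaries respect coverage weights and are seeded", {
  fx <- small_fixture(seed = 3)
  sspec <- summary_spec(n_summaries = 40, length_mean = 60, seed = 9)
  s1 <- generate_summaries(sspec, fx$truth)
  s2 <- generate_summaries(sspec, fx$truth)
  expect_identical(s1$corpus$documents, s2$corpus$documents)
  expect_equal(rowSums(s1$coverage), rep(0.8, 40), tolerance = 1e-12,
               ignore_attr = TRUE)
  # realized counts sum to summary length minus noise tokens
  expect_true(all(rowSums(s1$counts) <= s1$lengths))
  # expected token shares track coverage within multinomial error:
  # aggregate over summaries for stability
  topical <- rowSums(s1$counts)
  expect_equal(colSums(s1$counts) / sum(topical),
               colSums(s1$coverage * s1$lengths) /
                 sum(s1$coverage * s1$lengths),
               tolerance = 0.05, ignore_attr = TRUE)
  # pure concept-1 coverage puts every token in the topic-1 list
  W1 <- matrix(0, 5, 3); W1[, 1] <- 1
  one <- generate_summaries(summary_spec(n_summaries = 5, length_mean = 40,
                                         seed = 4), fx$truth, coverage = W1)
  topic1 <- c(fx$truth$topic_words[[1]], fx$truth$shared_words)
  expect_true(all(unlist(one$corpus$documents) %in% topic1))
  expect_true(all(one$counts[, 2:3] == 0))
})

test_that("simulated raters hit the reliability target and stay on scale", {
  fx <- small_fixture(seed = 3)
  sums <- generate_summaries(summary_spec(n_summaries = 200, seed = 9),
                             fx$truth)
  # perfect reliability: identical rating columns, consistency ICC 1
  rt1 <- generate_ratings(sums$counts, rater_spec(reliability = 1, seed = 2))
  m1 <- ratings_matrix(rt1, "concept1")
  expect_identical(m1[, 1], m1[, 2])
  expect_equal(icc_two_way_mixed(m1)$icc, 1, tolerance = 1e-12)
  # all scores within [0, scale_max]
  expect_true(all(rt1$score >= 0 & rt1$score <= 2))
  expect_error(rater_spec(reliability = 1.2), "reliability")
  # reliability 0.8 calibration: ICC within +/- 0.1 in >= 9 of 10 runs
  hits <- 0L
  for (s in 1:10) {
    rt <- generate_ratings(sums$counts, rater_spec(reliability = 0.8,
                                                   seed = 700 + s))
    iccs <- vapply(colnames(sums$counts), function(cc)
      icc_two_way_mixed(ratings_matrix(rt, cc))$icc, numeric(1))
    if (all(abs(iccs - 0.8) <= 0.1)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("rating tables slice correctly and round-trip through CSV", {
  fx <- small_fixture(seed = 3)
  sums <- generate_summaries(summary_spec(n_summaries = 20, seed = 9),
                             fx$truth)
  rt <- generate_ratings(sums$counts, rater_spec(seed = 4))
  expect_s3_class(rt, "rating_table")
  expect_equal(dim(ratings_matrix(rt, "concept2")), c(20, 2))
  expect_equal(dim(ratings_wide(rt)), c(20, 6))
  tot <- ratings_matrix(rt, "total")
  expect_equal(tot[3, 1],
               sum(rt$score[rt$doc_id == rt$doc_id[3] &
                              rt$rater_id == "r1"]))
  f <- tempfile(fileext = ".csv")
  write_rating_table(rt, f)
  rt2 <- read_rating_table(f)
  expect_equal(ratings_wide(rt2), ratings_wide(rt))
  unlink(f)
})

test_that("fixture dataset writes a complete plain-text artifact set", {
  dir <- file.path(tempdir(), "fixture_ds")
  write_fixture_dataset(
    dir,
    tspec = topic_spec(n_topics = 2, words_per_topic = 25,
                       docs_per_topic = 15, doc_length_mean = 20, seed = 1),
    sspec = summary_spec(n_summaries = 12, length_mean = 30, seed = 2),
    rspec = rater_spec(seed = 3))
  for (f in c("corpus.txt", "rubric.yaml", "summaries.txt", "coverage.csv",
              "ratings.csv", "doc_topics.csv"))
    expect_true(file.exists(file.path(dir, f)))
  # artifacts are loadable
  corp <- read_corpus(file.path(dir, "corpus.txt"))
  expect_length(corp, 30)
  rub <- read_rubric(file.path(dir, "rubric.yaml"))
  expect_length(rub$concepts, 2)
  rt <- read_rating_table(file.path(dir, "ratings.csv"))
  expect_equal(length(unique(rt$doc_id)), 12)
  unlink(dir, recursive = TRUE)
})

test_that("descriptor- and fragment-based scores agree on fixture summaries", {
  fx <- small_fixture(seed = 37, k = 15)
  ms_d <- build_meaningful_space(fx$space, fx$rubric, source = "descriptors",
                                 seed = 2)
  ms_f <- build_meaningful_space(fx$space, fx$rubric, source = "fragments",
                                 seed = 2)
  sums <- generate_summaries(summary_spec(n_summaries = 80, seed = 5),
                             fx$truth)
  sd_ <- score_matrix(score_corpus(ms_d, sums$corpus))
  sf_ <- score_matrix(score_corpus(ms_f, sums$corpus))
  for (j in 1:3) expect_gt(cor(sd_[, j], sf_[, j]), 0.7)
})
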