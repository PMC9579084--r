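# Shared test fixtures, all generated in code under fixed seeds.

# a small topic-structured space: 3 topics x 40 docs, vocab 120(+30 shared)
small_fixture <- function(seed = 7, shared = 0, k = 20) {
  tr <- generate_topic_corpus(topic_spec(
    n_topics = 3, words_per_topic = 40, shared_pool_size = 30,
    shared_vocab_fraction = shared, docs_per_topic = 40,
    doc_length_mean = 30, seed = seed))
  tdm <- build_term_doc_matrix(tr$corpus)
  lw <- log_entropy_weight(tdm)
  space <- train_space(lw, k = k)
  rubric <- generate_rubric_from_topics(tr, fragment_length = 10)
  list(truth = tr, tdm = tdm, space = space, rubric = rubric)
}

# deterministic tiny dense space from an explicit matrix (for unit tests
# that need exact control over term vectors)
toy_space <- function(tv) {
  structure(
    list(term_vectors = tv,
         singular_values = rev(sort(sqrt(colSums(tv^2)))),
         vocabulary = rownames(tv), k = ncol(tv),
         global_weights = stats::setNames(rep(1, nrow(tv)), rownames(tv))),
    class = "semantic_space")
}

# brute-force cosine by scalar loop (oracle)
cosine_loop <- function(a, b) {
  s <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    s <- s + a[i] * b[i]; na <- na + a[i]^2; nb <- nb + b[i]^2
  }
  s / (sqrt(na) * sqrt(nb))
}

topic_centroid <- function(space, words) {
  words <- intersect(words, space$vocabulary)
  colSums(space$term_vectors[match(words, space$vocabulary), , drop = FALSE])
}
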