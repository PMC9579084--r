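test_that("beta assembly is seeded, counted, and uniform over fill coordinates", {
  fx <- small_fixture(k = 10)
  cvs <- concept_vectors(fx$space, fx$rubric)[1:2]
  b1 <- assemble_beta(fx$space, cvs, seed = 42)
  b2 <- assemble_beta(fx$space, cvs, seed = 42)
  expect_identical(b1$columns, b2$columns)
  expect_identical(b1$fill_indices, b2$fill_indices)
  expect_equal(ncol(b1$columns), 10)
  expect_equal(length(b1$fill_indices), 8)
  # fill columns are distinct canonical unit vectors
  fill <- b1$columns[, 3:10]
  expect_true(all(colSums(fill) == 1 & colSums(fill^2) == 1))
  expect_false(anyDuplicated(b1$fill_indices) > 0)
  # k = p - 1 leaves exactly one fill column
  cvs9 <- rep(cvs, length.out = 9)
  # make 9 distinct unit vectors so assembly is legal
  set.seed(1)
  cvs9 <- lapply(1:9, function(i) {
    v <- rnorm(10); structure(list(concept_name = paste0("c", i),
                                   vector = v / sqrt(sum(v^2))),
                              class = "concept_vector")
  })
  b9 <- assemble_beta(fx$space, cvs9, seed = 1)
  expect_length(b9$fill_indices, 1)
  expect_error(assemble_beta(fx$space, c(cvs9, cvs9[1])[1:10], seed = 1),
               "must be <")
  # uniform coverage of fill coordinates across seeds (chi-square)
  counts <- integer(10)
  for (s in 1:200) {
    b <- assemble_beta(fx$space, cvs, seed = s)
    counts[b$fill_indices] <- counts[b$fill_indices] + 1L
  }
  expected <- 200 * 8 / 10
  chi2 <- sum((counts - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 9))
})

test_that("gram_schmidt orthonormalizes, is idempotent, and preserves span", {
  fx <- small_fixture(k = 10)
  cvs <- concept_vectors(fx$space, fx$rubric)
  beta <- assemble_beta(fx$space, cvs, seed = 5)
  ob <- gram_schmidt(beta)
  Q <- ob$columns
  expect_lt(max(abs(crossprod(Q) - diag(10))), 1e-10)
  expect_true(all(ob$fidelity >= -1 & ob$fidelity <= 1))
  # idempotence
  ob2 <- gram_schmidt(ob)
  expect_lt(max(abs(ob2$columns - Q)), 1e-12)
  expect_equal(unname(ob2$fidelity), rep(1, 3), tolerance = 1e-12)
  # projector equality: span(Q) = span(input)
  set.seed(8)
  for (r in 1:5) {
    B <- matrix(rnorm(100), 10, 10)
    bm <- structure(list(columns = B, meaningful_labels = "c1", k = 1,
                         has_general = FALSE, fill_indices = integer(0),
                         seed = 0L, orthonormal = FALSE),
                    class = "beta_matrix")
    qb <- gram_schmidt(bm)$columns
    P1 <- qb %*% t(qb)
    P2 <- B %*% solve(crossprod(B)) %*% t(B)
    expect_lt(max(abs(P1 - P2)), 1e-8)
    expect_lt(max(abs(crossprod(qb) - diag(10))), 1e-10)
  }
})

test_that("the 2-D worked case gives fidelity cos(45 deg) and trips the strict gate", {
  B <- cbind(c(1, 0), c(1, 1) / sqrt(2))
  bm <- structure(list(columns = B, meaningful_labels = c("c1", "c2"),
                       k = 2, has_general = FALSE, fill_indices = integer(0),
                       seed = 0L, orthonormal = FALSE),
                  class = "beta_matrix")
  expect_warning(ob <- gram_schmidt(bm), "fidelity below 0.8")
  expect_equal(ob$columns, cbind(c(1, 0), c(0, 1)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(ob$fidelity["c2"]), cos(pi / 4), tolerance = 1e-10)
  expect_error(gram_schmidt(bm, strict = TRUE), "fidelity below 0.8")
  # degenerate basis errors with the offending column named
  Bd <- cbind(c(1, 0), c(1, 1e-14))
  bmd <- bm; bmd$columns <- Bd
  expect_error(gram_schmidt(bmd), "degenerate basis")
})

test_that("change of basis is a rotation: coordinates read as inner products, cosines preserved", {
  fx <- small_fixture(k = 12)
  cvs <- concept_vectors(fx$space, fx$rubric)
  ob <- gram_schmidt(assemble_beta(fx$space, cvs, seed = 2))
  ms <- change_basis(fx$space, ob)
  # identity beta leaves the space unchanged
  id_beta <- structure(list(columns = diag(12),
                            meaningful_labels = paste0("d", 1:3), k = 3,
                            has_general = FALSE, fill_indices = 4:12,
                            seed = 0L, orthonormal = TRUE, fidelity = NULL),
                       class = "beta_matrix")
  ms_id <- change_basis(fx$space, id_beta)
  expect_equal(unname(ms_id$term_vectors), unname(fx$space$term_vectors))
  # v = c * beta_1 has rotated coordinates (c, 0, ..., 0)
  v <- 2.5 * ob$columns[, 1]
  expect_equal(as.numeric(crossprod(ob$columns, v)),
               c(2.5, rep(0, 11)), tolerance = 1e-10)
  # non-orthonormal input refused
  raw <- assemble_beta(fx$space, cvs, seed = 2)
  expect_error(change_basis(fx$space, raw), "not orthonormal")
  # rotation invariance on 1,000 random term pairs
  set.seed(21)
  nt <- nrow(fx$space$term_vectors)
  prs <- cbind(sample(nt, 1000, TRUE), sample(nt, 1000, TRUE))
  prs <- prs[prs[, 1] != prs[, 2], , drop = FALSE]
  for (i in seq_len(nrow(prs))) {
    c1 <- cosine(fx$space$term_vectors[prs[i, 1], ],
                 fx$space$term_vectors[prs[i, 2], ])
    c2 <- cosine(ms$term_vectors[prs[i, 1], ],
                 ms$term_vectors[prs[i, 2], ])
    expect_lt(abs(c1 - c2), 1e-10)
  }
  # norms preserved
  expect_equal(rowSums(ms$term_vectors^2), rowSums(fx$space$term_vectors^2),
               tolerance = 1e-8)
})

test_that("general-vector estimation handles rank-1 and k = 1 degenerate cases", {
  # all subset vectors identical: general vector is that direction
  tv <- rbind(a = c(3, 4, 0), b = c(3, 4, 0), other = c(0, 0, 1),
              pad1 = c(1, 0, 0), pad2 = c(0, 1, 0))
  colnames(tv) <- paste0("dim", 1:3)
  sp <- toy_space(tv)
  rub <- ir_rubric(list(suppressMessages(
    ir_concept("c1", descriptors = c("a", "b")))))
  gen <- suppressWarnings(estimate_general_vector(sp, rub, split_seed = 1))
  expect_equal(abs(sum(gen$general_vector * c(0.6, 0.8, 0))), 1,
               tolerance = 1e-6)
  expect_equal(gen$loadings[1], gen$loadings[2], tolerance = 1e-4)
  # k = 1 with a single lexeme duplicated across splits
  rub1 <- ir_rubric(list(suppressMessages(
    ir_concept("c1", descriptors = "a"))))
  expect_warning(gen1 <- estimate_general_vector(sp, rub1, split_seed = 1),
                 "fewer lexemes")
  expect_equal(abs(sum(gen1$general_vector * c(0.6, 0.8, 0))), 1,
               tolerance = 1e-6)
  expect_error(suppressWarnings(
    estimate_general_vector(sp, rub1, split_seed = 1, strict = TRUE)),
    "single usable lexeme")
})

test_that("general vector tracks a planted shared component", {
  fx <- small_fixture(seed = 11, shared = 0.25, k = 20)
  gen <- estimate_general_vector(fx$space, fx$rubric, split_seed = 3)
  shared_dir <- topic_centroid(fx$space, fx$truth$shared_words)
  cos_shared <- cosine(gen$general_vector, shared_dir)
  cos_specific <- vapply(fx$truth$topic_words, function(w) {
    own <- topic_centroid(fx$space, w)
    cosine(gen$general_vector, own)
  }, numeric(1))
  expect_gt(cos_shared, max(cos_specific))
})

test_that("bifactor beta places the general column as configured and counts fill", {
  fx <- small_fixture(seed = 11, shared = 0.25, k = 20)
  cvs <- concept_vectors(fx$space, fx$rubric)
  gen <- estimate_general_vector(fx$space, fx$rubric, split_seed = 3)
  ba <- assemble_beta_bifactor(fx$space, cvs, gen,
                               position = "after_concepts", seed = 4)
  expect_identical(ba$meaningful_labels,
                   c("concept1", "concept2", "concept3", "G"))
  bf <- assemble_beta_bifactor(fx$space, cvs, gen,
                               position = "general_first", seed = 4)
  expect_identical(bf$meaningful_labels,
                   c("G", "concept1", "concept2", "concept3"))
  expect_length(ba$fill_indices, 20 - 3 - 1)
  expect_true(ba$has_general)
  # collinear general vector refused
  gen_bad <- gen
  gen_bad$general_vector <- cvs[[2]]$vector
  expect_error(assemble_beta_bifactor(fx$space, cvs, gen_bad, seed = 4),
               "collinear")
})

test_that("identical seeds reproduce rotated spaces bit-identically", {
  fx <- small_fixture(k = 12)
  m1 <- build_meaningful_space(fx$space, fx$rubric, seed = 9)
  m2 <- build_meaningful_space(fx$space, fx$rubric, seed = 9)
  expect_identical(m1$term_vectors, m2$term_vectors)
  expect_identical(m1$fidelity, m2$fidelity)
})
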