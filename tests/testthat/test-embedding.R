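test_that("anonymization relabels by first appearance and is idempotent", {
  expect_equal(anonymize_walk(c("F3", "Cz", "F3", "Pz", "Cz", "O1")),
               c(1L, 2L, 1L, 3L, 2L, 4L))
  expect_equal(anonymize_walk(c("a", "b")), c(1L, 2L))
  w <- anonymize_walk(c(4, 7, 4, 2))
  expect_equal(anonymize_walk(w), w)
  expect_error(anonymize_walk(c("a", "a", "b")), "consecutive")
})

test_that("pattern enumeration matches brute-force expectations", {
  expect_equal(enumerate_walk_patterns(2), list(c(1L, 2L, 1L), c(1L, 2L, 3L)))
  expect_equal(enumerate_walk_patterns(3),
               list(c(1L, 2L, 1L, 2L), c(1L, 2L, 1L, 3L), c(1L, 2L, 3L, 1L),
                    c(1L, 2L, 3L, 2L), c(1L, 2L, 3L, 4L)))
  counts <- sapply(1:6, function(l) length(enumerate_walk_patterns(l)))
  expect_equal(counts, bell_numbers(6))   # 1 2 5 15 52 203
  expect_error(enumerate_walk_patterns(0), "l")
})

test_that("every enumerated pattern satisfies the anonymous-walk invariants", {
  for (l in 2:5) {
    pats <- enumerate_walk_patterns(l)
    labs <- pattern_labels(pats)
    expect_equal(anyDuplicated(labs), 0L)
    expect_identical(labs, sort(labs))   # canonical lexicographic order
    for (p in pats) {
      expect_equal(p[1], 1L)
      expect_true(all(diff(p) != 0))
      expect_true(all(p <= cummax(c(1L, head(p, -1))) + 1L))
      expect_equal(anonymize_walk(p), p)
    }
  }
})

test_that("exact embedding reproduces closed-form small-graph values", {
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(unname(walk_embedding(k3, l = 2)), c(1 / 2, 1 / 2))
  p3 <- matrix(0, 3, 3)
  p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(unname(walk_embedding(p3, l = 2)), c(2 / 3, 1 / 3))
  edgeless <- matrix(0, 16, 16)
  expect_equal(sum(walk_embedding(edgeless, l = 5)), 0)
})

test_that("the compiled kernel equals brute-force walk enumeration", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    adj <- random_adjacency(n, runif(1, 0.3, 0.9))
    for (l in 2:4) {
      got <- walk_embedding(adj, l = l)
      want <- brute_force_embedding(adj, l)
      expect_equal(got, want, tolerance = 1e-12)
      if (sum(adj) > 0) expect_equal(sum(got), 1, tolerance = 1e-12)
    }
  }
})

test_that("the embedding is invariant under node relabeling", {
  set.seed(8)
  adj <- random_adjacency(16, 0.25)
  perm <- sample(16)
  expect_equal(walk_embedding(adj, l = 5),
               walk_embedding(adj[perm, perm], l = 5), tolerance = 1e-12)
})

test_that("sampled embeddings converge to the exact distribution", {
  set.seed(9)
  adj <- random_adjacency(16, 0.3)
  exact <- walk_embedding(adj, l = 5)
  sampled <- walk_embedding(adj, l = 5, mode = "sampled",
                            n_samples = 1e5, seed = 99)
  expect_equal(sum(sampled), 1, tolerance = 1e-12)
  tv <- sum(abs(exact - sampled)) / 2
  expect_lt(tv, 0.02)

  one <- walk_embedding(adj, l = 5, mode = "sampled", n_samples = 1,
                        seed = 5)
  expect_equal(sum(one == 1), 1)    # a single walk is a one-hot vector
  expect_equal(sum(one), 1)

  again <- walk_embedding(adj, l = 5, mode = "sampled",
                          n_samples = 1e3, seed = 123)
  expect_identical(walk_embedding(adj, l = 5, mode = "sampled",
                                  n_samples = 1e3, seed = 123), again)
  expect_warning(walk_embedding(matrix(0, 4, 4), l = 3, mode = "sampled"),
                 "edgeless")
})

test_that("walk-length tuning maximizes cross-validated F1, ties to shorter", {
  study <- generate_study(study_config(n_players = 6, n_games = 4,
                                       saliency = 0.3, seed = 13))
  cv <- cv_config(k = 2, nrounds = 20, seed = 13)
  single <- tune_walk_length(study, lengths = 3, cv = cv)
  expect_equal(single$length, 3L)

  res <- tune_walk_length(study, lengths = c(2, 4), cv = cv)
  expect_true(res$length %in% c(2L, 4L))
  expect_equal(res$f1[[as.character(res$length)]], max(res$f1))
  expect_identical(tune_walk_length(study, lengths = c(2, 4), cv = cv)$f1,
                   res$f1)
  expect_error(tune_walk_length(study, lengths = integer(0)), "candidate")
})
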