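test_that("config validation rejects out-of-range parameters", {
  expect_error(study_config(saliency = 1.2), "saliency")
  expect_error(study_config(coupling = -0.1), "rho")
  expect_error(study_config(saliency = c(0.1, 0.2)), "length")
  expect_error(study_config(noise_sd = -1), "noise_sd")
})

test_that("saliency one forces unanimous focal choices", {
  ch <- sample_choices(study_config(saliency = 1, seed = 3))
  expect_true(all(ch == 1L))
  expect_equal(choice_tally(ch, 1), 10L)
})

test_that("uniform choices give mean CI near the multinomial expectation", {
  # for m ~ Multinomial(N, p), E[m_j (m_j - 1)] = N (N - 1) p_j^2, so
  # E[CI] = sum_j p_j^2 = 1/4 under uniform choice over 4 options
  cis <- unlist(lapply(1:50, function(s) {
    ch <- sample_choices(study_config(n_games = 200, saliency = 0, seed = s))
    ci_table(ch)$ci
  }))
  expect_length(cis, 10000)
  expect_equal(mean(cis), 0.25, tolerance = 0.02)
})

test_that("choices are reproducible and saliency-monotone in mean CI", {
  cfg <- study_config(seed = 11)
  expect_identical(sample_choices(cfg), sample_choices(cfg))
  mean_ci <- sapply(c(0, 0.4, 0.8), function(s) {
    cis <- unlist(lapply(1:10, function(sd) {
      ch <- sample_choices(study_config(n_games = 100, saliency = s, seed = sd))
      ci_table(ch)$ci
    }))
    mean(cis)
  })
  expect_true(all(diff(mean_ci) > 0))
})

test_that("templates are covering disjoint partitions, distinct per option", {
  cfg <- study_config(seed = 21)
  tpl <- build_templates(cfg)
  expect_length(tpl, cfg$n_games)
  for (g in seq_len(cfg$n_games)) {
    for (o in seq_len(cfg$n_options)) {
      part <- tpl[[g]][[o]]
      chans <- sort(unlist(part))
      expect_identical(as.integer(chans), seq_len(cfg$n_channels))
      # at most one singleton leftover, all other blocks >= 2
      expect_lte(sum(lengths(part) == 1L), 1L)
    }
    profiles <- sapply(tpl[[g]], function(p) paste(sort(lengths(p)), collapse = ","))
    expect_equal(anyDuplicated(profiles), 0L)
  }
  expect_identical(tpl, build_templates(cfg))
})

test_that("full coupling without noise duplicates module channels exactly", {
  cfg <- study_config(coupling = 1, noise_sd = 0, seed = 2)
  part <- list(1:8, 9:16)
  ep <- synthesize_epoch(part, cfg)
  for (mod in part)
    for (ch in mod[-1])
      expect_equal(unclass(ep)[ch, ], unclass(ep)[mod[1], ])
  pre <- preprocess_epoch(ep)
  coh <- pairwise_coherence(pre)
  expect_equal(unname(coh[1, 2]), 1, tolerance = 1e-8)
})

test_that("independent channels rarely cross the coherence threshold", {
  set.seed(42)
  cfg <- study_config(coupling = 0, seed = 1)
  part <- list(1:8, 9:16)
  frac <- replicate(100, {
    ep <- synthesize_epoch(part, cfg, seed = sample.int(2^31 - 1, 1))
    coh <- pairwise_coherence(preprocess_epoch(ep))
    mean(coh[upper.tri(coh)] >= 0.5)
  })
  expect_lt(mean(frac), 0.20)
})

test_that("strong coupling puts intra-module pairs above the threshold", {
  set.seed(43)
  cfg <- study_config(coupling = 0.95, seed = 1)
  part <- list(1:8, 9:16)
  intra <- outer(1:16, 1:16, function(i, j)
    (i <= 8 & j <= 8) | (i > 8 & j > 8))
  hits <- replicate(30, {
    ep <- synthesize_epoch(part, cfg, seed = sample.int(2^31 - 1, 1))
    coh <- pairwise_coherence(preprocess_epoch(ep))
    sel <- upper.tri(coh) & intra
    mean(coh[sel] >= 0.5)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("intra-module coherence increases with the coupling fraction", {
  set.seed(44)
  part <- list(1:8, 9:16)
  mean_intra <- sapply(c(0.2, 0.6, 0.95), function(rho) {
    cfg <- study_config(coupling = rho, seed = 1)
    mean(replicate(20, {
      ep <- synthesize_epoch(part, cfg, seed = sample.int(2^31 - 1, 1))
      coh <- pairwise_coherence(preprocess_epoch(ep))
      mean(coh[upper.tri(coh) & outer(1:16 <= 8, 1:16 <= 8, "==")])
    }))
  })
  expect_true(all(diff(mean_intra) > 0))
})

test_that("generate_study yields one epoch per (player, game), reproducibly", {
  cfg <- study_config(seed = 7)
  study <- generate_study(cfg)
  expect_length(study$epochs, 10)
  expect_equal(sum(lengths(study$epochs)), 120)
  expect_equal(dim(study$epochs[[3]][[5]]), c(16, 512))

  small <- generate_study(study_config(n_players = 2, n_games = 2, seed = 1))
  expect_equal(sum(lengths(small$epochs)), 4)

  again <- generate_study(cfg)
  expect_identical(study$choices, again$choices)
  expect_equal(unclass(study$epochs[[1]][[1]]),
               unclass(again$epochs[[1]][[1]]))
})

test_that("same-choice players have closer embeddings under strong coupling", {
  study <- generate_study(study_config(n_players = 6, n_games = 4, seed = 9,
                                       saliency = 0.3))
  emb <- embed_study(study)
  ds <- build_pair_dataset(emb, study$choices)
  d <- rowSums(feature_matrix(ds))
  expect_lt(mean(d[ds$label == 1]), mean(d[ds$label == 0]))
})
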