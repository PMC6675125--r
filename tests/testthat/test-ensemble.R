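test_that("global negative sampling is uniform, exact and reproducible", {
  a <- toy_assoc()
  U <- unknown_pairs(a)
  expect_equal(nrow(U), 12)

  set.seed(1); n1 <- sample_negatives_global(a, 5)
  set.seed(1); n2 <- sample_negatives_global(a, 5)
  expect_identical(n1, n2)
  expect_equal(nrow(n1), 5)
  # sampled pairs are truly unlabeled and distinct
  expect_true(all(a$Y[n1] == 0))
  expect_equal(anyDuplicated(n1), 0)

  # count = |U| returns all of U
  set.seed(2)
  expect_equal(nrow(sample_negatives_global(a, 12)), 12)
  expect_error(sample_negatives_global(a, 13), "more negatives")

  # uniformity: 1e4 single draws, each pair within 3 sigma of 1/12
  set.seed(3)
  draws <- replicate(1e4, {
    p <- sample_negatives_global(a, 1)
    (p[1, 2] - 1) * 4 + p[1, 1]
  })
  freq <- tabulate(match(draws, sort(unique(draws))), 12)
  p0 <- 1 / 12
  expect_true(all(abs(freq - 1e4 * p0) <= 3 * sqrt(1e4 * p0 * (1 - p0))))
})

test_that("local negative sampling matches per-disease positive counts", {
  a <- toy_assoc()   # disease degrees: 2, 1, 1, 0
  set.seed(4)
  N <- sample_negatives_local(a)
  expect_true(all(a$Y[N] == 0))
  counts <- tabulate(N[, 2], 4)
  expect_equal(counts, c(2, 1, 1, 0))

  # a disease whose unknowns are scarcer than its positives takes them all
  Y <- matrix(c(1, 1, 1, 0), 4, 1,
              dimnames = list(paste0("m", 1:4), "d1"))
  set.seed(5)
  N2 <- sample_negatives_local(assoc_matrix(Y))
  expect_equal(nrow(N2), 1)
  expect_equal(N2[1, 1], 4)
})

test_that("feature subsets have floor(r*d) sorted distinct indices", {
  set.seed(6)
  expect_length(sample_feature_subset(32, 0.5), 16)
  expect_length(sample_feature_subset(32, 0.8), 25)
  expect_equal(sample_feature_subset(32, 1), 1:32)
  s <- sample_feature_subset(32, 0.8)
  expect_false(is.unsorted(s))
  expect_equal(anyDuplicated(s), 0)
  expect_error(sample_feature_subset(10, 0.05), "empty")
})

test_that("base learner geometry: spliced PCA dimensions", {
  w <- small_world(seed = 8)
  sims <- integrated_similarity(w$simin, w$assoc)
  f <- build_feature_matrices(sims$SM, sims$SD, w$assoc)

  set.seed(9)
  lr <- fit_base_learner(f$FM, f$FD, w$assoc, ensemble_config())
  expect_length(lr$feat_idx, 25)                  # floor(0.8 * 32)
  expect_equal(ncol(lr$pca_m$rotation), 10)
  expect_equal(ncol(lr$pca_d$rotation), 10)       # spliced input = 20
  expect_equal(nrow(lr$negatives), nrow(positive_pairs(w$assoc)))

  # d1 = 6 features: projections shrink to min(10, 6) per side
  set.seed(10)
  lr6 <- fit_base_learner(f$FM, f$FD, w$assoc,
                          ensemble_config(r = 6 / 32))
  expect_length(lr6$feat_idx, 6)
  expect_equal(ncol(lr6$pca_m$rotation), 6)

  # training MSE of a fully grown tree on balanced 0/1 targets <= 0.25
  P <- positive_pairs(w$assoc)
  pairs <- rbind(P, lr$negatives)
  yy <- c(rep(1, nrow(P)), rep(0, nrow(lr$negatives)))
  PM <- mdforest:::apply_pca(lr$pca_m, f$FM[, lr$feat_idx])
  PD <- mdforest:::apply_pca(lr$pca_d, f$FD[, lr$feat_idx])
  pred <- predict_tree(lr$tree, mdforest:::splice_pairs(PM, PD, pairs))
  expect_lte(mean((pred - yy)^2), 0.25)
})

test_that("ensemble is deterministic, sized M, with bounded scores", {
  w <- small_world(seed = 12)
  sims <- integrated_similarity(w$simin, w$assoc)
  f <- build_feature_matrices(sims$SM, sims$SD, w$assoc)

  cfg <- ensemble_config(M = 7L, seed = 99L)
  m1 <- fit_ensemble(f$FM, f$FD, w$assoc, cfg)
  m2 <- fit_ensemble(f$FM, f$FD, w$assoc, cfg)
  expect_length(m1$learners, 7)
  s1 <- predict_scores(m1, f$FM, f$FD)
  s2 <- predict_scores(m2, f$FM, f$FD)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_equal(dim(s1), dim(w$assoc$Y))

  # growing M keeps earlier learners' streams untouched
  m10 <- fit_ensemble(f$FM, f$FD, w$assoc, ensemble_config(M = 10L, seed = 99L))
  expect_equal(m10$learners[[3]]$feat_idx, m1$learners[[3]]$feat_idx)
  expect_equal(m10$learners[[3]]$negatives, m1$learners[[3]]$negatives)

  # M = 1 is a single base learning
  mone <- fit_ensemble(f$FM, f$FD, w$assoc, ensemble_config(M = 1L, seed = 99L))
  expect_length(mone$learners, 1)
})

test_that("stale feature matrices are rejected", {
  w <- small_world(seed = 13)
  sims <- integrated_similarity(w$simin, w$assoc)
  f <- build_feature_matrices(sims$SM, sims$SD, w$assoc)
  P <- positive_pairs(w$assoc)
  Ym <- w$assoc$Y; Ym[P[1, 1], P[1, 2]] <- 0
  masked <- assoc_matrix(Ym, w$assoc$mirna_ids, w$assoc$disease_ids)
  expect_error(fit_ensemble(f$FM, f$FD, masked, ensemble_config(M = 2L)),
               "stale")
  model <- fit_ensemble(f$FM, f$FD, w$assoc, ensemble_config(M = 2L))
  fm2 <- build_feature_matrices(integrated_similarity(w$simin, masked)$SM,
                                integrated_similarity(w$simin, masked)$SD,
                                masked)
  expect_error(predict_scores(model, fm2$FM, fm2$FD), "fingerprint")
})

test_that("rf mode bags one fixed negative set", {
  w <- small_world(seed = 14)
  sims <- integrated_similarity(w$simin, w$assoc)
  f <- build_feature_matrices(sims$SM, sims$SD, w$assoc)
  m <- fit_ensemble(f$FM, f$FD, w$assoc,
                    ensemble_config(M = 4L, mode = "rf", seed = 3L))
  negs <- lapply(m$learners, `[[`, "negatives")
  expect_identical(negs[[1]], negs[[2]])
  expect_identical(negs[[1]], negs[[4]])
  expect_null(m$learners[[1]]$pca_m)
  expect_equal(m$learners[[1]]$feat_idx, 1:32)
  s <- predict_scores(m, f$FM, f$FD)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("per-learner PCA retains at least as much variance as random projections", {
  w <- small_world(seed = 15)
  sims <- integrated_similarity(w$simin, w$assoc)
  f <- build_feature_matrices(sims$SM, sims$SD, w$assoc)
  Xc <- scale(f$FM[, 1:20], center = TRUE, scale = FALSE)
  k <- 5
  pca <- mdforest:::fit_pca(f$FM[, 1:20], k)
  v_pca <- sum(apply(Xc %*% pca$rotation, 2, var))
  set.seed(16)
  for (i in 1:20) {
    Q <- qr.Q(qr(matrix(rnorm(20 * k), 20, k)))
    expect_lte(sum(apply(Xc %*% Q, 2, var)), v_pca + 1e-9)
  }
})

test_that("fresh-negative ensemble beats the bagging baseline on average", {
  # scaled down from the default world (30x20, M = 25, one 5-fold pass per
  # seed) to keep the suite fast; the direction is what matters
  res <- sapply(1:20, function(sd) {
    w <- simulate_dataset(synthetic_config(nm = 30L, nd = 20L,
                                           seed = 700 + sd))
    ens <- kfold_cv(w$assoc, w$simin,
                    ensemble_config(M = 25L, seed = sd), repeats = 1L)
    rf <- kfold_cv(w$assoc, w$simin,
                   ensemble_config(M = 25L, seed = sd, mode = "rf"),
                   repeats = 1L)
    c(ens$mean_auc, rf$mean_auc)
  })
  expect_gte(mean(res[1, ]), mean(res[2, ]))
})

test_that("training positives outrank unlabeled pairs on planted data", {
  diffs <- sapply(1:20, function(sd) {
    w <- small_world(seed = 100 + sd)
    fit <- train_and_score(w$assoc, w$simin,
                           ensemble_config(M = 15L, seed = sd))
    mean(fit$scores[positive_pairs(w$assoc)]) -
      mean(fit$scores[unknown_pairs(w$assoc)])
  })
  expect_gt(mean(diffs), 0)
})
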