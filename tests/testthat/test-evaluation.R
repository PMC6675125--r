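test_that("rank_auc counts candidates below, ties as half", {
  expect_equal(rank_auc(c(5, 6), c(1, 2, 3)), 1)
  expect_equal(rank_auc(c(0, 0.1), c(1, 2, 3)), 0)
  expect_equal(rank_auc(0.9, c(0.1, 0.5, 0.9, 0.95)), 0.625)
  expect_equal(rank_auc(1, rep(1, 4)), 0.5)
  expect_error(rank_auc(numeric(0), 1), "at least one")
})

test_that("rank_auc equals the swept ROC area, ties included", {
  set.seed(21)
  for (i in 1:25) {
    test <- sample(seq(0, 1, 0.05), sample(2:10, 1), replace = TRUE)
    cand <- sample(seq(0, 1, 0.05), sample(5:60, 1), replace = TRUE)
    expect_equal(rank_auc(test, cand), roc_curve(test, cand)$auc,
                 tolerance = 1e-9)
  }
})

test_that("LOOCV with an injected oracle or random scorer behaves as expected", {
  w <- small_world(seed = 22)
  truthY <- w$assoc$Y
  oracle <- function(masked) truthY          # knows every true positive
  g <- global_loocv(w$assoc, w$simin, scorer = oracle)
  expect_equal(g$mean_auc, 1)
  l <- local_loocv(w$assoc, w$simin, scorer = oracle)
  expect_equal(l$mean_auc, 1)

  # constant scorer ties everything: local AUC exactly 0.5
  flat <- function(masked) matrix(0.5, 20, 15)
  expect_equal(local_loocv(w$assoc, w$simin, scorer = flat)$mean_auc, 0.5)

  # random scorer is near chance (fast mode: a single scoring suffices)
  set.seed(23)
  rnd <- function(masked) matrix(runif(20 * 15), 20, 15)
  gr <- global_loocv(w$assoc, w$simin, scorer = rnd, fast = TRUE)
  expect_gt(gr$mean_auc, 0.35)
  expect_lt(gr$mean_auc, 0.65)
})

test_that("full LOOCV protocol recovers planted structure on a toy panel", {
  aucs <- sapply(1:10, function(sd) {
    w <- simulate_dataset(synthetic_config(nm = 8L, nd = 6L, n_blocks = 2L,
                                           density = 0.25, seed = 300 + sd))
    if (nrow(positive_pairs(w$assoc)) < 2) return(NA_real_)
    global_loocv(w$assoc, w$simin,
                 ensemble_config(M = 10L, seed = sd,
                                 svd_rank = 4L))$mean_auc
  })
  expect_gt(mean(aucs, na.rm = TRUE), 0.5)
})

test_that("k-fold partitions are balanced, disjoint and recomputed", {
  w <- small_world(seed = 24)
  P <- positive_pairs(w$assoc)
  seen <- list()
  spy <- function(masked) {
    seen[[length(seen) + 1L]] <<- masked
    matrix(runif(nrow(masked$Y) * ncol(masked$Y)), nrow(masked$Y))
  }
  res <- kfold_cv(w$assoc, w$simin, ensemble_config(seed = 1L),
                  k = 5L, repeats = 1L, scorer = spy)
  expect_length(res$aucs, 1)
  expect_equal(res$mean_auc, mean(res$aucs))
  expect_length(seen, 5)
  removed <- vapply(seen, function(m) nrow(P) - sum(m$Y), numeric(1))
  expect_lte(diff(range(removed)), 1)       # fold sizes differ by <= 1
  expect_equal(sum(removed), nrow(P))       # folds partition the positives
  # every fold's Y differs from the full Y (features cannot be stale)
  for (m in seen)
    expect_false(identical(assoc_fingerprint(m), assoc_fingerprint(w$assoc)))
})

test_that("repeated k-fold reports per-repeat AUCs with population sd", {
  w <- small_world(seed = 25)
  set.seed(1)
  rnd <- function(masked) matrix(runif(300), 20, 15)
  res <- kfold_cv(w$assoc, w$simin, ensemble_config(seed = 2L),
                  k = 5L, repeats = 3L, scorer = rnd)
  expect_length(res$aucs, 3)
  expect_equal(res$mean_auc, mean(res$aucs))
  expect_equal(res$sd_auc, sd(res$aucs) * sqrt(2 / 3), tolerance = 1e-12)
})

test_that("label randomization preserves counts and reproduces under seed", {
  w <- small_world(seed = 26)
  set.seed(5); r1 <- label_randomization(w$assoc)
  set.seed(5); r2 <- label_randomization(w$assoc)
  expect_identical(r1$Y, r2$Y)
  expect_equal(sum(r1$Y), sum(w$assoc$Y))
  expect_true(all(r1$Y %in% c(0, 1)))
})

test_that("candidate ranking is ordered, capped and handles new diseases", {
  w <- small_world(seed = 27)
  fit <- train_and_score(w$assoc, w$simin, ensemble_config(M = 5L, seed = 1L))
  d <- w$assoc$disease_ids[[1]]
  tab <- rank_candidates(fit$scores, w$assoc, d)
  cand_n <- sum(w$assoc$Y[, 1] == 0)
  expect_equal(nrow(tab), cand_n)
  expect_equal(tab$rank, seq_len(cand_n))
  expect_false(is.unsorted(rev(tab$score)))
  expect_equal(tab$score[[1]], max(fit$scores[w$assoc$Y[, 1] == 0, 1]))
  expect_lte(nrow(rank_candidates(fit$scores, w$assoc, d, top_k = 3)), 3)
  expect_error(rank_candidates(fit$scores, w$assoc, "bogus"), "unknown")

  # new-disease mode: wipe one disease's positives, retrain, still rankable
  j <- which.max(colSums(w$assoc$Y))
  Ym <- w$assoc$Y; Ym[, j] <- 0
  nd_assoc <- assoc_matrix(Ym, w$assoc$mirna_ids, w$assoc$disease_ids)
  fit2 <- train_and_score(nd_assoc, w$simin, ensemble_config(M = 5L, seed = 1L))
  tab2 <- rank_candidates(fit2$scores, nd_assoc, w$assoc$disease_ids[[j]])
  expect_equal(nrow(tab2), 20)              # every miRNA is a candidate
  # a disease with no unlabeled pairs yields an empty table
  Yfull <- w$assoc$Y; Yfull[, 2] <- 1
  afull <- assoc_matrix(Yfull, w$assoc$mirna_ids, w$assoc$disease_ids)
  expect_equal(nrow(rank_candidates(fit$scores, afull,
                                    w$assoc$disease_ids[[2]])), 0)
})
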