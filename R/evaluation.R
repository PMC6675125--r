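#' Rank-based AUC (Mann-Whitney estimator)
#'
#' Mean over test samples of the fraction of candidates scored strictly
#' lower, counting ties as one half. Equivalent to the trapezoidal area
#' under the ROC curve obtained by sweeping all score thresholds.
#'
#' @param test_scores scores of the held-out (true) samples.
#' @param candidate_scores scores of the candidate (unlabeled) samples.
#' @return scalar AUC in [0, 1].
#' @export
rank_auc <- function(test_scores, candidate_scores) {
  nc <- length(candidate_scores)
  if (nc == 0L || length(test_scores) == 0L)
    stop("need at least one test and one candidate score", call. = FALSE)
  u <- vapply(test_scores, function(t) {
    (sum(candidate_scores < t) + 0.5 * sum(candidate_scores == t)) / nc
  }, numeric(1))
  mean(u)
}

#' Explicit ROC curve by threshold sweeping
#'
#' Sweeps every distinct score as a threshold; a sample counts as called
#' positive when its score is >= the threshold. Serves as the independent
#' cross-check of \code{\link{rank_auc}} and as the exported curve.
#'
#' @inheritParams rank_auc
#' @return list with a data frame \code{points} (fpr, tpr) and the
#'   trapezoidal \code{auc}.
#' @export
roc_curve <- function(test_scores, candidate_scores) {
  thr <- sort(unique(c(test_scores, candidate_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(s) mean(test_scores >= s), numeric(1))
  fpr <- vapply(thr, function(s) mean(candidate_scores >= s), numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# ROC over per-sample normalized within-pool ranks: at threshold theta the
# false positive rate is 1 - theta by construction, the true positive rate
# the fraction of samples whose normalized rank exceeds theta.
normalized_rank_roc <- function(u, grid = seq(0, 1, length.out = 201)) {
  tpr <- vapply(grid, function(th) mean(u >= th), numeric(1))
  data.frame(fpr = rev(1 - grid), tpr = rev(tpr))
}

# default scorer: full retrain on the masked association matrix
default_scorer <- function(simin, config) {
  function(assoc_masked) {
    fit <- train_and_score(assoc_masked, simin, config)
    stopifnot(identical(fit$features$fingerprint,
                        assoc_fingerprint(assoc_masked)))
    fit$scores
  }
}

cv_result <- function(protocol, aucs, roc = NULL, per_sample = NULL) {
  structure(
    list(protocol = protocol, aucs = aucs, mean_auc = mean(aucs),
         sd_auc = if (length(aucs) > 1)
           stats::sd(aucs) * sqrt((length(aucs) - 1) / length(aucs)) else 0,
         roc = roc, per_sample = per_sample),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: AUC %.4f +/- %.4f (%d repeat%s)\n",
              x$protocol, x$mean_auc, x$sd_auc, length(x$aucs),
              if (length(x$aucs) == 1) "" else "s"))
  invisible(x)
}

#' Global leave-one-out cross validation
#'
#' Each known association is removed in turn; the interaction-profile
#' kernels, integrated similarities and feature matrices are recomputed from
#' the masked Y, the ensemble is retrained, and the held-out pair is ranked
#' against every unlabeled pair. The AUC is the mean per-sample normalized
#' rank (Mann-Whitney form); the reported ROC sweeps normalized-rank
#' thresholds.
#'
#' @param assoc an \code{\link{assoc_matrix}}.
#' @param simin a \code{\link{similarity_inputs}} bundle.
#' @param config an \code{\link{ensemble_config}}.
#' @param scorer optional function(assoc_masked) -> nm x nd score matrix;
#'   defaults to a full ensemble retrain (tests inject oracles here).
#' @param fast if TRUE, train once on the unmasked data and only mask the
#'   candidate pool; a labeled approximation of the full protocol.
#' @return a \code{cv_result}.
#' @export
global_loocv <- function(assoc, simin, config = ensemble_config(),
                         scorer = NULL, fast = FALSE) {
  if (is.null(scorer)) scorer <- default_scorer(simin, config)
  P <- positive_pairs(assoc)
  if (nrow(P) < 2L) stop("need at least 2 positives", call. = FALSE)
  U <- unknown_pairs(assoc)
  cand_idx <- (U[, 2L] - 1L) * nrow(assoc$Y) + U[, 1L]
  full_scores <- if (fast) scorer(assoc) else NULL
  u <- vapply(seq_len(nrow(P)), function(t) {
    i <- P[t, 1L]; j <- P[t, 2L]
    S <- if (fast) full_scores else {
      Ym <- assoc$Y; Ym[i, j] <- 0
      scorer(assoc_matrix(Ym, assoc$mirna_ids, assoc$disease_ids))
    }
    cand <- S[cand_idx]
    (sum(cand < S[i, j]) + 0.5 * sum(cand == S[i, j])) / length(cand)
  }, numeric(1))
  cv_result("global-loocv", mean(u), roc = normalized_rank_roc(u),
            per_sample = u)
}

#' Local leave-one-out cross validation
#'
#' As \code{\link{global_loocv}} but each held-out association is ranked
#' only against the unlabeled pairs of its own disease. Held-out pairs whose
#' disease has no unlabeled candidate are skipped.
#'
#' @inheritParams global_loocv
#' @return a \code{cv_result}.
#' @export
local_loocv <- function(assoc, simin, config = ensemble_config(),
                        scorer = NULL, fast = FALSE) {
  if (is.null(scorer)) scorer <- default_scorer(simin, config)
  P <- positive_pairs(assoc)
  if (nrow(P) < 2L) stop("need at least 2 positives", call. = FALSE)
  full_scores <- if (fast) scorer(assoc) else NULL
  u <- rep(NA_real_, nrow(P))
  for (t in seq_len(nrow(P))) {
    i <- P[t, 1L]; j <- P[t, 2L]
    cand_rows <- which(assoc$Y[, j] == 0)
    if (!length(cand_rows)) next
    S <- if (fast) full_scores else {
      Ym <- assoc$Y; Ym[i, j] <- 0
      scorer(assoc_matrix(Ym, assoc$mirna_ids, assoc$disease_ids))
    }
    cand <- S[cand_rows, j]
    u[[t]] <- (sum(cand < S[i, j]) + 0.5 * sum(cand == S[i, j])) / length(cand)
  }
  u <- u[!is.na(u)]
  if (!length(u)) stop("no held-out pair had candidates", call. = FALSE)
  cv_result("local-loocv", mean(u), roc = normalized_rank_roc(u),
            per_sample = u)
}

#' Repeated k-fold cross validation over the positive pairs
#'
#' Per repeat, the positives are partitioned into k folds (sizes differing
#' by at most one). Each fold is zeroed out of Y; kernels, similarities and
#' features are recomputed from the masked matrix; the ensemble is retrained
#' and the hidden positives are ranked against all pairs unlabeled in the
#' full matrix. One AUC per repeat; mean and population sd reported.
#'
#' @inheritParams global_loocv
#' @param k number of folds (default 5).
#' @param repeats number of random re-partitions (default 10; the reference
#'   experiment used 100).
#' @param seed seed for the fold partitions (defaults to the ensemble seed).
#' @return a \code{cv_result} with one AUC per repeat.
#' @export
kfold_cv <- function(assoc, simin, config = ensemble_config(), k = 5L,
                     repeats = 10L, seed = config$seed, scorer = NULL) {
  if (is.null(scorer)) scorer <- default_scorer(simin, config)
  P <- positive_pairs(assoc)
  np <- nrow(P)
  if (np < k) stop("fewer positives than folds", call. = FALSE)
  U <- unknown_pairs(assoc)
  cand_idx <- (U[, 2L] - 1L) * nrow(assoc$Y) + U[, 1L]
  aucs <- vapply(seq_len(repeats), function(rep_i) {
    set.seed((seed + 7919L * rep_i) %% .Machine$integer.max)
    fold <- sample(rep_len(seq_len(k), np))
    u_all <- numeric(0)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      Ym <- assoc$Y
      Ym[P[test, , drop = FALSE]] <- 0
      masked <- assoc_matrix(Ym, assoc$mirna_ids, assoc$disease_ids)
      S <- scorer(masked)
      cand <- S[cand_idx]
      u <- vapply(test, function(t) {
        s <- S[P[t, 1L], P[t, 2L]]
        (sum(cand < s) + 0.5 * sum(cand == s)) / length(cand)
      }, numeric(1))
      u_all <- c(u_all, u)
    }
    mean(u_all)
  }, numeric(1))
  cv_result("kfold", aucs)
}

#' Label randomization control
#'
#' Uniformly permutes the 0/1 entries of Y, preserving the number of
#' positives. Running the full pipeline on the shuffled matrix is the
#' overfitting control: cross-validated AUC should fall to about 0.5.
#'
#' @param assoc an \code{\link{assoc_matrix}}.
#' @return a new \code{assoc_matrix} with shuffled entries.
#' @export
label_randomization <- function(assoc) {
  Y <- matrix(sample(assoc$Y), nrow(assoc$Y), ncol(assoc$Y))
  assoc_matrix(Y, assoc$mirna_ids, assoc$disease_ids)
}

#' Rank candidate miRNAs for one disease
#'
#' Orders the miRNAs unlabeled for the disease by descending score, ties
#' broken by miRNA identifier for determinism.
#'
#' @param scores nm x nd score matrix (named).
#' @param assoc the \code{\link{assoc_matrix}} defining candidate status.
#' @param disease disease identifier.
#' @param top_k optional cap on the number of rows returned.
#' @return data frame (disease, mirna, score, rank).
#' @export
rank_candidates <- function(scores, assoc, disease, top_k = NULL) {
  j <- match(disease, assoc$disease_ids)
  if (is.na(j)) stop("unknown disease: ", disease, call. = FALSE)
  cand <- which(assoc$Y[, j] == 0)
  if (!length(cand))
    return(data.frame(disease = character(0), mirna = character(0),
                      score = numeric(0), rank = integer(0)))
  sc <- scores[cand, j]
  ids <- assoc$mirna_ids[cand]
  ord <- order(-sc, ids)
  out <- data.frame(disease = disease, mirna = ids[ord], score = sc[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
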