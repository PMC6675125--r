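#' Ensemble configuration
#'
#' Tunable parameters of the tree ensemble. Defaults follow the method's
#' stated operating point: 50 base learners, feature-subset ratio 0.8
#' (so 25 of the 32 per-side features survive subsetting), 10 principal
#' components per side giving a 20-dimensional spliced input, fully grown
#' trees.
#'
#' @param M number of base learners.
#' @param r feature-subset ratio in (0, 1]; each base learner keeps
#'   \code{floor(r * d)} features (the same index set on both sides).
#' @param n_components principal components retained per side; the actual
#'   number is \code{min(n_components, floor(r * d))}.
#' @param use_pca FALSE reproduces the dimensionality-reduction ablation:
#'   the subset features are spliced directly.
#' @param mode "ensemble" (fresh negatives per learner, all positives) or
#'   "rf" (random-forest style baseline: one fixed negative set, bootstrap
#'   resampling of the training pairs per tree, no feature subsetting, no
#'   PCA).
#' @param negative_sampling "global" (uniform over all unknown pairs) or
#'   "local" (per disease, matching its positive count).
#' @param seed master seed; learner k draws from a stream seeded seed + k.
#' @param gamma_prime interaction-profile kernel bandwidth multiplier.
#' @param svd_rank factorization feature rank.
#' @param min_samples_split,min_impurity_decrease,max_depth CART stopping.
#' @return list of class \code{ensemble_config}.
#' @export
ensemble_config <- function(M = 50L, r = 0.8, n_components = 10L,
                            use_pca = TRUE, mode = c("ensemble", "rf"),
                            negative_sampling = c("global", "local"),
                            seed = 1L, gamma_prime = 1, svd_rank = 11L,
                            min_samples_split = 2L,
                            min_impurity_decrease = 0, max_depth = Inf) {
  mode <- match.arg(mode)
  negative_sampling <- match.arg(negative_sampling)
  if (!(r > 0 && r <= 1)) stop("r must lie in (0, 1]", call. = FALSE)
  if (M < 1L) stop("M must be >= 1", call. = FALSE)
  structure(
    list(M = as.integer(M), r = r, n_components = as.integer(n_components),
         use_pca = use_pca, mode = mode,
         negative_sampling = negative_sampling, seed = as.integer(seed),
         gamma_prime = gamma_prime, svd_rank = as.integer(svd_rank),
         min_samples_split = as.integer(min_samples_split),
         min_impurity_decrease = min_impurity_decrease,
         max_depth = max_depth),
    class = "ensemble_config"
  )
}

#' Sample negative pairs uniformly from the unlabeled set
#'
#' @param assoc an \code{\link{assoc_matrix}}.
#' @param count number of pairs to draw (without replacement).
#' @return two-column integer matrix of (miRNA, disease) index pairs.
#' @export
sample_negatives_global <- function(assoc, count) {
  U <- unknown_pairs(assoc)
  if (count > nrow(U))
    stop("requested more negatives than unlabeled pairs", call. = FALSE)
  U[sample.int(nrow(U), count), , drop = FALSE]
}

#' Sample negatives per disease
#'
#' For each disease, draws as many unlabeled pairs as the disease has
#' positives (capped by availability). Used for the negative-sampling
#' comparison experiment.
#'
#' @inheritParams sample_negatives_global
#' @export
sample_negatives_local <- function(assoc) {
  out <- lapply(seq_len(ncol(assoc$Y)), function(j) {
    pos <- sum(assoc$Y[, j] == 1)
    unk <- which(assoc$Y[, j] == 0)
    if (pos == 0L || length(unk) == 0L) return(NULL)
    take <- min(pos, length(unk))
    sel <- if (take == length(unk)) unk else unk[sample.int(length(unk), take)]
    cbind(sel, j)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(integer(0), 0, 2)
  dimnames(res) <- NULL
  res
}

#' Random feature subset
#'
#' @param d total feature count.
#' @param r subset ratio in (0, 1].
#' @return sorted integer vector of \code{floor(r * d)} distinct indices.
#' @export
sample_feature_subset <- function(d, r) {
  d1 <- floor(r * d)
  if (d1 < 1L) stop("feature subset would be empty (r too small)",
                    call. = FALSE)
  sort(sample.int(d, d1))
}

# centering-only PCA fitted on all entities of one side
fit_pca <- function(X, k) {
  k <- min(k, ncol(X))
  center <- colMeans(X)
  s <- svd(sweep(X, 2L, center), nu = 0, nv = k)
  rot <- s$v
  if (ncol(rot) < k) rot <- cbind(rot, matrix(0, nrow(rot), k - ncol(rot)))
  list(center = center, rotation = rot)
}

apply_pca <- function(pca, X) {
  sweep(X, 2L, pca$center) %*% pca$rotation
}

splice_pairs <- function(PM, PD, pairs) {
  cbind(PM[pairs[, 1L], , drop = FALSE], PD[pairs[, 2L], , drop = FALSE])
}

check_fingerprint <- function(FM, assoc) {
  fp <- attr(FM, "y_fingerprint")
  if (!is.null(fp) && !identical(fp, assoc_fingerprint(assoc)))
    stop("stale feature matrix: fingerprint does not match Y", call. = FALSE)
  invisible(TRUE)
}

#' Fit one base learner
#'
#' One base learning: draw a fresh negative set the size of the positive
#' set, take a random feature subset (shared by both sides), fit a
#' centering-only PCA per side on all entities, splice each training pair's
#' reduced miRNA and disease vectors (20 dimensions at the defaults) and
#' grow a CART regression tree on the 0/1 targets.
#'
#' @param FM,FD feature matrices from \code{\link{build_feature_matrices}}.
#' @param assoc the matching \code{\link{assoc_matrix}}.
#' @param config an \code{\link{ensemble_config}}.
#' @param negatives optional fixed negative pair matrix ("rf" mode).
#' @return list with the learner's negatives, feature indices, per-side PCA
#'   (or NULL), and fitted tree.
#' @export
fit_base_learner <- function(FM, FD, assoc, config, negatives = NULL) {
  check_fingerprint(FM, assoc)
  P <- positive_pairs(assoc)
  d <- ncol(FM)
  if (config$mode == "rf") {
    stopifnot(!is.null(negatives))
    pairs <- rbind(P, negatives)
    y <- c(rep(1, nrow(P)), rep(0, nrow(negatives)))
    boot <- sample.int(nrow(pairs), nrow(pairs), replace = TRUE)
    pairs <- pairs[boot, , drop = FALSE]
    y <- y[boot]
    feat_idx <- seq_len(d)
    pca_m <- pca_d <- NULL
    PM <- FM; PD <- FD
  } else {
    N <- if (config$negative_sampling == "local") sample_negatives_local(assoc)
         else sample_negatives_global(assoc, nrow(P))
    pairs <- rbind(P, N)
    y <- c(rep(1, nrow(P)), rep(0, nrow(N)))
    feat_idx <- sample_feature_subset(d, config$r)
    Fm <- FM[, feat_idx, drop = FALSE]
    Fd <- FD[, feat_idx, drop = FALSE]
    if (config$use_pca) {
      pca_m <- fit_pca(Fm, config$n_components)
      pca_d <- fit_pca(Fd, config$n_components)
      PM <- apply_pca(pca_m, Fm)
      PD <- apply_pca(pca_d, Fd)
    } else {
      pca_m <- pca_d <- NULL
      PM <- Fm; PD <- Fd
    }
    negatives <- N
  }
  X <- splice_pairs(PM, PD, pairs)
  tree <- fit_tree(X, y,
                   min_samples_split = config$min_samples_split,
                   min_impurity_decrease = config$min_impurity_decrease,
                   max_depth = config$max_depth)
  list(negatives = negatives, feat_idx = feat_idx,
       pca_m = pca_m, pca_d = pca_d, tree = tree)
}

#' Fit the full tree ensemble
#'
#' M independent base learners; learner k uses the RNG stream seeded
#' \code{seed + k} so changing M never reshuffles earlier learners. In "rf"
#' mode a single negative set is drawn once (stream \code{seed}) and every
#' tree bootstraps the same training pairs.
#'
#' @inheritParams fit_base_learner
#' @return object of class \code{ensemble_model}.
#' @export
fit_ensemble <- function(FM, FD, assoc, config = ensemble_config()) {
  check_fingerprint(FM, assoc)
  fixed_neg <- NULL
  if (config$mode == "rf") {
    set.seed(config$seed %% .Machine$integer.max)
    fixed_neg <- sample_negatives_global(assoc, nrow(positive_pairs(assoc)))
  }
  learners <- lapply(seq_len(config$M), function(k) {
    set.seed((config$seed + k) %% .Machine$integer.max)
    fit_base_learner(FM, FD, assoc, config, negatives = fixed_neg)
  })
  structure(
    list(config = config, learners = learners,
         fingerprint = assoc_fingerprint(assoc),
         mirna_ids = assoc$mirna_ids, disease_ids = assoc$disease_ids),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %d trees (%s mode), %d x %d panel\n",
              length(x$learners), x$config$mode,
              length(x$mirna_ids), length(x$disease_ids)))
  invisible(x)
}

#' Score miRNA-disease pairs
#'
#' Each learner projects the feature matrices through its own feature
#' subset and PCA pair, splices and routes every requested pair through its
#' tree; the final score is the mean over learners. Scores of 0/1-target
#' leaf means averaged over trees always lie in [0, 1].
#'
#' @param model an \code{\link{ensemble_model}}.
#' @param FM,FD feature matrices computed from the same Y the model was
#'   trained on.
#' @param pairs optional two-column index matrix; default scores every pair.
#' @return if \code{pairs} is NULL an nm x nd score matrix, else a vector.
#' @export
predict_scores <- function(model, FM, FD, pairs = NULL) {
  if (!identical(attr(FM, "y_fingerprint"), model$fingerprint))
    stop("feature fingerprint does not match the model's training Y",
         call. = FALSE)
  nm <- nrow(FM); nd <- nrow(FD)
  full <- is.null(pairs)
  if (full)
    pairs <- cbind(rep(seq_len(nm), nd), rep(seq_len(nd), each = nm))
  acc <- numeric(nrow(pairs))
  for (lr in model$learners) {
    Fm <- FM[, lr$feat_idx, drop = FALSE]
    Fd <- FD[, lr$feat_idx, drop = FALSE]
    PM <- if (is.null(lr$pca_m)) Fm else apply_pca(lr$pca_m, Fm)
    PD <- if (is.null(lr$pca_d)) Fd else apply_pca(lr$pca_d, Fd)
    acc <- acc + predict_tree(lr$tree, splice_pairs(PM, PD, pairs))
  }
  sc <- acc / length(model$learners)
  if (full) {
    out <- matrix(sc, nm, nd, dimnames = list(model$mirna_ids,
                                              model$disease_ids))
    out
  } else sc
}

#' Train an ensemble end to end from raw inputs
#'
#' Convenience wrapper: recomputes kernels and features from the given
#' (possibly masked) association matrix and fits the ensemble.
#'
#' @param assoc an \code{\link{assoc_matrix}}.
#' @param simin a \code{\link{similarity_inputs}} bundle.
#' @param config an \code{\link{ensemble_config}}.
#' @return list with \code{model}, \code{features} and \code{scores}
#'   (full nm x nd score matrix).
#' @export
train_and_score <- function(assoc, simin, config = ensemble_config()) {
  sims <- integrated_similarity(simin, assoc, config$gamma_prime)
  feats <- build_feature_matrices(sims$SM, sims$SD, assoc, config$svd_rank)
  model <- fit_ensemble(feats$FM, feats$FD, assoc, config)
  scores <- predict_scores(model, feats$FM, feats$FD)
  list(model = model, features = feats, scores = scores)
}
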