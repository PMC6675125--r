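#' Statistical feature block (type 1)
#'
#' Per-entity summaries of its similarity row and association profile:
#' sum and mean of off-diagonal similarities, a 10-bin equal-width histogram
#' of those similarities over [0,1] normalized to proportions, and the
#' association-profile degree. 13 features.
#'
#' @param sim square similarity matrix aligned to the entities.
#' @param assoc_degree per-entity count of known associations.
#' @return entities x 13 matrix.
#' @export
statistical_features <- function(sim, assoc_degree) {
  n <- nrow(sim)
  out <- matrix(0, n, 13)
  for (i in seq_len(n)) {
    row <- sim[i, -i]
    if (length(row)) {
      h <- tabulate(pmin(floor(pmin(pmax(row, 0), 1) * 10) + 1L, 10L), 10L)
      out[i, ] <- c(sum(row), mean(row), h / length(row), assoc_degree[[i]])
    } else {
      out[i, 13] <- assoc_degree[[i]]
    }
  }
  colnames(out) <- c("t1_sum", "t1_mean", paste0("t1_hist", 1:10), "t1_degree")
  rownames(out) <- rownames(sim)
  out
}

#' Graph-theoretic feature block (type 2)
#'
#' Treats the similarity matrix as a weighted graph (self-loops removed,
#' zero-weight pairs unconnected). Path-based measures use distance
#' 1 - similarity; closeness is the harmonic variant so disconnected graphs
#' need no special casing. 6 features: count of neighbors above the mean
#' off-diagonal similarity, mean similarity of the 5 nearest neighbors,
#' weighted betweenness, harmonic closeness, eigenvector centrality and
#' PageRank.
#'
#' @param sim symmetric similarity matrix.
#' @return entities x 6 matrix.
#' @export
graph_features <- function(sim) {
  n <- nrow(sim)
  A <- sim
  diag(A) <- 0
  off_mean <- if (n > 1) sum(A) / (n * (n - 1)) else 0
  nbr_above <- rowSums(A > off_mean)
  k <- min(5L, n - 1L)
  knn_mean <- if (k > 0) {
    vapply(seq_len(n), function(i) {
      mean(sort(A[i, -i], decreasing = TRUE)[seq_len(k)])
    }, numeric(1))
  } else rep(0, n)

  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    w <- igraph::E(g)$weight
    dist_w <- pmax(1 - w, 1e-8)
    btw <- igraph::betweenness(g, weights = dist_w, normalized = TRUE)
    clo <- igraph::harmonic_centrality(g, weights = dist_w, normalized = TRUE)
    # leading eigenvector via LAPACK rather than igraph's ARPACK: ARPACK
    # starts from a random vector, which breaks bit-level determinism
    ev <- eigen(A, symmetric = TRUE)
    v <- abs(ev$vectors[, which.max(ev$values)])
    eig <- if (max(v) > 0) v / max(v) else rep(0, n)
    pr <- igraph::page_rank(g, weights = w)$vector
  } else {
    btw <- clo <- eig <- rep(0, n)
    pr <- rep(1 / n, n)
  }
  out <- cbind(t2_nbr_above_mean = nbr_above, t2_knn_mean = knn_mean,
               t2_betweenness = btw, t2_closeness = clo,
               t2_eigen = eig, t2_pagerank = pr)
  rownames(out) <- rownames(sim)
  out
}

#' Matrix-factorization feature block (type 3)
#'
#' Truncated SVD of Y at the given rank; each miRNA's features are its left
#' singular vector scaled by the singular values (the disease side uses the
#' right singular vectors), padded with zeros when Y has fewer non-trivial
#' singular values, plus the entity's degree in Y and the degree normalized
#' by the opposite panel size. rank + 2 features per side.
#'
#' @param assoc an \code{\link{assoc_matrix}}.
#' @param rank number of latent dimensions (default 11; must not exceed
#'   \code{min(nm, nd)}).
#' @return list with matrices \code{mirna} (nm x rank+2) and \code{disease}
#'   (nd x rank+2).
#' @export
factorization_features <- function(assoc, rank = 11L) {
  Y <- assoc$Y
  if (rank > min(dim(Y)))
    stop("factorization rank exceeds min(nm, nd)", call. = FALSE)
  s <- svd(Y, nu = rank, nv = rank)
  d <- s$d[seq_len(rank)]
  d[is.na(d)] <- 0
  M <- s$u %*% diag(d, rank, rank)
  D <- s$v %*% diag(d, rank, rank)
  mdeg <- rowSums(Y)
  ddeg <- colSums(Y)
  m <- cbind(M, t3_degree = mdeg, t3_degree_norm = mdeg / ncol(Y))
  dd <- cbind(D, t3_degree = ddeg, t3_degree_norm = ddeg / nrow(Y))
  colnames(m)[seq_len(rank)] <- colnames(dd)[seq_len(rank)] <-
    paste0("t3_svd", seq_len(rank))
  rownames(m) <- rownames(Y)
  rownames(dd) <- colnames(Y)
  list(mirna = m, disease = dd)
}

#' Build the per-miRNA and per-disease feature matrices
#'
#' Concatenates the three feature blocks in fixed order (statistical, graph,
#' factorization). With the default 10 histogram bins and factorization rank
#' 11 each side has d = 13 + 6 + 13 = 32 features. The returned matrices
#' carry the fingerprint of the Y they were computed from; the ensemble and
#' evaluation layers refuse feature matrices whose fingerprint does not
#' match the Y in play.
#'
#' @param SM,SD integrated similarity matrices.
#' @param assoc the \code{\link{assoc_matrix}} the similarities were
#'   computed from.
#' @param svd_rank factorization rank (default 11).
#' @return list with \code{FM} (nm x d), \code{FD} (nd x d) and
#'   \code{fingerprint}.
#' @export
build_feature_matrices <- function(SM, SD, assoc, svd_rank = 11L) {
  fact <- factorization_features(assoc, svd_rank)
  FM <- cbind(statistical_features(SM, rowSums(assoc$Y)),
              graph_features(SM), fact$mirna)
  FD <- cbind(statistical_features(SD, colSums(assoc$Y)),
              graph_features(SD), fact$disease)
  if (!all(is.finite(FM)) || !all(is.finite(FD)))
    stop("non-finite feature values", call. = FALSE)
  fp <- assoc_fingerprint(assoc)
  attr(FM, "y_fingerprint") <- fp
  attr(FD, "y_fingerprint") <- fp
  list(FM = FM, FD = FD, fingerprint = fp)
}
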