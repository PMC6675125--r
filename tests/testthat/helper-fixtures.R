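# Hand-built corpora and tiny worlds used across test files.

# chain D -> p -> g (child-to-parent direction)
chain_corpus <- function(delta = 0.5) {
  dag_corpus(parents = list(t_D = "p", p = "g", g = character(0)),
             disease_terms = c(D = "t_D"), delta = delta)
}

# diamond: D has parents p1 and p2, both children of g
diamond_corpus <- function(delta = 0.5) {
  dag_corpus(parents = list(t_D = c("p1", "p2"), p1 = "g", p2 = "g",
                            g = character(0)),
             disease_terms = c(D = "t_D"), delta = delta)
}

# two chains a -> r and b -> r sharing only the root r
shared_root_corpus <- function(delta = 0.5) {
  dag_corpus(parents = list(a = "r", b = "r", r = character(0)),
             disease_terms = c(A = "a", B = "b"), delta = delta)
}

# 4 diseases; term "t" is an ancestor of exactly two of them
four_disease_corpus <- function() {
  dag_corpus(
    parents = list(a = "t", b = "t", c = character(0), d = character(0),
                   t = character(0)),
    disease_terms = c(A = "a", B = "b", C = "c", D = "d"))
}

# deterministic tiny association matrix
toy_assoc <- function() {
  Y <- matrix(0, 4, 4, dimnames = list(paste0("m", 1:4), paste0("d", 1:4)))
  Y[1, 1] <- Y[2, 1] <- Y[2, 2] <- Y[3, 3] <- 1
  assoc_matrix(Y)
}

# small planted world for ensemble tests (cheaper than the default 60x40)
small_world <- function(seed = 1, nm = 20L, nd = 15L) {
  simulate_dataset(synthetic_config(nm = nm, nd = nd, seed = seed,
                                    n_blocks = 2L))
}

# direct double-loop evaluation of the interaction-profile kernel
gip_oracle <- function(profiles, gamma_prime = 1) {
  n <- nrow(profiles)
  gamma <- gamma_prime / mean(rowSums(profiles^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-gamma * sum((profiles[i, ] - profiles[j, ])^2))
  K
}

# brute-force enumeration of every (feature, midpoint-threshold) split
brute_force_split <- function(X, y) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2) next
    for (s in (utils::head(vals, -1) + utils::tail(vals, -1)) / 2) {
      left <- X[, j] <= s
      loss <- sum((y[left] - mean(y[left]))^2) +
        sum((y[!left] - mean(y[!left]))^2)
      if (is.null(best) || loss < best$loss - 1e-12)
        best <- list(j = j, s = s, loss = loss)
    }
  }
  best
}
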