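#' Exact best binary split for a regression node
#'
#' Scans every feature and every threshold midway between consecutive
#' distinct sorted feature values, minimizing the summed within-child
#' squared error \code{sum((y - mean_left)^2) + sum((y - mean_right)^2)}.
#' Rows with \code{x[j] <= s} go left. Ties are broken to the smallest
#' feature index, then the smallest threshold, so trees are deterministic.
#'
#' @param X numeric matrix (n x d), n >= 2.
#' @param y numeric targets of length n.
#' @param min_impurity_decrease minimum loss reduction for a split to count.
#' @return list(j, s, loss, decrease) or NULL when no split reduces the loss.
#' @export
best_split <- function(X, y, min_impurity_decrease = 0) {
  n <- length(y)
  if (n < 2L || nrow(X) != n) stop("need >= 2 samples", call. = FALSE)
  .best_split_cpp(as.matrix(X), as.numeric(y), min_impurity_decrease)
}

# pure-R reference implementation of the same search; retained as the
# second route for the oracle-equivalence tests
best_split_r <- function(X, y, min_impurity_decrease = 0) {
  n <- length(y)
  if (n < 2L || nrow(X) != n) stop("need >= 2 samples", call. = FALSE)
  tot <- sum(y); tot2 <- sum(y^2)
  parent_loss <- tot2 - tot^2 / n
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    valid <- which(xs[-n] < xs[-1L])       # split after position i
    if (!length(valid)) next
    cs <- cumsum(y[ord])[valid]
    cs2 <- cumsum(y[ord]^2)[valid]
    nl <- valid
    loss <- (cs2 - cs^2 / nl) + ((tot2 - cs2) - (tot - cs)^2 / (n - nl))
    i <- which.min(loss)                   # first minimum = smallest s
    if (is.null(best) || loss[[i]] < best$loss) {
      best <- list(j = j, s = (xs[valid[[i]]] + xs[valid[[i]] + 1L]) / 2,
                   loss = loss[[i]], decrease = parent_loss - loss[[i]])
    }
  }
  if (is.null(best)) return(NULL)
  eps <- 1e-12 * max(1, abs(parent_loss))
  if (best$decrease <= eps || best$decrease < min_impurity_decrease)
    return(NULL)
  best
}

#' Fit a CART regression tree
#'
#' Recursive binary splitting by \code{\link{best_split}}. A node becomes a
#' leaf when it holds fewer than \code{min_samples_split} samples, its
#' targets are constant, the depth cap is reached, or no split reduces the
#' loss by at least \code{min_impurity_decrease}. Leaves predict the mean of
#' their training targets.
#'
#' @param X numeric matrix (n x d).
#' @param y numeric targets.
#' @param min_samples_split minimum node size eligible for splitting
#'   (default 2: grow until pure or unsplittable).
#' @param min_impurity_decrease minimum loss reduction (default 0).
#' @param max_depth optional depth cap (default Inf).
#' @return object of class \code{cart_tree}: nested list of internal nodes
#'   \code{list(leaf=FALSE, j, s, left, right)} and leaves
#'   \code{list(leaf=TRUE, value, n)}.
#' @export
fit_tree <- function(X, y, min_samples_split = 2L, min_impurity_decrease = 0,
                     max_depth = Inf) {
  X <- as.matrix(X)
  if (length(y) == 0L) stop("empty training set", call. = FALSE)
  grow <- function(idx, depth) {
    yi <- y[idx]
    leaf <- list(leaf = TRUE, value = mean(yi), n = length(idx))
    if (length(idx) < min_samples_split || depth >= max_depth ||
        stats::var(yi) == 0 || is.na(stats::var(yi)))
      return(leaf)
    sp <- best_split(X[idx, , drop = FALSE], yi, min_impurity_decrease)
    if (is.null(sp)) return(leaf)
    go_left <- X[idx, sp$j] <= sp$s
    # midpoints between adjacent floats can round onto the upper value;
    # an empty child would recurse forever
    if (all(go_left) || !any(go_left)) return(leaf)
    list(leaf = FALSE, j = sp$j, s = sp$s,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }
  structure(grow(seq_along(y), 0L), class = "cart_tree")
}

#' Predict with a CART regression tree
#'
#' Routes each row by the stored split comparisons; a value exactly at a
#' threshold goes left.
#'
#' @param tree a \code{cart_tree}.
#' @param X numeric matrix of rows to score.
#' @return numeric predictions.
#' @export
predict_tree <- function(tree, X) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  route <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$value
      return(invisible(NULL))
    }
    go_left <- X[idx, node$j] <= node$s
    route(node$left, idx[go_left])
    route(node$right, idx[!go_left])
  }
  route(tree, seq_len(nrow(X)))
  out
}

#' @export
print.cart_tree <- function(x, ...) {
  count <- function(n) if (isTRUE(n$leaf)) c(1L, 0L) else
    c(0L, 1L) + count(n$left) + count(n$right)
  ct <- count(x)
  cat(sprintf("cart_tree: %d leaves, %d internal nodes\n", ct[[1]], ct[[2]]))
  invisible(x)
}

# plain-list form for JSON persistence
tree_to_list <- function(node) {
  if (isTRUE(node$leaf)) list(leaf = TRUE, value = node$value, n = node$n)
  else list(leaf = FALSE, j = node$j, s = node$s,
            left = tree_to_list(node$left), right = tree_to_list(node$right))
}

tree_from_list <- function(lst) {
  node <- if (isTRUE(lst$leaf)) {
    list(leaf = TRUE, value = as.numeric(lst$value), n = as.integer(lst$n))
  } else {
    list(leaf = FALSE, j = as.integer(lst$j), s = as.numeric(lst$s),
         left = tree_from_list(lst$left), right = tree_from_list(lst$right))
  }
  structure(node, class = "cart_tree")
}
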