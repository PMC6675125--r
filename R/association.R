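#' Binary miRNA-disease association matrix
#'
#' Light container for the adjacency matrix \code{Y} (rows = miRNAs,
#' columns = diseases). Entries are 0/1; the set of known associations is
#' \code{P = \{(i,j): Y[i,j] = 1\}} and the unlabeled candidate set is
#' \code{U = \{(i,j): Y[i,j] = 0\}}.
#'
#' @param Y numeric matrix of 0/1 entries.
#' @param mirna_ids,disease_ids character identifiers; default taken from
#'   \code{dimnames(Y)}.
#' @return An object of class \code{assoc_matrix}: a list with elements
#'   \code{Y} (named binary matrix), \code{mirna_ids}, \code{disease_ids}.
#' @export
assoc_matrix <- function(Y, mirna_ids = rownames(Y), disease_ids = colnames(Y)) {
  Y <- as.matrix(Y)
  if (is.null(mirna_ids)) mirna_ids <- paste0("m", seq_len(nrow(Y)))
  if (is.null(disease_ids)) disease_ids <- paste0("d", seq_len(ncol(Y)))
  if (length(mirna_ids) != nrow(Y) || length(disease_ids) != ncol(Y))
    stop("identifier length does not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA ids", call. = FALSE)
  if (anyDuplicated(disease_ids)) stop("duplicate disease ids", call. = FALSE)
  if (!all(Y %in% c(0, 1))) stop("Y must be binary (0/1)", call. = FALSE)
  storage.mode(Y) <- "double"
  dimnames(Y) <- list(mirna_ids, disease_ids)
  structure(
    list(Y = Y, mirna_ids = as.character(mirna_ids),
         disease_ids = as.character(disease_ids)),
    class = "assoc_matrix"
  )
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("assoc_matrix: %d miRNAs x %d diseases, %d positives (%.2f%%)\n",
              nrow(x$Y), ncol(x$Y), sum(x$Y),
              100 * mean(x$Y)))
  invisible(x)
}

#' Positive / unlabeled pair sets
#'
#' @param assoc an \code{\link{assoc_matrix}}.
#' @return Two-column integer matrix of (miRNA index, disease index) pairs.
#' @export
positive_pairs <- function(assoc) {
  which(assoc$Y == 1, arr.ind = TRUE, useNames = FALSE)
}

#' @rdname positive_pairs
#' @export
unknown_pairs <- function(assoc) {
  which(assoc$Y == 0, arr.ind = TRUE, useNames = FALSE)
}

#' Fingerprint of an association matrix
#'
#' Deterministic string identifying the exact 0/1 pattern of \code{Y}.
#' Feature matrices carry this fingerprint so that cross-validation folds
#' cannot accidentally reuse features computed from a stale (unmasked) Y.
#'
#' @param assoc an \code{assoc_matrix} (or a plain binary matrix).
#' @return character scalar.
#' @export
assoc_fingerprint <- function(assoc) {
  Y <- if (inherits(assoc, "assoc_matrix")) assoc$Y else assoc
  paste0(nrow(Y), "x", ncol(Y), ":",
         paste(which(Y != 0), collapse = ","))
}
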