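#' Gaussian interaction-profile kernel similarity
#'
#' Similarity of two entities' binary association profiles under a Gaussian
#' kernel whose bandwidth is scaled by the data:
#' \code{K(i,j) = exp(-gamma * ||y_i - y_j||^2)} with
#' \code{gamma = gamma_prime / mean_i(||y_i||^2)}. For miRNAs the profiles
#' are rows of Y, for diseases the columns.
#'
#' @param assoc an \code{\link{assoc_matrix}}.
#' @param gamma_prime positive bandwidth multiplier (default 1).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
gip_mirna <- function(assoc, gamma_prime = 1) {
  gip_kernel(assoc$Y, gamma_prime)
}

#' @rdname gip_mirna
#' @export
gip_disease <- function(assoc, gamma_prime = 1) {
  gip_kernel(t(assoc$Y), gamma_prime)
}

gip_kernel <- function(profiles, gamma_prime = 1) {
  stopifnot(gamma_prime > 0)
  n2 <- rowSums(profiles^2)
  denom <- mean(n2)
  if (denom == 0)
    stop("all interaction profiles are zero; kernel bandwidth undefined",
         call. = FALSE)
  gamma <- gamma_prime / denom
  d2 <- outer(n2, n2, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # numerical guard
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  K
}

#' Integrated disease similarity
#'
#' Where both diseases carry a DAG the similarity is the mean of the two
#' semantic models; otherwise the interaction-profile kernel value is used.
#'
#' @param ss1,ss2 semantic similarity matrices (NA where a side lacks a DAG).
#' @param gd disease interaction-profile kernel matrix.
#' @param has_dag logical vector flagging DAG-bearing diseases.
#' @return symmetric matrix SD in [0,1] with unit diagonal.
#' @export
integrate_disease <- function(ss1, ss2, gd, has_dag) {
  SD <- gd
  mask <- outer(has_dag, has_dag, "&")
  SD[mask] <- ((ss1 + ss2) / 2)[mask]
  diag(SD) <- 1
  SD
}

#' Integrated miRNA similarity
#'
#' Functional similarity where it exists for both miRNAs, interaction-profile
#' kernel otherwise.
#'
#' @param fs miRNA functional similarity matrix (full panel order; entries
#'   for miRNAs without functional similarity are ignored).
#' @param gm miRNA interaction-profile kernel matrix.
#' @param has_fs logical vector flagging miRNAs with functional similarity.
#' @return symmetric matrix SM in [0,1] with unit diagonal.
#' @export
integrate_mirna <- function(fs, gm, has_fs) {
  SM <- gm
  mask <- outer(has_fs, has_fs, "&")
  SM[mask] <- fs[mask]
  diag(SM) <- 1
  SM
}

#' Bundle the Y-independent similarity inputs
#'
#' Semantic similarities depend only on the ontology, and functional
#' similarity is a fixed input; only the interaction-profile kernels depend
#' on Y. Cross-validation masks Y repeatedly, so the Y-independent parts are
#' computed once and reused.
#'
#' @param corpus a \code{\link{dag_corpus}}.
#' @param fs functional similarity matrix over the miRNA panel.
#' @param has_fs logical per-miRNA flag (default: all TRUE).
#' @param mirna_ids,disease_ids panel orders (default from \code{fs} and the
#'   corpus is not enough: disease order must be supplied).
#' @return object of class \code{similarity_inputs}.
#' @export
similarity_inputs <- function(corpus, fs, disease_ids,
                              mirna_ids = rownames(fs),
                              has_fs = rep(TRUE, length(mirna_ids))) {
  sem <- semantic_similarity(corpus, disease_ids)
  structure(
    list(fs = fs, has_fs = has_fs, mirna_ids = mirna_ids,
         disease_ids = disease_ids,
         ss1 = sem$SS1, ss2 = sem$SS2, has_dag = sem$has_dag),
    class = "similarity_inputs"
  )
}

#' Integrated SM / SD for a (possibly masked) association matrix
#'
#' Recomputes both interaction-profile kernels from the supplied Y and
#' integrates them with the cached semantic / functional similarities.
#'
#' @param simin a \code{\link{similarity_inputs}} bundle.
#' @param assoc an \code{\link{assoc_matrix}} aligned to the bundle's panels.
#' @param gamma_prime kernel bandwidth multiplier.
#' @return list with \code{SM}, \code{SD}, \code{GM}, \code{GD}.
#' @export
integrated_similarity <- function(simin, assoc, gamma_prime = 1) {
  stopifnot(identical(assoc$mirna_ids, as.character(simin$mirna_ids)),
            identical(assoc$disease_ids, as.character(simin$disease_ids)))
  GM <- gip_mirna(assoc, gamma_prime)
  GD <- gip_disease(assoc, gamma_prime)
  SM <- integrate_mirna(simin$fs, GM, simin$has_fs)
  SD <- integrate_disease(simin$ss1, simin$ss2, GD, simin$has_dag)
  list(SM = SM, SD = SD, GM = GM, GD = GD)
}
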