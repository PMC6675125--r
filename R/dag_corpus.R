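#' Disease DAG corpus
#'
#' Holds the ontology of disease terms (a child -> parents relation, acyclic)
#' and the mapping from each disease to its own most-specific term. A
#' disease's DAG is the ancestor closure of its term: the term itself plus
#' every term reachable through parent links.
#'
#' @param parents named list: for each term, a character vector of parent
#'   terms (possibly empty). Terms appearing only as parents are added with
#'   an empty parent set.
#' @param disease_terms named character vector mapping disease id -> term id.
#'   Diseases absent from this map have no DAG (their similarity falls back
#'   to the interaction-profile kernel).
#' @param delta semantic contribution factor in (0,1); each step from a
#'   disease to a more general ancestor multiplies the ancestor's
#'   contribution by \code{delta}. Default 0.5.
#' @return An object of class \code{dag_corpus}.
#' @export
dag_corpus <- function(parents, disease_terms, delta = 0.5) {
  if (!(delta > 0 && delta < 1))
    stop("delta must lie strictly between 0 and 1", call. = FALSE)
  parents <- lapply(parents, as.character)
  all_terms <- unique(c(names(parents), unlist(parents, use.names = FALSE),
                        as.character(disease_terms)))
  for (t in setdiff(all_terms, names(parents))) parents[[t]] <- character(0)
  check_acyclic(parents)
  disease_terms <- vapply(disease_terms, as.character, character(1))
  missing <- setdiff(disease_terms, all_terms)
  if (length(missing))
    stop("disease terms absent from the ontology: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(
    list(terms = all_terms, parents = parents,
         disease_terms = disease_terms, delta = delta),
    class = "dag_corpus"
  )
}

#' @export
print.dag_corpus <- function(x, ...) {
  cat(sprintf("dag_corpus: %d terms, %d diseases with DAGs, delta = %g\n",
              length(x$terms), length(x$disease_terms), x$delta))
  invisible(x)
}

# Kahn's algorithm over child -> parent edges; stops with one cycle listed.
check_acyclic <- function(parents) {
  terms <- names(parents)
  npar <- lengths(parents)
  # children map
  kids <- new.env(hash = TRUE, parent = emptyenv())
  for (ch in terms) for (p in parents[[ch]]) {
    assign(p, c(if (exists(p, envir = kids)) get(p, envir = kids), ch),
           envir = kids)
  }
  pending <- npar
  queue <- terms[pending == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    chs <- if (exists(t, envir = kids)) get(t, envir = kids) else character(0)
    for (ch in chs) {
      pending[[ch]] <- pending[[ch]] - 1L
      if (pending[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(terms)) {
    cyc <- terms[pending > 0L]
    stop("cycle detected in term ontology involving: ",
         paste(utils::head(cyc, 10L), collapse = " -> "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @keywords internal
has_dag <- function(corpus, diseases) {
  diseases %in% names(corpus$disease_terms)
}

# ancestor closure of a term (term itself included)
ancestor_closure <- function(corpus, term) {
  out <- character(0)
  work <- term
  while (length(work)) {
    t <- work[[1L]]; work <- work[-1L]
    if (t %in% out) next
    out <- c(out, t)
    work <- c(work, corpus$parents[[t]])
  }
  out
}

#' Semantic value of a disease (model 1)
#'
#' The disease's own term contributes 1; every other term in the disease's
#' DAG contributes \code{delta} times the maximal contribution among its
#' children inside the DAG, so contributions decay geometrically with
#' distance from the disease term. The semantic value DV1 is the sum of all
#' contributions over the DAG.
#'
#' @param corpus a \code{\link{dag_corpus}}.
#' @param disease disease identifier with a DAG in the corpus.
#' @return list with \code{contrib} (named numeric over the DAG terms) and
#'   \code{dv} (their sum).
#' @export
semantic_value_m1 <- function(corpus, disease) {
  if (!disease %in% names(corpus$disease_terms))
    stop("disease has no DAG in the corpus: ", disease, call. = FALSE)
  term <- corpus$disease_terms[[disease]]
  terms <- ancestor_closure(corpus, term)
  tset <- stats::setNames(rep(TRUE, length(terms)), terms)
  # children of t inside the closure
  kids <- stats::setNames(vector("list", length(terms)), terms)
  for (ch in terms) for (p in corpus$parents[[ch]]) {
    if (isTRUE(tset[[p]])) kids[[p]] <- c(kids[[p]], ch)
  }
  contrib <- stats::setNames(rep(NA_real_, length(terms)), terms)
  rec <- function(t) {
    if (!is.na(contrib[[t]])) return(contrib[[t]])
    v <- if (t == term) 1 else {
      corpus$delta * max(vapply(kids[[t]], rec, numeric(1)))
    }
    contrib[[t]] <<- v
    v
  }
  for (t in terms) rec(t)
  list(contrib = contrib, dv = sum(contrib))
}

#' Semantic similarity between two diseases (model 1)
#'
#' Shared ancestors contribute from both sides; the similarity is the summed
#' shared contribution divided by the sum of the two semantic values, giving
#' a score in [0,1] that equals 1 on the diagonal.
#'
#' @inheritParams semantic_value_m1
#' @param d_i,d_j disease identifiers, both with DAGs.
#' @return scalar in [0,1].
#' @export
semantic_sim_m1 <- function(corpus, d_i, d_j) {
  a <- semantic_value_m1(corpus, d_i)
  b <- semantic_value_m1(corpus, d_j)
  common <- intersect(names(a$contrib), names(b$contrib))
  sum(a$contrib[common] + b$contrib[common]) / (a$dv + b$dv)
}

# term -> number of disease DAGs containing it, plus the disease count
dag_membership <- function(corpus) {
  dis <- names(corpus$disease_terms)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  closures <- stats::setNames(vector("list", length(dis)), dis)
  for (d in dis) {
    cl <- ancestor_closure(corpus, corpus$disease_terms[[d]])
    closures[[d]] <- cl
    for (t in cl) {
      assign(t, (if (exists(t, envir = counts)) get(t, envir = counts) else 0L) + 1L,
             envir = counts)
    }
  }
  cnt <- vapply(ls(counts), function(t) get(t, envir = counts), integer(1))
  list(counts = cnt, n_diseases = length(dis), closures = closures)
}

#' Semantic value of a disease (model 2)
#'
#' Model 2 weights each DAG term by its information content: a term present
#' in fewer disease DAGs is more specific, contributing
#' \code{-log(n_DAGs_containing_term / n_diseases_with_DAGs)} (natural log).
#' A term present in every DAG contributes 0.
#'
#' @inheritParams semantic_value_m1
#' @param membership optional precomputed \code{dag_membership} table
#'   (internal cache used when building whole similarity matrices).
#' @return list with \code{contrib} and \code{dv} as in
#'   \code{\link{semantic_value_m1}}.
#' @export
semantic_value_m2 <- function(corpus, disease, membership = NULL) {
  if (!disease %in% names(corpus$disease_terms))
    stop("disease has no DAG in the corpus: ", disease, call. = FALSE)
  term <- corpus$disease_terms[[disease]]
  if (is.null(membership)) membership <- dag_membership(corpus)
  cl <- membership$closures[[disease]]
  cnt <- membership$counts[cl]
  if (anyNA(cnt) || any(cnt < 1L))
    stop("internal consistency error: DAG term appears in zero DAGs",
         call. = FALSE)
  contrib <- -log(cnt / membership$n_diseases)
  names(contrib) <- cl
  list(contrib = contrib, dv = sum(contrib))
}

#' Semantic similarity between two diseases (model 2)
#'
#' Same ratio form as model 1 but with information-content contributions
#' (which do not depend on which disease's DAG the term sits in). Defined as
#' 1 on the diagonal; if both semantic values are 0 (every term appears in
#' every DAG) the off-diagonal similarity is defined as 0.
#'
#' @inheritParams semantic_sim_m1
#' @param membership optional precomputed membership table.
#' @return scalar, non-negative, 1 on the diagonal.
#' @export
semantic_sim_m2 <- function(corpus, d_i, d_j, membership = NULL) {
  if (is.null(membership)) membership <- dag_membership(corpus)
  if (identical(d_i, d_j)) return(1)
  a <- semantic_value_m2(corpus, d_i, membership)
  b <- semantic_value_m2(corpus, d_j, membership)
  denom <- a$dv + b$dv
  if (denom == 0) return(0)
  common <- intersect(names(a$contrib), names(b$contrib))
  sum(a$contrib[common] + b$contrib[common]) / denom
}

#' Pairwise semantic similarity matrices for a disease panel
#'
#' Computes both semantic models for every pair of DAG-bearing diseases in
#' \code{diseases}; pairs involving a disease without a DAG are NA (the
#' integration step substitutes the interaction-profile kernel there).
#'
#' @inheritParams semantic_value_m1
#' @param diseases character vector of disease identifiers (panel order).
#' @return list with symmetric matrices \code{SS1}, \code{SS2} (NA where a
#'   side has no DAG) and logical \code{has_dag}.
#' @export
semantic_similarity <- function(corpus, diseases) {
  nd <- length(diseases)
  hd <- has_dag(corpus, diseases)
  SS1 <- matrix(NA_real_, nd, nd, dimnames = list(diseases, diseases))
  SS2 <- SS1
  membership <- dag_membership(corpus)
  m1 <- lapply(diseases[hd], function(d) semantic_value_m1(corpus, d))
  m2 <- lapply(diseases[hd], function(d) semantic_value_m2(corpus, d, membership))
  names(m1) <- names(m2) <- diseases[hd]
  idx <- which(hd)
  for (ai in seq_along(idx)) {
    i <- idx[[ai]]
    for (bi in ai:length(idx)) {
      j <- idx[[bi]]
      di <- diseases[[i]]; dj <- diseases[[j]]
      ca <- m1[[di]]; cb <- m1[[dj]]
      common <- intersect(names(ca$contrib), names(cb$contrib))
      SS1[i, j] <- SS1[j, i] <-
        sum(ca$contrib[common] + cb$contrib[common]) / (ca$dv + cb$dv)
      if (i == j) {
        SS2[i, j] <- 1
      } else {
        da <- m2[[di]]; db <- m2[[dj]]
        denom <- da$dv + db$dv
        common2 <- intersect(names(da$contrib), names(db$contrib))
        SS2[i, j] <- SS2[j, i] <-
          if (denom == 0) 0 else
            sum(da$contrib[common2] + db$contrib[common2]) / denom
      }
    }
  }
  list(SS1 = SS1, SS2 = SS2, has_dag = hd)
}
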