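#' Synthetic world configuration
#'
#' Parameters of the generated fixtures: a bipartite block model for Y
#' (groups of miRNAs and diseases sharing elevated association probability,
#' the guilt-by-association structure the method assumes), a block-biased
#' Beta-distributed functional similarity matrix, and a term ontology with
#' shared upper levels so disease DAGs overlap.
#'
#' Defaults describe the desk-scale world used throughout the test suite:
#' 60 miRNAs x 40 diseases in 3 blocks at 5\% overall positive density with
#' a 1\% entry flip rate, depth-3 branching-2 shared ontology, and 10\% of
#' diseases (miRNAs) left without a DAG (functional similarity) to exercise
#' the kernel fallbacks.
#'
#' @param nm,nd entity counts.
#' @param n_blocks planted bicluster count.
#' @param density target overall positive rate.
#' @param noise per-entry flip probability applied after planting.
#' @param contrast ratio of within-block to cross-block positive
#'   probability (fixed design constant, default 15).
#' @param dag_depth,dag_branching shape of the shared term ontology.
#' @param frac_no_dag fraction of diseases without a DAG.
#' @param frac_no_fs fraction of miRNAs without functional similarity.
#' @param seed master seed.
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(nm = 60L, nd = 40L, n_blocks = 3L,
                             density = 0.20, noise = 0.005, contrast = 20,
                             dag_depth = 3L, dag_branching = 2L,
                             frac_no_dag = 0.1, frac_no_fs = 0.1,
                             seed = 1L) {
  stopifnot(density > 0, density < 1, noise >= 0, noise <= 1,
            frac_no_dag >= 0, frac_no_dag <= 1,
            frac_no_fs >= 0, frac_no_fs <= 1,
            density * nm * nd >= n_blocks)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a disease term ontology and DAG assignments
#'
#' Builds a shared tree of terms (one root, \code{dag_branching} children
#' per node, \code{dag_depth} levels), then gives each DAG-bearing disease
#' its own leaf term attached to the deepest shared level; occasionally a
#' second parent creates a diamond. Diseases of the same planted block
#' attach preferentially (probability 0.8) under the same block-specific
#' branch, so semantic similarity correlates with the planted association
#' structure -- the guilt-by-association premise the predictor assumes.
#' A fraction of diseases is left without a DAG to exercise the
#' interaction-profile fallback.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param disease_ids identifiers (default d1..d_nd).
#' @param disease_block optional block labels from
#'   \code{\link{generate_associations}}; NULL attaches uniformly.
#' @return a \code{\link{dag_corpus}}.
#' @export
generate_dag_corpus <- function(cfg, disease_ids = paste0("d", seq_len(cfg$nd)),
                                disease_block = NULL) {
  set.seed(cfg$seed + 101L)
  parents <- list(T_root = character(0))
  level <- "T_root"
  if (cfg$dag_depth > 0) {
    for (lv in seq_len(cfg$dag_depth)) {
      nxt <- character(0)
      for (p in level) {
        for (b in seq_len(cfg$dag_branching)) {
          ch <- paste0(p, ".", b)
          parents[[ch]] <- p
          nxt <- c(nxt, ch)
        }
      }
      level <- nxt
    }
  }
  n_dag <- round((1 - cfg$frac_no_dag) * cfg$nd)
  with_dag <- sort(sample.int(cfg$nd, n_dag))
  home <- if (is.null(disease_block)) NULL else
    level[((seq_len(max(disease_block)) - 1L) %% length(level)) + 1L]
  terms <- stats::setNames(character(0), character(0))
  for (i in with_dag) {
    t <- paste0("t_", disease_ids[[i]])
    if (cfg$dag_depth == 0) {
      parents[[t]] <- character(0)
    } else {
      p1 <- if (!is.null(home) && stats::runif(1) < 0.8)
        home[[disease_block[[i]]]] else sample(level, 1)
      p <- p1
      if (stats::runif(1) < 0.3 && length(level) > 1)
        p <- unique(c(p1, sample(setdiff(level, p1), 1)))
      parents[[t]] <- p
    }
    terms[[disease_ids[[i]]]] <- t
  }
  dag_corpus(parents, terms)
}

#' Generate a block-model association matrix with heterogeneous degrees
#'
#' MiRNAs and diseases are assigned to \code{n_blocks} groups and each
#' entity draws a log-normal association propensity (sdlog 1.3, a fixed
#' design constant emulating the heavy-tailed degree distributions of
#' curated association databases). A pair is positive with probability
#' proportional to the product of the two propensities, boosted by
#' \code{contrast} when the entities share a block, and scaled so the
#' pre-truncation mean equals \code{density}; individual probabilities are
#' capped at 0.95, so with heavy-tailed propensities the realized positive
#' rate is lower than \code{density} (about 0.12 at the defaults). Each
#' entry is then flipped with probability \code{noise}. Marginal (degree) signal and the planted
#' block interaction together make the structure recoverable by
#' similarity- and feature-based predictors.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @return list with \code{assoc} (an \code{\link{assoc_matrix}}) and
#'   \code{truth} (block labels, propensities, probability matrix).
#' @export
generate_associations <- function(cfg) {
  set.seed(cfg$seed + 202L)
  mb <- sample(rep_len(seq_len(cfg$n_blocks), cfg$nm))
  db <- sample(rep_len(seq_len(cfg$n_blocks), cfg$nd))
  a <- stats::rlnorm(cfg$nm, 0, 1.3)
  b <- stats::rlnorm(cfg$nd, 0, 1.3)
  boost <- ifelse(outer(mb, db, "=="), cfg$contrast, 1)
  raw <- outer(a, b) * boost
  p <- pmin(cfg$density * raw / mean(raw), 0.95)
  Y <- matrix(as.numeric(stats::runif(cfg$nm * cfg$nd) < p), cfg$nm, cfg$nd)
  flip <- stats::runif(cfg$nm * cfg$nd) < cfg$noise
  Y[flip] <- 1 - Y[flip]
  assoc <- assoc_matrix(Y, paste0("m", seq_len(cfg$nm)),
                        paste0("d", seq_len(cfg$nd)))
  list(assoc = assoc,
       truth = list(mirna_block = mb, disease_block = db,
                    mirna_propensity = a, disease_propensity = b,
                    prob = p))
}

#' Generate a block-biased miRNA functional similarity matrix
#'
#' Within-block similarities are drawn Beta(5,2) (mean 5/7), cross-block
#' Beta(2,5) (mean 2/7); the matrix is symmetrized with unit diagonal. A
#' fraction of miRNAs is flagged as lacking functional similarity.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param mirna_block block labels from \code{\link{generate_associations}}.
#' @return list with \code{FS} (named symmetric matrix) and logical
#'   \code{has_fs}.
#' @export
generate_mirna_similarity <- function(cfg, mirna_block) {
  set.seed(cfg$seed + 303L)
  nm <- cfg$nm
  inside <- outer(mirna_block, mirna_block, "==")
  FS <- matrix(0, nm, nm)
  up <- upper.tri(FS)
  n_up <- sum(up)
  vals <- ifelse(inside[up], stats::rbeta(n_up, 5, 2),
                 stats::rbeta(n_up, 2, 5))
  FS[up] <- vals
  FS <- FS + t(FS)
  diag(FS) <- 1
  dimnames(FS) <- list(paste0("m", seq_len(nm)), paste0("m", seq_len(nm)))
  has_fs <- rep(TRUE, nm)
  n_absent <- round(cfg$frac_no_fs * nm)
  if (n_absent > 0) has_fs[sample.int(nm, n_absent)] <- FALSE
  list(FS = FS, has_fs = has_fs)
}

#' Generate a complete synthetic dataset
#'
#' Runs the three generators under one seed and optionally writes the
#' fixtures in the package's file dialects (Y.tsv, FS.tsv restricted to
#' miRNAs with functional similarity, dag_edges.tsv, disease_roots.tsv,
#' truth.json).
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param out_dir optional directory to write fixture files into.
#' @return list with \code{assoc}, \code{FS}, \code{has_fs}, \code{corpus},
#'   \code{truth} and \code{simin} (a ready \code{\link{similarity_inputs}}).
#' @export
simulate_dataset <- function(cfg = synthetic_config(), out_dir = NULL) {
  ga <- generate_associations(cfg)
  fs <- generate_mirna_similarity(cfg, ga$truth$mirna_block)
  corpus <- generate_dag_corpus(cfg, ga$assoc$disease_ids,
                                disease_block = ga$truth$disease_block)
  simin <- similarity_inputs(corpus, fs$FS, ga$assoc$disease_ids,
                             mirna_ids = ga$assoc$mirna_ids,
                             has_fs = fs$has_fs)
  out <- list(assoc = ga$assoc, FS = fs$FS, has_fs = fs$has_fs,
              corpus = corpus, truth = ga$truth, simin = simin)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_matrix(ga$assoc$Y, file.path(out_dir, "Y.tsv"))
    keep <- which(fs$has_fs)
    write_matrix(fs$FS[keep, keep, drop = FALSE],
                 file.path(out_dir, "FS.tsv"))
    write_dag_corpus(corpus, file.path(out_dir, "dag_edges.tsv"),
                     file.path(out_dir, "disease_roots.tsv"))
    jsonlite::write_json(ga$truth[setdiff(names(ga$truth), "prob")],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
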