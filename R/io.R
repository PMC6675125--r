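#' Read a labeled matrix from TSV
#'
#' Dialect: first row holds the column identifiers, first column the row
#' identifiers, tab-separated numeric cells. Parsing is strict: ragged
#' rows, non-numeric cells and duplicate identifiers are errors reported
#' with the offending line.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file needs a header and at least one row: ",
                               path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids))
    stop("duplicate column id: ", col_ids[duplicated(col_ids)][1L],
         call. = FALSE)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  row_ids <- character(length(body))
  vals <- matrix(NA_real_, length(body), length(col_ids))
  for (i in seq_along(body)) {
    cells <- body[[i]]
    if (length(cells) != length(col_ids) + 1L)
      stop(sprintf("ragged row at line %d of %s", i + 1L, path),
           call. = FALSE)
    row_ids[[i]] <- cells[[1L]]
    v <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(v))
      stop(sprintf("non-numeric cell at line %d of %s", i + 1L, path),
           call. = FALSE)
    vals[i, ] <- v
  }
  if (anyDuplicated(row_ids))
    stop("duplicate row id: ", row_ids[duplicated(row_ids)][1L],
         call. = FALSE)
  dimnames(vals) <- list(row_ids, col_ids)
  vals
}

#' Write a labeled matrix to TSV
#'
#' @param m named numeric matrix.
#' @param path destination file.
#' @export
write_matrix <- function(m, path) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[[i]], sprintf("%.15g", m[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a disease DAG corpus from edge-list files
#'
#' \code{edges_path}: two tab-separated columns (child, parent) with a
#' header line. \code{roots_path}: two columns (disease id, term id) with a
#' header line mapping each DAG-bearing disease to its own most-specific
#' term. Acyclicity is validated; a term named in the roots file but absent
#' from the edge list becomes a singleton DAG.
#'
#' @param edges_path,roots_path file paths.
#' @param delta semantic contribution factor (default 0.5).
#' @return a \code{\link{dag_corpus}}.
#' @export
read_dag_corpus <- function(edges_path, roots_path, delta = 0.5) {
  ed <- utils::read.delim(edges_path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(ed) != 2L) stop("dag edge file must have 2 columns", call. = FALSE)
  ro <- utils::read.delim(roots_path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(ro) != 2L) stop("roots file must have 2 columns", call. = FALSE)
  parents <- split(ed[[2L]], ed[[1L]])
  terms <- stats::setNames(ro[[2L]], ro[[1L]])
  dag_corpus(parents, terms, delta = delta)
}

#' Write a disease DAG corpus to edge-list files
#'
#' @param corpus a \code{\link{dag_corpus}}.
#' @inheritParams read_dag_corpus
#' @export
write_dag_corpus <- function(corpus, edges_path, roots_path) {
  ch <- rep(names(corpus$parents), lengths(corpus$parents))
  pa <- unlist(corpus$parents, use.names = FALSE)
  utils::write.table(data.frame(child = ch, parent = pa),
                     edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(disease = names(corpus$disease_terms),
                                term = unname(corpus$disease_terms)),
                     roots_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(edges_path)
}

#' Write long-format predictions
#'
#' One row per candidate pair: disease, miRNA, score, rank. Rows are sorted
#' by disease (file panel order) then descending score, ties broken by
#' miRNA identifier.
#'
#' @param scores nm x nd score matrix.
#' @param assoc the \code{\link{assoc_matrix}} defining candidate status.
#' @param path destination file.
#' @param top_k optional per-disease cap.
#' @return the path, invisibly.
#' @export
write_predictions <- function(scores, assoc, path, top_k = NULL) {
  tabs <- lapply(assoc$disease_ids, function(d)
    rank_candidates(scores, assoc, d, top_k = top_k))
  out <- do.call(rbind, tabs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("disease\tmirna\tscore\trank", con)
  if (nrow(out))
    writeLines(sprintf("%s\t%s\t%.15g\t%d", out$disease, out$mirna,
                       out$score, out$rank), con)
  invisible(path)
}

# --- model persistence -----------------------------------------------------

#' Save / load a fitted ensemble
#'
#' The model directory holds config.json, the training-Y fingerprint and
#' one JSON file of learners (feature indices, PCA centers/rotations,
#' serialized trees). Plain-text JSON so models survive text-only
#' deployment.
#'
#' @param model an \code{\link{ensemble_model}}.
#' @param dir model directory.
#' @return the directory (save) or the model (load).
#' @export
save_ensemble <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  cfg$max_depth <- if (is.finite(cfg$max_depth)) cfg$max_depth else -1
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(fingerprint = model$fingerprint,
               mirna_ids = model$mirna_ids,
               disease_ids = model$disease_ids)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA)
  learners <- lapply(model$learners, function(lr) {
    list(negatives = lr$negatives, feat_idx = lr$feat_idx,
         pca_m = lr$pca_m, pca_d = lr$pca_d,
         tree = tree_to_list(lr$tree))
  })
  jsonlite::write_json(learners, file.path(dir, "learners.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  if (cfg$max_depth < 0) cfg$max_depth <- Inf
  config <- do.call(ensemble_config,
                    cfg[setdiff(names(cfg), character(0))])
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  raw <- jsonlite::read_json(file.path(dir, "learners.json"),
                             simplifyVector = FALSE)
  learners <- lapply(raw, function(lr) {
    as_mat <- function(x) if (is.null(x)) NULL else
      do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
    pca <- function(p) if (is.null(p)) NULL else
      list(center = as.numeric(unlist(p$center)),
           rotation = as_mat(p$rotation))
    list(negatives = as_mat(lr$negatives),
         feat_idx = as.integer(unlist(lr$feat_idx)),
         pca_m = pca(lr$pca_m), pca_d = pca(lr$pca_d),
         tree = tree_from_list(lr$tree))
  })
  structure(
    list(config = config, learners = learners,
         fingerprint = meta$fingerprint,
         mirna_ids = meta$mirna_ids, disease_ids = meta$disease_ids),
    class = "ensemble_model"
  )
}
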