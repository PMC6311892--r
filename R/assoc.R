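# Association matrices and run configuration.

#' Construct a labelled association matrix
#'
#' An association matrix `Y` holds the training signal of the bipartite
#' network: rows are one entity set (e.g. circRNAs), columns the other
#' (e.g. diseases), and `Y[i, j] = 1` records a known association. After
#' cold-start augmentation (see [augment_matrix()]) entries may lie anywhere
#' in `[0, 1]` and the matrix is no longer binary.
#'
#' @param values numeric matrix, `n_row x n_col`.
#' @param row_ids,col_ids character vectors of unique identifiers; default to
#'   the dimnames of `values`.
#' @param binary logical; if `TRUE` (default) every entry must be 0 or 1.
#' @return a numeric matrix of class `"assoc_matrix"` with dimnames set and a
#'   `"binary"` attribute.
#' @examples
#' y <- assoc_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)),
#'                   row_ids = c("c1", "c2", "c3"), col_ids = c("d1", "d2"))
#' @export
assoc_matrix <- function(values, row_ids = rownames(values),
                         col_ids = colnames(values), binary = TRUE) {
  values <- as.matrix(values)
  if (is.null(row_ids) || is.null(col_ids)) {
    stop("row_ids and col_ids are required (or set dimnames on `values`)")
  }
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  if (anyDuplicated(row_ids)) stop("duplicate row identifiers")
  if (anyDuplicated(col_ids)) stop("duplicate column identifiers")
  if (nrow(values) != length(row_ids) || ncol(values) != length(col_ids)) {
    stop("matrix shape does not match identifier lengths")
  }
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("association matrix has non-finite entries")
  if (binary && !all(values %in% c(0, 1))) {
    stop("association matrix is not binary (entries must be 0 or 1)")
  }
  if (!binary && (any(values < 0) || any(values > 1))) {
    stop("augmented association entries must lie in [0, 1]")
  }
  if (all(values == 0)) stop("association matrix has no associations")
  dimnames(values) <- list(row_ids, col_ids)
  structure(values, binary = binary, class = c("assoc_matrix", "matrix", "array"))
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d x %d, %s, %d nonzero entries\n",
              nrow(x), ncol(x), if (isTRUE(attr(x, "binary"))) "binary" else "augmented",
              sum(x != 0)))
  invisible(x)
}

is_binary01 <- function(Y) all(Y %in% c(0, 1))

# Strip the class so downstream matrix algebra returns plain matrices.
as_plain_matrix <- function(Y) {
  attr(Y, "binary") <- NULL
  unclass(Y)
}

#' Run configuration for the DWNN-RLS pipeline
#'
#' Collects the tunable parameters with their default values: `epsilon = 1`
#' (all neighbours used in the cold-start average), `sigma = 0.2` (RLS
#' regularization), `delta = 0.5` (per-layer decay of ancestor contributions
#' in the semantic similarity).
#'
#' @param epsilon neighbour-selection control in `(0, 1]`.
#' @param sigma ridge regularization, `> 0`.
#' @param delta DAG layer contribution factor in `(0, 1)`.
#' @param cv_scheme one of `"5CV"`, `"10CV"`, `"LOOCV"`.
#' @param n_repeats positive integer number of cross-validation repeats.
#' @param seed integer base seed.
#' @param disease_sim_mode `"mean_gip_semantic"` (average the GIP and DAG
#'   semantic similarities where the latter is defined) or `"gip_only"`.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(epsilon = 1.0, sigma = 0.2, delta = 0.5,
                       cv_scheme = c("10CV", "5CV", "LOOCV"),
                       n_repeats = 10L, seed = 1L,
                       disease_sim_mode = c("mean_gip_semantic", "gip_only")) {
  cv_scheme <- match.arg(cv_scheme)
  disease_sim_mode <- match.arg(disease_sim_mode)
  stopifnot(epsilon > 0, epsilon <= 1, sigma > 0, delta > 0, delta < 1,
            n_repeats >= 1)
  structure(list(epsilon = epsilon, sigma = sigma, delta = delta,
                 cv_scheme = cv_scheme, n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), disease_sim_mode = disease_sim_mode),
            class = "run_config")
}

#' Read a run configuration from a key:value file
#'
#' One `key: value` pair per line; `#` starts a comment. Unknown keys are an
#' error. Missing keys take the [run_config()] defaults.
#'
#' @param path file path.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    kv[[m[2]]] <- m[3]
  }
  allowed <- c("epsilon", "sigma", "delta", "cv_scheme", "n_repeats", "seed",
               "disease_sim_mode")
  bad <- setdiff(names(kv), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  num <- intersect(names(kv), c("epsilon", "sigma", "delta", "n_repeats", "seed"))
  for (k in num) kv[[k]] <- as.numeric(kv[[k]])
  do.call(run_config, kv)
}
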