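# Ontology DAG container (MeSH-style disease hierarchy).

#' Construct a disease DAG
#'
#' The hierarchy is stored as a directed graph with edges pointing from child
#' to parent, so "ancestors" of a term are the nodes reachable along directed
#' paths. Acyclicity is verified on construction. A column entity (disease)
#' may map to several DAG terms, as MeSH descriptors can occupy multiple tree
#' positions.
#'
#' @param edges two-column data frame or matrix of `(child, parent)` pairs.
#' @param mapping optional named list: disease id -> character vector of
#'   mapped term ids.
#' @return list of class `"disease_dag"` with elements `graph` (igraph,
#'   child -> parent), `nodes`, `mapping`.
#' @export
disease_dag <- function(edges, mapping = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("DAG edges need (child, parent) columns")
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2)
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- which(comp$csize[comp$membership] > 1)
    node <- if (length(bad)) igraph::V(g)$name[bad[1]] else
      igraph::V(g)$name[which(igraph::which_loop(g))[1]]
    stop("hierarchy contains a directed cycle through node '", node, "'")
  }
  nodes <- igraph::V(g)$name
  if (!is.null(mapping)) {
    mapping <- lapply(mapping, as.character)
    unknown <- setdiff(unlist(mapping, use.names = FALSE), nodes)
    if (length(unknown)) {
      stop("mapped terms not present in the DAG: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  structure(list(graph = g, nodes = nodes, mapping = mapping),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> %d terms, %d child->parent edges, %d mapped entities\n",
              length(x$nodes), igraph::ecount(x$graph),
              if (is.null(x$mapping)) 0L else length(x$mapping)))
  invisible(x)
}

#' Read a DAG from a child/parent edge list
#'
#' Each line is `child<TAB>parent`. A cycle anywhere in the file is an error
#' naming one offending node.
#'
#' @param path edge-list file path.
#' @param mapping_path optional TSV `disease<TAB>term` mapping file; repeated
#'   disease ids accumulate multiple terms.
#' @return a [disease_dag()].
#' @export
read_dag <- function(path, mapping_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty DAG file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    bad <- which(nf < 2)[1]
    stop(sprintf("malformed DAG line %d (need child<TAB>parent): %s",
                 bad, lines[bad]))
  }
  edges <- cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
  mapping <- if (!is.null(mapping_path)) read_term_mapping(mapping_path)
  disease_dag(edges, mapping = mapping)
}

#' Read a disease-to-term mapping file
#'
#' @param path TSV with lines `disease<TAB>term`.
#' @return named list disease id -> character vector of terms.
#' @export
read_term_mapping <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("malformed mapping line (need disease<TAB>term)")
  dis <- vapply(parts, `[[`, "", 1L)
  term <- vapply(parts, `[[`, "", 2L)
  split(term, factor(dis, levels = unique(dis)))
}

#' Write a DAG as a child/parent edge list
#' @param dag a [disease_dag()].
#' @param path output path.
#' @export
write_dag <- function(dag, path) {
  el <- igraph::as_edgelist(dag$graph)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  invisible(path)
}
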