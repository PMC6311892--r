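# Synthetic data with planted structure: a bipartite stochastic block model
# for the association matrix and a random rooted DAG whose branches follow
# the latent blocks, so semantic similarity correlates with block
# co-membership. The defaults are the benchmark world used throughout the
# test suite: 60 x 40 entities, 3 blocks, within-block association
# probability 0.3 against a 0.02 background.

#' Specification of a synthetic benchmark instance
#'
#' @param n_circ,n_disease entity counts.
#' @param n_blocks latent cluster count shared by both sides.
#' @param within_block_prob,between_block_prob Bernoulli association
#'   probabilities inside and across blocks; the planted signal requires
#'   `within > between`.
#' @param dag_branching children per internal node of the disease DAG.
#' @param dag_depth tree depth below the root.
#' @param second_parent_frac fraction of deep nodes that receive a second
#'   parent, turning the tree into a proper DAG.
#' @param multi_term_frac fraction of diseases mapped to two DAG terms
#'   (emulating multi-position ontology descriptors).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_circ = 60L, n_disease = 40L, n_blocks = 3L,
                           within_block_prob = 0.3, between_block_prob = 0.02,
                           dag_branching = 3L, dag_depth = 3L,
                           second_parent_frac = 0.15, multi_term_frac = 0.1,
                           seed = 1L) {
  stopifnot(n_circ >= 1, n_disease >= 1, n_blocks >= 1,
            within_block_prob >= 0, within_block_prob <= 1,
            between_block_prob >= 0, between_block_prob <= 1,
            within_block_prob > between_block_prob,
            dag_branching >= 1, dag_depth >= 1,
            second_parent_frac >= 0, second_parent_frac <= 1,
            multi_term_frac >= 0, multi_term_frac <= 1)
  structure(list(n_circ = as.integer(n_circ), n_disease = as.integer(n_disease),
                 n_blocks = as.integer(n_blocks),
                 within_block_prob = within_block_prob,
                 between_block_prob = between_block_prob,
                 dag_branching = as.integer(dag_branching),
                 dag_depth = as.integer(dag_depth),
                 second_parent_frac = second_parent_frac,
                 multi_term_frac = multi_term_frac,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a block-structured association matrix
#'
#' Rows and columns are assigned uniformly to blocks; `Y[i, j]` is Bernoulli
#' with the within-block probability when the two entities share a block and
#' the background probability otherwise. Latent block labels are returned
#' for diagnostics.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `Y` (an [assoc_matrix()]), `circ_blocks`,
#'   `disease_blocks`.
#' @export
generate_associations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    bc <- sample.int(spec$n_blocks, spec$n_circ, replace = TRUE)
    bd <- sample.int(spec$n_blocks, spec$n_disease, replace = TRUE)
    same <- outer(bc, bd, "==")
    p <- ifelse(same, spec$within_block_prob, spec$between_block_prob)
    Y <- matrix(stats::rbinom(length(p), 1, p), spec$n_circ, spec$n_disease)
    if (all(Y == 0)) stop("degenerate draw: no associations generated")
    rownames(Y) <- sprintf("c%03d", seq_len(spec$n_circ))
    colnames(Y) <- sprintf("d%03d", seq_len(spec$n_disease))
    list(Y = assoc_matrix(Y), circ_blocks = bc, disease_blocks = bd)
  })
}

#' Generate a random disease DAG correlated with the blocks
#'
#' Builds a rooted tree in which the root has one child subtree per block
#' and each subtree branches `dag_branching`-fold down to `dag_depth`
#' levels; a fraction of nodes at depth >= 2 receive a second parent chosen
#' among strictly shallower nodes (edges always point towards shallower
#' layers, so the graph stays acyclic). Diseases are mapped to uniformly
#' chosen terms inside their block's subtree, so same-block diseases share a
#' recent ancestor and their semantic similarity exceeds the between-block
#' level.
#'
#' @param spec a [synthetic_spec()].
#' @param disease_blocks block labels from [generate_associations()]; when
#'   omitted they are re-derived from the spec (the generators share the
#'   seed, so the labels agree).
#' @return list with `dag` (a [disease_dag()] whose `mapping` covers every
#'   disease) and `entity_to_terms`.
#' @export
generate_dag <- function(spec, disease_blocks = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(disease_blocks)) {
    disease_blocks <- generate_associations(spec)$disease_blocks
  }
  with_seed(spec$seed + 1L, {
    edges <- list()
    depth_of <- c(root = 0L)
    subtree <- vector("list", spec$n_blocks)
    for (g in seq_len(spec$n_blocks)) {
      top <- sprintf("T%d", g)
      edges[[length(edges) + 1L]] <- c(top, "root")
      depth_of[top] <- 1L
      level <- top
      nodes_g <- top
      d <- 1L
      while (d < spec$dag_depth) {
        nxt <- character(0)
        for (parent in level) {
          kids <- sprintf("%s.%d", parent, seq_len(spec$dag_branching))
          for (k in kids) {
            edges[[length(edges) + 1L]] <- c(k, parent)
            depth_of[k] <- d + 1L
          }
          nxt <- c(nxt, kids)
        }
        nodes_g <- c(nodes_g, nxt)
        level <- nxt
        d <- d + 1L
      }
      subtree[[g]] <- nodes_g
    }
    # second parents: deep node -> any strictly shallower non-ancestor layer
    deep <- names(depth_of)[depth_of >= 2L]
    n_extra <- floor(spec$second_parent_frac * length(deep))
    if (n_extra > 0) {
      chosen <- sample(deep, n_extra)
      for (v in chosen) {
        shallower <- setdiff(names(depth_of)[depth_of < depth_of[v]], "root")
        if (!length(shallower)) next
        p2 <- sample(shallower, 1)
        edges[[length(edges) + 1L]] <- c(v, p2)
      }
    }
    disease_ids <- sprintf("d%03d", seq_along(disease_blocks))
    mapping <- vector("list", length(disease_ids))
    names(mapping) <- disease_ids
    for (j in seq_along(disease_ids)) {
      pool <- subtree[[disease_blocks[j]]]
      n_terms <- if (stats::runif(1) < spec$multi_term_frac && length(pool) > 1) 2L else 1L
      mapping[[j]] <- sample(pool, n_terms)
    }
    dag <- disease_dag(do.call(rbind, edges), mapping = mapping)
    list(dag = dag, entity_to_terms = mapping)
  })
}

#' Generate a full synthetic benchmark instance
#'
#' Convenience wrapper returning associations, block labels, DAG and
#' mapping from one spec.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `Y`, `circ_blocks`, `disease_blocks`, `dag`,
#'   `entity_to_terms`.
#' @export
generate_instance <- function(spec) {
  assoc <- generate_associations(spec)
  dg <- generate_dag(spec, assoc$disease_blocks)
  c(assoc, dg)
}
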