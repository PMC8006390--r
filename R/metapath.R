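#' Define a metapath
#'
#' A metapath is a typed path pattern such as `"GDG"` (gene-disease-gene)
#' whose first and last node types coincide.  Each consecutive type pair
#' must correspond to a relation of the metagraph (in either direction).
#'
#' @param name Token string of single-letter node types, e.g. `"GDG"`.
#' @return An object of class `metapath_spec` with fields `name`,
#'   `type_sequence` and `endpoint_type`.
#' @export
#' @examples
#' metapath_spec("GDG")
metapath_spec <- function(name) {
  types <- strsplit(name, "")[[1]]
  if (length(types) < 1 || !all(types %in% NODE_TYPES)) {
    stop("metapath '", name, "' contains unknown node types", call. = FALSE)
  }
  if (types[1] != types[length(types)]) {
    stop("metapath '", name, "' must start and end on the same type",
         call. = FALSE)
  }
  mg <- metagraph()
  pair_key <- c(paste(mg$from, mg$to), paste(mg$to, mg$from))
  if (length(types) > 1) {
    steps <- paste(types[-length(types)], types[-1])
    bad <- steps[!steps %in% pair_key]
    if (length(bad)) {
      stop("metapath '", name, "' uses relation(s) absent from the ",
           "metagraph: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, type_sequence = types,
                 endpoint_type = types[1]),
            class = "metapath_spec")
}

#' @export
print.metapath_spec <- function(x, ...) {
  cat("<metapath>", x$name, "\n")
  invisible(x)
}

#' Default metapath registry
#'
#' The metapaths used for genes are GG (protein interaction), GDG (shared
#' disease) and GOG (shared GO annotation); for diseases, DGD (shared gene)
#' and DSD (shared symptom).
#'
#' @return Named list of [metapath_spec()] objects.
#' @export
default_metapaths <- function() {
  paths <- c("GG", "GDG", "GOG", "DGD", "DSD")
  setNames(lapply(paths, metapath_spec), paths)
}

# Sparse incidence/adjacency of one relation step `a -> b`.
step_matrix <- function(g, a, b) {
  mg <- metagraph()
  rel <- mg$relation[(mg$from == a & mg$to == b) |
                       (mg$from == b & mg$to == a)]
  if (!length(rel)) stop("no relation between ", a, " and ", b,
                         call. = FALSE)
  ed <- g$edges[g$edges$relation == rel, , drop = FALSE]
  na <- length(g$nodes[[a]]); nb <- length(g$nodes[[b]])
  fwd <- mg$from[mg$relation == rel] == a
  i <- g$index[[a]][if (fwd) ed$src else ed$dst]
  j <- g$index[[b]][if (fwd) ed$dst else ed$src]
  m <- Matrix::sparseMatrix(i = as.integer(i), j = as.integer(j), x = 1,
                            dims = c(na, nb))
  if (a == b) m <- m + Matrix::t(m)  # symmetric same-type relation
  m
}

#' Build the homogeneous graph induced by a metapath
#'
#' Converts the heterogeneous graph into a homogeneous graph over the
#' metapath's endpoint type: nodes are all nodes of that type, and an
#' undirected edge `(u, v)` with weight `w` records that `w` distinct
#' metapath instances connect `u` to `v`.  Trivial self-loops from
#' back-tracking along the same edge are excluded.
#'
#' @param g A [hetero_graph()].
#' @param m A [metapath_spec()], or its token string.
#' @return An object of class `metapath_graph` with fields `metapath`,
#'   `nodes` (endpoint-type identifiers; row/column order of the adjacency)
#'   and `adjacency` (sparse symmetric matrix of path counts).
#' @export
#' @examples
#' ed <- data.frame(src = c("g1", "g2"), dst = "d1", relation = "G-D")
#' g <- hetero_graph(ed)
#' build_metapath_graph(g, "GDG")$adjacency
build_metapath_graph <- function(g, m) {
  stopifnot(inherits(g, "hetero_graph"))
  if (is.character(m)) m <- metapath_spec(m)
  types <- m$type_sequence
  n <- length(g$nodes[[m$endpoint_type]])
  if (length(types) == 1) {
    adj <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n))
  } else {
    adj <- step_matrix(g, types[1], types[2])
    if (length(types) > 2) {
      for (k in seq(2, length(types) - 1)) {
        adj <- adj %*% step_matrix(g, types[k], types[k + 1])
      }
    }
  }
  diag(adj) <- 0
  adj <- Matrix::drop0(adj)
  dimnames(adj) <- list(g$nodes[[m$endpoint_type]],
                        g$nodes[[m$endpoint_type]])
  structure(list(metapath = m, nodes = g$nodes[[m$endpoint_type]],
                 adjacency = adj),
            class = "metapath_graph")
}

#' @export
print.metapath_graph <- function(x, ...) {
  cat("<metapath_graph>", x$metapath$name, ":", length(x$nodes), "nodes,",
      Matrix::nnzero(x$adjacency) / 2, "undirected edges\n")
  invisible(x)
}

#' Sample a node's neighbourhood in a metapath graph
#'
#' Returns up to `limit` neighbours of `node`, sampled uniformly without
#' replacement when the degree exceeds `limit`, with the node itself always
#' appended last (aggregation neighbourhoods include the target node).  An
#' isolated node yields just itself.
#'
#' @param mg A [metapath_graph()].
#' @param node Node identifier (must be of the endpoint type).
#' @param limit Maximum number of neighbours (default 100, the fixed
#'   neighbour budget used during training).
#' @param seed Optional integer making the subsample reproducible.
#' @return Character vector of neighbour identifiers, ending with `node`.
#' @export
sample_neighbors <- function(mg, node, limit = 100, seed = NULL) {
  stopifnot(inherits(mg, "metapath_graph"), limit >= 1)
  idx <- match(node, mg$nodes)
  if (is.na(idx)) stop("node '", node, "' is not of type ",
                       mg$metapath$endpoint_type, call. = FALSE)
  nb <- which(mg$adjacency[idx, ] > 0)
  if (length(nb) > limit) {
    nb <- with_seed(seed, sample(nb, limit))
  }
  c(mg$nodes[sort(nb)], node)
}
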