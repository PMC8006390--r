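#' @importFrom stats rnorm runif setNames rbinom
#' @importFrom utils head read.delim write.table modifyList
NULL

# Node types and permitted relations of the four-type biomedical network:
# genes (G), diseases (D), Gene Ontology terms (O), disease symptoms (S).
NODE_TYPES <- c("G", "D", "O", "S")

#' Metagraph of the four-type heterogeneous network
#'
#' The schema of permitted relations: gene-gene (protein interactions),
#' gene-disease associations, gene-GO annotations and disease-symptom
#' associations.  Every edge of a [hetero_graph()] must instantiate one of
#' these relations.
#'
#' @return A data frame with columns `from`, `to` (node types) and
#'   `relation` (canonical relation label).
#' @export
#' @examples
#' metagraph()
metagraph <- function() {
  data.frame(
    from     = c("G", "G", "G", "D"),
    to       = c("G", "D", "O", "S"),
    relation = c("G-G", "G-D", "G-O", "D-S"),
    stringsAsFactors = FALSE
  )
}

relation_types <- function(relation) {
  mg <- metagraph()
  i <- match(relation, mg$relation)
  if (anyNA(i)) {
    stop("unknown relation(s): ", paste(relation[is.na(i)], collapse = ", "),
         "; permitted relations are ", paste(mg$relation, collapse = ", "),
         call. = FALSE)
  }
  mg[i, c("from", "to"), drop = FALSE]
}

#' Construct a typed heterogeneous graph
#'
#' Builds a validated in-memory heterogeneous graph from a typed edge table.
#' Node sets per type are inferred from edge endpoints (plus optional
#' explicit node lists); external string identifiers are interned to dense
#' 1-based per-type indices.  Duplicate edges are collapsed; edges of the
#' symmetric gene-gene relation are stored with endpoints in sorted order.
#'
#' @param edges Data frame with columns `src`, `dst`, `relation` and
#'   optionally `weight`.  `src` must be an identifier of the relation's
#'   first node type and `dst` of its second (e.g. for `"G-D"`, `src` is a
#'   gene, `dst` a disease).  Unknown relations are an error.  Edge weights
#'   default to 1, the initial weight of every edge in the network.
#' @param nodes Optional data frame with columns `id`, `type` declaring the
#'   node universe.  When given, every edge endpoint must appear in it;
#'   dangling endpoints raise an error that reports the offending rows.
#' @param features Optional named list of per-type numeric feature matrices
#'   with row names equal to node identifiers (one row per node of that
#'   type).
#' @return An object of class `hetero_graph`: a list with elements `nodes`
#'   (named list of per-type identifier vectors; position = dense index),
#'   `edges` (deduplicated edge table), `index` (per-type id to index
#'   lookups) and `features`.
#' @export
#' @examples
#' ed <- data.frame(src = c("g1", "g1"), dst = c("d1", "d2"),
#'                  relation = "G-D")
#' g <- hetero_graph(ed)
#' hetnet_counts(g)
hetero_graph <- function(edges = NULL, nodes = NULL, features = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(src = character(), dst = character(),
                        relation = character(), weight = numeric(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("src", "dst", "relation") %in% names(edges))) {
    stop("`edges` needs columns src, dst, relation", call. = FALSE)
  }
  edges$src <- as.character(edges$src)
  edges$dst <- as.character(edges$dst)
  edges$relation <- as.character(edges$relation)
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))

  rt <- if (nrow(edges)) relation_types(edges$relation) else
    data.frame(from = character(), to = character())

  # canonical order for the symmetric same-type relation, then dedupe
  if (nrow(edges)) {
    same <- rt$from == rt$to
    flip <- same & edges$src > edges$dst
    if (any(flip)) {
      tmp <- edges$src[flip]
      edges$src[flip] <- edges$dst[flip]
      edges$dst[flip] <- tmp
    }
    self <- same & edges$src == edges$dst
    if (any(self)) edges <- edges[!self, , drop = FALSE]
    rt <- relation_types(edges$relation)
    key <- paste(edges$relation, edges$src, edges$dst, sep = "\r")
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    rt <- rt[keep, , drop = FALSE]
    rownames(edges) <- NULL
  }

  node_ids <- setNames(vector("list", length(NODE_TYPES)), NODE_TYPES)
  for (tp in NODE_TYPES) {
    ids <- character()
    if (nrow(edges)) {
      ids <- c(edges$src[rt$from == tp], edges$dst[rt$to == tp])
    }
    if (!is.null(nodes)) {
      declared <- as.character(nodes$id[nodes$type == tp])
      missing_nodes <- setdiff(unique(ids), declared)
      if (length(missing_nodes)) {
        bad <- edges[rt$from == tp & edges$src %in% missing_nodes |
                       rt$to == tp & edges$dst %in% missing_nodes, ,
                     drop = FALSE]
        stop("dangling endpoint(s) of type ", tp, ": ",
             paste(head(missing_nodes, 5), collapse = ", "),
             " (first offending row: ",
             paste(unlist(bad[1, 1:3]), collapse = " / "), ")",
             call. = FALSE)
      }
      ids <- declared
    }
    node_ids[[tp]] <- sort(unique(ids))
  }

  if (!is.null(features)) {
    for (tp in names(features)) {
      fm <- as.matrix(features[[tp]])
      miss <- setdiff(node_ids[[tp]], rownames(fm))
      if (length(miss)) {
        stop("feature matrix for type ", tp, " lacks rows for: ",
             paste(head(miss, 5), collapse = ", "), call. = FALSE)
      }
      features[[tp]] <- fm[node_ids[[tp]], , drop = FALSE]
    }
  }

  g <- structure(
    list(
      nodes    = node_ids,
      edges    = edges,
      index    = lapply(node_ids, function(x) setNames(seq_along(x), x)),
      features = features
    ),
    class = "hetero_graph"
  )
  g
}

#' Node and edge counts of a heterogeneous graph
#'
#' @param g A [hetero_graph()].
#' @return A list with `nodes` (named integer vector, per type) and `edges`
#'   (named integer vector, per relation).
#' @export
hetnet_counts <- function(g) {
  stopifnot(inherits(g, "hetero_graph"))
  rel <- metagraph()$relation
  list(
    nodes = vapply(g$nodes, length, integer(1)),
    edges = setNames(vapply(rel, function(r) sum(g$edges$relation == r),
                            integer(1)), rel)
  )
}

#' @export
print.hetero_graph <- function(x, ...) {
  cnt <- hetnet_counts(x)
  cat("<hetero_graph>", sum(cnt$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  nodes:", paste(names(cnt$nodes), cnt$nodes, collapse = "  "), "\n")
  cat("  edges:", paste(names(cnt$edges), cnt$edges, collapse = "  "), "\n")
  invisible(x)
}

#' Validate a heterogeneous graph against the metagraph
#'
#' Checks the heterogeneity property (more than two node plus relation
#' types present), metagraph conformance of every edge, uniqueness of
#' identifiers within a type, and feature-matrix alignment.
#'
#' @param g A [hetero_graph()].
#' @return Invisibly, a character vector of problems (empty when valid).
#'   With `error = TRUE` (default) any problem raises an error instead.
#' @param error Raise an error on the first problem?
#' @export
validate_hetnet <- function(g, error = TRUE) {
  problems <- character()
  if (!inherits(g, "hetero_graph")) problems <- "not a hetero_graph"
  if (!length(problems)) {
    bad_rel <- setdiff(unique(g$edges$relation), metagraph()$relation)
    if (length(bad_rel)) {
      problems <- c(problems,
                    paste("edges with unknown relation:",
                          paste(bad_rel, collapse = ", ")))
    }
    if (nrow(g$edges)) {
      rt <- relation_types(g$edges$relation)
      for (k in seq_len(nrow(g$edges))) {
        if (!g$edges$src[k] %in% g$nodes[[rt$from[k]]] ||
            !g$edges$dst[k] %in% g$nodes[[rt$to[k]]]) {
          problems <- c(problems, paste("edge row", k, "has an endpoint",
                                        "missing from its node type"))
          break
        }
      }
    }
    for (tp in NODE_TYPES) {
      if (anyDuplicated(g$nodes[[tp]])) {
        problems <- c(problems, paste("duplicate node ids of type", tp))
      }
      if (!is.null(g$features) && !is.null(g$features[[tp]]) &&
          nrow(g$features[[tp]]) != length(g$nodes[[tp]])) {
        problems <- c(problems, paste("feature rows mismatch for type", tp))
      }
    }
    n_types <- sum(vapply(g$nodes, length, integer(1)) > 0)
    n_rel <- length(unique(g$edges$relation))
    if (nrow(g$edges) && n_types + n_rel <= 2) {
      problems <- c(problems, "graph is not heterogeneous (|A| + |R| <= 2)")
    }
  }
  if (error && length(problems)) stop(problems[[1]], call. = FALSE)
  invisible(problems)
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

read_edge_file <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("edge file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- guess_sep(path)
  df <- read.delim(path, sep = sep, header = TRUE,
                   colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("edge file needs two id columns: ", path,
                         call. = FALSE)
  out <- data.frame(src = df[[1]], dst = df[[2]], stringsAsFactors = FALSE)
  if (ncol(df) >= 3 && !anyNA(suppressWarnings(as.numeric(df[[3]])))) {
    out$weight <- as.numeric(df[[3]])
  }
  out
}

#' Load a heterogeneous network from per-relation edge-list files
#'
#' Reads one tabular edge-list file per relation (TSV or CSV with a header
#' row; first two columns are the source and target identifiers, an
#' optional third numeric column is an edge weight).  The relation of each
#' file is given by the names of `edge_files`.  All edge weights default to
#' 1, duplicate rows are collapsed, and identifiers are interned to dense
#' per-type indices retrievable from the returned object's `index` field.
#'
#' @param edge_files Named character vector or list mapping relation labels
#'   (`"G-G"`, `"G-D"`, `"G-O"`, `"D-S"`) to file paths.
#' @param feature_files Optional named character vector mapping node types
#'   to tabular feature files (first column: node id; remaining columns:
#'   numeric features).
#' @param nodes Optional node universe, as in [hetero_graph()].
#' @return A validated [hetero_graph()].
#' @export
load_hetnet <- function(edge_files, feature_files = NULL, nodes = NULL) {
  edge_files <- unlist(edge_files)
  if (is.null(names(edge_files)) || any(names(edge_files) == "")) {
    stop("`edge_files` must be named by relation", call. = FALSE)
  }
  relation_types(names(edge_files))  # schema check up front
  parts <- lapply(names(edge_files), function(rel) {
    df <- read_edge_file(edge_files[[rel]])
    if (is.null(df$weight)) df$weight <- rep(1, nrow(df))
    df$relation <- rep(rel, nrow(df))
    df[, c("src", "dst", "relation", "weight")]
  })
  edges <- do.call(rbind, parts)

  features <- NULL
  if (!is.null(feature_files)) {
    features <- lapply(feature_files, function(p) {
      df <- read.delim(p, sep = guess_sep(p), header = TRUE,
                       check.names = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      storage.mode(m) <- "double"
      rownames(m) <- as.character(df[[1]])
      m
    })
    names(features) <- names(feature_files)
  }

  g <- hetero_graph(edges, nodes = nodes, features = features)
  validate_hetnet(g)
  g
}

#' Write a heterogeneous network as per-relation edge-list files
#'
#' Emits one TSV per relation present in the graph (`G-G.tsv`, `G-D.tsv`,
#' ...), each with header `src  dst  weight` — the same format
#' [load_hetnet()] reads.
#'
#' @param g A [hetero_graph()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_hetnet <- function(g, dir) {
  stopifnot(inherits(g, "hetero_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rels <- unique(g$edges$relation)
  paths <- setNames(file.path(dir, paste0(rels, ".tsv")), rels)
  for (rel in rels) {
    df <- g$edges[g$edges$relation == rel, c("src", "dst", "weight")]
    write.table(df, paths[[rel]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}
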