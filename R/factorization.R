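sigmoid <- function(x) stats::plogis(x)

leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)

elu <- function(x) {
  neg <- x <= 0
  x[neg] <- exp(x[neg]) - 1
  x
}

# Glorot-uniform initializer for a fan_out x fan_in matrix.
glorot <- function(n_out, n_in) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Per-type linear projection into a common feature space
#'
#' Node features of the four types live in different spaces (and
#' dimensions), so each type `a` gets a linear transformation matrix
#' `M_a` of shape `d_prime x d_a` mapping its raw features into a shared
#' `d_prime`-dimensional space: `h'_v = M_a x_v`.
#'
#' @param dims Named integer vector of raw feature dimensions per type.
#' @param d_prime Common projected dimension.
#' @param seed Integer seed for the Glorot-uniform initialization.
#' @return A `feature_projector`: named list of projection matrices.
#' @export
feature_projector <- function(dims, d_prime, seed = 1) {
  stopifnot(d_prime >= 1, length(dims) >= 1, !is.null(names(dims)))
  mats <- with_seed(seed, lapply(dims, function(d) glorot(d_prime, d)))
  structure(mats, class = "feature_projector", d_prime = d_prime)
}

#' Project raw node features into the common space
#'
#' Applies the type-specific linear map: for a single feature vector `x`
#' of type `type`, returns `M_a x`; for a feature matrix (nodes in rows),
#' returns the row-wise projection.
#'
#' @param x Numeric vector (length `d_a`) or matrix (`n x d_a`).
#' @param proj A [feature_projector()].
#' @param type Node type label, one of the projector's names.
#' @return Projected vector of length `d_prime`, or `n x d_prime` matrix.
#' @export
project_nodes <- function(x, proj, type) {
  if (!type %in% names(proj)) {
    stop("no projection registered for type ", type, call. = FALSE)
  }
  M <- proj[[type]]
  if (is.matrix(x)) {
    if (ncol(x) != ncol(M)) stop("feature dimension mismatch for type ",
                                 type, call. = FALSE)
    x %*% t(M)
  } else {
    if (length(x) != ncol(M)) stop("feature dimension mismatch for type ",
                                   type, call. = FALSE)
    drop(M %*% x)
  }
}

#' Initialize a set of factor-graph scorers for one metapath
#'
#' A metapath-induced homogeneous graph is factorized into `n_factors`
#' factor graphs.  Each factor graph `e` reweights the same edge set by a
#' learned pairwise scorer: a single affine layer on the concatenated pair
#' features, `S_e(h'_v, h'_u) = a_e . [h'_v || h'_u] + b_e`, squashed
#' through a sigmoid.  All factor graphs share the node features and the
#' sparsity pattern; only the edge weights differ.
#'
#' @param m A [metapath_spec()] (or token string) the set belongs to.
#' @param d_prime Common feature dimension.
#' @param n_factors Number of factor graphs (default 16, the count at
#'   which the factorization performs best).
#' @param seed Integer seed.
#' @return A `factor_graph_set` with one `(a, b)` scorer per factor.
#' @export
factor_graph_set <- function(m, d_prime, n_factors = 16, seed = 1) {
  if (is.character(m)) m <- metapath_spec(m)
  stopifnot(n_factors >= 1, d_prime >= 1)
  scorers <- with_seed(seed, lapply(seq_len(n_factors), function(e) {
    list(a = drop(glorot(1, 2 * d_prime)), b = 0)
  }))
  structure(list(metapath = m, n_factors = n_factors, d_prime = d_prime,
                 scorers = scorers),
            class = "factor_graph_set")
}

# Pairwise pre-sigmoid score, symmetrized over the two argument orders.
# With an affine scorer on the concatenation, averaging the two orders
# collapses to q_v/2 + q_u/2 + b with q = h' (a1 + a2).
factor_logit_vec <- function(h, scorer) {
  d <- ncol(h)
  drop(h %*% (scorer$a[seq_len(d)] + scorer$a[d + seq_len(d)]))
}

#' Reconstructed edge weights of each factor graph
#'
#' Evaluates every factor scorer on every edge of the metapath graph:
#' `W_e[v, u] = sigmoid((S_e(h'_v, h'_u) + S_e(h'_u, h'_v)) / 2)`.  The
#' average over both argument orders makes the weights symmetric, as an
#' undirected graph requires.  Weights are computed only on existing
#' edges, so all factor graphs share the metapath graph's sparsity
#' pattern, and every stored weight lies strictly in (0, 1).
#'
#' @param mg A [metapath_graph()].
#' @param h Projected feature matrix (`n x d_prime`, rows aligned with
#'   `mg$nodes`).
#' @param fset A [factor_graph_set()].
#' @return List of `n_factors` sparse symmetric weight matrices.
#' @export
factor_edge_weights <- function(mg, h, fset) {
  stopifnot(inherits(mg, "metapath_graph"),
            inherits(fset, "factor_graph_set"))
  if (nrow(h) != length(mg$nodes)) {
    stop("feature rows must cover every node of the metapath graph",
         call. = FALSE)
  }
  if (ncol(h) != fset$d_prime) {
    stop("scorer dimension (", fset$d_prime, ") does not match features (",
         ncol(h), ")", call. = FALSE)
  }
  pat <- methods::as(mg$adjacency, "TsparseMatrix")
  i <- pat@i + 1L; j <- pat@j + 1L
  lapply(fset$scorers, function(sc) {
    q <- factor_logit_vec(h, sc)
    w <- sigmoid((q[i] + q[j]) / 2 + sc$b)
    Matrix::sparseMatrix(i = i, j = j, x = w, dims = dim(mg$adjacency),
                         dimnames = dimnames(mg$adjacency))
  })
}

#' Permutation-invariant encoding of a factor graph
#'
#' Encodes a factor graph `(W_e, h')` as a fixed-length vector: one round
#' of weight-averaged neighbourhood aggregation per node (the node itself
#' enters with weight 1), followed by global mean pooling over nodes.
#' This is the simplest permutation-invariant encoder that uses both the
#' reconstructed edge weights and the node features; an empty edge set
#' degenerates to the global mean of `h'`.
#'
#' @param W_e Sparse (or dense) symmetric `n x n` edge-weight matrix.
#' @param h Feature matrix `n x d_prime`.
#' @return Numeric vector of length `d_prime`.
#' @export
encode_factor_graph <- function(W_e, h) {
  if (nrow(h) != nrow(W_e)) stop("dimension mismatch", call. = FALSE)
  agg <- as.matrix(W_e %*% h)
  denom <- 1 + Matrix::rowSums(W_e)
  colMeans((h + agg) / denom)
}

#' Initialize the factor-graph discriminator
#'
#' A single fully-connected layer mapping a graph encoding to one logit
#' per factor label; the label count equals the number of factor graphs
#' so that every factor graph must be distinguishable.
#'
#' @param d_prime Encoding dimension.
#' @param n_factors Number of factor graphs (= number of labels).
#' @param seed Integer seed.
#' @return A `factor_classifier` with weight matrix `W` and bias `b`.
#' @export
factor_classifier <- function(d_prime, n_factors, seed = 1) {
  structure(list(W = with_seed(seed, glorot(n_factors, d_prime)),
                 b = rep(0, n_factors)),
            class = "factor_classifier")
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Classify factor-graph encodings
#'
#' @param enc Matrix of graph encodings (one row per factor graph).
#' @param clf A [factor_classifier()].
#' @return Matrix of softmax label probabilities (rows sum to 1).
#' @export
classify_factor_graphs <- function(enc, clf) {
  if (!is.matrix(enc)) enc <- matrix(enc, nrow = 1)
  softmax_rows(enc %*% t(clf$W) + matrix(clf$b, nrow(enc), length(clf$b),
                                         byrow = TRUE))
}

#' Factor-graph discrimination loss
#'
#' Cross-entropy that forces the factor graphs apart: each factor graph
#' carries its own index as label, and the loss is the mean negative log
#' probability assigned to the correct label,
#' `L_Factor = (1/N) sum_i -log P_i[label_i]`.
#' A classifier that outputs the uniform distribution yields `log(N)`;
#' perfect discrimination drives the loss to 0.
#'
#' @param prob Matrix of predicted label probabilities, one row per factor
#'   graph (e.g. from [classify_factor_graphs()]).
#' @param labels Integer label per row; defaults to the row index (each
#'   factor graph is its own class).
#' @param eps Probability floor guarding the logarithm.
#' @return Scalar non-negative loss.
#' @export
factor_discriminant_loss <- function(prob, labels = seq_len(nrow(prob)),
                                     eps = 1e-12) {
  if (!is.matrix(prob)) prob <- matrix(prob, nrow = 1)
  stopifnot(length(labels) == nrow(prob),
            all(labels >= 1), all(labels <= ncol(prob)))
  if (nrow(prob) < 2) {
    warning("fewer than 2 factor graphs: nothing to discriminate",
            call. = FALSE)
  }
  p <- pmax(prob[cbind(seq_len(nrow(prob)), labels)], eps)
  mean(-log(p))
}
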