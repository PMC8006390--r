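#' Initialize an intra-metapath attention layer
#'
#' Multi-head graph attention applied inside every factor graph of one
#' metapath.  Each (factor, head) pair owns a linear map `W` (`d_head x
#' d_prime`) and an attention vector `a` (length `2 d_head`); the
#' attention logit between nodes `i` and `j` is
#' `LeakyReLU(a^T [W h'_i || W h'_j])` (negative slope `slope`), shifted
#' by `log W_e[i, j]` so that the learned factor-graph edge weights
#' modulate the softmax (the self edge has weight 1).
#'
#' @param d_prime Input (common-space) feature dimension.
#' @param n_factors Number of factor graphs.
#' @param n_heads Number of attention heads `K` (default 8).
#' @param d_head Output dimension per head (default `hidden_dim /
#'   n_heads` with a hidden dimension of 128).
#' @param slope Negative slope of the logit nonlinearity (default 0.2).
#' @param use_elu Apply an elementwise ELU to each aggregated head output?
#' @param seed Integer seed.
#' @return An `intra_attention_layer`.
#' @export
intra_attention_layer <- function(d_prime, n_factors = 16, n_heads = 8,
                                  d_head = 128 / n_heads, slope = 0.2,
                                  use_elu = TRUE, seed = 1) {
  stopifnot(d_head >= 1, n_heads >= 1, n_factors >= 1)
  heads <- with_seed(seed, lapply(seq_len(n_factors), function(e) {
    lapply(seq_len(n_heads), function(k) {
      list(W = glorot(d_head, d_prime), a = drop(glorot(1, 2 * d_head)))
    })
  }))
  structure(list(heads = heads, n_factors = n_factors, n_heads = n_heads,
                 d_head = d_head, d_prime = d_prime, slope = slope,
                 use_elu = use_elu),
            class = "intra_attention_layer")
}

# Attention weights and aggregate for one node's neighbourhood under one
# (factor, head): the per-node reference implementation.  `nb_idx` are the
# neighbour indices *including* the node itself; `w` the factor-graph edge
# weights towards each neighbour (self weight 1).
attend_one <- function(i, nb_idx, h, W, a, w, slope, use_elu) {
  t_mat <- h[nb_idx, , drop = FALSE] %*% t(W)
  t_i <- drop(h[i, , drop = FALSE] %*% t(W))
  d <- length(t_i)
  logit <- leaky_relu(drop(t_mat %*% a[d + seq_len(d)]) +
                        sum(t_i * a[seq_len(d)]), slope) + log(w)
  alpha <- exp(logit - max(logit))
  alpha <- alpha / sum(alpha)
  out <- drop(crossprod(t_mat, alpha))
  if (use_elu) out <- elu(out)
  attr(out, "alpha") <- alpha
  out
}

#' Aggregate one node's neighbourhood inside one factor graph
#'
#' Computes the attention coefficients over the node's sampled
#' neighbourhood (softmax of the shifted logits; they sum to 1 by
#' construction) and returns the coefficient-weighted sum of the
#' transformed neighbour features for each head, concatenated.
#'
#' @param node Node identifier.
#' @param neighborhood Character vector of neighbour identifiers
#'   including the node itself (e.g. from [sample_neighbors()]).
#' @param mg The [metapath_graph()] the neighbourhood lives in.
#' @param h Projected features (`n x d_prime`, rows aligned to
#'   `mg$nodes`).
#' @param W_e Factor edge-weight matrix for this factor (one element of
#'   [factor_edge_weights()]); `NULL` sets all neighbour weights to 1.
#' @param layer An [intra_attention_layer()].
#' @param factor Factor index whose heads to use.
#' @return Numeric vector of length `n_heads * d_head`, with the per-head
#'   attention coefficients in attribute `"alpha"`.
#' @export
intra_factor_aggregate <- function(node, neighborhood, mg, h, W_e, layer,
                                   factor = 1) {
  i <- match(node, mg$nodes)
  nb_idx <- match(neighborhood, mg$nodes)
  if (anyNA(c(i, nb_idx))) stop("unknown node in neighbourhood",
                                call. = FALSE)
  if (!i %in% nb_idx) stop("neighbourhood must include the node itself",
                           call. = FALSE)
  w <- if (is.null(W_e)) rep(1, length(nb_idx)) else {
    wv <- as.numeric(W_e[i, nb_idx])
    wv[nb_idx == i] <- 1
    wv
  }
  heads <- layer$heads[[factor]]
  outs <- lapply(heads, function(hd) {
    attend_one(i, nb_idx, h, hd$W, hd$a, w, layer$slope, layer$use_elu)
  })
  out <- unlist(lapply(outs, as.numeric))
  attr(out, "alpha") <- lapply(outs, attr, "alpha")
  out
}

# Vectorized dense forward over one metapath: all factors and heads.
# Hp: n x d'; nb_mask: n x n logical, row i = sampled neighbourhood of i
# (diagonal TRUE).  scorers: list of (a, b); heads: nested [[e]][[k]]
# (W, a).  Returns Z (n x n_factors*n_heads*d_head), and caches for
# backpropagation when `cache = TRUE`.
dense_metapath_forward <- function(Hp, nb_mask, scorers, heads,
                                   slope = 0.2, use_elu = TRUE,
                                   cache = FALSE) {
  n <- nrow(Hp)
  n_factors <- length(scorers)
  n_heads <- length(heads[[1]])
  d_head <- nrow(heads[[1]][[1]]$W)
  Z <- matrix(0, n, n_factors * n_heads * d_head)
  caches <- if (cache) vector("list", n_factors) else NULL

  for (e in seq_len(n_factors)) {
    q <- factor_logit_vec(Hp, scorers[[e]])
    X <- (outer(q, q, "+")) / 2 + scorers[[e]]$b
    Wfull <- sigmoid(X)
    # additive log-weight mask: -Inf outside the neighbourhood, 0 on the
    # self edge (weight 1), log W_e on sampled neighbour edges
    shift <- matrix(-Inf, n, n)
    shift[nb_mask] <- log(Wfull[nb_mask])
    diag(shift) <- 0
    ecache <- if (cache) list(q = q, Wfull = Wfull, heads = vector("list",
                                                                   n_heads))
    for (k in seq_len(n_heads)) {
      hd <- heads[[e]][[k]]
      T_ <- Hp %*% t(hd$W)
      f <- drop(T_ %*% hd$a[seq_len(d_head)])
      gv <- drop(T_ %*% hd$a[d_head + seq_len(d_head)])
      C <- outer(f, gv, "+")
      Cact <- leaky_relu(C, slope)
      L <- Cact + shift
      mx <- L[cbind(seq_len(n), max.col(L, ties.method = "first"))]
      A <- exp(L - mx)
      A[!is.finite(A)] <- 0
      A <- A / rowSums(A)
      S <- A %*% T_
      Zek <- if (use_elu) elu(S) else S
      cols <- ((e - 1) * n_heads + (k - 1)) * d_head + seq_len(d_head)
      Z[, cols] <- Zek
      if (cache) ecache$heads[[k]] <- list(T_ = T_, C = C, A = A, S = S)
    }
    if (cache) caches[[e]] <- ecache
  }
  list(Z = Z, caches = caches)
}

#' Per-metapath node embeddings
#'
#' Runs the full intra-metapath pipeline for one metapath: reconstructs
#' the factor-graph edge weights, aggregates every node's neighbourhood
#' with multi-head attention inside each factor graph, and concatenates
#' the `K` head outputs and then the `N` factor outputs into the
#' metapath embedding `Z^m` of dimension `N * K * d_head` per node.
#'
#' @param mg A [metapath_graph()].
#' @param h Projected features (`n x d_prime`).
#' @param fset A [factor_graph_set()] for this metapath.
#' @param layer An [intra_attention_layer()] with the same factor count.
#' @param neighbor_limit Neighbour budget per node (default 100).
#' @param seed Seed for the neighbourhood subsample.
#' @return Matrix `n x (n_factors * n_heads * d_head)` (rows aligned with
#'   `mg$nodes`).
#' @export
metapath_embed <- function(mg, h, fset, layer, neighbor_limit = 100,
                           seed = NULL) {
  stopifnot(inherits(mg, "metapath_graph"),
            inherits(fset, "factor_graph_set"),
            inherits(layer, "intra_attention_layer"))
  if (fset$n_factors != layer$n_factors) {
    stop("factor count mismatch between factor set (", fset$n_factors,
         ") and attention layer (", layer$n_factors, ")", call. = FALSE)
  }
  nb_mask <- neighborhood_mask(mg$adjacency, neighbor_limit, seed)
  out <- dense_metapath_forward(h, nb_mask, fset$scorers, layer$heads,
                                layer$slope, layer$use_elu)
  rownames(out$Z) <- mg$nodes
  out$Z
}

# Sampled-neighbourhood mask: row i marks up to `limit` neighbours of i
# plus i itself.
neighborhood_mask <- function(adjacency, limit = 100, seed = NULL) {
  n <- nrow(adjacency)
  adj <- as.matrix(adjacency) > 0
  deg <- rowSums(adj)
  with_seed(seed, {
    mask <- adj
    for (i in which(deg > limit)) {
      keep <- sample(which(adj[i, ]), limit)
      mask[i, ] <- FALSE
      mask[i, keep] <- TRUE
    }
  })
  diag(mask) <- TRUE
  mask
}

#' Initialize semantic (metapath-level) attention
#'
#' One linear summary transform `W` plus bias `b` per node type, and an
#' attention vector `Q` scoring the metapath summaries.
#'
#' @param d_in Dimension of the per-metapath embeddings `Z^m`.
#' @param d_sem Dimension of the summary space (default 128).
#' @param seed Integer seed.
#' @return A `semantic_attention` with fields `W`, `b`, `Q`.
#' @export
semantic_attention <- function(d_in, d_sem = 128, seed = 1) {
  with_seed(seed, structure(
    list(W = glorot(d_sem, d_in), b = rep(0, d_sem),
         Q = drop(glorot(1, d_sem))),
    class = "semantic_attention"
  ))
}

#' Summarize one metapath's embeddings
#'
#' The metapath summary is the node-average of a squashed linear
#' transform: `P_m = (1/|V_a|) sum_v tanh(W Z^m_v + b)`.
#'
#' @param Z Per-node metapath embeddings (`n x d_in`).
#' @param sem A [semantic_attention()].
#' @return Numeric summary vector of length `d_sem`.
#' @export
summarize_metapath <- function(Z, sem) {
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1)
  if (nrow(Z) == 0) stop("cannot summarize an empty node set",
                         call. = FALSE)
  if (ncol(Z) != ncol(sem$W)) stop("dimension mismatch between Z and the ",
                                   "summary transform", call. = FALSE)
  colMeans(tanh(Z %*% t(sem$W) +
                  matrix(sem$b, nrow(Z), length(sem$b), byrow = TRUE)))
}

#' Fuse per-metapath embeddings with semantic attention
#'
#' Scores each metapath summary against the attention vector,
#' `w_m = <Q, P_m>`, softmax-normalizes the scores into metapath weights
#' `omega` (identical for all nodes of the type), and returns the
#' weighted combination `H_v = sum_m omega_m Z^m_v`.
#'
#' @param Z_list Named list of per-metapath embedding matrices (all
#'   `n x d_in`, same row order).
#' @param sem A [semantic_attention()].
#' @return List with `H` (`n x d_in` fused embeddings) and `omega`
#'   (named metapath weights summing to 1).
#' @export
fuse_metapaths <- function(Z_list, sem) {
  stopifnot(length(Z_list) >= 1)
  P <- vapply(Z_list, summarize_metapath, numeric(length(sem$b)),
              sem = sem)
  w <- drop(sem$Q %*% P)
  omega <- exp(w - max(w))
  omega <- omega / sum(omega)
  H <- Reduce(`+`, Map(`*`, Z_list, as.list(omega)))
  list(H = H, omega = setNames(omega, names(Z_list)))
}
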