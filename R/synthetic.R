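#' Configuration for the synthetic heterogeneous-network generator
#'
#' Describes a four-type network (genes, diseases, GO terms, symptoms)
#' with planted community structure: nodes of every type are assigned to
#' `n_blocks` latent communities and each permitted relation is drawn from
#' a stochastic block model with within-community probability `p_in` and
#' cross-community probability `p_out`.  Gene-disease edges are the
#' positives for link prediction, so `p_in > p_out` plants a learnable
#' association signal; `p_in == p_out` is the no-signal control.
#'
#' @param n_G,n_D,n_O,n_S Node counts per type.
#' @param n_blocks Number of latent communities (default 2).
#' @param p_in Within-community edge probability, a scalar or a vector
#'   named by relation (default 0.3).
#' @param p_out Cross-community edge probability (default 0.02).
#' @param feature_mode `"onehot"` (identity features, the default) or
#'   `"gaussian"` (random features of dimension `feature_dim`).
#' @param feature_dim Dimension of Gaussian features.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_G = 200, n_D = 100, n_O = 150, n_S = 80,
                         n_blocks = 2, p_in = 0.3, p_out = 0.02,
                         feature_mode = c("onehot", "gaussian"),
                         feature_dim = 32, seed = 1) {
  feature_mode <- match.arg(feature_mode)
  counts <- c(G = n_G, D = n_D, O = n_O, S = n_S)
  if (any(counts < n_blocks)) {
    stop("every node count must be >= n_blocks", call. = FALSE)
  }
  rel <- metagraph()$relation
  expand <- function(p, what) {
    if (length(p) == 1 && is.null(names(p))) p <- setNames(rep(p, 4), rel)
    if (!all(rel %in% names(p))) stop(what, " must cover all relations",
                                      call. = FALSE)
    p[rel]
  }
  p_in <- expand(p_in, "p_in"); p_out <- expand(p_out, "p_out")
  if (any(p_in < 0 | p_in > 1 | p_out < 0 | p_out > p_in)) {
    stop("need 0 <= p_out <= p_in <= 1 per relation", call. = FALSE)
  }
  if (n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
  structure(list(counts = counts, n_blocks = n_blocks,
                 p_in = p_in, p_out = p_out,
                 feature_mode = feature_mode, feature_dim = feature_dim,
                 seed = seed),
            class = "synth_config")
}

# Bernoulli draw of one bipartite (or same-type) relation under the block
# model; returns an edge data frame in loader format.
sbm_relation <- function(rel, ids_a, ids_b, blocks_a, blocks_b,
                         p_in, p_out, same_type) {
  na <- length(ids_a); nb <- length(ids_b)
  prob <- matrix(p_out, na, nb)
  prob[outer(blocks_a, blocks_b, "==")] <- p_in
  draw <- matrix(runif(na * nb) < prob, na, nb)
  if (same_type) draw[lower.tri(draw, diag = TRUE)] <- FALSE
  hit <- which(draw, arr.ind = TRUE)
  data.frame(src = ids_a[hit[, 1]], dst = ids_b[hit[, 2]],
             relation = rep(rel, nrow(hit)), weight = rep(1, nrow(hit)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic heterogeneous network with planted structure
#'
#' Draws a four-type network under the block model of [synth_config()].
#' Node identifiers are `g1..`, `d1..`, `o1..`, `s1..`; communities are
#' assigned in balanced random fashion within each type; every permitted
#' relation (G-G, G-D, G-O, D-S) is sampled independently.  The result
#' conforms to the metagraph and is reproducible under the config seed.
#'
#' @param cfg A [synth_config()].
#' @return A list with `graph` (validated [hetero_graph()]), `labels`
#'   (data frame `id`, `type`, `community`) and `config`.
#' @export
#' @examples
#' net <- synth_hetnet(synth_config(n_G = 40, n_D = 20, n_O = 30, n_S = 10))
#' hetnet_counts(net$graph)
synth_hetnet <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  prefixes <- c(G = "g", D = "d", O = "o", S = "s")
  with_seed(cfg$seed, {
    ids <- blocks <- list()
    for (tp in names(cfg$counts)) {
      n <- cfg$counts[[tp]]
      ids[[tp]] <- paste0(prefixes[[tp]], seq_len(n))
      blocks[[tp]] <- sample(rep_len(seq_len(cfg$n_blocks), n))
    }
    ends <- metagraph()
    edges <- do.call(rbind, lapply(seq_len(nrow(ends)), function(k) {
      a <- ends$from[k]; b <- ends$to[k]; rel <- ends$relation[k]
      exp_edges <- cfg$p_in[[rel]] *
        (if (a == b) cfg$counts[[a]] * (cfg$counts[[a]] - 1) / 2
         else cfg$counts[[a]] * cfg$counts[[b]]) / cfg$n_blocks
      if (exp_edges < 1) {
        warning("relation ", rel, " has an expected edge count below 1; ",
                "the benchmark is degenerate", call. = FALSE)
      }
      sbm_relation(rel, ids[[a]], ids[[b]], blocks[[a]], blocks[[b]],
                   cfg$p_in[[rel]], cfg$p_out[[rel]], a == b)
    }))
    features <- NULL
    if (cfg$feature_mode == "gaussian") {
      features <- lapply(names(cfg$counts), function(tp) {
        m <- matrix(rnorm(cfg$counts[[tp]] * cfg$feature_dim),
                    nrow = cfg$counts[[tp]])
        rownames(m) <- ids[[tp]]
        m
      })
      names(features) <- names(cfg$counts)
    }
  })
  nodes <- data.frame(id = unlist(ids, use.names = FALSE),
                      type = rep(names(ids), lengths(ids)),
                      stringsAsFactors = FALSE)
  g <- hetero_graph(edges, nodes = nodes, features = features)
  validate_hetnet(g)
  labels <- data.frame(id = nodes$id,
                       type = nodes$type,
                       community = unlist(blocks, use.names = FALSE),
                       stringsAsFactors = FALSE)
  list(graph = g, labels = labels, config = cfg)
}
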