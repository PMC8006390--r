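# Shared fixtures and independent oracles used across the suite.

# A small hand-written four-type graph whose metapath instances are easy
# to enumerate by eye.
toy_graph <- function() {
  hetero_graph(data.frame(
    src = c("g1", "g1", "g2", "g2", "g3", "g1", "g2", "d1"),
    dst = c("g2", "d1", "d1", "d2", "d2", "o1", "o1", "s1"),
    relation = c("G-G", "G-D", "G-D", "G-D", "G-D", "G-O", "G-O", "D-S"),
    stringsAsFactors = FALSE
  ))
}

# Random metagraph-conforming heterogeneous graph for property tests.
random_hetnet <- function(n = c(G = 8, D = 5, O = 4, S = 3), p = 0.3) {
  ids <- list(G = paste0("g", seq_len(n[["G"]])),
              D = paste0("d", seq_len(n[["D"]])),
              O = paste0("o", seq_len(n[["O"]])),
              S = paste0("s", seq_len(n[["S"]])))
  mk <- function(rel, a, b, same = FALSE) {
    pairs <- expand.grid(src = ids[[a]], dst = ids[[b]],
                         stringsAsFactors = FALSE)
    if (same) pairs <- pairs[pairs$src < pairs$dst, ]
    keep <- runif(nrow(pairs)) < p
    if (!any(keep)) return(NULL)
    cbind(pairs[keep, ], relation = rel)
  }
  edges <- rbind(mk("G-G", "G", "G", TRUE), mk("G-D", "G", "D"),
                 mk("G-O", "G", "O"), mk("D-S", "D", "S"))
  nodes <- data.frame(id = unlist(ids, use.names = FALSE),
                      type = rep(names(ids), lengths(ids)))
  hetero_graph(edges, nodes = nodes)
}

# Brute-force metapath instance counting: walk the typed steps node by
# node and count every conforming path between distinct endpoints.
brute_metapath_counts <- function(g, spec) {
  types <- spec$type_sequence
  mg <- metagraph()
  nbrs <- function(id, a, b) {
    rel <- mg$relation[(mg$from == a & mg$to == b) |
                         (mg$from == b & mg$to == a)]
    ed <- g$edges[g$edges$relation == rel, ]
    fwd <- mg$from[mg$relation == rel] == a
    c(ed$dst[ed$src == id], ed$src[ed$dst == id])
  }
  n <- length(g$nodes[[spec$endpoint_type]])
  counts <- matrix(0, n, n,
                   dimnames = list(g$nodes[[spec$endpoint_type]],
                                   g$nodes[[spec$endpoint_type]]))
  for (u in g$nodes[[spec$endpoint_type]]) {
    ends <- character()
    if (length(types) == 1) next
    for (v1 in nbrs(u, types[1], types[2])) {
      if (length(types) == 2) ends <- c(ends, v1)
      else {
        res <- lapply(nbrs(v1, types[2], types[3]), function(v2) v2)
        ends <- c(ends, unlist(res))
      }
    }
    ends <- ends[ends != u]
    for (v in ends) counts[u, v] <- counts[u, v] + 1
  }
  counts
}

# Pairwise-comparison AUC oracle: average over all positive-negative
# pairs, ties counted half.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Stepwise precision-recall summation oracle for average precision,
# recomputing P_k and R_k from scratch at every rank.
brute_ap <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  npos <- sum(labels == 1)
  ap <- 0; r_prev <- 0
  for (k in seq_along(lab)) {
    tp <- sum(lab[seq_len(k)] == 1)
    p_k <- tp / k
    r_k <- tp / npos
    ap <- ap + (r_k - r_prev) * p_k
    r_prev <- r_k
  }
  ap
}

brute_p_at_k <- function(scores, labels, k) {
  ord <- order(-scores)
  sum(labels[ord][1:k] == 1) / k
}

brute_r_at_k <- function(scores, labels, k) {
  ord <- order(-scores)
  sum(labels[ord][1:k] == 1) / sum(labels == 1)
}

# Small planted network + matching small model config for training tests.
small_planted <- function(seed = 1) {
  synth_hetnet(synth_config(n_G = 60, n_D = 30, n_O = 40, n_S = 20,
                            p_in = 0.5, p_out = 0.05, seed = seed))
}

small_config <- function(epochs = 30, val_fraction = 0, ...) {
  fghne_config(d_prime = 8, n_factors = 2, n_heads = 2, hidden_dim = 8,
               sem_dim = 8, epochs = epochs, patience = Inf,
               val_fraction = val_fraction, neighbor_limit = 25,
               seed = 1, ...)
}

# The scaled-down study configuration used for the planted benchmark
# (also used by scripts/acceptance.R).
benchmark_config <- function(seed, ...) {
  fghne_config(d_prime = 32, n_factors = 4, n_heads = 2, hidden_dim = 32,
               sem_dim = 32, epochs = 120, patience = 20, seed = seed, ...)
}
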