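#' Model and training configuration
#'
#' Collects every tunable of the embedding model and its optimizer.
#' Defaults follow the reference training setup: Adam with learning rate
#' 0.005 and L2 penalty weight 0.001, 100 sampled neighbours per node,
#' 16 factor graphs, 8 attention heads, hidden dimension 128.
#'
#' @param d_prime Common projected feature dimension (default 64).
#' @param n_factors Number of factor graphs per metapath (default 16).
#' @param n_heads Attention heads `K` (default 8).
#' @param hidden_dim Total attention output dimension per factor; split
#'   across heads as `d_head = hidden_dim / n_heads` (default 128).
#' @param sem_dim Semantic-attention summary dimension (default 128).
#' @param slope Negative slope of the attention logit nonlinearity.
#' @param use_elu Apply an ELU to each aggregated head output?
#' @param feature_mode `"onehot"` identity features (the default when the
#'   graph carries no feature matrices) or `"gaussian"` random features.
#' @param feature_dim Dimension of generated Gaussian features.
#' @param lr Adam learning rate (default 0.005).
#' @param l2 L2 penalty weight (default 0.001).
#' @param gamma Weight of the factor-discrimination loss in the joint
#'   objective (default 1; 0 disables factorization).
#' @param epochs Maximum training epochs (default 200).
#' @param patience Early-stopping patience on validation AUC (default 30;
#'   `Inf` disables early stopping).
#' @param val_fraction Fraction of training pairs carved out for
#'   validation (default 0.1; 0 disables validation).
#' @param neighbor_limit Neighbour budget per node (default 100).
#' @param seed Integer seed governing initialization, neighbourhood
#'   resampling and the validation carve-out.
#' @return A `fghne_config` list.
#' @export
fghne_config <- function(d_prime = 64, n_factors = 16, n_heads = 8,
                         hidden_dim = 128, sem_dim = 128, slope = 0.2,
                         use_elu = TRUE,
                         feature_mode = c("onehot", "gaussian"),
                         feature_dim = 64, lr = 0.005, l2 = 0.001,
                         gamma = 1, epochs = 200, patience = 30,
                         val_fraction = 0.1, neighbor_limit = 100,
                         seed = 1) {
  feature_mode <- match.arg(feature_mode)
  if (hidden_dim %% n_heads != 0) {
    stop("hidden_dim must be divisible by n_heads", call. = FALSE)
  }
  stopifnot(d_prime >= 1, n_factors >= 1, gamma >= 0, lr > 0, l2 >= 0,
            epochs >= 0, neighbor_limit >= 1,
            val_fraction >= 0, val_fraction < 1)
  cfg <- list(d_prime = d_prime, n_factors = n_factors, n_heads = n_heads,
              hidden_dim = hidden_dim, d_head = hidden_dim %/% n_heads,
              sem_dim = sem_dim, slope = slope, use_elu = use_elu,
              feature_mode = feature_mode, feature_dim = feature_dim,
              lr = lr, l2 = l2, gamma = gamma, epochs = epochs,
              patience = patience, val_fraction = val_fraction,
              neighbor_limit = neighbor_limit, seed = seed)
  class(cfg) <- "fghne_config"
  cfg
}

# Static per-run tensors: raw features, metapath adjacencies, id maps.
prepare_model_data <- function(g, metapaths, cfg) {
  mp_type <- vapply(metapaths, function(m) m$endpoint_type, character(1))
  types <- unique(mp_type)
  X <- list(); d_a <- integer()
  for (tp in NODE_TYPES) {
    n <- length(g$nodes[[tp]])
    if (!is.null(g$features) && !is.null(g$features[[tp]])) {
      X[[tp]] <- g$features[[tp]]
      d_a[[tp]] <- ncol(g$features[[tp]])
    } else if (cfg$feature_mode == "gaussian") {
      X[[tp]] <- with_seed(cfg$seed + match(tp, NODE_TYPES),
                           matrix(rnorm(n * cfg$feature_dim), n))
      d_a[[tp]] <- cfg$feature_dim
    } else {
      X[tp] <- list(NULL)           # identity (one-hot) features
      d_a[[tp]] <- n
    }
  }
  adj <- lapply(metapaths, function(m) {
    mg <- build_metapath_graph(g, m)
    unname(as.matrix(mg$adjacency) > 0)
  })
  list(metapaths = metapaths, mp_type = mp_type, types = types,
       X = X, d_a = d_a, nodes = g$nodes,
       n = vapply(g$nodes, length, integer(1)), adj = adj)
}

# Glorot-initialized nested parameter list for one model.
init_params <- function(data, cfg) {
  d <- cfg$d_prime; dh <- cfg$d_head
  dz <- cfg$n_factors * cfg$n_heads * dh
  with_seed(cfg$seed, {
    params <- list()
    params$proj <- lapply(data$d_a, function(da) glorot(d, da))
    params$scorer <- lapply(data$metapaths, function(m) {
      lapply(seq_len(cfg$n_factors), function(e) {
        list(a = drop(glorot(1, 2 * d)), b = 0)
      })
    })
    params$attn <- lapply(data$metapaths, function(m) {
      lapply(seq_len(cfg$n_factors), function(e) {
        lapply(seq_len(cfg$n_heads), function(k) {
          list(W = glorot(dh, d), a = drop(glorot(1, 2 * dh)))
        })
      })
    })
    params$sem <- setNames(lapply(data$types, function(tp) {
      list(W = glorot(cfg$sem_dim, dz), b = rep(0, cfg$sem_dim))
    }), data$types)
    params$Q <- drop(glorot(1, cfg$sem_dim))
    params$clf <- list(W = glorot(cfg$n_factors, d),
                       b = rep(0, cfg$n_factors))
    params
  })
}

zero_like <- function(params) rapply(params, function(x) x * 0,
                                     how = "replace")

# Per-epoch sampled neighbourhood masks for every metapath.
epoch_masks <- function(data, cfg, seed) {
  with_seed(seed, lapply(data$adj, function(a) {
    mask <- a
    deg <- rowSums(a)
    for (i in which(deg > cfg$neighbor_limit)) {
      keep <- sample(which(a[i, ]), cfg$neighbor_limit)
      mask[i, ] <- FALSE
      mask[i, keep] <- TRUE
    }
    diag(mask) <- TRUE
    mask
  }))
}

# Common-space features per endpoint type.
project_all <- function(params, data, types) {
  out <- list()
  for (tp in types) {
    out[[tp]] <- if (is.null(data$X[[tp]])) t(params$proj[[tp]])
    else data$X[[tp]] %*% t(params$proj[[tp]])
  }
  out
}
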