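#' Association score of a gene-disease pair
#'
#' The decoder is the sigmoid of the inner product of the two final
#' embeddings: `Score_gd = sigmoid(<H_g, H_d>)`.  Symmetric in its
#' arguments and strictly inside (0, 1).
#'
#' @param h_g Gene embedding vector, or matrix of embeddings (one row per
#'   pair).
#' @param h_d Disease embedding of equal dimension (vector or matrix).
#' @return Numeric score(s) in (0, 1).
#' @export
#' @examples
#' score_pair(c(1, 0), c(2, 0))   # sigmoid(2)
score_pair <- function(h_g, h_d) {
  if (is.matrix(h_g) || is.matrix(h_d)) {
    if (!is.matrix(h_g)) h_g <- matrix(h_g, nrow(h_d), length(h_g),
                                       byrow = TRUE)
    if (!is.matrix(h_d)) h_d <- matrix(h_d, nrow(h_g), length(h_d),
                                       byrow = TRUE)
    if (!all(dim(h_g) == dim(h_d))) stop("dimension mismatch",
                                         call. = FALSE)
    sigmoid(rowSums(h_g * h_d))
  } else {
    if (length(h_g) != length(h_d)) stop("dimension mismatch",
                                         call. = FALSE)
    sigmoid(sum(h_g * h_d))
  }
}

#' Link-prediction loss
#'
#' Binary cross-entropy over scored pairs:
#' `L_Pred = -sum_(pos) log(Score) - sum_(neg) log(1 - Score)`.
#' Scores are clamped to `[eps, 1 - eps]` before the logarithms.
#'
#' @param scores Numeric vector of pair scores in (0, 1).
#' @param labels 0/1 vector (1 = observed association).
#' @param reduction `"sum"` (the objective as written; default) or
#'   `"mean"`.
#' @param eps Clamping constant (default 1e-7).
#' @return Non-negative scalar.
#' @export
prediction_loss <- function(scores, labels, reduction = c("sum", "mean"),
                            eps = 1e-7) {
  reduction <- match.arg(reduction)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  p <- pmin(pmax(scores, eps), 1 - eps)
  ll <- -(labels * log(p) + (1 - labels) * log(1 - p))
  if (reduction == "sum") sum(ll) else mean(ll)
}

#' Joint training objective
#'
#' `Loss = L_Pred + gamma * L_Factor`: the link-prediction loss plus the
#' factor-discrimination loss scaled by `gamma`.  `gamma = 0` reduces the
#' objective to pure link prediction.
#'
#' @param l_pred Link-prediction loss.
#' @param l_factor Factor-discrimination loss.
#' @param gamma Non-negative factorization weight.
#' @return Scalar.
#' @export
total_loss <- function(l_pred, l_factor, gamma = 1) {
  stopifnot(gamma >= 0)
  l_pred + gamma * l_factor
}

# Full forward pass + joint loss + (optionally) analytic gradients of
# every parameter.  `pairs` is a list(g_idx, d_idx, y) of training pairs
# indexed into the dense G / D node orders.  The objective is the summed
# binary cross-entropy over pairs plus gamma times the (mean) factor
# loss; the L2 penalty is applied inside the optimizer.
loss_and_grads <- function(params, data, cfg, masks, pairs,
                           need_grads = TRUE) {
  d <- cfg$d_prime
  nF <- cfg$n_factors; nK <- cfg$n_heads; dh <- cfg$d_head
  mps <- names(data$metapaths)
  Hp <- project_all(params, data, data$types)

  ## ---- intra-metapath attention over every factor graph ----
  Z <- fwd <- list()
  for (m in mps) {
    fwd[[m]] <- dense_metapath_forward(
      Hp[[data$mp_type[[m]]]], masks[[m]],
      params$scorer[[m]], params$attn[[m]],
      cfg$slope, cfg$use_elu, cache = TRUE)
    Z[[m]] <- fwd[[m]]$Z
  }

  ## ---- semantic attention per node type ----
  H <- list(); semc <- list()
  for (tp in data$types) {
    ms <- mps[data$mp_type[mps] == tp]
    W <- params$sem[[tp]]$W; b <- params$sem[[tp]]$b
    U <- lapply(ms, function(m) {
      tanh(Z[[m]] %*% t(W) + matrix(b, nrow(Z[[m]]), length(b),
                                    byrow = TRUE))
    })
    names(U) <- ms
    P <- vapply(U, colMeans, numeric(cfg$sem_dim))
    wv <- drop(params$Q %*% P)
    omega <- exp(wv - max(wv)); omega <- omega / sum(omega)
    H[[tp]] <- Reduce(`+`, Map(`*`, Z[ms], as.list(omega)))
    semc[[tp]] <- list(ms = ms, U = U, P = P, omega = omega)
  }

  ## ---- link-prediction loss ----
  np <- length(pairs$y)
  if (np > 0) {
    dot <- rowSums(H$G[pairs$g_idx, , drop = FALSE] *
                     H$D[pairs$d_idx, , drop = FALSE])
    p <- sigmoid(dot)
    l_pred_mean <- prediction_loss(p, pairs$y, "mean")
  } else {
    p <- numeric(0)
    l_pred_mean <- 0
  }
  l_pred_sum <- l_pred_mean * np

  ## ---- factor-discrimination loss ----
  enc <- NULL; encc <- list()
  for (m in mps) {
    tp <- data$mp_type[[m]]
    A <- data$adj[[m]]
    hp <- Hp[[tp]]
    encc[[m]] <- vector("list", nF)
    for (e in seq_len(nF)) {
      Wm <- fwd[[m]]$caches[[e]]$Wfull * A
      denom <- 1 + rowSums(Wm)
      Mfeat <- (hp + Wm %*% hp) / denom
      r <- colMeans(Mfeat)
      encc[[m]][[e]] <- list(Wm = Wm, denom = denom, Mfeat = Mfeat)
      enc <- rbind(enc, r)
    }
  }
  labels <- rep(seq_len(nF), times = length(mps))
  logits <- enc %*% t(params$clf$W) +
    matrix(params$clf$b, nrow(enc), nF, byrow = TRUE)
  prob <- softmax_rows(logits)
  l_factor <- factor_discriminant_loss(prob, labels)

  total <- total_loss(l_pred_sum, l_factor, cfg$gamma)
  out <- list(loss = total, l_pred = l_pred_sum, l_pred_mean = l_pred_mean,
              l_factor = l_factor, H = H, scores = p, omega =
                lapply(semc, function(s) setNames(s$omega, s$ms)))
  if (!need_grads) return(out)

  ## ================= backward pass =================
  gr <- zero_like(params)

  # link loss -> final embeddings
  dzdim <- ncol(Z[[1]])
  dH <- lapply(data$types, function(tp) matrix(0, data$n[[tp]], dzdim))
  names(dH) <- data$types
  if (np > 0) {
    coef <- p - pairs$y
    aggG <- rowsum(coef * H$D[pairs$d_idx, , drop = FALSE], pairs$g_idx)
    dH$G[as.integer(rownames(aggG)), ] <- aggG
    aggD <- rowsum(coef * H$G[pairs$g_idx, , drop = FALSE], pairs$d_idx)
    dH$D[as.integer(rownames(aggD)), ] <- aggD
  }

  # semantic attention backward -> per-metapath dZ, sem/Q grads
  dZ <- list()
  for (tp in data$types) {
    sc <- semc[[tp]]
    W <- params$sem[[tp]]$W
    n <- data$n[[tp]]
    domega <- vapply(sc$ms, function(m) sum(dH[[tp]] * Z[[m]]),
                     numeric(1))
    dwv <- sc$omega * (domega - sum(sc$omega * domega))
    gr$Q <- gr$Q + drop(sc$P %*% dwv)
    for (idx in seq_along(sc$ms)) {
      m <- sc$ms[[idx]]
      dZ[[m]] <- sc$omega[[idx]] * dH[[tp]]
      dP <- dwv[[idx]] * params$Q
      dpre <- matrix(dP / n, n, cfg$sem_dim, byrow = TRUE) *
        (1 - sc$U[[m]]^2)
      dZ[[m]] <- dZ[[m]] + dpre %*% W
      gr$sem[[tp]]$W <- gr$sem[[tp]]$W + crossprod(dpre, Z[[m]])
      gr$sem[[tp]]$b <- gr$sem[[tp]]$b + colSums(dpre)
    }
  }

  # factor loss backward -> classifier, edge weights, features
  nsamp <- nrow(prob)
  dlogits <- prob
  dlogits[cbind(seq_len(nsamp), labels)] <-
    dlogits[cbind(seq_len(nsamp), labels)] - 1
  dlogits <- cfg$gamma * dlogits / nsamp
  gr$clf$W <- gr$clf$W + crossprod(dlogits, enc)
  gr$clf$b <- gr$clf$b + colSums(dlogits)
  dr_all <- dlogits %*% params$clf$W

  dHp <- lapply(data$types, function(tp)
    matrix(0, data$n[[tp]], d))
  names(dHp) <- data$types
  dWfull <- list()
  row_i <- 0
  for (m in mps) {
    tp <- data$mp_type[[m]]
    hp <- Hp[[tp]]
    n <- data$n[[tp]]
    A <- data$adj[[m]]
    dWfull[[m]] <- vector("list", nF)
    for (e in seq_len(nF)) {
      row_i <- row_i + 1
      ec <- encc[[m]][[e]]
      dMfeat <- matrix(dr_all[row_i, ] / n, n, d, byrow = TRUE)
      dnum <- dMfeat / ec$denom
      dHp[[tp]] <- dHp[[tp]] + dnum + crossprod(ec$Wm, dnum)
      dWm <- (dnum %*% t(hp)) * A
      ddenom <- -rowSums(dMfeat * ec$Mfeat) / ec$denom
      dWm <- dWm + ddenom * A
      dWfull[[m]][[e]] <- dWm
    }
  }

  # attention backward per metapath: heads, scorers, features
  for (m in mps) {
    tp <- data$mp_type[[m]]
    hp <- Hp[[tp]]
    n <- data$n[[tp]]
    nb <- masks[[m]]
    offdiag <- nb; diag(offdiag) <- FALSE
    for (e in seq_len(nF)) {
      ec <- fwd[[m]]$caches[[e]]
      dWf <- dWfull[[m]][[e]]
      for (k in seq_len(nK)) {
        hd <- params$attn[[m]][[e]][[k]]
        hc <- ec$heads[[k]]
        cols <- ((e - 1) * nK + (k - 1)) * dh + seq_len(dh)
        dZek <- dZ[[m]][, cols, drop = FALSE]
        dS <- if (cfg$use_elu) {
          ds <- exp(pmin(hc$S, 0))   # elu'(s) = 1 for s > 0, exp(s) below
          dZek * ds
        } else dZek
        dA <- dS %*% t(hc$T_)
        dT <- crossprod(hc$A, dS)
        rs <- rowSums(hc$A * dA)
        dL <- hc$A * (dA - rs)
        dCact <- dL * ((hc$C > 0) + cfg$slope * (hc$C <= 0))
        df <- rowSums(dCact); dg <- colSums(dCact)
        a1 <- hd$a[seq_len(dh)]; a2 <- hd$a[dh + seq_len(dh)]
        gr$attn[[m]][[e]][[k]]$a <- gr$attn[[m]][[e]][[k]]$a +
          c(drop(crossprod(hc$T_, df)), drop(crossprod(hc$T_, dg)))
        dT <- dT + outer(df, a1) + outer(dg, a2)
        gr$attn[[m]][[e]][[k]]$W <- gr$attn[[m]][[e]][[k]]$W +
          crossprod(dT, hp)
        dHp[[tp]] <- dHp[[tp]] + dT %*% hd$W
        # log-weight shift: gradient into the factor edge weights
        dWf[offdiag] <- dWf[offdiag] + dL[offdiag] / ec$Wfull[offdiag]
      }
      # scorer backward through W_e = sigmoid((q_i + q_j)/2 + b)
      G <- dWf * ec$Wfull * (1 - ec$Wfull)
      dq <- (rowSums(G) + colSums(G)) / 2
      gr$scorer[[m]][[e]]$b <- gr$scorer[[m]][[e]]$b + sum(G)
      asum <- drop(crossprod(hp, dq))
      gr$scorer[[m]][[e]]$a <- gr$scorer[[m]][[e]]$a + c(asum, asum)
      sc <- params$scorer[[m]][[e]]
      dHp[[tp]] <- dHp[[tp]] +
        outer(dq, sc$a[seq_len(d)] + sc$a[d + seq_len(d)])
    }
  }

  # projection backward
  for (tp in data$types) {
    gr$proj[[tp]] <- gr$proj[[tp]] +
      if (is.null(data$X[[tp]])) t(dHp[[tp]])
    else crossprod(dHp[[tp]], data$X[[tp]])
  }

  out$grads <- gr
  out
}

adam_step <- function(theta, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  state$theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  state
}

# Dense (g_idx, d_idx, y) triplets for a set of pos/neg pair tables.
pair_indices <- function(g, pos, neg) {
  list(g_idx = unname(g$index$G[c(pos$gene, neg$gene)]),
       d_idx = unname(g$index$D[c(pos$disease, neg$disease)]),
       y = c(rep(1, nrow(pos)), rep(0, nrow(neg))))
}

#' Train the factor-graph embedding model end-to-end
#'
#' Builds the training graph (test positives removed so metapath graphs
#' cannot leak held-out edges), initializes all parameters, and runs
#' full-batch Adam on the joint objective `L_Pred + gamma * L_Factor`
#' with an L2 penalty.  Neighbourhoods are resampled every epoch under a
#' seed derived from the configuration seed, so runs are bit-reproducible.
#' When `val_fraction > 0`, a slice of the training pairs is carved out
#' for validation and the parameters with the best validation AUC are
#' kept (early stopping after `patience` stagnant epochs).
#'
#' @param g A [hetero_graph()].
#' @param split An [make_split()] result for `g`.
#' @param cfg A [fghne_config()].
#' @param metapaths Metapath registry (default [default_metapaths()]).
#' @param verbose Print per-epoch losses?
#' @return An object of class `fghne`: trained parameters, final node
#'   embeddings `H` (per type), the per-epoch `trace` data frame (columns
#'   `epoch`, `l_pred`, `l_factor`, `loss`, `val_auc`), and bookkeeping
#'   (config, id maps, training positives).
#' @export
fghne_train <- function(g, split, cfg = fghne_config(),
                        metapaths = default_metapaths(),
                        verbose = FALSE) {
  stopifnot(inherits(g, "hetero_graph"), inherits(split, "edge_split"),
            inherits(cfg, "fghne_config"))
  tg <- train_graph(g, split)
  data <- prepare_model_data(tg, metapaths, cfg)
  params <- init_params(data, cfg)

  # validation carve-out from the training pairs
  tr_pos <- split$train_pos; tr_neg <- split$train_neg
  val <- NULL
  if (cfg$val_fraction > 0) {
    with_seed(cfg$seed + 211L, {
      vp <- sample.int(nrow(tr_pos),
                       max(1, round(cfg$val_fraction * nrow(tr_pos))))
      vn <- sample.int(nrow(tr_neg),
                       max(1, round(cfg$val_fraction * nrow(tr_neg))))
    })
    val <- pair_indices(tg, tr_pos[vp, , drop = FALSE],
                        tr_neg[vn, , drop = FALSE])
    tr_pos <- tr_pos[-vp, , drop = FALSE]
    tr_neg <- tr_neg[-vn, , drop = FALSE]
  }
  pairs <- pair_indices(tg, tr_pos, tr_neg)

  theta <- unlist(params)
  state <- list(m = theta * 0, v = theta * 0, theta = theta)
  trace <- data.frame(epoch = integer(), l_pred = numeric(),
                      l_factor = numeric(), loss = numeric(),
                      val_auc = numeric())
  best <- list(auc = -Inf, theta = theta, epoch = 0L)
  stale <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    eseed <- as.integer((as.numeric(cfg$seed) * 1009 + epoch) %%
                          2147483647)
    masks <- epoch_masks(data, cfg, eseed)
    res <- loss_and_grads(params, data, cfg, masks, pairs)
    if (!is.finite(res$loss)) {
      stop("training diverged at epoch ", epoch, " (loss = ", res$loss,
           "); lower the learning rate", call. = FALSE)
    }
    gflat <- unlist(res$grads) + cfg$l2 * state$theta
    state <- adam_step(state$theta, gflat, state, cfg$lr, epoch)
    params <- utils::relist(state$theta, params)

    val_auc <- NA_real_
    if (!is.null(val)) {
      vs <- sigmoid(rowSums(res$H$G[val$g_idx, , drop = FALSE] *
                              res$H$D[val$d_idx, , drop = FALSE]))
      val_auc <- auc_score(vs, val$y)
      if (val_auc > best$auc + 1e-12) {
        best <- list(auc = val_auc, theta = state$theta, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
    trace <- rbind(trace, data.frame(epoch = epoch, l_pred = res$l_pred,
                                     l_factor = res$l_factor,
                                     loss = res$loss, val_auc = val_auc))
    if (verbose) {
      message(sprintf(
        "epoch %3d  L_pred %.4f  L_factor %.4f  loss %.4f  val AUC %s",
        epoch, res$l_pred, res$l_factor, res$loss,
        ifelse(is.na(val_auc), "-", sprintf("%.4f", val_auc))))
    }
    if (!is.null(val) && is.finite(cfg$patience) && stale >= cfg$patience)
      break
  }

  if (!is.null(val) && best$epoch > 0) {
    params <- utils::relist(best$theta, params)
  }
  # deterministic final forward for the stored embeddings
  masks <- epoch_masks(data, cfg, cfg$seed)
  final <- loss_and_grads(params, data, cfg, masks,
                          pair_indices(tg, split$train_pos,
                                       split$train_neg),
                          need_grads = FALSE)
  structure(
    list(config = cfg, metapaths = metapaths, params = params,
         nodes = tg$nodes, index = tg$index, H = final$H,
         omega = final$omega, trace = trace, best_epoch = best$epoch,
         train_pos = split$train_pos),
    class = "fghne"
  )
}

#' @export
print.fghne <- function(x, ...) {
  cat("<fghne> trained model:", nrow(x$trace), "epochs,",
      length(x$nodes$G), "genes,", length(x$nodes$D), "diseases\n")
  if (nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final loss %.4f (L_pred %.4f, L_factor %.4f)\n",
                last$loss, last$l_pred, last$l_factor))
  }
  invisible(x)
}

#' Final node embeddings of a trained model
#'
#' @param model A trained [fghne_train()] model.
#' @param type Node type (`"G"` or `"D"`).
#' @return Matrix of embeddings with node identifiers as row names.
#' @export
fghne_embeddings <- function(model, type = c("G", "D")) {
  type <- match.arg(type)
  H <- model$H[[type]]
  rownames(H) <- model$nodes[[type]]
  H
}

#' Score gene-disease pairs with a trained model
#'
#' @param model A trained [fghne_train()] model.
#' @param pairs Data frame with columns `gene`, `disease`.
#' @return Numeric vector of association scores in (0, 1).
#' @export
predict_scores <- function(model, pairs) {
  gi <- model$index$G[as.character(pairs$gene)]
  di <- model$index$D[as.character(pairs$disease)]
  if (anyNA(gi) || anyNA(di)) {
    stop("unknown gene/disease identifiers in `pairs`", call. = FALSE)
  }
  sigmoid(rowSums(model$H$G[gi, , drop = FALSE] *
                    model$H$D[di, , drop = FALSE]))
}
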