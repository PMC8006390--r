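test_that("the inner-product decoder matches its closed forms and is
           symmetric", {
  expect_equal(score_pair(c(1, 0), c(0, 1)), 0.5)      # orthogonal
  expect_equal(score_pair(c(1, 0), c(2, 0)), 1 / (1 + exp(-2)))
  expect_equal(score_pair(c(1, 0), c(2, 0)), 0.8808, tolerance = 1e-4)
  expect_gt(score_pair(c(3, 1), 1e4 * c(3, 1)), 1 - 1e-12)  # c -> Inf
  set.seed(1)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(score_pair(a, b), score_pair(b, a))
  expect_error(score_pair(c(1, 2), c(1, 2, 3)), "dimension")
  # matrix form scores row-wise
  expect_equal(score_pair(rbind(a, a), rbind(b, b)),
               rep(score_pair(a, b), 2), ignore_attr = TRUE)
})

test_that("the link loss matches its closed forms and clamps extremes", {
  # P positives and Q negatives all scored 0.5 -> (P + Q) ln 2
  scores <- rep(0.5, 7); labels <- c(rep(1, 3), rep(0, 4))
  expect_equal(prediction_loss(scores, labels), 7 * log(2))
  expect_equal(prediction_loss(scores, labels, "mean"), log(2))
  # perfect fit -> loss near 0
  expect_lt(prediction_loss(c(1 - 1e-9, 1e-9), c(1, 0)), 1e-5)
  # hand evaluation: one positive at 0.9, one negative at 0.2
  expect_equal(prediction_loss(c(0.9, 0.2), c(1, 0)),
               -log(0.9) - log(0.8))
  expect_equal(-log(0.9) - log(0.8), 0.3285, tolerance = 1e-4)
  # scores of exactly 0 or 1 stay finite through clamping
  expect_true(is.finite(prediction_loss(c(0, 1), c(1, 0))))
})

test_that("the joint objective is the exact weighted sum", {
  expect_equal(total_loss(2, 3, gamma = 0), 2)      # weight annihilation
  expect_equal(total_loss(2, 3, gamma = 1), 5)
  gammas <- seq(0, 2, by = 0.5)
  losses <- vapply(gammas, function(gm) total_loss(1.5, 0.7, gm),
                   numeric(1))
  expect_true(all(diff(losses) > 0))                # monotone in gamma
  expect_error(total_loss(1, 1, gamma = -1))
})

test_that("analytic gradients of the full joint objective agree with
           finite differences", {
  net <- synth_hetnet(synth_config(n_G = 14, n_D = 8, n_O = 8, n_S = 5,
                                   p_in = 0.5, p_out = 0.1, seed = 6))
  split <- make_split(net$graph, 0.25, 1, seed = 6)
  cfg <- small_config()
  tg <- train_graph(net$graph, split)
  data <- fghne:::prepare_model_data(tg, default_metapaths(), cfg)
  params <- fghne:::init_params(data, cfg)
  masks <- fghne:::epoch_masks(data, cfg, 31)
  pairs <- fghne:::pair_indices(tg, split$train_pos, split$train_neg)
  res <- fghne:::loss_and_grads(params, data, cfg, masks, pairs)
  theta <- unlist(params); gan <- unlist(res$grads)
  f <- function(th) fghne:::loss_and_grads(
    utils::relist(th, params), data, cfg, masks, pairs,
    need_grads = FALSE)$loss
  set.seed(2)
  idx <- sample(length(theta), 50)
  eps <- 1e-5
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + eps; fp <- f(tp)
    tp[i] <- tp[i] - 2 * eps; fm <- f(tp)
    gnum <- (fp - fm) / (2 * eps)
    expect_equal(gan[[i]], gnum, tolerance = 1e-3,
                 label = paste("d loss /", names(theta)[i]))
  }
})

test_that("training runs are reproducible, decrease the loss, and respect
           the epoch budget", {
  net <- small_planted(seed = 3)
  split <- make_split(net$graph, 0.2, 1, seed = 3)

  # 0 epochs: initialized model, empty trace
  m0 <- fghne_train(net$graph, split, small_config(epochs = 0))
  expect_equal(nrow(m0$trace), 0L)
  expect_true(is.matrix(m0$H$G))

  # training decreases the joint objective by >= 50% within 200 epochs
  cfg <- fghne_config(d_prime = 16, n_factors = 2, n_heads = 2,
                      hidden_dim = 16, sem_dim = 8, epochs = 200,
                      patience = Inf, val_fraction = 0,
                      neighbor_limit = 25, seed = 1)
  m <- fghne_train(net$graph, split, cfg)
  expect_equal(nrow(m$trace), 200L)
  expect_lt(m$trace$loss[200], m$trace$loss[1])
  expect_lt(m$trace$loss[200], 0.5 * m$trace$loss[1])
  expect_true(all(is.finite(m$trace$loss)))

  # bit-reproducible under identical config + seed
  cfg5 <- small_config(epochs = 5)
  m1 <- fghne_train(net$graph, split, cfg5)
  m2 <- fghne_train(net$graph, split, cfg5)
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$H, m2$H)

  # semantic attention weights are normalized per node type
  for (om in m$omega) expect_equal(sum(om), 1, tolerance = 1e-9)
})

test_that("ranking metrics match brute-force enumeration on small
           pools", {
  # printed pool: 0.9/+, 0.8/-, 0.7/+, 0.1/-
  sc <- c(0.9, 0.8, 0.7, 0.1); lb <- c(1, 0, 1, 0)
  expect_equal(auc_score(sc, lb), 0.75)
  expect_equal(precision_at_k(sc, lb, 2), 0.5)

  # perfect separation
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(precision_at_k(c(0.9, 0.8, 0.2), c(1, 1, 0), 2), 1)

  # all scores tied -> AUC 0.5 under tie averaging
  expect_equal(auc_score(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)

  # random pools against the oracles, exactly
  set.seed(8)
  for (trial in 1:30) {
    n <- sample(4:20, 1)
    sc <- round(runif(n), 2)           # force occasional ties
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) == 0 || sum(lb) == n) next
    expect_equal(auc_score(sc, lb), brute_auc(sc, lb), tolerance = 1e-12)
    expect_equal(average_precision(sc, lb), brute_ap(sc, lb),
                 tolerance = 1e-12)
    k <- sample(n, 1)
    expect_equal(precision_at_k(sc, lb, k), brute_p_at_k(sc, lb, k))
    expect_equal(recall_at_k(sc, lb, k), brute_r_at_k(sc, lb, k))
  }

  # K beyond the pool size truncates with a warning
  expect_warning(p <- precision_at_k(c(0.9, 0.1), c(1, 0), 5),
                 "truncated")
  expect_equal(p, 0.5)
})

test_that("model evaluation reports all metrics on the held-out pool", {
  net <- small_planted(seed = 4)
  split <- make_split(net$graph, 0.2, 1, seed = 4)
  m <- fghne_train(net$graph, split, small_config(epochs = 15))
  rep <- suppressWarnings(evaluate_model(m, split, k_list = c(5, 1e6)))
  expect_true(all(c(rep$ap, rep$auc, rep$precision_at, rep$recall_at) >= 0))
  expect_true(all(c(rep$ap, rep$auc, rep$precision_at, rep$recall_at) <= 1))
  expect_equal(nrow(rep$scores),
               nrow(split$test_pos) + nrow(split$test_neg))
  # recall at the full pool size is 1 by definition
  expect_equal(unname(rep$recall_at[2]), 1)
})

test_that("candidate ranking follows the decoder with stable ties and
           known-association exclusion", {
  net <- small_planted(seed = 5)
  split <- make_split(net$graph, 0.2, 1, seed = 5)
  m <- fghne_train(net$graph, split, small_config(epochs = 5))
  d <- net$graph$nodes$D[1]

  top <- rank_candidates(m, d, top_k = 20, exclude_known = FALSE)
  expect_equal(nrow(top), 20L)
  expect_equal(top$rank, 1:20)
  expect_true(all(diff(top$score) <= 0))

  # excluded genes are exactly the training-known associations
  known <- split$train_pos$gene[split$train_pos$disease == d]
  top_ex <- rank_candidates(m, d, top_k = 1e6, exclude_known = TRUE)
  expect_length(intersect(top_ex$gene, known), 0)
  expect_equal(nrow(top_ex), length(net$graph$nodes$G) - length(known))

  # ties: duplicate embeddings rank adjacently in gene-index order
  m2 <- m
  m2$H$G[2, ] <- m2$H$G[1, ]
  all_rank <- rank_candidates(m2, d, top_k = 1e6, exclude_known = FALSE)
  pos <- match(m2$nodes$G[1:2], all_rank$gene)
  expect_equal(pos[2], pos[1] + 1)

  expect_error(rank_candidates(m, "nonexistent-disease"), "unknown")
})
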