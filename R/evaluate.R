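#' Ranking metrics for scored pairs
#'
#' `auc_score` is the area under the ROC curve computed from the
#' tie-averaged rank statistic (equivalent to the Wilcoxon/Mann-Whitney
#' estimator; all scores identical gives 0.5).  `average_precision` is
#' the area under the precision-recall curve by stepwise summation over
#' the ranked list: `AP = sum_k (R_k - R_{k-1}) P_k`.  `precision_at_k`
#' and `recall_at_k` threshold at the K-th largest score: the fraction of
#' positives among the top-K scores, and the fraction of all positives
#' recovered in the top K.  Ties are broken by stable (input) order.
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels 0/1 vector of true labels.
#' @param k Cut-off rank.
#' @return A scalar in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("AUC needs both positive and negative pairs", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' @rdname auc_score
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0) stop("AP needs at least one positive", call. = FALSE)
  ord <- order(-scores)            # stable: ties keep input order
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab == 1]) / npos
}

#' @rdname auc_score
#' @export
precision_at_k <- function(scores, labels, k) {
  k <- check_k(k, length(scores))
  ord <- order(-scores)
  sum(labels[ord][seq_len(k)]) / k
}

#' @rdname auc_score
#' @export
recall_at_k <- function(scores, labels, k) {
  k <- check_k(k, length(scores))
  npos <- sum(labels == 1)
  if (npos == 0) stop("recall needs at least one positive", call. = FALSE)
  ord <- order(-scores)
  sum(labels[ord][seq_len(k)]) / npos
}

check_k <- function(k, n) {
  stopifnot(k >= 1)
  if (k > n) {
    warning("K = ", k, " exceeds the pool size (", n, "); truncated",
            call. = FALSE)
    k <- n
  }
  as.integer(k)
}

#' Evaluate a trained model on the held-out test pairs
#'
#' Scores the split's test positives and negatives with the decoder and
#' reports AP, AUC, and precision/recall at each requested cut-off.
#'
#' @param model A trained [fghne_train()] model.
#' @param split The [make_split()] used for training.
#' @param k_list Cut-offs for precision/recall at K (default
#'   `c(1000, 10000, 20000)`, truncated with a warning when larger than
#'   the pool).
#' @return An object of class `eval_report`: list with `ap`, `auc`,
#'   `precision_at`, `recall_at` and the per-pair `scores` data frame
#'   (gene, disease, score, label).
#' @export
evaluate_model <- function(model, split, k_list = c(1000, 10000, 20000)) {
  stopifnot(inherits(model, "fghne"), inherits(split, "edge_split"))
  if (nrow(split$test_pos) == 0 || nrow(split$test_neg) == 0) {
    stop("test positives and negatives must be non-empty", call. = FALSE)
  }
  pairs <- rbind(split$test_pos, split$test_neg)
  labels <- c(rep(1, nrow(split$test_pos)), rep(0, nrow(split$test_neg)))
  scores <- predict_scores(model, pairs)
  structure(
    list(ap = average_precision(scores, labels),
         auc = auc_score(scores, labels),
         precision_at = setNames(
           vapply(k_list, function(k)
             suppressWarnings(precision_at_k(scores, labels, k)),
             numeric(1)), k_list),
         recall_at = setNames(
           vapply(k_list, function(k)
             suppressWarnings(recall_at_k(scores, labels, k)),
             numeric(1)), k_list),
         scores = data.frame(gene = pairs$gene, disease = pairs$disease,
                             score = scores, label = labels,
                             stringsAsFactors = FALSE)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report>  AP %.4f   AUC %.4f\n", x$ap, x$auc))
  for (k in names(x$precision_at)) {
    cat(sprintf("  P@%s %.4f   R@%s %.4f\n", k, x$precision_at[[k]],
                k, x$recall_at[[k]]))
  }
  invisible(x)
}

#' ROC and precision-recall curve points
#'
#' @param scores,labels As in [auc_score()].
#' @return Data frame with columns `threshold`, `fpr`, `tpr`,
#'   `precision`, `recall` (one row per distinct score threshold).
#' @export
curve_points <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  keep <- !duplicated(sc, fromLast = TRUE)
  data.frame(threshold = sc[keep],
             fpr = fp[keep] / max(1, sum(lab == 0)),
             tpr = tp[keep] / max(1, sum(lab == 1)),
             precision = tp[keep] / (tp[keep] + fp[keep]),
             recall = tp[keep] / max(1, sum(lab == 1)))
}

#' Rank candidate genes for a disease
#'
#' Scores every gene in the model against the query disease with the
#' inner-product decoder, sorts descending (ties broken by gene index,
#' stable), optionally removes genes whose association with the disease
#' was already known during training, and returns the top of the list.
#'
#' @param model A trained [fghne_train()] model.
#' @param disease Disease identifier.
#' @param top_k Number of candidates to return (default 20); larger than
#'   the gene count returns the full ranking.
#' @param exclude_known Drop training-known associations first (default
#'   `TRUE`)?
#' @return Data frame with columns `rank`, `gene`, `score`.
#' @export
rank_candidates <- function(model, disease, top_k = 20,
                            exclude_known = TRUE) {
  stopifnot(inherits(model, "fghne"))
  di <- model$index$D[as.character(disease)]
  if (is.na(di)) {
    near <- utils::head(model$nodes$D, 5)
    stop("unknown disease '", disease, "'; known ids start: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  scores <- sigmoid(drop(model$H$G %*% model$H$D[di, ]))
  genes <- model$nodes$G
  if (exclude_known) {
    known <- model$train_pos$gene[model$train_pos$disease ==
                                    as.character(disease)]
    keep <- !genes %in% known
    genes <- genes[keep]; scores <- scores[keep]
  }
  ord <- order(-scores, seq_along(scores))
  n_out <- min(top_k, length(genes))
  out <- data.frame(rank = seq_len(n_out), gene = genes[ord][seq_len(n_out)],
                    score = scores[ord][seq_len(n_out)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
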