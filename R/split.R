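#' Train/test split of gene-disease edges with negative sampling
#'
#' Partitions the deduplicated gene-disease positive edges uniformly at
#' random into train and test sets, and draws negative gene-disease pairs
#' uniformly from the non-edges of the *original* (pre-split) positive set,
#' so that no negative pair is a true association.  Train and test
#' negatives are disjoint.
#'
#' @param g A [hetero_graph()] containing `G-D` edges.
#' @param test_fraction Fraction of positives held out for testing
#'   (default 0.2).
#' @param neg_ratio Negatives per positive in each partition (default 1,
#'   i.e. a balanced pool).
#' @param seed Integer seed for the partition and the negative draws.
#' @return An object of class `edge_split`: a list of data frames
#'   `train_pos`, `train_neg`, `test_pos`, `test_neg`, each with columns
#'   `gene`, `disease`, plus the call's parameters.
#' @export
make_split <- function(g, test_fraction = 0.2, neg_ratio = 1, seed = 1) {
  stopifnot(inherits(g, "hetero_graph"),
            test_fraction > 0, test_fraction < 1, neg_ratio > 0)
  pos <- g$edges[g$edges$relation == "G-D", c("src", "dst")]
  names(pos) <- c("gene", "disease")
  n_pos <- nrow(pos)
  if (n_pos < 2) stop("need at least 2 G-D edges to split", call. = FALSE)
  n_g <- length(g$nodes$G); n_d <- length(g$nodes$D)

  n_test <- round(test_fraction * n_pos)
  n_test <- max(1L, min(n_pos - 1L, n_test))
  n_train <- n_pos - n_test
  n_neg <- round(neg_ratio * c(train = n_train, test = n_test))

  pos_key <- (g$index$G[pos$gene] - 1) * n_d + g$index$D[pos$disease]
  n_nonedge <- as.double(n_g) * n_d - n_pos
  if (sum(n_neg) > n_nonedge) {
    stop("cannot draw ", sum(n_neg), " negatives: only ", n_nonedge,
         " gene-disease non-edges exist", call. = FALSE)
  }

  with_seed(seed, {
    perm <- sample.int(n_pos)
    test_idx <- perm[seq_len(n_test)]

    # rejection-sample distinct non-edges, uniform over the complement
    want <- sum(n_neg)
    neg_key <- numeric(0)
    tries <- 0
    while (length(neg_key) < want) {
      tries <- tries + 1
      if (tries > 100) stop("negative sampling failed to converge",
                            call. = FALSE)
      batch <- (sample.int(n_g, 2 * want + 20, replace = TRUE) - 1) * n_d +
        sample.int(n_d, 2 * want + 20, replace = TRUE)
      batch <- setdiff(batch, pos_key)
      neg_key <- unique(c(neg_key, batch))
    }
    neg_key <- neg_key[seq_len(want)]
  })

  neg <- data.frame(
    gene    = g$nodes$G[(neg_key - 1) %/% n_d + 1],
    disease = g$nodes$D[(neg_key - 1) %% n_d + 1],
    stringsAsFactors = FALSE
  )
  train_neg <- neg[seq_len(n_neg[["train"]]), , drop = FALSE]
  test_neg <- neg[n_neg[["train"]] + seq_len(n_neg[["test"]]), ,
                  drop = FALSE]
  rownames(train_neg) <- rownames(test_neg) <- NULL

  structure(
    list(
      train_pos = pos[-test_idx, , drop = FALSE],
      train_neg = train_neg,
      test_pos  = pos[test_idx, , drop = FALSE],
      test_neg  = test_neg,
      test_fraction = test_fraction, neg_ratio = neg_ratio, seed = seed
    ),
    class = "edge_split"
  )
}

#' @export
print.edge_split <- function(x, ...) {
  cat("<edge_split> train:", nrow(x$train_pos), "pos /",
      nrow(x$train_neg), "neg;  test:", nrow(x$test_pos), "pos /",
      nrow(x$test_neg), "neg\n")
  invisible(x)
}

#' Write / read an edge split as four TSV files
#'
#' Serializes the split as `train_pos.tsv`, `train_neg.tsv`,
#' `test_pos.tsv`, `test_neg.tsv` for exact re-runs.
#'
#' @param split An [make_split()] result.
#' @param dir Directory to write to / read from.
#' @return `write_split` invisibly returns the file paths; `read_split`
#'   returns an `edge_split`.
#' @export
write_split <- function(split, dir) {
  stopifnot(inherits(split, "edge_split"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- c("train_pos", "train_neg", "test_pos", "test_neg")
  paths <- setNames(file.path(dir, paste0(parts, ".tsv")), parts)
  for (p in parts) {
    write.table(split[[p]], paths[[p]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_split
#' @export
read_split <- function(dir) {
  parts <- c("train_pos", "train_neg", "test_pos", "test_neg")
  out <- lapply(parts, function(p) {
    path <- file.path(dir, paste0(p, ".tsv"))
    if (!file.exists(path)) stop("missing split file: ", path,
                                 call. = FALSE)
    read.delim(path, colClasses = "character")
  })
  names(out) <- parts
  structure(out, class = "edge_split")
}

#' Training graph with held-out test edges removed
#'
#' Removes the split's test positives from the gene-disease edges so that
#' metapath graphs built for training cannot traverse held-out
#' associations (no test leakage through GDG/DGD instances).
#'
#' @param g A [hetero_graph()].
#' @param split An [make_split()] result.
#' @return A new [hetero_graph()] with the same node universe.
#' @export
train_graph <- function(g, split) {
  stopifnot(inherits(g, "hetero_graph"), inherits(split, "edge_split"))
  gd <- g$edges$relation == "G-D"
  key <- paste(g$edges$src, g$edges$dst, sep = "\r")
  drop <- gd & key %in% paste(split$test_pos$gene, split$test_pos$disease,
                              sep = "\r")
  nodes <- data.frame(
    id = unlist(g$nodes, use.names = FALSE),
    type = rep(names(g$nodes), vapply(g$nodes, length, integer(1))),
    stringsAsFactors = FALSE
  )
  hetero_graph(g$edges[!drop, , drop = FALSE], nodes = nodes,
               features = g$features)
}
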