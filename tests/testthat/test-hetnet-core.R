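test_that("loader reads per-relation edge lists, collapses duplicates and
           sets unit weights", {
  dir <- withr::local_tempdir()
  write.table(data.frame(gene = c("g1", "g2", "g1"),
                         disease = c("d1", "d1", "d2")),
              file.path(dir, "gd.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(a = "g1", b = "g2"),
              file.path(dir, "gg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  g <- load_hetnet(c("G-D" = file.path(dir, "gd.tsv"),
                     "G-G" = file.path(dir, "gg.tsv")))
  cnt <- hetnet_counts(g)
  expect_equal(unname(cnt$nodes[c("G", "D")]), c(2L, 2L))
  expect_equal(unname(cnt$edges[["G-D"]]), 3L)
  expect_true(all(g$edges$weight == 1))

  # a duplicated G-D row collapses to one edge
  write.table(data.frame(gene = c("g1", "g1"), disease = c("d1", "d1")),
              file.path(dir, "dup.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  g2 <- load_hetnet(c("G-D" = file.path(dir, "dup.tsv")))
  expect_equal(nrow(g2$edges), 1L)

  # unknown relation is a schema error
  expect_error(load_hetnet(c("G-S" = file.path(dir, "gd.tsv"))),
               "unknown relation")
})

test_that("empty input yields an empty graph; dangling endpoints are
           reported", {
  g <- hetero_graph()
  expect_equal(sum(hetnet_counts(g)$nodes), 0L)
  expect_equal(nrow(g$edges), 0L)

  nodes <- data.frame(id = c("g1", "d1"), type = c("G", "D"))
  expect_error(
    hetero_graph(data.frame(src = "g9", dst = "d1", relation = "G-D"),
                 nodes = nodes),
    "dangling")
})

test_that("bundled deposited-format fixture loads and validates", {
  dir <- system.file("extdata", "synthetic_hetnet", package = "fghne")
  rel <- metagraph()$relation
  g <- load_hetnet(setNames(file.path(dir, paste0(rel, ".tsv")), rel))
  expect_length(validate_hetnet(g, error = FALSE), 0)
  # node counts as loaded (nodes are inferred from edge endpoints, so one
  # edgeless GO term and one edgeless symptom of the generating config do
  # not appear) and relation counts of the fixture
  expect_equal(unname(hetnet_counts(g)$nodes), c(40L, 20L, 29L, 9L))
  expect_equal(unname(hetnet_counts(g)$edges),
               c(110L, 147L, 182L, 23L))
})

test_that("metapath specs validate against the metagraph", {
  m <- metapath_spec("GDG")
  expect_equal(m$endpoint_type, "G")
  expect_equal(m$type_sequence, c("G", "D", "G"))
  expect_error(metapath_spec("GSG"), "absent from the\\s+metagraph|absent")
  expect_error(metapath_spec("GD"), "same type")
  expect_named(default_metapaths(), c("GG", "GDG", "GOG", "DGD", "DSD"))
})

test_that("metapath graph construction matches hand enumeration on toys", {
  # {G1-D1, D1-G2} under GDG -> the single edge (g1, g2), weight 1
  g <- hetero_graph(data.frame(src = c("g1", "g2"), dst = "d1",
                               relation = "G-D"))
  mg <- build_metapath_graph(g, "GDG")
  expect_equal(as.numeric(mg$adjacency["g1", "g2"]), 1)
  expect_equal(Matrix::nnzero(mg$adjacency), 2)  # symmetric pair

  # no intermediate nodes -> empty adjacency
  g2 <- hetero_graph(data.frame(src = "g1", dst = "g2", relation = "G-G"))
  expect_equal(Matrix::nnzero(build_metapath_graph(g2, "GDG")$adjacency), 0)

  # GG is the original G-G edge set
  mg3 <- build_metapath_graph(toy_graph(), "GG")
  expect_equal(as.numeric(mg3$adjacency["g1", "g2"]), 1)
  expect_equal(Matrix::nnzero(mg3$adjacency), 2)

  # two shared diseases -> weight 2
  g4 <- hetero_graph(data.frame(src = c("g1", "g2", "g1", "g2"),
                                dst = c("d1", "d1", "d2", "d2"),
                                relation = "G-D"))
  expect_equal(as.numeric(build_metapath_graph(g4, "GDG")$adjacency["g1",
                                                                    "g2"]),
               2)
})

test_that("metapath graphs equal brute-force path enumeration on random
           graphs and are symmetric", {
  set.seed(7)
  for (trial in 1:20) {
    g <- random_hetnet()
    for (mp in default_metapaths()) {
      mg <- build_metapath_graph(g, mp)
      expect_equal(unname(as.matrix(mg$adjacency)),
                   unname(brute_metapath_counts(g, mp)),
                   info = paste("trial", trial, mp$name))
      expect_true(Matrix::isSymmetric(mg$adjacency))
      expect_true(all(Matrix::diag(mg$adjacency) == 0))
    }
  }
})

test_that("bipartite metapath weights are co-membership counts of the
           incidence matrix", {
  set.seed(11)
  g <- random_hetnet()
  B <- fghne:::step_matrix(g, "G", "D")
  expected <- B %*% Matrix::t(B)
  diag(expected) <- 0
  mg <- build_metapath_graph(g, "GDG")
  expect_equal(as.matrix(mg$adjacency), as.matrix(Matrix::drop0(expected)),
               ignore_attr = TRUE)
})

test_that("neighbour sampling respects the limit, always appends self,
           and is reproducible", {
  n <- 300
  edges <- data.frame(src = "g1", dst = paste0("g", 2:(n + 1)),
                      relation = "G-G")
  mg <- build_metapath_graph(hetero_graph(edges), "GG")

  # under the limit: full neighbourhood + self
  nb <- sample_neighbors(mg, "g300", limit = 100)
  expect_equal(nb, c("g1", "g300"))

  # over the limit: exactly limit + self, no duplicates
  nb2 <- sample_neighbors(mg, "g1", limit = 100, seed = 3)
  expect_length(nb2, 101)
  expect_equal(nb2[101], "g1")
  expect_false(anyDuplicated(nb2) > 0)

  # determinism under the same seed
  expect_identical(nb2, sample_neighbors(mg, "g1", limit = 100, seed = 3))

  # isolated node -> just itself
  g_iso <- hetero_graph(data.frame(src = c("g1", "g3"),
                                   dst = c("d1", "d1"),
                                   relation = "G-D"),
                        nodes = data.frame(id = c("g1", "g2", "g3", "d1"),
                                           type = c("G", "G", "G", "D")))
  mg_iso <- build_metapath_graph(g_iso, "GG")
  expect_equal(sample_neighbors(mg_iso, "g2"), "g2")
})

test_that("edge splits conserve positives, keep sets disjoint, and keep
           negatives outside the original positive set", {
  set.seed(1)
  g <- random_hetnet(n = c(G = 20, D = 10, O = 4, S = 3), p = 0.25)
  n_pos <- sum(g$edges$relation == "G-D")
  sp <- make_split(g, test_fraction = 0.2, neg_ratio = 1, seed = 9)

  expect_equal(nrow(sp$train_pos) + nrow(sp$test_pos), n_pos)
  expect_equal(nrow(sp$test_pos), round(0.2 * n_pos))
  expect_equal(nrow(sp$train_neg), nrow(sp$train_pos))
  expect_equal(nrow(sp$test_neg), nrow(sp$test_pos))

  key <- function(df) paste(df$gene, df$disease)
  pos_key <- key(data.frame(gene = g$edges$src[g$edges$relation == "G-D"],
                            disease = g$edges$dst[g$edges$relation ==
                                                    "G-D"]))
  expect_length(intersect(key(sp$test_neg), pos_key), 0)
  expect_length(intersect(key(sp$train_neg), pos_key), 0)
  expect_length(intersect(key(sp$train_pos), key(sp$test_pos)), 0)
  expect_length(intersect(key(sp$train_neg), key(sp$test_neg)), 0)

  # determinism
  sp2 <- make_split(g, test_fraction = 0.2, neg_ratio = 1, seed = 9)
  expect_identical(sp, sp2)

  # split round trip through TSV
  dir <- withr::local_tempdir()
  write_split(sp, dir)
  sp3 <- read_split(dir)
  expect_equal(sp3$test_pos$gene, sp$test_pos$gene)
  expect_equal(sp3$train_neg$disease, sp$train_neg$disease)
})

test_that("negative sampling fails cleanly when no non-edges exist", {
  full <- expand.grid(src = paste0("g", 1:3), dst = paste0("d", 1:3),
                      stringsAsFactors = FALSE)
  full$relation <- "G-D"
  g <- hetero_graph(full)
  expect_error(make_split(g, 0.2, 1, seed = 1), "non-edges")
})

test_that("test positives are absent from the training graph's metapath
           construction", {
  set.seed(2)
  g <- random_hetnet(n = c(G = 15, D = 8, O = 4, S = 3), p = 0.3)
  sp <- make_split(g, 0.3, 1, seed = 4)
  tg <- train_graph(g, sp)
  key <- paste(tg$edges$src[tg$edges$relation == "G-D"],
               tg$edges$dst[tg$edges$relation == "G-D"])
  expect_length(intersect(key, paste(sp$test_pos$gene,
                                     sp$test_pos$disease)), 0)
  # node universe is preserved even if a node loses all its edges
  expect_identical(tg$nodes, g$nodes)
})
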