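# Run manifest: every artifact a pipeline step writes, with digests, so a
# run can be re-verified and reproduced exactly.
write_manifest <- function(dir, step, config, seed, files) {
  files <- normalizePath(files, mustWork = TRUE)
  manifest <- list(
    step = step,
    package = "fghne",
    version = as.character(utils::packageVersion("fghne")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    files = data.frame(path = files,
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

read_config_file <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    if (grepl("[.](ya?ml)$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs needs the 'yaml' package",
             call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  } else {
    as.list(config)
  }
}

#' Simulate a synthetic network and write it to disk
#'
#' Generates a planted-structure heterogeneous network (see
#' [synth_hetnet()]) and writes one TSV edge list per relation plus a
#' `labels.tsv` with the ground-truth communities and a `manifest.json`
#' referencing every written file with its MD5 digest.
#'
#' @param config A [synth_config()], a named list of its arguments, or a
#'   path to a YAML/JSON file of them.
#' @param out_dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
fg_simulate <- function(config = synth_config(), out_dir) {
  if (!inherits(config, "synth_config")) {
    config <- do.call(synth_config, read_config_file(config))
  }
  net <- synth_hetnet(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_hetnet(net$graph, out_dir)
  lab_path <- file.path(out_dir, "labels.tsv")
  write.table(net$labels, lab_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, labels = lab_path)
  write_manifest(out_dir, "simulate", unclass(config), config$seed, paths)
  invisible(paths)
}

#' Train a model from on-disk edge lists
#'
#' Loads the per-relation edge lists from `data_dir` (written by
#' [fg_simulate()] or following the same layout), splits the
#' gene-disease edges, trains the model, and writes the checkpoint
#' (`model.rds`), the split (four TSVs under `split/`), the per-epoch
#' loss trace (`trace.tsv`) and a manifest.
#'
#' @param data_dir Directory containing `G-G.tsv`, `G-D.tsv`, `G-O.tsv`,
#'   `D-S.tsv`.
#' @param out_dir Output directory.
#' @param config A [fghne_config()], a named list of overrides, or a
#'   YAML/JSON file path.
#' @param test_fraction,neg_ratio Split parameters (see [make_split()]).
#' @return Invisibly, a list with the trained `model`, the `split` and
#'   the written paths.
#' @export
fg_train <- function(data_dir, out_dir, config = list(),
                     test_fraction = 0.2, neg_ratio = 1) {
  if (!inherits(config, "fghne_config")) {
    config <- do.call(fghne_config, read_config_file(config))
  }
  rel <- metagraph()$relation
  files <- setNames(file.path(data_dir, paste0(rel, ".tsv")), rel)
  missing_rel <- rel[!file.exists(files)]
  if (length(missing_rel)) {
    stop("missing edge list(s) for relation(s): ",
         paste(missing_rel, collapse = ", "), " in ", data_dir,
         call. = FALSE)
  }
  g <- load_hetnet(files)
  split <- make_split(g, test_fraction, neg_ratio, seed = config$seed)
  model <- fghne_train(g, split, config)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ckpt <- file.path(out_dir, "model.rds")
  saveRDS(model, ckpt)
  split_paths <- write_split(split, file.path(out_dir, "split"))
  trace_path <- file.path(out_dir, "trace.tsv")
  write.table(model$trace, trace_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(checkpoint = ckpt, split_paths, trace = trace_path)
  write_manifest(out_dir, "train", unclass(config), config$seed, paths)
  invisible(list(model = model, split = split, paths = paths))
}

#' Evaluate trained checkpoints on a held-out split
#'
#' Writes the evaluation report as JSON, the per-pair scores as TSV, and
#' ROC/PR curve points as TSV.  Several checkpoints (e.g. the same
#' configuration trained under different seeds) may be given; the report
#' then carries the per-seed values plus mean and standard deviation of
#' every metric.
#'
#' @param checkpoints Path(s) to `model.rds` checkpoint(s).
#' @param split_dir Directory holding the four split TSVs.
#' @param out_dir Output directory.
#' @param k_list Precision/recall cut-offs (default
#'   `c(1000, 10000, 20000)`).
#' @return Invisibly, the report list.
#' @export
fg_evaluate <- function(checkpoints, split_dir, out_dir,
                        k_list = c(1000, 10000, 20000)) {
  split <- read_split(split_dir)
  reports <- lapply(checkpoints, function(p) {
    model <- readRDS(p)
    test_ids_known <- all(split$test_pos$gene %in% model$nodes$G) &&
      all(split$test_pos$disease %in% model$nodes$D) &&
      all(split$test_neg$gene %in% model$nodes$G) &&
      all(split$test_neg$disease %in% model$nodes$D)
    if (!test_ids_known) {
      stop("checkpoint and split are incompatible (id maps differ)",
           call. = FALSE)
    }
    evaluate_model(model, split, k_list)
  })
  flat <- function(r) {
    c(ap = r$ap, auc = r$auc,
      setNames(r$precision_at, paste0("precision_at_",
                                      names(r$precision_at))),
      setNames(r$recall_at, paste0("recall_at_", names(r$recall_at))))
  }
  vals <- t(vapply(reports, flat, flat(reports[[1]])))
  report <- list(n_models = length(reports),
                 metrics = as.list(colMeans(vals)))
  if (length(reports) > 1) {
    report$sd <- as.list(apply(vals, 2, stats::sd))
    report$per_model <- as.data.frame(vals)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  scores_path <- file.path(out_dir, "scores.tsv")
  write.table(reports[[1]]$scores, scores_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  curves_path <- file.path(out_dir, "curves.tsv")
  write.table(curve_points(reports[[1]]$scores$score,
                           reports[[1]]$scores$label),
              curves_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "evaluate", list(k_list = k_list), NA,
                 c(json_path, scores_path, curves_path))
  invisible(report)
}

#' Rank candidate genes for a disease from a checkpoint
#'
#' @param checkpoint Path to a `model.rds` checkpoint.
#' @param disease Disease identifier.
#' @param out_file Output TSV path (`rank`, `gene`, `score`).
#' @param top_k,exclude_known See [rank_candidates()].
#' @return Invisibly, the ranking data frame.
#' @export
fg_rank <- function(checkpoint, disease, out_file, top_k = 20,
                    exclude_known = TRUE) {
  model <- readRDS(checkpoint)
  ranking <- rank_candidates(model, disease, top_k, exclude_known)
  dir.create(dirname(out_file), showWarnings = FALSE, recursive = TRUE)
  write.table(ranking, out_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ranking)
}
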