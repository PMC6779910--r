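# Config-driven orchestration of the two end-to-end workflows:
# unsupervised (embed -> distances -> dendrogram + MDS) and supervised
# (embed -> cross-validated classification -> confusion matrix).

#' Assemble a workflow configuration
#'
#' Exactly one of `images_dir` / `embeddings_file` must be given. Values
#' mirror the CLI flags; [read_workflow_config()] loads the same fields from
#' a YAML file.
#'
#' @param images_dir Directory of images (first-level subdirectories as
#'   class labels), or `NULL`.
#' @param embeddings_file Pre-computed embedding CSV
#'   (see [write_embedding_csv()]), or `NULL`.
#' @param backend Embedding backend name (default `"filterbank"`).
#' @param metric Distance metric, `"cosine"` (default) or `"euclidean"`.
#' @param linkage Clustering linkage (default `"ward"`).
#' @param cut_k Optional cluster count for a flat cut of the dendrogram.
#' @param folds CV fold count (default 10).
#' @param seed Seed for all stochastic stages (default 0).
#' @param output_dir Where artifacts are written.
#' @param cache_dir Optional embedding cache directory.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(images_dir = NULL, embeddings_file = NULL,
                            backend = "filterbank",
                            metric = "cosine", linkage = "ward",
                            cut_k = NULL, folds = 10L, seed = 0L,
                            output_dir, cache_dir = NULL) {
  if (is.null(images_dir) == is.null(embeddings_file)) {
    abort_input("exactly one of `images_dir` / `embeddings_file` must be set")
  }
  get_backend(backend) # validate registered names early
  if (!metric %in% c("cosine", "euclidean")) {
    abort_input(sprintf("unknown metric '%s'", metric))
  }
  if (!linkage %in% c("ward", "average", "complete", "single")) {
    abort_input(sprintf("unknown linkage '%s'", linkage))
  }
  if (!is.null(cut_k)) stopifnot_count(cut_k, "cut_k", min = 1L)
  stopifnot_count(folds, "folds", min = 2L)
  structure(list(images_dir = images_dir, embeddings_file = embeddings_file,
                 backend = backend, metric = metric, linkage = linkage,
                 cut_k = cut_k, folds = as.integer(folds),
                 seed = as.integer(seed), output_dir = output_dir,
                 cache_dir = cache_dir),
            class = "workflow_config")
}

#' Read a workflow configuration from YAML
#'
#' Keys mirror the arguments of [workflow_config()]; `overrides` (typically
#' parsed CLI flags) take precedence over file values.
#'
#' @param path YAML file.
#' @param overrides Named list of values overriding the file.
#' @return A `workflow_config`.
#' @export
read_workflow_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort_input(sprintf("no such config file: '%s'", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort_input(sprintf("config file '%s' is not a YAML mapping", path))
  cfg <- modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])
  known <- names(formals(workflow_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort_input(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(workflow_config, cfg)
}

workflow_input <- function(cfg, stage) {
  with_stage(stage, {
    if (!is.null(cfg$images_dir)) {
      table <- scan_image_directory(cfg$images_dir)
      embed_images(table, backend = cfg$backend, cache_dir = cfg$cache_dir)
    } else {
      read_embedding_csv(cfg$embeddings_file)
    }
  })
}

# prefix stage name onto propagated errors, preserving the condition class
with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                        class = class(e)))
  })
}

write_run_log <- function(cfg, path, extra = character()) {
  lines <- c(
    sprintf("imagemine %s on R %s.%s", as.character(packageVersion("imagemine")),
            R.version$major, R.version$minor),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    "config:",
    vapply(names(unclass(cfg)), function(k) {
      sprintf("  %s: %s", k, if (is.null(cfg[[k]])) "~" else as.character(cfg[[k]]))
    }, character(1)),
    extra
  )
  writeLines(lines, path)
  invisible(path)
}

#' Run the unsupervised workflow
#'
#' Load (or read) embeddings, compute pairwise distances, cluster them into
#' a dendrogram (optionally cut into `cut_k` flat clusters) and project them
#' into the plane by metric MDS. Writes `embeddings.csv`, `distances.csv`,
#' `tree.nwk`, `clusters.csv` (when `cut_k` is set), `mds.csv` and
#' `run_log.txt` under `output_dir`. All stages are deterministic given the
#' config, so rerunning reproduces the artifacts byte for byte.
#'
#' @param cfg A `workflow_config`.
#' @return Named list of artifact paths, invisibly; component `objects`
#'   holds the in-memory results (embedding, distances, dendrogram, cut
#'   labels, projection).
#' @export
run_unsupervised <- function(cfg) {
  stopifnot(inherits(cfg, "workflow_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)

  E <- workflow_input(cfg, "embed")
  write_embedding_csv(E, out("embeddings.csv"))
  D <- with_stage("distances", pairwise_distances(E, cfg$metric))
  write_distance_csv(D, out("distances.csv"))
  dendro <- with_stage("cluster", hierarchical_cluster(D, cfg$linkage))
  writeLines(to_newick(dendro), out("tree.nwk"))
  cut <- NULL
  if (!is.null(cfg$cut_k)) {
    cut <- with_stage("cluster", cut_dendrogram(dendro, cfg$cut_k))
    write.csv(data.frame(image_path = E$table$path, cluster = cut),
              out("clusters.csv"), row.names = FALSE)
  }
  proj <- with_stage("project", mds_project(D, seed = cfg$seed))
  write_projection_csv(proj, out("mds.csv"))
  write_run_log(cfg, out("run_log.txt"),
                sprintf("mds stress1: %.10g (%d iterations)", proj$stress1, proj$n_iter))

  artifacts <- list(embeddings = out("embeddings.csv"),
                    distances = out("distances.csv"),
                    newick = out("tree.nwk"),
                    clusters = if (!is.null(cut)) out("clusters.csv"),
                    mds = out("mds.csv"),
                    log = out("run_log.txt"),
                    objects = list(embedding = E, distances = D,
                                   dendrogram = dendro, clusters = cut,
                                   projection = proj))
  invisible(artifacts)
}

#' Run the supervised workflow
#'
#' Load (or read) labeled embeddings, evaluate a logistic-regression
#' classifier by stratified k-fold cross-validation and write
#' `embeddings.csv`, `metrics.json`, `confusion.csv`, `predictions.csv`
#' (out-of-fold label, probabilities and fold per image) and `run_log.txt`
#' under `output_dir`.
#'
#' @param cfg A `workflow_config`.
#' @return Named list of artifact paths, invisibly; component `objects`
#'   holds the `cv_result`, `confusion_matrix` and `classification_metrics`.
#' @export
run_supervised <- function(cfg) {
  stopifnot(inherits(cfg, "workflow_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$output_dir, f)

  E <- workflow_input(cfg, "embed")
  write_embedding_csv(E, out("embeddings.csv"))
  ev <- with_stage("evaluate", cross_validate(E, k = cfg$folds, seed = cfg$seed))
  cm <- confusion_matrix(ev)
  metrics <- compute_metrics(ev)
  write_metrics_json(metrics, out("metrics.json"), ev)
  write_confusion_csv(cm, out("confusion.csv"))
  pred_df <- data.frame(image_path = E$table$path, label = ev$true_labels,
                        predicted = ev$predicted_labels, fold = ev$fold_of,
                        stringsAsFactors = FALSE)
  pred_df <- cbind(pred_df, as.data.frame(ev$probabilities))
  write.csv(pred_df, out("predictions.csv"), row.names = FALSE)
  write_run_log(cfg, out("run_log.txt"),
                sprintf("cv accuracy: %.10g", metrics$CA))

  invisible(list(embeddings = out("embeddings.csv"),
                 metrics = out("metrics.json"),
                 confusion = out("confusion.csv"),
                 predictions = out("predictions.csv"),
                 log = out("run_log.txt"),
                 objects = list(evaluation = ev, confusion = cm,
                                metrics = metrics)))
}
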