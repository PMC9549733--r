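#' Hash of a run configuration
#'
#' MD5 of the canonical YAML serialisation of the configuration list; every
#' output table of a run carries this hash in its provenance header, so any
#' change to any parameter changes every output's header.
#'
#' @param config A named list.
#' @return 32-character hash string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}

#' Default run configuration
#'
#' The default 2D study scenario: two simulated conditions (untreated,
#' treated) of mixed low-motility and motile cells, the full feature
#' battery, and the standard state-space settings (95% variance target, at
#' most 30 components, two clusters, t-SNE perplexity 35).
#'
#' @param seed Integer seed.
#' @param n_tracks Tracks per condition.
#' @return A named configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, n_tracks = 216L) {
  list(
    mode = "simulate",
    seed = as.integer(seed),
    n_tracks = as.integer(n_tracks),
    filter = list(min_length = 61L, require_in_field = FALSE),
    features = list(rw_n_sim = 100L, subtrack_len = 20L),
    statespace = list(var_target = 0.95, max_components = 30L, k = 2L,
                      perplexity = 35),
    drift = list(threshold = 0.95)
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(default_config(), config)
}

load_input_tracks <- function(config) {
  if (identical(config$mode, "simulate")) {
    scen <- default_scenario(config$n_tracks, config$seed)
    sims <- lapply(names(scen), function(cond)
      simulate_tracks(scen[[cond]], condition = cond))
    tracks <- trackset(unlist(lapply(sims, function(s) s$tracks$tracks),
                              recursive = FALSE))
    labels <- do.call(rbind, lapply(sims, `[[`, "labels"))
    list(tracks = tracks, truth = labels)
  } else if (identical(config$mode, "tables")) {
    if (is.null(config$inputs)) stop("tables mode needs config$inputs")
    sets <- lapply(config$inputs, function(inp)
      read_tracks_table(inp$path,
                        dialect = inp$dialect %||% "generic",
                        frame_interval = inp$frame_interval,
                        condition = inp$condition))
    tracks <- trackset(unlist(lapply(sets, function(s) s$tracks),
                              recursive = FALSE))
    list(tracks = tracks, truth = NULL)
  } else {
    stop("unknown mode: ", config$mode)
  }
}

#' Run the full 2D motility analysis pipeline
#'
#' filter -> feature battery -> state space (PCA, Ward clustering,
#' silhouette, t-SNE) -> condition-by-cluster chi-squared test ->
#' normalised feature means. Writes `features.tsv`, `labels.tsv`,
#' `contingency.tsv`, `embedding.tsv`, `normalized_means.tsv` and
#' `run_log.txt` to `output_dir`, every file carrying the configuration
#' hash. Identical configuration (including seed) yields byte-identical
#' outputs.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure.
#' @param output_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results: `features`,
#'   `statespace`, `test`, `embedding`, `normalized_means`, `config_hash`
#'   and (for simulated runs) `truth`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = tempfile()) {
  config <- read_run_config(config)
  hash <- config_hash(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("cellmotility %s run, config_hash=%s",
                         utils::packageVersion("cellmotility"), hash),
                 sprintf("seed=%d mode=%s", config$seed, config$mode))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  inp <- stage("input", load_input_tracks(config))
  log_lines <- c(log_lines, sprintf("input: %d tracks", length(inp$tracks)))

  filtered <- stage("filter", filter_tracks(
    inp$tracks, min_length = config$filter$min_length,
    require_in_field = isTRUE(config$filter$require_in_field)))
  log_lines <- c(log_lines, sprintf(
    "filter: kept %d (dropped %d short, %d out-of-field)",
    length(filtered), attr(filtered, "n_dropped_short"),
    attr(filtered, "n_dropped_out_of_field")))

  fp <- do.call(feature_params,
                config$features[names(config$features) %in%
                                  names(formals(feature_params))])
  fm <- stage("features", feature_table(filtered, fp))
  log_lines <- c(log_lines, sprintf(
    "features: %d tracks x %d features, %d missing values imputed downstream",
    nrow(fm), length(feature_columns(fm)), sum(is.na(fm[feature_columns(fm)]))))

  ss <- stage("statespace", reduce_and_cluster(
    fm, var_target = config$statespace$var_target,
    max_components = config$statespace$max_components,
    k = config$statespace$k))
  log_lines <- c(log_lines, sprintf(
    "statespace: %d PCs, silhouette %.3f", ss$kept_components, ss$silhouette))

  emb <- NULL
  if (config$statespace$perplexity < (nrow(fm) - 1) / 3) {
    emb <- stage("embedding", tsne_embed(
      ss$pc_scores, perplexity = config$statespace$perplexity,
      seed = config$seed))
  } else {
    log_lines <- c(log_lines, "embedding: skipped (too few tracks for perplexity)")
  }

  test <- stage("test", condition_cluster_test(ss$cluster_labels,
                                               fm$condition))
  log_lines <- c(log_lines, sprintf(
    "chi2 = %.4f, df = %d, p = %.3g", test$chi2, test$df, test$p))

  nm <- stage("normalized_means",
              normalized_feature_means(fm, ss$cluster_labels))

  write_output_table(fm, file.path(output_dir, "features.tsv"),
                     config_hash = hash)
  labels_df <- data.frame(track_id = fm$track_id, condition = fm$condition,
                          cluster = ss$cluster_labels)
  if (!is.null(inp$truth))
    labels_df$component <- inp$truth$component[
      match(labels_df$track_id, inp$truth$track_id)]
  write_output_table(labels_df, file.path(output_dir, "labels.tsv"),
                     config_hash = hash)
  cont_df <- as.data.frame(test$contingency)
  cont_df$chi2 <- test$chi2
  cont_df$df <- test$df
  cont_df$p <- test$p
  write_output_table(cont_df, file.path(output_dir, "contingency.tsv"),
                     config_hash = hash)
  if (!is.null(emb)) {
    emb_df <- data.frame(track_id = fm$track_id, emb)
    write_output_table(emb_df, file.path(output_dir, "embedding.tsv"),
                       config_hash = hash)
  }
  write_output_table(nm, file.path(output_dir, "normalized_means.tsv"),
                     config_hash = hash)
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))

  invisible(list(features = fm, statespace = ss, test = test,
                 embedding = emb, normalized_means = nm, truth = inp$truth,
                 config_hash = hash, output_dir = output_dir))
}

#' Run the 3D tissue migration analysis
#'
#' The 3D chain: estimate rigid construct drift from fiducial tracks
#' (cosine-similarity selection), subtract it from the cell tracks, compute
#' total distance travelled per cell, Ward-cluster that single feature into
#' `k` groups, and chi-squared-test the condition-by-cluster proportions.
#' Writes `corrected_tracks.tsv`, `distance_clusters.tsv`,
#' `drift_report.tsv` and `contingency_3d.tsv`.
#'
#' @param cells A [trackset()] of 3D cell tracks (conditions in the tracks).
#' @param fiducials A [trackset()] of fiducial tracks of the construct.
#' @param threshold Cosine similarity threshold for fiducial selection.
#' @param k Number of distance clusters.
#' @param min_length Minimum track length for inclusion.
#' @param output_dir Optional output directory; `NULL` skips writing.
#' @return List with `drift`, `corrected`, `total_distance`, `clusters`,
#'   `test` (or `NULL` when only one condition is present).
#' @export
run_pipeline_3d <- function(cells, fiducials, threshold = 0.95, k = 2L,
                            min_length = 2L, output_dir = NULL) {
  drift <- estimate_drift(fiducials, threshold = threshold)
  corrected <- apply_drift_correction(cells, drift)
  corrected <- filter_tracks(corrected, min_length = max(min_length, 2L))
  td <- vapply(corrected$tracks, function(t) path_metrics(t)$total_distance,
               numeric(1))
  cl <- cluster_1d(td, k = k)
  conditions <- vapply(corrected$tracks, function(t) t$condition,
                       character(1))
  test <- if (length(unique(conditions)) >= 2L)
    condition_cluster_test(cl$labels, conditions) else NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_tracks_table(corrected,
                       file.path(output_dir, "corrected_tracks.tsv"))
    cl_df <- data.frame(track_id = names(td), condition = conditions,
                        total_distance = unname(td),
                        cluster = unname(cl$labels))
    write_output_table(cl_df, file.path(output_dir, "distance_clusters.tsv"))
    drift_df <- data.frame(frame = drift$frames, drift$drift_path)
    names(drift_df) <- c("frame", c("x", "y", "z")[seq_len(
      ncol(drift$drift_path))])
    write_output_table(drift_df, file.path(output_dir, "drift_report.tsv"))
    if (!is.null(test)) {
      cont_df <- as.data.frame(test$contingency)
      cont_df$chi2 <- test$chi2
      cont_df$p <- test$p
      write_output_table(cont_df,
                         file.path(output_dir, "contingency_3d.tsv"))
    }
  }
  list(drift = drift, corrected = corrected, total_distance = td,
       clusters = cl, test = test)
}
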