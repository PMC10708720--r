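#' Write / read one epoch as a delimited numeric matrix
#'
#' Tab-separated channels-by-samples text with full `%.17g` precision, so a
#' write/read round trip reproduces the matrix exactly. The sampling rate is
#' carried in a `# fs=<Hz>` header line.
#'
#' @param epoch an [eeg_epoch()].
#' @param path output file path.
#' @return `write_epoch_matrix()` the path invisibly; `read_epoch_matrix()`
#'   an [eeg_epoch()].
#' @export
write_epoch_matrix <- function(epoch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g", epoch_fs(epoch)), con)
  writeLines(apply(unclass(epoch), 1L, function(ch)
    paste(sprintf("%.17g", ch), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_epoch_matrix
#' @export
read_epoch_matrix <- function(path) {
  if (!file.exists(path)) stop("no such epoch file: ", path)
  lines <- readLines(path)
  fs <- as.numeric(sub("^# fs=", "", lines[1]))
  dat <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  eeg_epoch(dat, fs = fs)
}

#' Run the whole pipeline and persist every stage
#'
#' Executes simulate -> preprocess -> coherence graphs -> embeddings ->
#' pair dataset -> cross-validated classifier -> difficulty analysis, and
#' writes each stage's artifact as CSV into `out_dir` (created if needed),
#' plus a JSON manifest with the configuration, seeds and file hashes.
#' Rerunning with the same configuration reproduces every CSV byte for
#' byte.
#'
#' Artifacts: `choices.csv`, `epochs/epoch_p<p>_g<g>.tsv` (raw epochs, if
#' `write_epochs`), `edges.csv` (all graphs as labeled edge lists),
#' `embeddings.csv`, `pairs.csv`, `predictions.csv`, `metrics_global.csv`,
#' `metrics_per_game.csv`, `ci.csv`, `regressions.json`, `manifest.json`.
#'
#' @param config a [study_config()].
#' @param out_dir output directory.
#' @param walk_length,threshold,cv passed to [coordination_fit()].
#' @param write_epochs also persist the raw epochs (the bulkiest artifact).
#' @return The `"coord_fit"`, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, walk_length = 5, threshold = 0.5,
                         cv = cv_config(seed = config$seed),
                         write_epochs = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(config)

  ch <- as.data.frame(as.table(study$choices))
  names(ch) <- c("player", "game", "option")
  write.csv(ch, file.path(out_dir, "choices.csv"), row.names = FALSE)

  if (write_epochs) {
    epo_dir <- file.path(out_dir, "epochs")
    dir.create(epo_dir, showWarnings = FALSE)
    for (p in seq_len(config$n_players))
      for (g in seq_len(config$n_games))
        write_epoch_matrix(study$epochs[[p]][[g]],
                           file.path(epo_dir, sprintf("epoch_p%d_g%d.tsv", p, g)))
  }

  edges <- NULL
  for (p in seq_len(config$n_players)) {
    for (g in seq_len(config$n_games)) {
      pre <- preprocess_epoch(study$epochs[[p]][[g]])
      gph <- threshold_graph(pairwise_coherence(pre), threshold)
      el <- graph_to_edgelist(gph)
      if (nrow(el))
        edges <- rbind(edges, cbind(player = p, game = g, el))
    }
  }
  if (is.null(edges))
    edges <- data.frame(player = integer(), game = integer(),
                        from = character(), to = character())
  write.csv(edges, file.path(out_dir, "edges.csv"), row.names = FALSE)

  fit <- coordination_fit(study, walk_length = walk_length,
                          threshold = threshold, cv = cv)

  emb <- data.frame(epoch = rownames(fit$embeddings), fit$embeddings,
                    check.names = FALSE)
  write.csv(emb, file.path(out_dir, "embeddings.csv"), row.names = FALSE)
  write.csv(fit$dataset, file.path(out_dir, "pairs.csv"), row.names = FALSE)
  write.csv(cbind(fit$dataset[, c("pair_i", "pair_j", "game", "label")],
                  fit$predictions),
            file.path(out_dir, "predictions.csv"), row.names = FALSE)

  glob <- data.frame(metric = c("accuracy", "precision_0", "precision_1",
                                "recall_0", "recall_1", "f1_0", "f1_1"),
                     value = c(fit$metrics$accuracy, fit$metrics$precision,
                               fit$metrics$recall, fit$metrics$f1))
  write.csv(glob, file.path(out_dir, "metrics_global.csv"), row.names = FALSE)
  write.csv(fit$per_game, file.path(out_dir, "metrics_per_game.csv"),
            row.names = FALSE)
  write.csv(ci_table(study$choices), file.path(out_dir, "ci.csv"),
            row.names = FALSE)

  regs <- lapply(fit$regressions, function(r)
    r[c("slope", "intercept", "pearson_r", "p_value", "n")])
  jsonlite::write_json(regs, file.path(out_dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA)

  write_manifest(out_dir, config, cv, walk_length, threshold)
  invisible(fit)
}

# Manifest: config + seeds + md5 of every artifact (written last).
write_manifest <- function(out_dir, config, cv, walk_length, threshold) {
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("coordwalk")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    cv = unclass(cv),
    walk_length = walk_length, threshold = threshold,
    files = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
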