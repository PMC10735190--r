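#' @title End-to-end pipeline steps
#' @name pipeline
#' @description
#' File-level orchestration of the full analysis: simulate a synthetic
#' cohort to EDF + manifest, extract the 570-value feature table from a
#' directory of recordings, and run one experiment design to a prediction
#' table and summary. These functions (with [reproduce_tables()],
#' [order_sweep()] and [render_topomap()]) are the package's command
#' surface; a thin script wrapper is installed under `inst/cli/cogload.R`.
NULL

#' Simulate a cohort to EDF files and a manifest CSV
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed). One
#'   `<subject>_<condition>.edf` per subject-condition plus `manifest.csv`
#'   (columns `subject_id`, `X`, `group`).
#' @return The manifest data frame, invisibly.
#' @export
simulate_cohort_edf <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- generate_cohort(cfg)
  for (rec in cohort$recordings) {
    write_edf(rec, file.path(dir, paste0(rec$subject_id, "_", rec$condition, ".edf")))
  }
  utils::write.csv(cohort$manifest[, c("subject_id", "X", "group")],
                   file.path(dir, "manifest.csv"), row.names = FALSE, quote = FALSE)
  message("simulated ", nrow(cohort$manifest), " subjects (seed ", cfg$seed,
          ") into ", dir)
  invisible(cohort$manifest)
}

#' Extract the feature table from a directory of EDF recordings
#'
#' @param dir Directory holding `<subject>_<condition>.edf` files.
#' @param out Optional CSV path for the feature table.
#' @param ... Passed to [recording_features()] (`n_modes`, `q`, `max_iter`).
#' @param use_aliases Passed to [read_recording()].
#' @return Feature table data frame (one row per recording, 570 feature
#'   columns).
#' @export
extract_features_dir <- function(dir, out = NULL, use_aliases = FALSE, ...) {
  files <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no EDF files in ", dir, call. = FALSE)
  recs <- lapply(files, read_recording, use_aliases = use_aliases)
  features <- extract_cohort_features(recs, ...)
  if (!is.null(out)) write_features(features, out)
  features
}

#' Run one experiment design end to end
#'
#' @param features Feature table (data frame or CSV path).
#' @param manifest Manifest (data frame or CSV path).
#' @param design Design name `"E1"`..`"E5"` (see [make_design()]).
#' @param order,C SVM hyper-parameters.
#' @param out_predictions,out_summary Optional CSV / JSON output paths.
#' @return List with `predictions` (prediction table) and `summary`
#'   (`evaluation_summary`).
#' @export
run_design_pipeline <- function(features, manifest, design = "E5",
                                order = 4L, C = 1,
                                out_predictions = NULL, out_summary = NULL) {
  if (is.character(features)) features <- read_features(features)
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  des <- make_design(design, manifest)
  tab <- run_experiment(des, features, manifest, order = order, C = C)
  summ <- evaluate_prediction_table(tab)
  if (!is.null(out_predictions))
    utils::write.csv(tab, out_predictions, row.names = FALSE, quote = FALSE)
  if (!is.null(out_summary))
    jsonlite::write_json(unclass(summ), out_summary, auto_unbox = TRUE, digits = NA)
  list(predictions = tab, summary = summ)
}

#' Group-wise power topography from a directory of recordings
#'
#' Normalizes each subject's rest/task pair, computes channel powers,
#' grand-averages them by performance group and renders one topomap per
#' (group, condition) together with the rest-vs-task image similarity per
#' group.
#'
#' @param recordings List of `eeg_recording`s (both conditions per subject).
#' @param manifest Manifest data frame.
#' @param grid_n Topomap grid resolution.
#' @return List with `grand_average` (data frame), `topomaps` (nested list
#'   `[[group]][[condition]]`) and `isi` (named vector: rest-vs-task SSIM
#'   per group).
#' @export
power_topography <- function(recordings, manifest, grid_n = 64L) {
  ids <- vapply(recordings, `[[`, "", "subject_id")
  conds <- vapply(recordings, `[[`, "", "condition")
  powers <- list()
  for (sid in unique(ids)) {
    rest <- recordings[[which(ids == sid & conds == "rest")[1]]]
    task <- recordings[[which(ids == sid & conds == "task")[1]]]
    pair <- normalize_pair(rest, task)
    powers <- c(powers, list(channel_power(pair$rest), channel_power(pair$task)))
  }
  ga <- grand_average(powers, manifest)
  chans <- montage_1020()
  maps <- list(); isi <- c()
  for (g in unique(ga$group)) {
    maps[[g]] <- list()
    for (cond in c("rest", "task")) {
      vals <- as.numeric(ga[ga$group == g & ga$condition == cond, chans])
      maps[[g]][[cond]] <- render_topomap(vals, grid_n = grid_n)
    }
    isi[g] <- image_similarity(maps[[g]]$rest, maps[[g]]$task)
  }
  list(grand_average = ga, topomaps = maps, isi = isi)
}

#' Run the experiment designs on the real recordings, if present
#'
#' The real 36-subject mental-arithmetic recordings are not distributed
#' with the package; point `data_dir` at a local copy holding
#' `<subject>_<condition>.edf` files and a `manifest.csv` with the
#' problem-completion scores to reproduce the published designs for manual
#' comparison. Errors informatively when the directory is absent.
#'
#' @param data_dir Directory with the real recordings.
#' @param designs Design names to run.
#' @param ... Passed to [extract_features_dir()].
#' @return Named list of `run_design_pipeline()` results.
#' @export
run_real_designs <- function(data_dir, designs = c("E1", "E2", "E3", "E4", "E5"),
                             ...) {
  if (!dir.exists(data_dir))
    stop("real dataset directory not found: ", data_dir,
         " (the recordings are not bundled; download them separately)",
         call. = FALSE)
  manifest <- load_manifest(file.path(data_dir, "manifest.csv"))
  features <- extract_features_dir(data_dir, ...)
  res <- lapply(designs, function(d)
    run_design_pipeline(features, manifest, design = d))
  stats::setNames(res, designs)
}
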