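## End-to-end orchestration: cohort in (synthetic or manifest), four report
## tables out (AU comparison, episode durations, symmetry + permutation,
## classifier performance). Every number in the bundle comes from a module
## operation; the orchestrator only wires them together.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort from `cohort`) or
#'   `"manifest"` (read clips listed in `manifest`).
#' @param cohort a [cohort_spec()] or list of its arguments.
#' @param manifest path to a clip manifest CSV (manifest mode).
#' @param au_set `"seven_au"` (default; the classifier's feature list) or
#'   `"six_au"` (the classical fear prototype without AU07).
#' @param micro_ms,macro_ms micro/macro expression thresholds (ms).
#' @param n_boot bootstrap iterations; `n_perm` permutation count.
#' @param alpha family-wise level; `m_comparisons` defaults to the AU count.
#' @param classifiers learners to evaluate.
#' @param n_train number of participants in the training split.
#' @param smote apply SMOTE to training frames.
#' @param smote_k SMOTE neighbour count.
#' @param n_trees ensemble-size override (NULL = learner default).
#' @param run_loocv also run leave-one-person-out cross-validation
#'   (costly; off by default).
#' @param episode_au AU whose episode durations are analysed (default 20,
#'   the lip stretcher).
#' @param seed master seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "manifest"),
                            cohort = cohort_spec(), manifest = NULL,
                            au_set = c("seven_au", "six_au"),
                            micro_ms = 200, macro_ms = 500,
                            n_boot = 1000, n_perm = 10000, alpha = 0.05,
                            m_comparisons = NULL,
                            classifiers = c("random_forest", "knn",
                                            "bagging"),
                            n_train = 12, smote = TRUE, smote_k = 5,
                            n_trees = NULL, run_loocv = FALSE,
                            episode_au = "20", seed = 1L) {
  mode <- match.arg(mode)
  au_set <- match.arg(au_set)
  if (mode == "manifest" && is.null(manifest))
    fl_stop("InvalidSpec", "manifest mode needs a manifest path")
  cfg <- as.list(environment())
  cfg$aus <- if (au_set == "seven_au") FEAR_AUS_7 else FEAR_AUS_6
  if (is.null(m_comparisons)) cfg$m_comparisons <- length(cfg$aus)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full leaked-fear analysis
#'
#' Produces the four report tables of the analysis chain: (i) paired AU
#' comparison with Bonferroni threshold, (ii) episode-duration summaries
#' per condition with micro/macro counts and the independent bootstrap
#' comparison of total and apex-to-offset durations, (iii) per-clip mean
#' coherence with the two-sample permutation test, (iv) classifier reports
#' on the participant-held-out split (plus optional LOOCV). Deterministic
#' given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return List of class `fearleak_report`.
#' @export
run_full_analysis <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  clips <- if (config$mode == "synthetic") {
    sp <- config$cohort
    if (!inherits(sp, "cohort_spec")) sp <- do.call(cohort_spec, sp)
    sp$seed <- seed
    note("stage=cohort mode=synthetic n_participants=%d seed=%d",
         sp$n_participants, seed)
    generate_cohort(sp)
  } else {
    note("stage=cohort mode=manifest path=%s", config$manifest)
    read_manifest(config$manifest, au_set = config$aus)
  }
  note("stage=cohort clips=%d frames=%d", length(clips),
       sum(vapply(clips, length, 0L)))

  ## (i) paired AU comparison
  summaries <- cohort_mean_aus(clips, au_set = config$aus)
  au_table <- au_comparison_table(summaries, config$aus,
                                  alpha = config$alpha,
                                  n_boot = config$n_boot, seed = seed)
  attr(au_table, "alpha_bonferroni") <-
    bonferroni_alpha(config$alpha, config$m_comparisons)
  note("stage=au_comparison aus=%d alpha_bonf=%.3f", nrow(au_table),
       attr(au_table, "alpha_bonferroni"))

  ## (ii) episode durations
  eps <- cohort_episodes(clips, au = config$episode_au)
  frame_rate <- clips[[1]]$frame_rate
  by_cond <- split(eps, eps$condition)
  durations <- lapply(by_cond, duration_summary, frame_rate = frame_rate,
                      micro_ms = config$micro_ms, macro_ms = config$macro_ms,
                      n_boot = config$n_boot, seed = seed)
  dur_tests <- NULL
  if (all(c("truth", "lie") %in% names(by_cond))) {
    dur_tests <- list(
      total = independent_bootstrap_t(by_cond$truth$total_frames,
                                      by_cond$lie$total_frames,
                                      config$n_boot, seed),
      apex_to_offset = independent_bootstrap_t(
        by_cond$truth$apex_to_offset_frames,
        by_cond$lie$apex_to_offset_frames, config$n_boot, seed))
  }
  note("stage=episodes au=AU%s truth=%d lie=%d", config$episode_au,
       sum(eps$condition == "truth"), sum(eps$condition == "lie"))

  ## (iii) symmetry
  sym <- cohort_symmetry(clips)
  sym_test <- permutation_test(sym$mean_coherence[sym$condition == "lie"],
                               sym$mean_coherence[sym$condition == "truth"],
                               n_perm = config$n_perm, seed = seed)
  note("stage=symmetry mean_lie=%.4f mean_truth=%.4f p=%.4f",
       mean(sym$mean_coherence[sym$condition == "lie"]),
       mean(sym$mean_coherence[sym$condition == "truth"]), sym_test$p)

  ## (iv) classification
  ds <- frame_dataset(clips, au_set = config$aus)
  ids <- sort(unique(ds$groups))
  train_ids <- head(ids, config$n_train)
  cls_rows <- lapply(config$classifiers, function(cf) {
    rep <- train_eval_split(ds, train_ids, cf, seed = seed,
                            smote = config$smote, k = config$smote_k,
                            n_trees = config$n_trees)
    cbind(data.frame(classifier = cf, stringsAsFactors = FALSE),
          as.data.frame(rep))
  })
  classifier_table <- do.call(rbind, cls_rows)
  note("stage=classify train=%d test=%d classifiers=%s",
       length(train_ids), length(ids) - length(train_ids),
       paste(config$classifiers, collapse = ","))
  loocv <- NULL
  if (isTRUE(config$run_loocv)) {
    loocv <- leave_one_person_out(ds, config$classifiers[1], seed = seed,
                                  smote = config$smote, k = config$smote_k,
                                  n_trees = config$n_trees)
    note("stage=loocv mean_accuracy=%.2f", loocv$mean_accuracy)
  }

  structure(list(au_comparison = au_table, au_summaries = summaries,
                 episodes = eps, duration_summaries = durations,
                 duration_tests = dur_tests, symmetry = sym,
                 symmetry_test = sym_test,
                 classifier_table = classifier_table, loocv = loocv,
                 config = config, log = log),
            class = "fearleak_report")
}

#' @export
print.fearleak_report <- function(x, ...) {
  cat("== fearleak report ==\n\n-- paired AU comparison (lie vs truth), ")
  cat(sprintf("Bonferroni threshold %.3f --\n",
              attr(x$au_comparison, "alpha_bonferroni")))
  print(format(x$au_comparison, digits = 3), row.names = FALSE)
  cat(sprintf("\n-- AU%s episode durations --\n", x$config$episode_au))
  for (cond in names(x$duration_summaries)) {
    cat(cond, ": ", sep = "")
    print(x$duration_summaries[[cond]])
  }
  if (!is.null(x$duration_tests)) {
    cat("total duration (truth vs lie): ")
    print(x$duration_tests$total)
    cat("apex-to-offset (truth vs lie): ")
    print(x$duration_tests$apex_to_offset)
  }
  cat("\n-- facial symmetry (mean in-cone wavelet coherence) --\n")
  m <- tapply(x$symmetry$mean_coherence, x$symmetry$condition, mean)
  cat(sprintf("means: lie %.4f, truth %.4f; ", m[["lie"]], m[["truth"]]))
  print(x$symmetry_test)
  cat("\n-- classification (held-out participants) --\n")
  print(format(x$classifier_table, digits = 3), row.names = FALSE)
  if (!is.null(x$loocv))
    cat(sprintf("LOOCV mean accuracy: %.2f%% (range %.2f-%.2f)\n",
                x$loocv$mean_accuracy, min(x$loocv$per_fold$accuracy),
                max(x$loocv$per_fold$accuracy)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits the four tables as CSV, the scalar results as JSON, and the run
#' log as plain text.
#'
#' @param report a `fearleak_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$au_comparison,
                   file.path(dir, "au_comparison.csv"), row.names = FALSE)
  utils::write.csv(report$symmetry, file.path(dir, "symmetry.csv"),
                   row.names = FALSE)
  utils::write.csv(report$episodes, file.path(dir, "episodes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$classifier_table,
                   file.path(dir, "classifiers.csv"), row.names = FALSE)
  scalars <- list(
    alpha_bonferroni = attr(report$au_comparison, "alpha_bonferroni"),
    duration_summaries = lapply(report$duration_summaries, unclass),
    duration_tests = lapply(report$duration_tests, unclass),
    symmetry_test = unclass(report$symmetry_test),
    loocv_mean_accuracy = if (is.null(report$loocv)) NULL
                          else report$loocv$mean_accuracy)
  jsonlite::write_json(scalars, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(report$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Read a flat key:value pipeline configuration file
#'
#' Debian-control-style file (`key: value`, one per line). Recognised keys
#' mirror [pipeline_config()] arguments plus cohort fields
#' (`n_participants`, `truth_clip_seconds`, `lie_clip_seconds`,
#' `frame_rate`, `episode_rate`); `classifiers` is comma-separated.
#' Unknown keys raise an error rather than being silently dropped.
#'
#' @param path config file.
#' @param overrides named list applied on top of the file values.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  raw <- as.list(read.dcf(path)[1, ])
  raw[names(overrides)] <- overrides
  cohort_keys <- c("n_participants", "truth_clip_seconds",
                   "lie_clip_seconds", "frame_rate", "episode_rate")
  num_keys <- c("micro_ms", "macro_ms", "n_boot", "n_perm", "alpha",
                "m_comparisons", "n_train", "smote_k", "n_trees", "seed")
  lgl_keys <- c("smote", "run_loocv")
  args <- list()
  cohort_args <- list()
  for (key in names(raw)) {
    val <- raw[[key]]
    if (key %in% cohort_keys) {
      cohort_args[[key]] <- as.numeric(val)
    } else if (key %in% num_keys) {
      args[[key]] <- as.numeric(val)
    } else if (key %in% lgl_keys) {
      args[[key]] <- as.logical(val)
    } else if (key == "classifiers") {
      args[[key]] <- trimws(strsplit(val, ",")[[1]])
    } else if (key %in% c("mode", "manifest", "au_set", "episode_au")) {
      args[[key]] <- val
    } else {
      fl_stop("InvalidSpec", "unknown config key: %s", key)
    }
  }
  if (length(cohort_args)) args$cohort <- do.call(cohort_spec, cohort_args)
  do.call(pipeline_config, args)
}
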