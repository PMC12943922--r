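#' Run the full analysis pipeline
#'
#' Chains the stages end to end: (optionally) simulate a cohort, extract
#' per-epoch SSA + Hilbert features per recording, align them to the coarse
#' grid with BIS, take the cohort median, fit the full 12-parameter BIS
#' regression, reduce it to the significant parameters, and summarise the
#' parameters per anesthetic phase. All artifacts are written as TSV under
#' `out_dir` (`features/`, `models/`, `summaries/`, `logs/`); rerunning
#' with the same configuration and seed reproduces them byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param recordings List of [eeg_recording()]s, or `NULL` to simulate.
#' @param synthetic Config for simulation when `recordings` is `NULL`
#'   (default [synthetic_config()]).
#' @param seed Seed for the simulated cohort.
#' @param cfg [epoching_config()].
#' @param K,grouping,trim_seconds Passed to [epoch_features()].
#' @param grid_seconds,alpha,span_seconds Feature-grid step, selection
#'   level, phase-summary span.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `tables` (per-recording aligned feature
#'   tables), `cohort` (median table), `model_full`, `model_reduced`,
#'   `summary` (phase summary), `predicted` (data frame `t`, `BIS`,
#'   `predicted`).
#' @export
run_pipeline <- function(out_dir, recordings = NULL,
                         synthetic = synthetic_config(), seed = 1L,
                         cfg = epoching_config(), K = 256L, grouping = NULL,
                         trim_seconds = 0, grid_seconds = 8, alpha = 0.05,
                         span_seconds = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  for (d in c("", "features", "models", "summaries", "logs"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "logs", "pipeline.log")
  log_lines <- character(0)
  log_add <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (is.null(recordings)) {
    say("simulating %d recordings (seed %d)", synthetic$n_recordings, seed)
    cohort <- generate_cohort(synthetic, base_seed = seed)
    recordings <- lapply(cohort, `[[`, "recording")
    log_add("simulate: n=%d seed=%d duration=%gs fs=%gHz",
            length(recordings), seed, synthetic$duration_s, synthetic$fs)
  }
  span <- span_seconds %||% recording_duration(recordings[[1]])

  tables <- lapply(recordings, function(rec) {
    say("features: %s", rec$recording_id)
    feat <- epoch_features(rec, cfg = cfg, K = K, grouping = grouping,
                           trim_seconds = trim_seconds)
    tab <- align_to_grid(feat, grid_seconds = grid_seconds, bis = rec$bis,
                         span_seconds = span)
    n_missing <- sum(is.na(tab[, setdiff(names(tab), "t")]))
    log_add("features: %s epochs=%d grid_rows=%d missing_cells=%d",
            rec$recording_id, nrow(feat), nrow(tab), n_missing)
    write_feature_table(tab, file.path(out_dir, "features",
                                       paste0(rec$recording_id, ".tsv")))
    tab
  })

  cohort_tab <- cohort_median(tables)
  write_feature_table(cohort_tab,
                      file.path(out_dir, "features", "cohort-median.tsv"))

  say("fitting BIS regression (n = %d rows)", nrow(cohort_tab))
  model_full <- fit_mlr(cohort_tab)
  model_red <- tryCatch(select_significant(model_full, cohort_tab,
                                           alpha = alpha),
                        ssaeeg_empty_model = function(e) NULL)
  log_add("regress: full R2=%.4f MAE=%.4f RMSE=%.4f n=%d dropped=%d",
          model_full$r2, model_full$mae, model_full$rmse,
          model_full$n_obs, model_full$n_dropped)
  if (!is.null(model_red))
    log_add("regress: reduced (%d params) R2=%.4f MAE=%.4f RMSE=%.4f",
            length(model_red$included_params), model_red$r2, model_red$mae,
            model_red$rmse)

  coef_tab <- function(m) data.frame(param = m$included_params,
                                     coefficient = unname(m$coefficients),
                                     p_value = unname(m$p_values))
  write_feature_table(coef_tab(model_full),
                      file.path(out_dir, "models", "coefficients-full.tsv"))
  metrics <- data.frame(
    model = c("full", if (!is.null(model_red)) "reduced"),
    n_params = c(length(model_full$included_params),
                 if (!is.null(model_red)) length(model_red$included_params)),
    r2 = c(model_full$r2, if (!is.null(model_red)) model_red$r2),
    mae = c(model_full$mae, if (!is.null(model_red)) model_red$mae),
    rmse = c(model_full$rmse, if (!is.null(model_red)) model_red$rmse),
    intercept = c(model_full$intercept,
                  if (!is.null(model_red)) model_red$intercept),
    n = c(model_full$n_obs, if (!is.null(model_red)) model_red$n_obs))
  write_feature_table(metrics, file.path(out_dir, "models", "metrics.tsv"))
  if (!is.null(model_red))
    write_feature_table(coef_tab(model_red),
                        file.path(out_dir, "models",
                                  "coefficients-reduced.tsv"))

  pred_model <- model_red %||% model_full
  predicted <- data.frame(t = cohort_tab$t, BIS = cohort_tab$BIS,
                          predicted = predict_bis(pred_model, cohort_tab))
  write_feature_table(predicted,
                      file.path(out_dir, "models", "predicted-bis.tsv"))

  summ <- phase_summary(cohort_tab, span_seconds = span)
  write_feature_table(summ,
                      file.path(out_dir, "summaries", "phase-summary.tsv"))
  writeLines(log_lines, log_file)
  say("done: %s", out_dir)
  invisible(list(tables = tables, cohort = cohort_tab,
                 model_full = model_full, model_reduced = model_red,
                 summary = summ, predicted = predicted))
}
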