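feature_params <- function() c(paste0("CF", 1:6), paste0("TP", 1:6))

#' Per-epoch 12-parameter feature table
#'
#' Runs the SSA + Hilbert pipeline over every epoch of a recording and
#' returns one row per epoch (indexed at the epoch center) with the center
#' frequency `CF1..CF6` (Hz) and total power `TP1..TP6` (dB) of the six
#' IMFs. Silent IMFs give `NA` cells; an all-zero epoch gives an all-`NA`
#' row.
#'
#' @param rec An [eeg_recording()].
#' @param cfg An [epoching_config()].
#' @param K Trajectory-matrix window length in samples (default 256).
#' @param grouping Eigentriple `grouping`, or `NULL` for the default.
#' @param trim_seconds,weighted Passed to [hilbert_features()].
#' @param epoch_filter Optional function `(t_center) -> logical`; epochs for
#'   which it returns FALSE are skipped (e.g. to restrict analysis to
#'   selected anesthetic phases).
#' @return Data frame with columns `t`, `CF1..CF6`, `TP1..TP6`; attribute
#'   `recording_id`.
#' @export
epoch_features <- function(rec, cfg = epoching_config(), K = 256L,
                           grouping = NULL, trim_seconds = 0,
                           weighted = TRUE, epoch_filter = NULL) {
  epochs <- segment_epochs(rec, cfg)
  if (!is.null(epoch_filter))
    epochs <- Filter(function(e) isTRUE(epoch_filter(e$t_center)), epochs)
  rows <- lapply(epochs, function(e) {
    dec <- ssa_decompose_epoch(e, K = K, grouping = grouping)
    hf <- hilbert_features(dec, trim_seconds = trim_seconds,
                           weighted = weighted)
    row <- c(e$t_center, hf$cf, hf$tp_db)
    names(row) <- c("t", paste0("CF", hf$imf), paste0("TP", hf$imf))
    row
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "recording_id") <- rec$recording_id
  out
}

#' Aggregate epoch features onto a coarse time grid
#'
#' Collapses the epoch-grid feature table onto a regular grid (8 s by
#' default, the cadence of processed depth-of-anesthesia parameters): each
#' grid row takes the median over the epochs whose centers fall in
#' `[t, t + grid)`, ignoring missing cells. A sparse BIS series is matched
#' to each grid time at the nearest timestamp within half a grid step.
#'
#' @param features Epoch-grid table from [epoch_features()].
#' @param grid_seconds Grid step in seconds (default 8).
#' @param bis Optional data frame `time`, `bis` (e.g. `rec$bis`).
#' @param span_seconds Span to cover; defaults to the last epoch center
#'   rounded up to a whole grid step.
#' @return Data frame `t`, `CF1..TP6` and (when `bis` is given) `BIS`;
#'   grid cells containing no epoch give all-`NA` rows.
#' @export
align_to_grid <- function(features, grid_seconds = 8, bis = NULL,
                          span_seconds = NULL) {
  stopifnot(is.data.frame(features), nrow(features) > 0)
  span <- span_seconds %||% (ceiling(max(features$t) / grid_seconds) *
                             grid_seconds)
  t_grid <- seq(0, span - grid_seconds, by = grid_seconds)
  cols <- setdiff(names(features), "t")
  cell <- findInterval(features$t, c(t_grid, span))
  agg <- matrix(NA_real_, length(t_grid), length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_along(t_grid)) {
    sub <- features[cell == i, cols, drop = FALSE]
    if (nrow(sub))
      agg[i, ] <- vapply(sub, function(v)
        if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE),
        numeric(1))
  }
  out <- data.frame(t = t_grid, agg, check.names = FALSE)
  if (!is.null(bis) && nrow(bis)) {
    out$BIS <- vapply(t_grid, function(tt) {
      d <- abs(bis$time - tt)
      j <- which.min(d)
      if (d[j] <= grid_seconds / 2) bis$bis[j] else NA_real_
    }, numeric(1))
  }
  attr(out, "recording_id") <- attr(features, "recording_id")
  out
}

#' Cellwise median across recordings
#'
#' Collapses per-recording feature tables that share a time grid into one
#' cohort-median table (the representation used for the cohort-level BIS
#' regression): every cell is the median of the corresponding cells,
#' ignoring missing values.
#'
#' @param tables Non-empty list of aligned feature tables (same `t` grid
#'   and columns).
#' @return One feature table; attribute `recording_id = "cohort-median"`.
#' @export
cohort_median <- function(tables) {
  if (!length(tables)) ssa_stop("no feature tables supplied", "empty_input")
  t0 <- tables[[1]]$t
  for (tab in tables)
    if (!isTRUE(all.equal(tab$t, t0)))
      ssa_stop("feature tables do not share a time grid", "config")
  cols <- setdiff(Reduce(intersect, lapply(tables, names)), "t")
  out <- data.frame(t = t0)
  for (cl in cols) {
    m <- vapply(tables, function(tab) tab[[cl]], numeric(length(t0)))
    out[[cl]] <- apply(m, 1, function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  }
  attr(out, "recording_id") <- "cohort-median"
  out
}
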