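#' EEG recording container
#'
#' Bundles a uniformly sampled voltage series with its sampling rate and any
#' sparse, timestamped processed parameters (BIS, SEF95) recorded alongside.
#'
#' @param samples Numeric vector of EEG voltages (microvolts). Must be finite.
#' @param fs Sampling rate in Hz (default 128, the rate of BIS-monitor
#'   exports this package targets).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param bis Optional data frame with columns `time` (s) and `bis`
#'   (unitless, 0-100) holding a sparse depth-of-anesthesia index.
#' @param sef95 Optional data frame with columns `time` (s) and `sef95` (Hz).
#' @param recording_id Character label for provenance tracking.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs = 128, start_time = 0,
                          bis = NULL, sef95 = NULL,
                          recording_id = "recording") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    ssa_stop("recording has no samples", "empty_input")
  if (!all(is.finite(samples)))
    ssa_stop("EEG samples must be finite", "numeric")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    ssa_stop("fs must be a single positive number", "config")
  span <- c(start_time, start_time + length(samples) / fs)
  check_sparse <- function(df, value_col) {
    if (is.null(df)) return(NULL)
    stopifnot(is.data.frame(df), all(c("time", value_col) %in% names(df)))
    df <- df[, c("time", value_col)]
    if (nrow(df) && (min(df$time) < span[1] - 1e-9 ||
                     max(df$time) > span[2] + 1e-9))
      ssa_stop(sprintf("%s timestamps fall outside the recording span",
                       value_col), "config")
    df
  }
  structure(
    list(samples = samples, fs = fs, start_time = start_time,
         bis = check_sparse(bis, "bis"), sef95 = check_sparse(sef95, "sef95"),
         recording_id = as.character(recording_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording '%s': %d samples @ %g Hz (%.1f s)%s>\n",
              x$recording_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (!is.null(x$bis)) sprintf(", %d BIS values", nrow(x$bis))
              else ""))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$fs

#' Epoching configuration
#'
#' Controls how a recording is sliced into overlapping analysis epochs. The
#' defaults reproduce the analysis conditions this package is built around:
#' 3-s epochs at 128 Hz (384 samples) advanced by 2 s, so consecutive epochs
#' share 1 s. `embed_length` is the number of leading samples of each epoch
#' actually embedded in the trajectory matrix; the default (one less than the
#' epoch length, 383 at the default rate) makes the matrix exactly
#' 128 x 256 with the default window `K = 256`.
#'
#' @param epoch_seconds Epoch length in seconds (default 3).
#' @param hop_seconds Epoch advance in seconds (default 2; must satisfy
#'   `0 < hop_seconds <= epoch_seconds`).
#' @param embed_length Number of samples embedded per epoch, or `NULL` for
#'   `round(epoch_seconds * fs) - 1` resolved at segmentation time.
#'
#' @return An `epoching_config` list.
#' @export
epoching_config <- function(epoch_seconds = 3, hop_seconds = 2,
                            embed_length = NULL) {
  if (!(hop_seconds > 0 && hop_seconds <= epoch_seconds))
    ssa_stop("need 0 < hop_seconds <= epoch_seconds", "config")
  structure(list(epoch_seconds = epoch_seconds, hop_seconds = hop_seconds,
                 embed_length = embed_length),
            class = "epoching_config")
}

#' Read a tab-separated EEG recording
#'
#' Reads one-sample-per-row TSV exports (the dialect of public BIS-monitor
#' dumps): tab-delimited, optional single header line, decimal point, no
#' quoting. Columns are picked by name or 0-based index. Non-numeric cells in
#' optional columns (e.g. BIS printed only once per second) become `NA` and
#' are dropped from the sparse series; non-numeric cells in the EEG column
#' are an error.
#'
#' @param path Path to a .tsv file.
#' @param eeg_col EEG column: name (character) or 0-based index (numeric).
#'   Default 0 (first column).
#' @param bis_col,sef95_col Optional columns for the processed parameters,
#'   same addressing. Sparse: rows with non-numeric/missing cells are
#'   dropped; timestamps are the row times (`row / fs`).
#' @param fs Sampling rate in Hz of the EEG rows (default 128).
#' @param recording_id Label; defaults to the file name.
#'
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, eeg_col = 0, bis_col = NULL,
                           sef95_col = NULL, fs = 128,
                           recording_id = NULL) {
  if (!file.exists(path)) ssa_stop(paste("no such file:", path), "io")
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) ssa_stop(paste("empty file:", path), "empty_input")
  has_header <- any(is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]]))))
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          quote = "", comment.char = "",
                          colClasses = "character",
                          check.names = FALSE)
  if (nrow(df) == 0L) ssa_stop(paste("no data rows in", path), "empty_input")

  pick <- function(col, what) {
    if (is.null(col)) return(NULL)
    if (is.character(col)) {
      if (!col %in% names(df))
        ssa_stop(sprintf("%s column '%s' not found (columns: %s)", what, col,
                         paste(names(df), collapse = ", ")), "format")
      df[[col]]
    } else {
      idx <- as.integer(col) + 1L
      if (idx < 1L || idx > ncol(df))
        ssa_stop(sprintf("%s column index %s out of range (file has %d columns)",
                         what, col, ncol(df)), "format")
      df[[idx]]
    }
  }
  eeg <- suppressWarnings(as.numeric(pick(eeg_col, "EEG")))
  if (all(is.na(eeg)))
    ssa_stop("EEG column contains no numeric values", "format")
  if (anyNA(eeg))
    ssa_stop("EEG column contains non-numeric cells", "format")

  sparse <- function(col, what, value_col) {
    raw <- pick(col, what)
    if (is.null(raw)) return(NULL)
    v <- suppressWarnings(as.numeric(raw))
    keep <- which(!is.na(v))
    if (!length(keep)) return(NULL)
    out <- data.frame(time = (keep - 1L) / fs, v = v[keep])
    names(out)[2] <- value_col
    out
  }
  eeg_recording(eeg, fs = fs,
                bis = sparse(bis_col, "BIS", "bis"),
                sef95 = sparse(sef95_col, "SEF95", "sef95"),
                recording_id = recording_id %||% basename(path))
}

#' Write a recording as TSV
#'
#' One sample per row, tab-delimited, with a header. Sparse BIS/SEF95 values
#' are placed on their nearest sample row (empty cells elsewhere), so a file
#' written here round-trips through [read_recording()].
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- length(rec$samples)
  cols <- list(eeg = format(rec$samples, digits = 15, trim = TRUE,
                            scientific = FALSE))
  for (nm in c("bis", "sef95")) {
    sp <- rec[[nm]]
    if (is.null(sp)) next
    col <- rep("", n)
    idx <- pmin(pmax(round(sp$time * rec$fs) + 1L, 1L), n)
    col[idx] <- format(sp[[nm]], digits = 15, trim = TRUE, scientific = FALSE)
    cols[[nm]] <- col
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(cols), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(cols), sep = "\t")), con)
  invisible(path)
}

#' Slice a recording into overlapping epochs
#'
#' Epochs start at `t = 0, hop, 2*hop, ...` relative to the recording start;
#' each carries exactly `round(epoch_seconds * fs)` samples and a trailing
#' partial window is discarded.
#'
#' @param rec An [eeg_recording()].
#' @param cfg An [epoching_config()].
#' @return List of `epoch` objects, each with `values`, `fs`, `t_start`,
#'   `t_center`, `index` and `embed_length`.
#' @export
segment_epochs <- function(rec, cfg = epoching_config()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(cfg, "epoching_config"))
  n_epoch <- round(cfg$epoch_seconds * rec$fs)
  hop <- round(cfg$hop_seconds * rec$fs)
  n <- length(rec$samples)
  if (n < n_epoch)
    ssa_stop(sprintf("recording (%d samples) shorter than one epoch (%d)",
                     n, n_epoch), "empty_input")
  embed <- cfg$embed_length %||% (n_epoch - 1L)
  if (embed > n_epoch)
    ssa_stop("embed_length exceeds the epoch length", "config")
  starts <- seq.int(0L, n - n_epoch, by = hop)
  lapply(seq_along(starts), function(i) {
    s0 <- starts[i]
    structure(
      list(values = rec$samples[(s0 + 1L):(s0 + n_epoch)],
           fs = rec$fs,
           t_start = rec$start_time + s0 / rec$fs,
           t_center = rec$start_time + s0 / rec$fs + cfg$epoch_seconds / 2,
           index = i,
           embed_length = embed),
      class = "epoch")
  })
}

#' Write a feature table as TSV
#'
#' @param table A feature table (data frame with a `t` column and CF/TP
#'   columns) as produced by [epoch_features()] or [align_to_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    ssa_stop("feature table is empty; nothing to write", "empty_input")
  utils::write.table(format(table, digits = 15, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) ssa_stop(paste("no such file:", path), "io")
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
}
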