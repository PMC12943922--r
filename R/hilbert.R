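#' Analytic signal of a real series
#'
#' FFT construction of `z(t) = x(t) + i H[x](t)`: the spectrum is doubled on
#' positive frequencies, zeroed on negative frequencies, and left unchanged
#' at DC (and Nyquist for even lengths). The real part of the result equals
#' the input; the imaginary part is the discrete Hilbert transform.
#'
#' @param x Numeric vector, length >= 8, finite.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) ssa_stop("series too short for an analytic signal", "dimension")
  if (!all(is.finite(x))) ssa_stop("series must be finite", "numeric")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  complex(real = x, imaginary = Im(z))  # keep Re(z) exactly the input
}

#' Instantaneous amplitude (envelope)
#'
#' @param z Complex analytic signal.
#' @return `|z|`, elementwise (same units as the input signal).
#' @export
instantaneous_amplitude <- function(z) Mod(z)

#' Instantaneous frequency from an analytic signal
#'
#' Derivative of the unwrapped analytic phase, in Hz: central differences on
#' interior samples, one-sided at the two ends. Samples where the envelope
#' falls below `floor_ratio * max(|z|)` (where the phase is numerically
#' meaningless) and samples whose estimate falls outside `[0, fs/2]` are
#' returned as `NA` rather than clamped.
#'
#' @param z Complex analytic signal.
#' @param fs Sampling rate (Hz).
#' @param floor_ratio Amplitude floor relative to the envelope maximum
#'   (default 1e-6).
#' @return Numeric vector of instantaneous frequencies (Hz) with `NA` where
#'   undefined.
#' @export
instantaneous_frequency <- function(z, fs, floor_ratio = 1e-6) {
  ia <- Mod(z)
  if (all(ia == 0))
    ssa_stop("zero signal has no instantaneous frequency", "degenerate_input")
  n <- length(z)
  phi <- signal::unwrap(Arg(z))
  f <- numeric(n)
  f[2L:(n - 1L)] <- (phi[3L:n] - phi[1L:(n - 2L)]) * fs / (4 * pi)
  f[1L] <- (phi[2L] - phi[1L]) * fs / (2 * pi)
  f[n] <- (phi[n] - phi[n - 1L]) * fs / (2 * pi)
  f[ia < floor_ratio * max(ia)] <- NA_real_
  f[!is.na(f) & (f < 0 | f > fs / 2)] <- NA_real_
  f
}

#' Hilbert analysis of one IMF
#'
#' Convenience constructor bundling the analytic signal, instantaneous
#' amplitude and instantaneous frequency of a real IMF series.
#'
#' @param imf Numeric series (microvolts).
#' @param fs Sampling rate (Hz).
#' @param trim_seconds Seconds to discard from each end when later computing
#'   scalar features (default 0; Hilbert edge effects on short epochs can
#'   bias the center frequency).
#' @param floor_ratio Passed to [instantaneous_frequency()].
#' @return An `analytic_imf`: list with `imf`, `z`, `ia`, `if_hz`, `fs`,
#'   `active` (logical mask of samples inside the trim).
#' @export
hilbert_imf <- function(imf, fs, trim_seconds = 0, floor_ratio = 1e-6) {
  z <- analytic_signal(imf)
  ia <- instantaneous_amplitude(z)
  if_hz <- if (all(ia == 0)) rep(NA_real_, length(imf))
           else instantaneous_frequency(z, fs, floor_ratio)
  n <- length(imf)
  k <- min(round(trim_seconds * fs), floor((n - 1) / 2))
  active <- rep(TRUE, n)
  if (k > 0) active[c(seq_len(k), (n - k + 1L):n)] <- FALSE
  structure(list(imf = as.numeric(imf), z = z, ia = ia, if_hz = if_hz,
                 fs = fs, active = active),
            class = "analytic_imf")
}

#' Marginal Hilbert spectrum of an IMF
#'
#' Accumulates the squared instantaneous amplitude of every sample with a
#' defined instantaneous frequency into uniform frequency bins from 0 to
#' Nyquist: the time-integrated Hilbert amplitude spectrum. Bins are
#' centered on multiples of `bin_hz` (so a tone at a round frequency falls
#' inside one bin rather than on an edge). Total binned power equals the
#' summed `ia^2` of the included samples.
#'
#' @param aimf An [hilbert_imf()] result.
#' @param bin_hz Bin width in Hz (default 0.5).
#' @return A `marginal_spectrum`: data frame with `freq` (bin center, Hz)
#'   and `power` (summed ia^2, microvolts^2).
#' @export
marginal_spectrum <- function(aimf, bin_hz = 0.5) {
  stopifnot(inherits(aimf, "analytic_imf"))
  ok <- aimf$active & !is.na(aimf$if_hz)
  if (!any(ok))
    ssa_stop("no samples with a defined instantaneous frequency",
             "degenerate_input")
  centers <- seq(0, aimf$fs / 2 + bin_hz / 2, by = bin_hz)
  bin <- pmin(round(aimf$if_hz[ok] / bin_hz), length(centers) - 1L) + 1L
  power <- numeric(length(centers))
  acc <- rowsum(aimf$ia[ok]^2, bin)
  power[as.integer(rownames(acc))] <- acc
  structure(data.frame(freq = centers, power = power),
            class = c("marginal_spectrum", "data.frame"))
}

#' Center frequency of an IMF (Hz)
#'
#' The power-weighted mean instantaneous frequency, `CF = sum(ia^2 * IF) /
#' sum(ia^2)` over samples with a defined IF — the first moment of the
#' marginal Hilbert spectrum in the limit of vanishing bin width. With
#' `weighted = FALSE` the unweighted mean of the defined IF samples is
#' returned instead.
#'
#' @param aimf An [hilbert_imf()] result.
#' @param weighted Weight by `ia^2` (default TRUE).
#' @return CF in Hz, or `NA` for a silent IMF.
#' @export
center_frequency <- function(aimf, weighted = TRUE) {
  stopifnot(inherits(aimf, "analytic_imf"))
  ok <- aimf$active & !is.na(aimf$if_hz)
  if (!any(ok)) return(NA_real_)
  if (!weighted) return(mean(aimf$if_hz[ok]))
  w <- aimf$ia[ok]^2
  if (sum(w) == 0) return(NA_real_)
  sum(w * aimf$if_hz[ok]) / sum(w)
}

#' Total power of an IMF
#'
#' Mean squared instantaneous amplitude over the epoch (microvolts^2), so
#' the value does not scale with epoch length, reported in decibels via
#' `dB = 10 log10 P`.
#'
#' @param aimf An [hilbert_imf()] result.
#' @return `total_power_db`: TP in dB (NA for a silent IMF);
#'   `total_power_uv2`: raw mean power in microvolts^2.
#' @export
total_power_db <- function(aimf) {
  p <- total_power_uv2(aimf)
  if (p <= 0) NA_real_ else 10 * log10(p)
}

#' @rdname total_power_db
#' @export
total_power_uv2 <- function(aimf) {
  stopifnot(inherits(aimf, "analytic_imf"))
  mean(aimf$ia[aimf$active]^2)
}

#' Per-IMF scalar features of one SSA decomposition
#'
#' Applies [hilbert_imf()] to each IMF of an [ssa_decompose_epoch()] result
#' and extracts the center frequency (Hz) and total power (dB) of each.
#'
#' @param decomp An `ssa_decomposition`.
#' @param fs Sampling rate (Hz); defaults to the decomposition's own.
#' @param trim_seconds,weighted Passed through to [hilbert_imf()] /
#'   [center_frequency()].
#' @return Data frame with one row per IMF: `imf`, `cf`, `tp_db`, `tp_uv2`.
#' @export
hilbert_features <- function(decomp, fs = NULL, trim_seconds = 0,
                             weighted = TRUE) {
  stopifnot(inherits(decomp, "ssa_decomposition"))
  fs <- fs %||% decomp$fs
  if (is.na(fs)) ssa_stop("sampling rate unknown; pass fs", "config")
  res <- lapply(seq_len(ncol(decomp$imfs)), function(j) {
    a <- hilbert_imf(decomp$imfs[, j], fs, trim_seconds)
    data.frame(imf = j, cf = center_frequency(a, weighted),
               tp_db = total_power_db(a), tp_uv2 = total_power_uv2(a))
  })
  do.call(rbind, res)
}
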