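#' Configuration of the synthetic anesthesia-like EEG generator
#'
#' Describes a 10-minute single-channel frontal EEG emerging from
#' sevoflurane-like anesthesia as three equal contiguous phases
#' (maintenance, transition, emergence) whose parameters are cross-faded
#' over `fade_seconds`. Each phase mixes: a slow delta oscillation
#' (`delta_amp` peak microvolts at `delta_freq` Hz), Hann-windowed alpha
#' spindle bursts (`spindle_rate` per minute, `spindle_dur` s, carrier
#' `alpha_freq` Hz, peak `alpha_amp` microvolts), broadband theta-range
#' activity (`theta_amp` microvolts RMS over `theta_band` Hz, the diffuse
#' 4-12 Hz power that dominates anesthetized frontal EEG between the slow
#' and spindle rhythms), band-limited beta noise
#' (`beta_amp` microvolts RMS over `beta_band` Hz), and a 1/f^2
#' power-spectrum background (`noise_sd` microvolts RMS over 0.5-64 Hz,
#' mirroring the steep spectral decay of anesthetized frontal EEG) plus a
#' small white measurement-noise floor (0.3 microvolts RMS, the noise level
#' of clinical frontal-EEG acquisition). Maintenance is delta/alpha-dominant
#' with dense spindles; transition attenuates the alpha and grows beta
#' activity; emergence is low-amplitude and beta-dominant. On top of the
#' phase schedule, the delta, alpha and beta amplitudes each carry an
#' independent slow lognormal modulation (`mod_sd` log-units, `mod_tau_s`
#' correlation time) emulating the minute-scale waxing and waning of
#' anesthetic depth; this gives the band powers partially independent
#' variation, which is what makes the BIS regression identifiable.
#'
#' The accompanying BIS-like index is a clipped affine function of the
#' log10 per-second band powers (delta 0.5-4, alpha 8-13, beta 15-30 Hz)
#' of the generated signal, plus Gaussian noise; with the default weights
#' it rises monotonically in expectation from about 40 in maintenance to
#' about 90 at emergence, the clinically expected course.
#'
#' @param duration_s Recording length (default 600 s).
#' @param fs Sampling rate (default 128 Hz).
#' @param n_recordings Cohort size (default 10).
#' @param phases Named list of three per-phase parameter lists; see
#'   Details/defaults.
#' @param fade_seconds Cross-fade length at phase boundaries (default 10).
#' @param bis_model List `intercept`, `w_delta`, `w_alpha`, `w_beta`,
#'   `noise_sd` for the BIS-like index.
#' @param jitter Relative amplitude/frequency jitter across cohort
#'   recordings (default 0.1).
#' @param mod_sd,mod_tau_s Slow amplitude-modulation depth (log-units,
#'   default 0.25) and correlation time (default 20 s).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(duration_s = 600, fs = 128, n_recordings = 10,
                             phases = NULL, fade_seconds = 10,
                             bis_model = NULL, jitter = 0.1,
                             mod_sd = 0.25, mod_tau_s = 20) {
  phases <- phases %||% list(
    maintenance = list(delta_amp = 25, delta_freq = 1.2,
                       theta_amp = 4, theta_band = c(4, 12),
                       alpha_amp = 12, alpha_freq = 11,
                       spindle_rate = 40, spindle_dur = 1.0,
                       beta_amp = 0.5, beta_band = c(15, 30), noise_sd = 3),
    transition  = list(delta_amp = 12, delta_freq = 1.0,
                       theta_amp = 2.5, theta_band = c(4, 12),
                       alpha_amp = 6, alpha_freq = 10,
                       spindle_rate = 25, spindle_dur = 0.8,
                       beta_amp = 4, beta_band = c(15, 30), noise_sd = 3),
    emergence   = list(delta_amp = 4, delta_freq = 0.8,
                       theta_amp = 1, theta_band = c(4, 12),
                       alpha_amp = 1.5, alpha_freq = 10,
                       spindle_rate = 8, spindle_dur = 0.6,
                       beta_amp = 7, beta_band = c(15, 30), noise_sd = 3))
  bis_model <- bis_model %||% list(intercept = 78, w_delta = -14,
                                   w_alpha = -10, w_beta = 20, noise_sd = 2)
  for (ph in phases) {
    if (any(unlist(ph[c("delta_amp", "alpha_amp", "beta_amp",
                        "noise_sd", "spindle_rate")]) < 0))
      ssa_stop("synthetic amplitudes/rates must be >= 0", "config")
    if (ph$beta_band[1] >= ph$beta_band[2] || ph$beta_band[2] > fs / 2)
      ssa_stop("invalid beta band edges", "config")
  }
  structure(list(duration_s = duration_s, fs = fs,
                 n_recordings = n_recordings, phases = phases,
                 fade_seconds = fade_seconds, bis_model = bis_model,
                 jitter = jitter, mod_sd = mod_sd, mod_tau_s = mod_tau_s),
            class = "synthetic_config")
}

## per-sample phase weights: 3 plateaus with linear cross-fades of
## fade_seconds centred on the phase boundaries; rows sum to 1
phase_weights <- function(t, duration_s, fade_seconds) {
  b <- duration_s * c(1, 2) / 3
  half <- fade_seconds / 2
  ramp <- function(tb) pmin(1, pmax(0, (t - (tb - half)) / fade_seconds))
  r1 <- ramp(b[1]); r2 <- ramp(b[2])
  cbind(maintenance = 1 - r1, transition = r1 - r2, emergence = r2)
}

## 1/f^2 power-shaped Gaussian background over [f_lo, f_hi], unit RMS;
## the steep spectral decay typical of anesthetized frontal EEG
background_noise <- function(n, fs, f_lo = 0.5, f_hi = 64) {
  white <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  shape <- ifelse(f >= f_lo & f <= f_hi, 1 / pmax(f, f_lo), 0)
  x <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

## slow lognormal amplitude modulation: smoothed Gaussian noise with
## correlation time tau_s, sd in log-units, mean multiplier ~1
slow_modulation <- function(n, fs, sd_log, tau_s) {
  if (sd_log <= 0) return(rep(1, n))
  m <- stats::filter(stats::rnorm(n), exp(-1 / (tau_s * fs)), "recursive")
  exp(sd_log * as.numeric(m) / stats::sd(m))
}

## band-limited Gaussian noise, unit RMS
band_noise <- function(n, fs, band) {
  white <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, fs - f)
  keep <- f >= band[1] & f <= band[2]
  x <- Re(stats::fft(stats::fft(white) * keep, inverse = TRUE)) / n
  x / stats::sd(x)
}

## mean power (microvolts^2) in a frequency band of one window, by periodogram
band_power <- function(x, fs, band) {
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / n^2          # two-sided mean-power spectrum
  f <- (seq_len(n) - 1L) * fs / n
  half <- f <= fs / 2
  p <- 2 * spec
  p[1] <- spec[1]
  sum(p[half & f >= band[1] & f <= band[2]])
}

#' Generate one synthetic anesthesia-like recording
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param recording_id Label for the embedded [eeg_recording()].
#' @return A `synthetic_recording`: list with `recording` (an
#'   [eeg_recording()] whose `bis` holds the programmed index), `true_bis`
#'   (dense data frame `time`, `bis`), and `ground_truth` (per-second band
#'   powers `time`, `p_delta`, `p_alpha`, `p_beta` used to build the index).
#' @export
generate_recording <- function(cfg = synthetic_config(), seed = 1L,
                               recording_id = sprintf("synth-%d", seed)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(as.integer(seed))
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  W <- phase_weights(t, cfg$duration_s, cfg$fade_seconds)
  pp <- function(field) vapply(cfg$phases, function(ph) ph[[field]],
                               numeric(1))
  mix <- function(field) as.vector(W %*% pp(field))

  mod <- function() slow_modulation(n, fs, cfg$mod_sd, cfg$mod_tau_s)

  # delta: slow oscillation with phase-integrated time-varying frequency
  delta <- mix("delta_amp") * mod() *
    sin(2 * pi * cumsum(mix("delta_freq")) / fs + stats::runif(1, 0, 2 * pi))

  # alpha spindles: inhomogeneous Poisson events, Hann-windowed bursts
  rate_t <- mix("spindle_rate") / 60          # events per second
  lambda_max <- max(rate_t)
  alpha <- numeric(n)
  if (lambda_max > 0) {
    n_cand <- stats::rpois(1, lambda_max * cfg$duration_s)
    starts <- sort(stats::runif(n_cand, 0, cfg$duration_s))
    keep <- stats::runif(n_cand) <
      rate_t[pmin(floor(starts * fs) + 1L, n)] / lambda_max
    amp_t <- mix("alpha_amp") * mod(); f_t <- mix("alpha_freq")
    dur_t <- mix("spindle_dur")
    for (s0 in starts[keep]) {
      i0 <- floor(s0 * fs) + 1L
      dur <- dur_t[i0] * stats::runif(1, 0.8, 1.2)
      len <- max(round(dur * fs), 8L)
      idx <- i0:min(i0 + len - 1L, n)
      env <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / len))   # Hann
      fcar <- f_t[i0] * stats::runif(1, 0.95, 1.05)
      alpha[idx] <- alpha[idx] + amp_t[i0] * stats::runif(1, 0.8, 1.2) *
        env * sin(2 * pi * fcar * (t[idx] - s0) + stats::runif(1, 0, 2 * pi))
    }
  }

  theta <- mix("theta_amp") * mod() *
    band_noise(n, fs, cfg$phases[[1]]$theta_band)
  beta <- mix("beta_amp") * mod() *
    band_noise(n, fs, cfg$phases[[1]]$beta_band)
  background <- mix("noise_sd") * background_noise(n, fs)
  floor_noise <- 0.3 * stats::rnorm(n)
  eeg <- delta + theta + alpha + beta + background + floor_noise

  # BIS-like index: affine in log10 per-second band powers, clipped to 0-100
  n_win <- floor(cfg$duration_s)
  gt <- t(vapply(seq_len(n_win), function(w) {
    x <- eeg[((w - 1L) * fs + 1L):(w * fs)]
    c(p_delta = band_power(x, fs, c(0.5, 4)),
      p_alpha = band_power(x, fs, c(8, 13)),
      p_beta = band_power(x, fs, c(15, 30)))
  }, numeric(3)))
  bm <- cfg$bis_model
  eps <- 1e-3                                  # power floor for the logs
  bis_raw <- bm$intercept +
    bm$w_delta * log10(pmax(gt[, "p_delta"], eps)) +
    bm$w_alpha * log10(pmax(gt[, "p_alpha"], eps)) +
    bm$w_beta * log10(pmax(gt[, "p_beta"], eps)) +
    stats::rnorm(n_win, 0, bm$noise_sd)
  bis <- pmin(100, pmax(0, bis_raw))
  true_bis <- data.frame(time = seq_len(n_win) - 0.5, bis = bis)

  rec <- eeg_recording(eeg, fs = fs, bis = true_bis,
                       recording_id = recording_id)
  structure(list(recording = rec, true_bis = true_bis,
                 ground_truth = data.frame(time = true_bis$time, gt)),
            class = "synthetic_recording")
}

#' Generate a synthetic cohort
#'
#' Draws `cfg$n_recordings` recordings with per-recording jitter (default
#' +/-10%) on every phase amplitude and frequency; the BIS model is shared
#' across the cohort. All randomness flows from `base_seed` through one
#' seed tree (base seed -> per-recording seeds -> per-component draws).
#'
#' @param cfg A [synthetic_config()].
#' @param base_seed Integer seed for the whole cohort.
#' @return List of `synthetic_recording` objects.
#' @export
generate_cohort <- function(cfg = synthetic_config(), base_seed = 1L) {
  if (cfg$n_recordings < 1L) ssa_stop("n_recordings must be >= 1", "config")
  set.seed(as.integer(base_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_recordings)
  jit_fields <- c("delta_amp", "delta_freq", "theta_amp", "alpha_amp",
                  "alpha_freq", "spindle_rate", "spindle_dur", "beta_amp",
                  "noise_sd")
  lapply(seq_len(cfg$n_recordings), function(i) {
    set.seed(seeds[i])
    cfg_i <- cfg
    for (ph in names(cfg_i$phases))
      for (f in jit_fields)
        cfg_i$phases[[ph]][[f]] <- cfg_i$phases[[ph]][[f]] *
          stats::runif(1, 1 - cfg$jitter, 1 + cfg$jitter)
    generate_recording(cfg_i, seed = seeds[i],
                       recording_id = sprintf("synth%02d", i))
  })
}
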