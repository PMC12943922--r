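# Signal constructors and brute-force oracles shared across the test files.

fs_default <- 128

make_tone <- function(freq, seconds = 3, fs = fs_default, amp = 1,
                      phase = 0) {
  t <- (seq_len(round(seconds * fs)) - 1) / fs
  amp * cos(2 * pi * freq * t + phase)
}

# linear chirp f0 -> f1 over the duration; instantaneous frequency
# f(t) = f0 + (f1 - f0) t / T by construction
make_chirp <- function(f0, f1, seconds = 3, fs = fs_default) {
  t <- (seq_len(round(seconds * fs)) - 1) / fs
  T <- seconds
  list(x = cos(2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * T))),
       if_true = f0 + (f1 - f0) * t / T,
       t = t)
}

# brute-force anti-diagonal means, straight from the definition
diag_average_bruteforce <- function(M) {
  L <- nrow(M); K <- ncol(M)
  out <- numeric(L + K - 1)
  for (s in seq_len(L + K - 1)) {
    vals <- c()
    for (p in seq_len(L)) {
      q <- s - p + 1
      if (q >= 1 && q <= K) vals <- c(vals, M[p, q])
    }
    out[s] <- mean(vals)
  }
  out
}

# singular values via an independent eigen-decomposition of X X^T
singular_values_bruteforce <- function(X) {
  lambda <- eigen(tcrossprod(X), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(lambda, 0))[seq_len(min(dim(X)))]
}

# brute-force count of sliding-window starts
count_epochs_bruteforce <- function(duration_s, epoch_s, hop_s, fs) {
  n <- round(duration_s * fs); len <- round(epoch_s * fs)
  hop <- round(hop_s * fs)
  cnt <- 0L; s0 <- 0L
  while (s0 + len <= n) { cnt <- cnt + 1L; s0 <- s0 + hop }
  cnt
}

# small fast synthetic recording for structural tests
quick_recording <- function(seconds = 30, seed = 1, fs = fs_default) {
  cfg <- synthetic_config(duration_s = seconds)
  generate_recording(cfg, seed = seed)
}
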