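#' Build the Hankel trajectory matrix of a series
#'
#' Embeds a length-N series into an `L x K` Hankel matrix whose row `p` is
#' the window `series[p .. p+K-1]` (`L = N - K + 1` lagged rows). Entry
#' `(p, q)` depends only on `p + q`, the defining Hankel property. At the
#' package defaults (383 embedded samples, `K = 256`) the matrix is
#' 128 x 256.
#'
#' @param series Numeric vector (microvolts), length >= K.
#' @param K Window length in samples (>= 2).
#' @return A `trajectory_matrix`: numeric matrix with attributes `L`, `K`,
#'   `source_length`.
#' @export
build_trajectory_matrix <- function(series, K) {
  series <- as.numeric(series)
  n <- length(series)
  K <- as.integer(K)
  if (K < 2L) ssa_stop("window length K must be >= 2", "dimension")
  if (K > n)
    ssa_stop(sprintf("window K = %d exceeds series length %d", K, n),
             "dimension")
  if (!all(is.finite(series)))
    ssa_stop("series must be finite", "numeric")
  L <- n - K + 1L
  # outer(0:(L-1), 1:K) indexes series[p + q]: Hankel by construction
  X <- matrix(series[outer(seq_len(L) - 1L, seq_len(K), `+`)], L, K)
  structure(X, L = L, K = K, source_length = n,
            class = c("trajectory_matrix", class(X)))
}

#' Singular value decomposition into eigentriples
#'
#' Full SVD `X = U S V^T` of a trajectory matrix, returned as `d =
#' min(L, K)` eigentriples `(sigma_i, u_i, v_i)` sorted by non-increasing
#' singular value. For reproducibility the sign of each pair is fixed so the
#' largest-magnitude entry of `u_i` is non-negative (with `v_i` flipped to
#' match).
#'
#' @param X A matrix (typically a [build_trajectory_matrix()] result).
#' @return An `eigentriples` object: list with `sigma` (length d), `U`
#'   (L x d), `V` (K x d), `L`, `K`, `d`.
#' @export
svd_decompose <- function(X) {
  if (!all(is.finite(X))) ssa_stop("matrix has non-finite entries", "numeric")
  L <- nrow(X); K <- ncol(X)
  s <- svd(X)
  d <- min(L, K)
  # deterministic sign: largest-|entry| of each u non-negative
  flip <- vapply(seq_len(d), function(i) {
    u <- s$u[, i]
    u[which.max(abs(u))] < 0
  }, logical(1))
  s$u[, flip] <- -s$u[, flip]
  s$v[, flip] <- -s$v[, flip]
  structure(list(sigma = s$d, U = s$u, V = s$v, L = L, K = K, d = d),
            class = "eigentriples")
}

#' @export
print.eigentriples <- function(x, ...) {
  cat(sprintf("<eigentriples: d = %d from a %d x %d matrix; sigma[1] = %.4g>\n",
              x$d, x$L, x$K, x$sigma[1]))
  invisible(x)
}

#' Relative and cumulative contributions of the eigentriples
#'
#' The relative contribution of eigentriple `i` is `sigma_i^2 / sum_k
#' sigma_k^2`; the cumulative contribution is its running sum. These are the
#' quantities used to decide how finely to group eigentriples into modes.
#'
#' @param x An `eigentriples` object, an `ssa_decomposition`, or a numeric
#'   vector of singular values.
#' @return List with numeric vectors `relative` and `cumulative`.
#' @export
contribution_profile <- function(x) {
  sigma <- if (is.numeric(x)) x else x$sigma
  if (length(sigma) == 0L || all(sigma == 0))
    ssa_stop("all singular values are zero (zero signal)", "degenerate_input")
  rel <- sigma^2 / sum(sigma^2)
  list(relative = rel, cumulative = cumsum(rel))
}

## anti-diagonal membership counts: element (p,q), 1-based, has s = p + q - 1
## in 1..L+K-1 and each anti-diagonal s holds min(s, L, K, L+K-s) elements
diag_counts <- function(L, K) {
  s <- seq_len(L + K - 1L)
  pmin(s, L, K, L + K - s)
}

#' Diagonal averaging (Hankelization) of a matrix
#'
#' Averages an `L x K` matrix along its anti-diagonals, mapping it to a
#' series of length `L + K - 1`: `out[s] = mean(M[p, q] : p + q = s)`. For a
#' Hankel matrix built from a series this recovers the series exactly, which
#' is the property that pins down the averaging weights.
#'
#' @param M A numeric matrix.
#' @return Numeric vector of length `nrow(M) + ncol(M) - 1`.
#' @export
diagonal_average <- function(M) {
  if (!all(is.finite(M))) ssa_stop("matrix has non-finite entries", "numeric")
  L <- nrow(M); K <- ncol(M)
  grp <- rep(seq_len(L), K) + rep(seq_len(K), each = L) - 1L
  sums <- rowsum(as.vector(M), grp)
  as.vector(sums) / diag_counts(L, K)
}

#' Reconstruct the series of one eigentriple group
#'
#' Sums the rank-one elementary matrices `sigma_i u_i v_i^T` over the group
#' and diagonally averages the result. Reconstruction is linear in the
#' group: the series of a union of disjoint groups is the sum of their
#' series, and the union of all groups returns the embedded series.
#'
#' @param et An `eigentriples` object from [svd_decompose()].
#' @param index_set Integer vector of eigentriple ranks (1-based, within
#'   `1..d`). May be empty, giving a zero series.
#' @return Numeric vector of length `L + K - 1`.
#' @export
reconstruct_group <- function(et, index_set) {
  stopifnot(inherits(et, "eigentriples"))
  index_set <- as.integer(index_set)
  if (length(index_set) &&
      (min(index_set) < 1L || max(index_set) > et$d))
    ssa_stop(sprintf("eigentriple indices must lie in 1..%d", et$d), "index")
  if (!length(index_set)) return(numeric(et$L + et$K - 1L))
  Ug <- et$U[, index_set, drop = FALSE]
  SVg <- t(et$V[, index_set, drop = FALSE]) * et$sigma[index_set]
  diagonal_average(Ug %*% SVg)
}

#' Default six-way eigentriple grouping
#'
#' The grouping used throughout this package: ranks are split (1-based) into
#' 1-2, 3-4, 5-7, 8-10, 11-20 and 21-d, i.e. the strongest eigentriples are
#' resolved finely and the weak tail is pooled. With `d = 128` the last
#' group is 21-128. For `d < 128` ranges are clipped to `d` (a range lying
#' wholly above `d` becomes an empty group yielding a zero IMF), keeping the
#' six-IMF contract for any window length.
#'
#' @param d Number of eigentriples available (default 128).
#' @return A `grouping`: list of six integer vectors, disjoint, covering
#'   `1..d`.
#' @export
default_grouping <- function(d = 128L) {
  ranges <- list(c(1L, 2L), c(3L, 4L), c(5L, 7L), c(8L, 10L),
                 c(11L, 20L), c(21L, as.integer(d)))
  ranges[[6]][2] <- max(ranges[[6]][2], 21L)  # keep a well-formed range
  grp <- lapply(ranges, function(r) {
    if (r[1] > d) integer(0) else seq.int(r[1], min(r[2], d))
  })
  validate_grouping(grp, d)
}

#' Validate (and normalise) an eigentriple grouping
#'
#' @param groups List of integer vectors of eigentriple ranks (1-based).
#' @param d Number of eigentriples the grouping must cover.
#' @return The grouping, classed, with empty groups allowed.
#' @export
validate_grouping <- function(groups, d) {
  groups <- lapply(groups, as.integer)
  all_idx <- unlist(groups)
  if (anyDuplicated(all_idx))
    ssa_stop("grouping has overlapping index sets", "config")
  if (length(all_idx) &&
      (min(all_idx) < 1L || max(all_idx) > d))
    ssa_stop(sprintf("grouping indices must lie in 1..%d", d), "config")
  if (!setequal(all_idx, seq_len(d)))
    ssa_stop("grouping must cover every eigentriple rank exactly once",
             "config")
  structure(groups, class = "grouping", d = as.integer(d))
}

#' Parse a grouping string
#'
#' Accepts the compact form `"0-1,2-3,4-6,7-9,10-19,20-127"` with 0-based
#' inclusive rank ranges (the convention used when labelling eigentriples
#' from 0), returning the 1-based grouping used internally.
#'
#' @param spec Character scalar of comma-separated `lo-hi` ranges.
#' @param d Number of eigentriples; the final range is clipped to `d`.
#' @return A `grouping` (list of integer vectors).
#' @export
parse_grouping <- function(spec, d = 128L) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  grp <- lapply(parts, function(p) {
    lo_hi <- as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1]])
    if (length(lo_hi) == 1L) lo_hi <- c(lo_hi, lo_hi)
    if (anyNA(lo_hi) || lo_hi[2] < lo_hi[1])
      ssa_stop(paste("cannot parse grouping range:", p), "config")
    r <- seq.int(lo_hi[1] + 1L, lo_hi[2] + 1L)
    r[r <= d]
  })
  validate_grouping(grp, d)
}

#' SSA decomposition of one epoch into six IMFs
#'
#' The full per-epoch pipeline: the first `embed_length` samples of the
#' epoch are embedded into an `L x K` trajectory matrix, decomposed by SVD,
#' and each eigentriple group is reconstructed into an intrinsic mode
#' function (IMF) by diagonal averaging. The IMFs sum to the embedded
#' series (SVD completeness plus linearity of the averaging).
#'
#' Group reconstructions use the convolution identity for anti-diagonal
#' sums of an outer product (`sum_{p+q=s} u_p v_q` is the linear
#' convolution of `u` and `v`), evaluated by FFT for all eigentriples at
#' once; [reconstruct_group()] is the direct-definition reference path.
#'
#' @param epoch An `epoch` from [segment_epochs()], or a bare numeric
#'   vector.
#' @param K Window length in samples (default 256, i.e. 2 s at 128 Hz).
#' @param grouping A `grouping`, or `NULL` for [default_grouping()] of the
#'   resulting `d`.
#' @param embed_length Samples to embed; defaults to the epoch's own
#'   `embed_length` (383 at package defaults) or to the full length for a
#'   bare vector.
#' @return An `ssa_decomposition`: list with `imfs` (embed_length x 6
#'   matrix), `eigentriples`, `relative_contrib`, `cumulative_contrib`,
#'   `grouping`, `series` (the embedded samples), `degenerate` (TRUE for an
#'   all-zero epoch, whose contributions are undefined and whose IMFs are
#'   zero).
#' @export
ssa_decompose_epoch <- function(epoch, K = 256L, grouping = NULL,
                                embed_length = NULL) {
  values <- if (inherits(epoch, "epoch")) epoch$values else as.numeric(epoch)
  embed <- embed_length %||%
    (if (inherits(epoch, "epoch")) epoch$embed_length else length(values))
  if (embed > length(values))
    ssa_stop("embed_length exceeds the epoch length", "dimension")
  series <- values[seq_len(embed)]
  if (K > embed)
    ssa_stop(sprintf("window K = %d exceeds embed_length %d", K, embed),
             "dimension")
  X <- build_trajectory_matrix(series, K)
  et <- svd_decompose(X)
  grouping <- grouping %||% default_grouping(et$d)
  if (attr(grouping, "d") != et$d)  # clip ranges beyond d, keep six groups
    grouping <- validate_grouping(lapply(unclass(grouping),
                                         function(g) g[g <= et$d]), et$d)

  degenerate <- all(et$sigma == 0)
  contrib <- if (degenerate) list(relative = rep(NA_real_, et$d),
                                  cumulative = rep(NA_real_, et$d))
             else contribution_profile(et)

  n <- et$L + et$K - 1L
  if (degenerate) {
    imfs <- matrix(0, n, length(grouping))
  } else {
    # batched anti-diagonal sums: conv(u_i, v_i) for every eigentriple via FFT
    nfft <- stats::nextn(n, 2)
    pad <- function(M, len) rbind(M, matrix(0, len - nrow(M), ncol(M)))
    FU <- stats::mvfft(pad(et$U, nfft))
    FV <- stats::mvfft(pad(et$V, nfft))
    conv <- Re(stats::mvfft(FU * FV, inverse = TRUE))[seq_len(n), ,
                                                      drop = FALSE] / nfft
    conv <- conv * rep(et$sigma, each = n)  # sigma_i * antidiag-sums
    w <- diag_counts(et$L, et$K)
    imfs <- vapply(grouping, function(g) {
      if (!length(g)) return(numeric(n))
      rowSums(conv[, g, drop = FALSE]) / w
    }, numeric(n))
  }
  colnames(imfs) <- paste0("imf", seq_len(ncol(imfs)))
  structure(
    list(imfs = imfs, eigentriples = et,
         relative_contrib = contrib$relative,
         cumulative_contrib = contrib$cumulative,
         grouping = grouping, series = series, degenerate = degenerate,
         fs = if (inherits(epoch, "epoch")) epoch$fs else NA_real_,
         t_center = if (inherits(epoch, "epoch")) epoch$t_center else NA_real_),
    class = "ssa_decomposition")
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  cat(sprintf(
    "<ssa_decomposition: %d IMFs of %d samples; top-2 contribution %.1f%%%s>\n",
    ncol(x$imfs), nrow(x$imfs),
    if (x$degenerate) NA else 100 * x$cumulative_contrib[2],
    if (x$degenerate) " (degenerate zero epoch)" else ""))
  invisible(x)
}
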