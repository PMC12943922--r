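test_that("trajectory matrix is Hankel with the documented shape", {
  # direct construction from the definition
  X <- build_trajectory_matrix(c(1, 2, 3, 4), 2)
  expect_equal(unclass(X)[, ], matrix(c(1, 2, 3, 2, 3, 4), 3, 2),
               ignore_attr = TRUE)

  # canonical epoch embedding: 383 samples, K = 256 -> 128 x 256
  X <- build_trajectory_matrix(rnorm(383), 256)
  expect_identical(dim(X), c(128L, 256L))

  # Hankel property: entry (p, q) depends only on p + q
  set.seed(3)
  s <- rnorm(40)
  X <- build_trajectory_matrix(s, 15)
  for (ss in c(5, 20, 30))
    expect_true(all(abs(X[row(X) + col(X) == ss] -
                        X[row(X) + col(X) == ss][1]) == 0))

  # constant series -> rank-1 matrix of that constant
  Xc <- build_trajectory_matrix(rep(2.5, 20), 6)
  expect_true(all(Xc == 2.5))
  expect_identical(qr(Xc)$rank, 1L)

  expect_error(build_trajectory_matrix(rnorm(10), 11),
               class = "ssaeeg_dimension")
})

test_that("SVD eigentriples match closed forms and the eigen oracle", {
  # rank-1 closed form: all-c L x K matrix has sigma = c * sqrt(L * K)
  M <- matrix(2, 3, 2)
  et <- svd_decompose(M)
  expect_equal(et$sigma[1], 2 * sqrt(6), tolerance = 1e-12)
  expect_equal(et$sigma[2], 0, tolerance = 1e-12)

  # oracle equivalence + ordering + unit norms on random matrices
  set.seed(21)
  for (i in 1:20) {
    n <- sample(40:80, 1); K <- sample(10:30, 1)
    X <- build_trajectory_matrix(rnorm(n), K)
    et <- svd_decompose(X)
    expect_lt(max(abs(et$sigma - singular_values_bruteforce(X))),
              1e-8 * max(et$sigma[1], 1))
    expect_true(all(diff(et$sigma) <= 1e-12))
    expect_equal(colSums(et$U^2), rep(1, et$d), tolerance = 1e-9)
    expect_equal(colSums(et$V^2), rep(1, et$d), tolerance = 1e-9)
    # sign convention: largest-|entry| of each u is non-negative
    expect_true(all(apply(et$U, 2, function(u) u[which.max(abs(u))]) >= 0))
    # rank-one sum reconstructs X
    R <- et$U %*% (t(et$V) * et$sigma)
    expect_lt(norm(R - X, "F") / norm(X, "F"), 1e-9)
  }

  expect_error(svd_decompose(matrix(c(1, NA, 2, 3), 2)),
               class = "ssaeeg_numeric")
})

test_that("contribution profile normalises and orders energies", {
  prof <- contribution_profile(c(4, 3))
  expect_equal(prof$relative, c(0.64, 0.36))
  expect_equal(prof$cumulative, c(0.64, 1))

  set.seed(5)
  et <- svd_decompose(matrix(rnorm(60), 6, 10))
  prof <- contribution_profile(et)
  expect_equal(prof$cumulative[length(prof$cumulative)], 1,
               tolerance = 1e-12)
  expect_true(all(diff(prof$relative) <= 1e-12))  # energy ordering
  expect_true(all(prof$relative >= 0 & prof$relative <= 1))

  expect_error(contribution_profile(c(0, 0)),
               class = "ssaeeg_degenerate_input")
})

test_that("diagonal averaging matches its definition and inverts embedding", {
  expect_equal(diagonal_average(matrix(c(1, 3, 2, 4), 2)), c(1, 2.5, 4))

  # oracle: brute-force double loop on random matrices
  set.seed(8)
  M <- matrix(rnorm(35), 7, 5)
  expect_equal(diagonal_average(M), diag_average_bruteforce(M),
               tolerance = 1e-12)

  # Hankel fixed point on 100 random series
  set.seed(9)
  for (i in 1:100) {
    n <- sample(20:60, 1); K <- sample(2:(n - 1), 1)
    s <- rnorm(n)
    expect_lt(max(abs(diagonal_average(build_trajectory_matrix(s, K)) - s)),
              1e-12)
  }
})

test_that("group reconstruction is linear and complete", {
  set.seed(31)
  s <- rnorm(383)
  et <- svd_decompose(build_trajectory_matrix(s, 256))

  expect_equal(reconstruct_group(et, integer(0)), numeric(383))
  full <- reconstruct_group(et, seq_len(et$d))
  expect_lt(max(abs(full - s)) / max(abs(s)), 1e-9)

  a <- reconstruct_group(et, 1:3); b <- reconstruct_group(et, 7:10)
  ab <- reconstruct_group(et, c(1:3, 7:10))
  expect_lt(max(abs(ab - (a + b))), 1e-10 * max(abs(ab)))

  expect_error(reconstruct_group(et, c(1, 999)), class = "ssaeeg_index")
})

test_that("grouping defaults, parsing and validation enforce a partition", {
  g <- default_grouping(128)
  expect_length(g, 6L)
  expect_identical(g[[1]], 1:2)
  expect_identical(g[[6]], 21:128)
  expect_identical(sort(unlist(g)), 1:128)

  # the same grouping in the 0-based field notation
  g2 <- parse_grouping("0-1,2-3,4-6,7-9,10-19,20-127", 128)
  expect_identical(lapply(g2, as.integer), lapply(g, as.integer))

  # small d: clipped ranges, possibly-empty tail groups
  g3 <- default_grouping(15)
  expect_length(g3, 6L)
  expect_identical(sort(unlist(g3)), 1:15)
  expect_length(g3[[6]], 0L)

  expect_error(validate_grouping(list(1:3, 3:5), 5), class = "ssaeeg_config")
  expect_error(validate_grouping(list(1:2), 5), class = "ssaeeg_config")
})

test_that("epoch decomposition yields six additive IMFs", {
  set.seed(41)
  rec <- quick_recording(seconds = 9)
  eps <- segment_epochs(rec$recording, epoching_config())
  dec <- ssa_decompose_epoch(eps[[2]])

  expect_identical(ncol(dec$imfs), 6L)
  expect_identical(nrow(dec$imfs), 383L)
  expect_identical(dec$eigentriples$d, 128L)
  # exact additivity: IMFs sum to the embedded series
  expect_lt(max(abs(rowSums(dec$imfs) - dec$series)),
            1e-9 * max(abs(dec$series)))
  # fast reconstruction path agrees with the direct-definition path
  for (j in c(1, 4, 6))
    expect_equal(dec$imfs[, j],
                 reconstruct_group(dec$eigentriples, dec$grouping[[j]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate and structured epochs decompose as expected", {
  # constant epoch: all energy in eigentriple 1 -> IMF-1 carries it
  dec <- ssa_decompose_epoch(rep(3, 384), embed_length = 383)
  expect_equal(dec$imfs[, 1], rep(3, 383), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(dec$imfs[, 2:6])), 1e-9)

  # pure sinusoid: rank-2 trajectory matrix, first two triples ~ all energy
  tone <- make_tone(10, seconds = 3)[1:383]
  dec <- ssa_decompose_epoch(tone, K = 256)
  expect_gte(dec$cumulative_contrib[2], 0.99)

  # all-zero epoch: flagged degenerate, six zero IMFs, no error
  dec0 <- ssa_decompose_epoch(numeric(384), embed_length = 383)
  expect_true(dec0$degenerate)
  expect_true(all(dec0$imfs == 0))
  expect_true(all(is.na(dec0$relative_contrib)))
})
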