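make_table <- function(n = 75, seed = 1, noise_sd = 0, beta = NULL,
                       intercept = 10) {
  set.seed(seed)
  tab <- as.data.frame(matrix(rnorm(n * 12), n,
                              dimnames = list(NULL, feature_cols())))
  beta <- beta %||% stats::setNames(rep(0, 12), feature_cols())
  tab$BIS <- intercept + as.matrix(tab) %*% beta + rnorm(n, 0, noise_sd)
  tab$BIS <- as.vector(tab$BIS)
  tab <- cbind(t = seq(0, by = 8, length.out = n), tab)
  tab
}
feature_cols <- function() c(paste0("CF", 1:6), paste0("TP", 1:6))
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("exact linear tables are fit perfectly", {
  beta <- stats::setNames(c(-2.5, 0.5, -0.1, 0.3, 1.1, 2.6,
                            0.2, 0.04, -0.4, -0.6, -1.8, -0.3),
                          feature_cols())
  tab <- make_table(beta = beta, noise_sd = 0)
  m <- suppressWarnings(fit_mlr(tab))  # summary.lm warns on a perfect fit
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_lt(m$mae, 1e-8)
  expect_equal(unname(m$coefficients), unname(beta), tolerance = 1e-8)
  expect_equal(m$intercept, 10, tolerance = 1e-8)

  # prediction on the training table equals the observations
  expect_equal(predict_bis(m, tab), tab$BIS, tolerance = 1e-8)
})

test_that("fit metrics are self-consistent with independent formulas", {
  beta <- stats::setNames(rnorm(12, sd = 0.5), feature_cols())
  tab <- make_table(seed = 3, beta = beta, noise_sd = 4)
  m <- fit_mlr(tab)
  pred <- predict_bis(m, tab)
  res <- tab$BIS - pred
  # R^2 = 1 - SSE/SST computed independently
  expect_equal(m$r2, 1 - sum(res^2) / sum((tab$BIS - mean(tab$BIS))^2),
               tolerance = 1e-10)
  expect_equal(m$mae, mean(abs(res)), tolerance = 1e-9)
  expect_equal(m$rmse, sqrt(mean(res^2)), tolerance = 1e-9)
  expect_lte(m$mae, m$rmse)
  # OLS residual orthogonality
  expect_lt(abs(sum(res)), 1e-8)
  for (p in feature_cols())
    expect_lt(abs(sum(res * tab[[p]])), 1e-7)
})

test_that("rank-deficient designs raise a collinearity error naming columns", {
  tab <- make_table(seed = 5, noise_sd = 1)
  tab$TP6 <- 3                           # constant column
  err <- expect_error(fit_mlr(tab), class = "ssaeeg_collinearity")
  expect_match(conditionMessage(err), "TP6")

  tab2 <- make_table(seed = 6, noise_sd = 1)
  tab2$TP5 <- 2 * tab2$CF1 - tab2$CF2    # exact linear dependence
  expect_error(fit_mlr(tab2), class = "ssaeeg_collinearity")

  expect_error(fit_mlr(make_table(n = 10)), class = "ssaeeg_empty_input")
  expect_error(fit_mlr(make_table()[, -2]), class = "ssaeeg_schema")
})

test_that("significance selection keeps p < alpha parameters, single pass", {
  beta <- stats::setNames(c(5, 5, 0, 0, 0, 0, 5, 0, 0, 0, 0, 5),
                          feature_cols())
  tab <- make_table(seed = 7, beta = beta, noise_sd = 1)
  full <- fit_mlr(tab)
  red <- select_significant(full, tab)
  expect_true(all(c("CF1", "CF2", "TP1", "TP6") %in% red$included_params))

  # alpha = 1 keeps everything (p-values are < 1 almost surely)
  expect_identical(select_significant(full, tab, alpha = 1)$included_params,
                   full$included_params)

  # pure-noise response: typically nothing survives -> empty-model error
  tab0 <- make_table(seed = 8, noise_sd = 50)
  full0 <- fit_mlr(tab0)
  if (all(full0$p_values >= 0.05))
    expect_error(select_significant(full0, tab0),
                 class = "ssaeeg_empty_model")
})

test_that("predictions propagate missing inputs and schema errors", {
  tab <- make_table(seed = 9, noise_sd = 1)
  m <- fit_mlr(tab)
  # prediction MAE on the training table equals the model's own MAE
  expect_equal(mean(abs(tab$BIS - predict_bis(m, tab))), m$mae,
               tolerance = 1e-9)

  tab$CF1[3] <- NA
  pred <- predict_bis(m, tab)
  expect_true(is.na(pred[3]) && !anyNA(pred[-3]))
  expect_error(predict_bis(m, tab[, -2]), class = "ssaeeg_schema")
})

test_that("phase summary medians, %change and tests behave", {
  # programmed difference: CF6 doubles at emergence
  set.seed(11)
  n <- 75
  t <- seq(0, by = 8, length.out = n)
  phase <- cut(t, c(0, 200, 400, 600), right = FALSE)
  tab <- data.frame(t = t,
                    CF6 = c(10, 10, 20)[as.integer(phase)] + rnorm(n),
                    TP1 = rnorm(n))
  ps <- phase_summary(tab, span_seconds = 600, params = c("CF6", "TP1"))
  expect_identical(levels(factor(ps$phase,
                                 c("maintenance", "transition", "emergence"))),
                   c("maintenance", "transition", "emergence"))
  cf6 <- ps[ps$parameter == "CF6", ]
  expect_equal(cf6$pct_change[cf6$phase == "maintenance"], 0)
  expect_gt(cf6$pct_change[cf6$phase == "emergence"], 50)
  expect_lt(cf6$p_vs_maintenance[cf6$phase == "emergence"], 0.05)
  expect_lt(cf6$p_kruskal[1], 0.05)
  # undifferentiated parameter: %change near 0, tests not significant
  tp1 <- ps[ps$parameter == "TP1", ]
  expect_gt(tp1$p_kruskal[1], 0.05)

  # median 10 -> 5 is a -50% change
  tab2 <- data.frame(t = t, CF1 = c(10, 10, 5)[as.integer(phase)])
  ps2 <- phase_summary(tab2, span_seconds = 600, params = "CF1")
  expect_equal(ps2$pct_change[ps2$phase == "emergence"], -50)

  # a phase with < 3 rows flags its tests as insufficient
  tab3 <- data.frame(t = c(1, 2, 3, 4, 250, 450, 500, 520),
                     CF1 = rnorm(8))
  ps3 <- phase_summary(tab3, span_seconds = 600, params = "CF1")
  expect_true(any(ps3$insufficient))
  expect_true(is.na(ps3$p_kruskal[1]))
})
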