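#' Multiple linear regression of BIS on IMF parameters
#'
#' Ordinary least squares with intercept of the `BIS` column on the named
#' feature columns, on complete cases. Reports per-coefficient two-sided
#' t-test p-values and the in-sample fit metrics used throughout this
#' package: coefficient of determination R^2, mean absolute error and
#' root-mean-squared error.
#'
#' @param table Aligned feature table with a `BIS` column (see
#'   [align_to_grid()], [cohort_median()]).
#' @param params Character vector of explanatory columns (default: all 12
#'   `CF1..TP6`).
#' @param response Name of the response column (default `"BIS"`).
#' @return A `bis_mlr`: list with `intercept`, `coefficients` (named),
#'   `p_values`, `r2`, `mae`, `rmse`, `n_obs`, `included_params`, and the
#'   underlying `lm` fit.
#' @export
fit_mlr <- function(table, params = feature_params(), response = "BIS") {
  missing_cols <- setdiff(c(params, response), names(table))
  if (length(missing_cols))
    ssa_stop(paste("table lacks columns:",
                   paste(missing_cols, collapse = ", ")), "schema")
  dat <- table[, c(response, params)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_dropped <- nrow(table) - nrow(dat)
  if (nrow(dat) < length(params) + 2L)
    ssa_stop(sprintf("only %d complete rows for %d parameters",
                     nrow(dat), length(params)), "empty_input")
  fml <- stats::reformulate(sprintf("`%s`", params),
                            response = sprintf("`%s`", response))
  fit <- stats::lm(fml, data = dat)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    bad <- gsub("`", "", names(beta)[is.na(beta)])
    ssa_stop(paste("collinear (or constant) explanatory columns:",
                   paste(bad, collapse = ", ")), "collinearity")
  }
  sm <- summary(fit)
  cf <- sm$coefficients
  rn <- gsub("`", "", rownames(cf))
  res <- stats::residuals(fit)
  structure(
    list(intercept = unname(beta[1]),
         coefficients = stats::setNames(unname(beta[-1]), params),
         p_values = stats::setNames(cf[match(params, rn), 4], params),
         r2 = sm$r.squared,
         mae = mean(abs(res)),
         rmse = sqrt(mean(res^2)),
         n_obs = nrow(dat), n_dropped = n_dropped,
         included_params = params, response = response, lm_fit = fit),
    class = "bis_mlr")
}

#' @export
print.bis_mlr <- function(x, ...) {
  cat(sprintf("<bis_mlr: %d params, n = %d | R2 = %.3f, MAE = %.3f, RMSE = %.3f>\n",
              length(x$included_params), x$n_obs, x$r2, x$mae, x$rmse))
  cat(sprintf("  intercept %.4g; significant (p<0.05): %s\n", x$intercept,
              paste(names(x$p_values)[x$p_values < 0.05], collapse = ", ")))
  invisible(x)
}

#' Reduce a model to its significant parameters
#'
#' Single-pass selection: keep the parameters whose p-values in the full
#' model fall below `alpha`, and refit once on those alone (no stepwise
#' iteration).
#'
#' @param model A fitted `bis_mlr`.
#' @param table The feature table to refit on.
#' @param alpha Significance level (default 0.05).
#' @return A new `bis_mlr` on the reduced parameter set.
#' @export
select_significant <- function(model, table, alpha = 0.05) {
  stopifnot(inherits(model, "bis_mlr"))
  keep <- names(model$p_values)[model$p_values < alpha]
  if (!length(keep))
    ssa_stop(sprintf("no parameter significant at alpha = %g", alpha),
             "empty_model")
  fit_mlr(table, params = keep, response = model$response)
}

#' Predict BIS from a fitted model
#'
#' Linear prediction `intercept + X beta` per row; rows with a missing
#' required cell give a missing prediction.
#'
#' @param model A `bis_mlr`.
#' @param table Feature table containing the model's parameters.
#' @return Numeric vector, one prediction per row of `table`.
#' @export
predict_bis <- function(model, table) {
  stopifnot(inherits(model, "bis_mlr"))
  missing_cols <- setdiff(model$included_params, names(table))
  if (length(missing_cols))
    ssa_stop(paste("table lacks model columns:",
                   paste(missing_cols, collapse = ", ")), "schema")
  X <- as.matrix(table[, model$included_params, drop = FALSE])
  as.vector(model$intercept + X %*% model$coefficients)
}

#' Phase summary of a feature table
#'
#' Splits the analyzed span into `n_phases` equal contiguous phases
#' (maintenance, transition, emergence for the default three over 600 s,
#' i.e. 200 s each) and summarises every parameter per phase: median, IQR,
#' and percent change relative to the maintenance median,
#' `100 * (median_phase - median_maint) / |median_maint|`. Differences
#' across phases are tested with an omnibus Kruskal-Wallis test per
#' parameter and pairwise Mann-Whitney tests against maintenance and
#' transition, Bonferroni-corrected for the three pairwise comparisons.
#'
#' @param table Aligned feature table (time column `t`).
#' @param span_seconds Span to analyse (default 600).
#' @param n_phases Number of equal phases (default 3).
#' @param params Columns to summarise (default: the 12 CF/TP parameters,
#'   plus `BIS` when present).
#' @return A `phase_summary` data frame: one row per parameter x phase with
#'   `parameter`, `phase`, `n`, `median`, `iqr`, `pct_change`, `p_kruskal`,
#'   `p_vs_maintenance`, `p_vs_transition` (Bonferroni-corrected; `NA` where
#'   a phase has fewer than 3 rows, flagged in `insufficient`).
#' @export
phase_summary <- function(table, span_seconds = 600, n_phases = 3L,
                          params = NULL) {
  stopifnot(is.data.frame(table))
  if (max(table$t) < span_seconds * (n_phases - 1) / n_phases)
    ssa_stop("table does not cover the requested span", "empty_input")
  params <- params %||%
    intersect(c(feature_params(), "BIS"), names(table))
  phase_names <- if (n_phases == 3L) c("maintenance", "transition", "emergence")
                 else paste0("phase", seq_len(n_phases))
  bounds <- seq(0, span_seconds, length.out = n_phases + 1L)
  phase <- cut(table$t, bounds, labels = phase_names, right = FALSE,
               include.lowest = TRUE)
  n_comp <- choose(n_phases, 2)

  rows <- lapply(params, function(p) {
    v <- table[[p]]
    by_phase <- split(v[!is.na(phase)], phase[!is.na(phase)])
    by_phase <- lapply(by_phase, function(x) x[!is.na(x)])
    enough <- vapply(by_phase, length, 1L) >= 3L
    p_kw <- if (all(enough))
      stats::kruskal.test(by_phase)$p.value else NA_real_
    pw <- function(a, b) {
      if (!enough[a] || !enough[b]) return(NA_real_)
      p <- suppressWarnings(stats::wilcox.test(by_phase[[a]],
                                               by_phase[[b]])$p.value)
      min(1, p * n_comp)  # Bonferroni over the pairwise comparisons
    }
    med <- vapply(by_phase, function(x)
      if (length(x)) stats::median(x) else NA_real_, numeric(1))
    iqr <- vapply(by_phase, function(x)
      if (length(x) > 1) stats::IQR(x) else NA_real_, numeric(1))
    data.frame(
      parameter = p, phase = phase_names,
      n = vapply(by_phase, length, 1L),
      median = med, iqr = iqr,
      pct_change = 100 * (med - med[1]) / abs(med[1]),
      p_kruskal = p_kw,
      p_vs_maintenance = c(NA, vapply(seq_len(n_phases)[-1], function(i)
        pw(1L, i), numeric(1))),
      p_vs_transition = if (n_phases >= 2L)
        c(NA, NA, vapply(seq_len(n_phases)[-(1:2)], function(i)
          pw(2L, i), numeric(1)))
        else NA_real_,
      insufficient = !enough,
      row.names = NULL)
  })
  structure(do.call(rbind, rows), class = c("phase_summary", "data.frame"))
}
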