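#' Multiple linear regression of an outcome on focal predictors
#'
#' Ordinary least squares with intercept, entering both focal predictors
#' jointly together with the adjustment covariates, on complete-case rows
#' (the number dropped is reported). Two-sided t-based p-values.
#'
#' @param data Data frame holding outcome, predictors and covariates.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of focal predictor columns.
#' @param covariates Character vector of adjustment covariate columns
#'   (may be empty).
#' @param standardize If `TRUE`, the focal predictors are z-scored (mean
#'   0, SD 1) on the analysis sample before fitting; covariates are left
#'   untouched. Standardization is a linear reparameterization, so
#'   p-values are unchanged.
#' @param condition_limit Error when the design's condition number exceeds
#'   this (collinearity guard).
#' @return Data frame with one row per focal predictor: `outcome`,
#'   `predictor`, `beta`, `se`, `p`, `n_used`, `n_dropped`,
#'   `standardized`.
#' @export
fit_mlr <- function(data, outcome, predictors, covariates = character(0),
                    standardize = FALSE, condition_limit = 1e8) {
  cols <- c(outcome, predictors, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[cols]
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  if (standardize) {
    for (p in predictors) {
      s <- stats::sd(d[[p]])
      if (!is.finite(s) || s == 0)
        stop("zero-variance focal predictor: ", p)
      d[[p]] <- (d[[p]] - mean(d[[p]])) / s
    }
  }
  f <- stats::reformulate(c(predictors, covariates), response = outcome)
  mm <- stats::model.matrix(f, d)
  if (qr(mm)$rank < ncol(mm) || kappa(mm, exact = TRUE) > condition_limit) {
    qrx <- qr(mm)
    bad <- colnames(mm)[qrx$pivot[seq_len(ncol(mm)) > qrx$rank]]
    stop("collinear design; offending column(s): ",
         paste(if (length(bad)) bad else "(ill-conditioned)",
               collapse = ", "))
  }
  fit <- stats::lm(f, data = d)
  co <- summary(fit)$coefficients
  data.frame(outcome = outcome, predictor = predictors,
             beta = co[predictors, "Estimate"],
             se = co[predictors, "Std. Error"],
             p = co[predictors, "Pr(>|t|)"],
             n_used = nrow(d), n_dropped = sum(!cc),
             standardized = standardize,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Refit with standardized focal predictors
#'
#' Convenience wrapper around [fit_mlr()] that returns the raw fit merged
#' with the standardized refit (columns `beta_standardized`,
#' `se_standardized`). The p-values of the two fits are identical up to
#' numerical error.
#'
#' @inheritParams fit_mlr
#' @return Data frame with raw and standardized estimates per predictor.
#' @export
standardize_refit <- function(data, outcome, predictors,
                              covariates = character(0)) {
  raw <- fit_mlr(data, outcome, predictors, covariates, standardize = FALSE)
  std <- fit_mlr(data, outcome, predictors, covariates, standardize = TRUE)
  raw$beta_standardized <- std$beta
  raw$se_standardized <- std$se
  raw$standardized <- NULL
  raw
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up BH adjustment (with monotonicity enforcement) over a
#' family of `m` comparisons, delegated to [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param m Family size (default `length(p)`; 8 in the motivating
#'   two-outcomes-by-four-predictors design).
#' @return Adjusted p-values, same length as `p`.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Blood-pressure association table
#'
#' Fits the full two-outcome design: SBP and DBP each regressed on the two
#' subject-level PC scores (jointly) and, separately, on the two POPAI
#' summaries (jointly), always adjusting for the supplied covariates;
#' collects the 8 predictor-outcome comparisons, adds standardized refits,
#' and applies BH FDR across the family. For predictors measured in
#' minutes a per-hour rescaling of the raw coefficient is included as a
#' convenience column.
#'
#' @param pheno Data frame with one row per participant holding the
#'   outcome columns, covariate columns, and a `participant` id.
#' @param scores Data frame `participant`, `PC1`, `PC2` (level-1 scores).
#' @param popai Data frame from [popai_summary()].
#' @param outcomes Outcome column names (default `c("SBP", "DBP")`).
#' @param covariates Adjustment covariate column names in `pheno`.
#' @return Data frame of class `"association_result"`: one row per
#'   comparison with `beta`, `se`, `beta_standardized`, `se_standardized`,
#'   `beta_per_hour` (minute-scale predictors only), `p_raw`, `p_fdr`,
#'   `n_used`.
#' @export
association_table <- function(pheno, scores, popai,
                              outcomes = c("SBP", "DBP"),
                              covariates = character(0)) {
  d <- merge(pheno, scores, by = "participant")
  d <- merge(d, popai[c("participant", "avg_daily_inactive_sitting_min",
                        "avg_daily_active_sitting_min")],
             by = "participant")
  sets <- list(mfpca = c("PC1", "PC2"),
               popai = c("avg_daily_inactive_sitting_min",
                         "avg_daily_active_sitting_min"))
  rows <- list()
  for (oc in outcomes) {
    for (nm in names(sets)) {
      r <- standardize_refit(d, oc, sets[[nm]], covariates)
      r$method <- nm
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "p"] <- "p_raw"
  out$p_fdr <- bh_fdr(out$p_raw)
  out$beta_per_hour <- ifelse(grepl("_min$", out$predictor),
                              out$beta * 60, NA_real_)
  class(out) <- c("association_result", class(out))
  out
}
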