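#' Quantify the impact of block missingness on PC1 recovery
#'
#' Pseudo-simulation: per replicate, a complete dataset is drawn from a
#' known truth and fitted; bout-level block missingness is then applied to
#' the same realization and the model refitted; the two fits are compared
#' on the leading subject-level component by sign-aligned eigenfunction
#' |cosine| similarity and level-1 score correlation. By default the
#' masked fit is compared against the complete-data fit (the complete fit
#' is the reference the masked data degrade from); `compare = "truth"`
#' compares against the generating truth instead.
#'
#' @param truth A [curve_truth()] object (grid length must be
#'   triangular).
#' @param n Subjects per replicate.
#' @param days Days per subject.
#' @param missingness Function of bout length giving the unregistered
#'   probability (e.g. [bout_missingness_curve()]).
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Integer seed; replicate r uses `seed + r` offsets.
#' @param compare `"complete"` (default) or `"truth"`.
#' @param ... Passed to [mfpca()] (e.g. `pve`).
#' @return Object of class `"missingness_report"`: `per_replicate`
#'   (data.frame `replicate`, `pc1_similarity`, `score1_correlation`),
#'   `summary` (means and Monte-Carlo standard errors), and the
#'   configuration echo.
#' @export
run_missingness_study <- function(truth, n, days, missingness,
                                  replicates = 5, seed = 1,
                                  compare = c("complete", "truth"), ...) {
  compare <- match.arg(compare)
  stopifnot(inherits(truth, "curve_truth"), is.function(missingness))
  replicates <- check_pos_int(replicates, "replicates")
  seed <- check_pos_int(seed, "seed")
  per <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sim <- simulate_curves(truth, n = n, days_per_subject = days,
                           seed = seed + 2L * r)
    masked <- apply_bout_missingness(sim, missingness, seed = seed + 2L * r + 1L)
    fit_m <- tryCatch(mfpca(masked, ...), error = function(e)
      stop("replicate ", r, ": ", conditionMessage(e)))
    if (compare == "complete") {
      fit_c <- mfpca(sim, ...)
      phi_ref <- fit_c$phi1[1, ]
      sc_ref <- fit_c$scores1[, 1]
    } else {
      phi_ref <- truth$phi1[, 1]
      sc_ref <- stats::setNames(sim$scores1[, 1],
                                unique(sim$index$participant))
    }
    if (fit_m$N1 < 1L) {  # no subject-level component survived
      sim_pc1 <- NA_real_; corr <- NA_real_
    } else {
      sim_pc1 <- abs(cosine_sim(phi_ref, fit_m$phi1[1, ]))
      common <- intersect(names(sc_ref) %||% rownames(fit_m$scores1),
                          rownames(fit_m$scores1))
      # sign-align the masked scores with the reference eigenfunction sign
      sgn <- sign(cosine_sim(phi_ref, fit_m$phi1[1, ]))
      corr <- stats::cor(sc_ref[common], sgn * fit_m$scores1[common, 1])
    }
    per[[r]] <- data.frame(replicate = r, pc1_similarity = sim_pc1,
                           score1_correlation = corr)
  }
  per <- do.call(rbind, per)
  mc_se <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    per_replicate = per,
    summary = data.frame(
      metric = c("pc1_similarity", "score1_correlation"),
      mean = c(mean(per$pc1_similarity), mean(per$score1_correlation)),
      mc_se = c(mc_se(per$pc1_similarity), mc_se(per$score1_correlation))),
    config = list(n = n, days = days, replicates = replicates,
                  seed = seed, compare = compare,
                  missingness = attr(missingness, "params"))),
    class = "missingness_report")
}

#' @export
print.missingness_report <- function(x, ...) {
  cat("Block-missingness impact study (", x$config$replicates,
      " replicates, compare = ", x$config$compare, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
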