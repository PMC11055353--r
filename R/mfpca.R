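#' Estimate the overall mean and day-specific shifts
#'
#' Pointwise method-of-moments estimates on the registered grid:
#' `mu(t)` is the mean of all observed values at `t`; `eta_j(t)` is the
#' mean at `t` among rows with within-subject day order `j`, minus `mu(t)`.
#' Grid points unobserved for a given day order get `eta_j(t) = 0` (the
#' shift is unidentifiable there).
#'
#' @param X Numeric matrix (participant-day rows x grid), `NA` where
#'   missing.
#' @param mask Logical matrix, `TRUE` = observed.
#' @param day_order Integer vector, within-subject day rank of each row.
#' @return List with `mu` (length-T vector) and `eta`
#'   (`max(day_order)` x T matrix).
#' @export
estimate_mean_and_shift <- function(X, mask, day_order) {
  stopifnot(dim(X) == dim(mask), length(day_order) == nrow(X))
  nobs <- colSums(mask)
  if (any(nobs == 0L))
    stop("grid point(s) observed in zero rows: t = ",
         paste(utils::head(which(nobs == 0L), 10L), collapse = ", "),
         "; reduce B or supply more data")
  X0 <- X; X0[!mask] <- 0
  mu <- colSums(X0) / nobs
  d_max <- max(day_order)
  eta <- matrix(0, d_max, ncol(X))
  for (j in seq_len(d_max)) {
    rows <- day_order == j
    nj <- colSums(mask[rows, , drop = FALSE])
    mj <- colSums(X0[rows, , drop = FALSE])
    seen <- nj > 0L
    eta[j, seen] <- mj[seen] / nj[seen] - mu[seen]
  }
  list(mu = mu, eta = eta)
}

#' Estimate between- and within-subject covariance surfaces
#'
#' Method-of-moments two-level decomposition: with residuals
#' `R_ij(t) = X_ij(t) - mu(t) - eta_j(t)`,
#' the total surface `K_total(s,t)` averages products of same-row residual
#' pairs, the between-subject surface `K_between(s,t)` averages products
#' from different days of the same subject, and
#' `K_within = K_total - K_between`. Every surface cell uses only pairs
#' where both points are observed. The white-noise variance `sigma^2`
#' contaminates only the diagonal of `K_total`; it is estimated as the
#' average gap between the raw diagonal and a diagonal extrapolated from
#' near-off-diagonal cells (or, when smoothing is on, from the smoothed
#' surface fitted with the diagonal excluded), floored at zero.
#'
#' Cells with zero contributing pairs are imputed by a normalized 2-D
#' Gaussian kernel smooth of the observed cells; the imputed fraction is
#' reported and more than 95% empty cells is an error.
#'
#' @param X,mask As in [estimate_mean_and_shift()].
#' @param subject Integer/character vector of subject ids per row.
#' @param day_order Within-subject day rank per row.
#' @param smooth `"on"` (always smooth; the default, and standard FPCA
#'   practice — raw method-of-moments surfaces carry a positive
#'   noise-eigenvalue tail that inflates pooled variance shares),
#'   `"auto"` (smooth only when some cells are pair-empty), or `"off"`.
#' @param bandwidth Gaussian kernel SD in grid units (default 2).
#' @return List with `K_total`, `K_between`, `K_within` (T x T, symmetric,
#'   diagonal of `K_total` noise-corrected), `sigma2`, `empty_frac`
#'   (fraction of pair-empty cells in the total surface), and `smoothed`
#'   (logical).
#' @export
estimate_covariances <- function(X, mask, subject, day_order,
                                 smooth = c("on", "auto", "off"),
                                 bandwidth = 2) {
  smooth <- match.arg(smooth)
  ms <- estimate_mean_and_shift(X, mask, day_order)
  Tn <- ncol(X)
  R <- X - matrix(ms$mu, nrow(X), Tn, byrow = TRUE) -
    ms$eta[day_order, , drop = FALSE]
  R[!mask] <- 0
  M <- mask * 1
  S <- crossprod(R)                      # same-row cross-products
  N <- crossprod(M)                      # pair counts
  sid <- as.integer(factor(subject))
  A <- rowsum(R, sid)                    # per-subject row sums
  AM <- rowsum(M, sid)
  CS <- crossprod(A) - S                 # different-row, same-subject
  CN <- crossprod(AM) - N
  if (!any(CN > 0))
    stop("no subject has two days; between/within decomposition unidentifiable")
  empty_frac <- mean(N == 0)
  if (empty_frac > 0.95)
    stop("more than 95% of covariance cells have no contributing pairs")
  K_total <- S / N                       # NaN where N == 0
  K_between <- CS / CN
  do_smooth <- smooth == "on" || (smooth == "auto" && empty_frac > 0)
  if (do_smooth) {
    W <- gauss_kernel_weights(Tn, bandwidth)
    diag_raw <- diag(K_total)
    K_total_off <- K_total; diag(K_total_off) <- NA  # sigma2 identifiability
    K_total_sm <- smooth_surface(K_total_off, N, W)
    sigma2 <- max(0, mean(diag_raw - diag(K_total_sm), na.rm = TRUE))
    K_total <- K_total_sm
    K_between <- smooth_surface(K_between, CN, W)
  } else {
    if (empty_frac > 0 || any(CN == 0))
      stop("pair-empty covariance cells require smoothing (smooth = 'auto' or 'on')")
    diag_raw <- diag(K_total)
    diag_est <- neighbor_diagonal(K_total)
    sigma2 <- max(0, mean(diag_raw - diag_est))
    diag(K_total) <- diag_raw - sigma2
  }
  K_total <- (K_total + t(K_total)) / 2
  K_between <- (K_between + t(K_between)) / 2
  K_within <- K_total - K_between
  list(K_total = K_total, K_between = K_between, K_within = K_within,
       sigma2 = sigma2, empty_frac = empty_frac, smoothed = do_smooth,
       mu = ms$mu, eta = ms$eta)
}

# truncated Gaussian kernel weight matrix (T x T band)
gauss_kernel_weights <- function(Tn, bandwidth) {
  d <- abs(outer(seq_len(Tn), seq_len(Tn), "-"))
  W <- exp(-0.5 * (d / bandwidth)^2)
  W[d > 4 * bandwidth] <- 0
  W
}

# normalized (Nadaraya-Watson) separable smooth of a surface with
# cell weights 'w' (pair counts); NA/empty cells get imputed
smooth_surface <- function(K, w, W) {
  Z <- w * 1
  Z[is.na(K)] <- 0
  if (all(Z == 0)) return(matrix(0, nrow(K), ncol(K)))
  K0 <- K; K0[Z == 0] <- 0
  num <- W %*% (K0 * Z) %*% W
  den <- W %*% Z %*% W
  out <- num / den
  if (any(den == 0))  # isolated regions: fall back to global weighted mean
    out[den == 0] <- sum(K0 * Z) / sum(Z)
  out
}

# diagonal extrapolated from off-diagonal neighbors within distance 2
neighbor_diagonal <- function(K) {
  Tn <- ncol(K)
  vapply(seq_len(Tn), function(t) {
    nb <- c(t - 2L, t - 1L, t + 1L, t + 2L)
    nb <- nb[nb >= 1L & nb <= Tn]
    mean(K[t, nb])
  }, numeric(1))
}

#' Eigendecompose a covariance surface on the index grid
#'
#' Discrete eigenanalysis with rectangle-rule quadrature at unit grid
#' spacing (the domain is an index set, so each grid cell has weight 1):
#' eigenvalues of the matrix are the functional eigenvalues and unit-norm
#' eigenvectors are the eigenfunctions. Negative eigenvalues (sampling
#' artifacts) are truncated and excluded. The sign of each eigenfunction is
#' fixed so its largest-magnitude entry is positive.
#'
#' @param K Symmetric T x T surface (asymmetry beyond 1e-8 is an error).
#' @param pve Optional cumulative proportion-of-variance cutoff or integer
#'   count to truncate the returned components; default keeps all positive
#'   ones.
#' @return List with `functions` (n_comp x T matrix, rows = eigenfunctions)
#'   and `values` (positive, non-increasing).
#' @export
eigendecompose_level <- function(K, pve = NULL) {
  if (max(abs(K - t(K))) > 1e-8) stop("'K' must be symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  pos <- e$values > max(0, .Machine$double.eps * max(abs(e$values)) * ncol(K))
  values <- e$values[pos]
  vectors <- e$vectors[, pos, drop = FALSE]
  if (!is.null(pve) && length(values)) {
    n_keep <- if (pve >= 1) min(as.integer(pve), length(values))
    else max(1L, which(cumsum(values) / sum(values) >= pve)[1])
    values <- values[seq_len(n_keep)]
    vectors <- vectors[, seq_len(n_keep), drop = FALSE]
  }
  funs <- t(vectors)
  for (k in seq_len(nrow(funs))) {
    i <- which.max(abs(funs[k, ]))
    if (funs[k, i] < 0) funs[k, ] <- -funs[k, ]
  }
  list(functions = funs, values = values)
}

#' Choose the number of components per level (90% rule)
#'
#' Components from both levels are pooled, sorted by eigenvalue, and added
#' greedily until their cumulative share of the combined total variance
#' reaches `total_pve`; the per-level counts of the selected set are
#' returned, with a floor of one retained component per level (when that
#' level has any positive eigenvalue).
#'
#' @param lambda1_full,lambda2_full Non-negative, non-increasing spectra.
#' @param total_pve Cumulative-share threshold (default 0.90).
#' @return List with `N1` and `N2`.
#' @export
select_components <- function(lambda1_full, lambda2_full, total_pve = 0.90) {
  l1 <- lambda1_full; l2 <- lambda2_full
  if (any(c(l1, l2) < 0)) stop("spectra must be non-negative")
  total <- sum(l1) + sum(l2)
  if (total <= 0) stop("all-zero spectra")
  pooled <- data.frame(level = rep(c(1L, 2L), c(length(l1), length(l2))),
                       value = c(l1, l2))
  pooled <- pooled[order(-pooled$value, pooled$level), ]
  n_sel <- which(cumsum(pooled$value) / total >= total_pve)[1]
  if (is.na(n_sel)) n_sel <- nrow(pooled)
  sel <- pooled$level[seq_len(n_sel)]
  list(N1 = max(sum(sel == 1L), min(1L, length(l1))),
       N2 = max(sum(sel == 2L), min(1L, length(l2))))
}

#' Fit the two-level functional PCA
#'
#' Full pipeline on a registered curve matrix: mean and day-shift
#' estimation, between/within covariance surfaces with noise-variance
#' estimation, per-level eigendecomposition, pooled-greedy component
#' selection at `pve` total variance, and BLUP score prediction.
#'
#' @param x A `"registered_matrix"` (from [build_matrix()]), a
#'   `"sim_curves"` object, or a numeric matrix.
#' @param mask,subject,day_order Required when `x` is a bare matrix.
#' @param pve Total proportion-of-variance threshold for component
#'   selection (default 0.90).
#' @param smooth,bandwidth Passed to [estimate_covariances()].
#' @return Object of class `"mfpca_model"` with elements `mu`, `eta`,
#'   `phi1` (N1 x T), `lambda1`, `phi2` (N2 x T), `lambda2`,
#'   `lambda1_full`, `lambda2_full`, `sigma2`, `N1`, `N2`, `rho`
#'   (level-1 share of total variance over the full spectra), `pve1`,
#'   `pve2` (within-level shares of retained components), `scores1`
#'   (one row per subject), `scores2` (one row per participant-day),
#'   `subjects`, `index`, and the fit configuration.
#' @export
mfpca <- function(x, mask = NULL, subject = NULL, day_order = NULL,
                  pve = 0.90, smooth = c("on", "auto", "off"),
                  bandwidth = 2) {
  smooth <- match.arg(smooth)
  if (inherits(x, "sim_curves")) {
    X <- x$curves; mask <- x$mask
    subject <- x$index$participant; day_order <- x$index$day_order
    index <- x$index
  } else if (inherits(x, "registered_matrix")) {
    X <- x$values; mask <- x$mask
    subject <- x$index$participant; day_order <- x$index$day_order
    index <- x$index
  } else {
    X <- as.matrix(x)
    if (is.null(mask)) mask <- !is.na(X)
    if (is.null(subject) || is.null(day_order))
      stop("'subject' and 'day_order' required for a bare matrix")
    index <- data.frame(participant = subject, day_order = day_order)
  }
  obs_cols <- colSums(mask) > 0L
  if (!any(obs_cols)) stop("no observed grid point in any row")
  if (!all(obs_cols)) {
    # grid points observed in no row carry no information: restrict the fit
    # to the observed sub-grid and zero-pad the estimates back afterwards
    warning(sum(!obs_cols), " grid point(s) observed in no row; ",
            "fit restricted to the observed sub-grid")
  }
  cov <- estimate_covariances(X[, obs_cols, drop = FALSE],
                              mask[, obs_cols, drop = FALSE],
                              subject, day_order,
                              smooth = smooth, bandwidth = bandwidth)
  e1 <- eigendecompose_level(cov$K_between)
  e2 <- eigendecompose_level(cov$K_within)
  sel <- select_components(e1$values, e2$values, total_pve = pve)
  embed_vec <- function(v) {
    out <- numeric(ncol(X)); out[obs_cols] <- v; out
  }
  embed_rows <- function(m) {
    out <- matrix(0, nrow(m), ncol(X)); out[, obs_cols] <- m; out
  }
  model <- structure(list(
    T = ncol(X),
    mu = embed_vec(cov$mu), eta = embed_rows(cov$eta),
    phi1 = embed_rows(e1$functions[seq_len(sel$N1), , drop = FALSE]),
    lambda1 = e1$values[seq_len(sel$N1)],
    phi2 = embed_rows(e2$functions[seq_len(sel$N2), , drop = FALSE]),
    lambda2 = e2$values[seq_len(sel$N2)],
    lambda1_full = e1$values, lambda2_full = e2$values,
    sigma2 = cov$sigma2, N1 = sel$N1, N2 = sel$N2,
    rho = sum(e1$values) / (sum(e1$values) + sum(e2$values)),
    pve1 = e1$values[seq_len(sel$N1)] / sum(e1$values),
    pve2 = e2$values[seq_len(sel$N2)] / sum(e2$values),
    empty_frac = cov$empty_frac, smoothed = cov$smoothed,
    config = list(pve = pve, smooth = smooth, bandwidth = bandwidth,
                  sign_convention = "largest-|value| entry positive"),
    index = index), class = "mfpca_model")
  sc <- estimate_scores(model, X, mask, subject, day_order)
  model$scores1 <- sc$scores1
  model$scores2 <- sc$scores2
  model$subjects <- sc$subjects
  model
}

#' Predict principal component scores by BLUP
#'
#' Joint best linear unbiased prediction per subject under the Gaussian
#' model: for each subject the level-1 scores (shared across its days) and
#' per-day level-2 scores are predicted from all of that subject's observed
#' residual values,
#' `scores = (G'G + sigma^2 D^{-1})^{-1} G' r`,
#' where `G` stacks the eigenfunctions at the observed grid points (level-1
#' columns repeat across days, level-2 columns are block-diagonal by day)
#' and `D = diag(lambda1, lambda2 x days)`. With full observation and
#' `sigma^2 = 0` this reduces to the direct inner-product projection; with
#' noise it shrinks scores toward zero. A jitter of `1e-8` is added when
#' the normal matrix is numerically singular.
#'
#' @param model A fitted `"mfpca_model"`.
#' @param X,mask Data matrix and observation mask on the model's grid.
#' @param subject,day_order Row indexing (defaults: those stored in the
#'   model's `index`).
#' @return List with `scores1` (n_subjects x N1, rownames = subject ids),
#'   `scores2` (rows x N2), and `subjects` (ids in `scores1` order).
#' @export
estimate_scores <- function(model, X, mask, subject = NULL,
                            day_order = NULL) {
  stopifnot(inherits(model, "mfpca_model"))
  subject <- subject %||% model$index$participant
  day_order <- day_order %||% model$index$day_order
  Tn <- ncol(X)
  if (Tn != model$T) stop("grid mismatch")
  R <- X - matrix(model$mu, nrow(X), Tn, byrow = TRUE) -
    model$eta[pmin(day_order, nrow(model$eta)), , drop = FALSE]
  N1 <- model$N1; N2 <- model$N2
  P1 <- t(model$phi1)                    # T x N1
  P2 <- t(model$phi2)                    # T x N2
  lam <- c(model$lambda1, model$lambda2) # for D^{-1} blocks
  sid <- factor(subject, levels = unique(subject))
  subjects <- levels(sid)
  scores1 <- matrix(NA_real_, length(subjects), N1)
  rownames(scores1) <- subjects
  if (N1 > 0L) colnames(scores1) <- paste0("PC", seq_len(N1))
  scores2 <- matrix(NA_real_, nrow(X), N2)
  if (N2 > 0L) colnames(scores2) <- paste0("PC", seq_len(N2))
  for (s in seq_along(subjects)) {
    rows <- which(sid == subjects[s])
    obs <- lapply(rows, function(r) which(mask[r, ]))
    if (sum(lengths(obs)) == 0L)
      stop("subject ", subjects[s], " has zero observed entries")
    d <- length(rows)
    q <- N1 + d * N2
    GtG <- matrix(0, q, q)
    Gtr <- numeric(q)
    for (k in seq_len(d)) {
      o <- obs[[k]]
      if (!length(o)) next
      r <- R[rows[k], o]
      P1o <- P1[o, , drop = FALSE]
      P2o <- P2[o, , drop = FALSE]
      i2 <- N1 + (k - 1L) * N2 + seq_len(N2)
      GtG[seq_len(N1), seq_len(N1)] <-
        GtG[seq_len(N1), seq_len(N1)] + crossprod(P1o)
      GtG[i2, i2] <- crossprod(P2o)
      cross <- crossprod(P1o, P2o)
      GtG[seq_len(N1), i2] <- cross
      GtG[i2, seq_len(N1)] <- t(cross)
      Gtr[seq_len(N1)] <- Gtr[seq_len(N1)] + crossprod(P1o, r)
      Gtr[i2] <- crossprod(P2o, r)
    }
    Dinv <- diag(1 / c(model$lambda1, rep(model$lambda2, d)), q)
    A <- GtG + model$sigma2 * Dinv
    est <- tryCatch(solve(A, Gtr), error = function(e) {
      solve(A + 1e-8 * mean(diag(A)) * diag(q), Gtr)
    })
    scores1[s, ] <- est[seq_len(N1)]
    for (k in seq_len(d))
      scores2[rows[k], ] <- est[N1 + (k - 1L) * N2 + seq_len(N2)]
  }
  list(scores1 = scores1, scores2 = scores2, subjects = subjects)
}

#' Incremental model-based reconstruction of a participant-day curve
#'
#' Builds the fitted curve one model term at a time: stage 1 is the
#' overall mean `mu`; stage 2 adds the day shift `eta_j`; stage 3 adds the
#' subject-level component contribution; stage 4 adds the day-level
#' contribution. Stages are nested by construction.
#'
#' @param model Fitted `"mfpca_model"` (with scores).
#' @param participant,day_order Identify the participant-day (must be
#'   present in the fitted index).
#' @param stage Integer 1-4.
#' @return Numeric fitted curve over the grid.
#' @export
reconstruct <- function(model, participant, day_order, stage = 4L) {
  stopifnot(inherits(model, "mfpca_model"), stage %in% 1:4)
  fit <- model$mu
  if (stage >= 2)
    fit <- fit + model$eta[min(day_order, nrow(model$eta)), ]
  if (stage >= 3) {
    s <- match(as.character(participant), rownames(model$scores1))
    if (is.na(s)) stop("unknown participant: ", participant)
    fit <- fit + drop(model$scores1[s, , drop = FALSE] %*% model$phi1)
  }
  if (stage >= 4) {
    row <- which(model$index$participant == participant &
                   model$index$day_order == day_order)
    if (length(row) != 1L)
      stop("unknown participant-day: ", participant, ", ", day_order)
    fit <- fit + drop(model$scores2[row, , drop = FALSE] %*% model$phi2)
  }
  fit
}

#' Variance decomposition summary
#'
#' Per-level, per-component eigenvalues with within-level and total-variance
#' proportions, plus `rho`, the share of total process variance attributed
#' to the subject level (computed over the full non-negative spectra, not
#' just the retained components).
#'
#' @param model Fitted `"mfpca_model"`.
#' @return Data frame (`level`, `component`, `eigenvalue`,
#'   `prop_within_level`, `prop_total`) with attribute `rho`.
#' @export
variance_summary <- function(model) {
  stopifnot(inherits(model, "mfpca_model"))
  l1 <- model$lambda1_full; l2 <- model$lambda2_full
  total <- sum(l1) + sum(l2)
  out <- data.frame(
    level = rep(c(1L, 2L), c(length(l1), length(l2))),
    component = c(seq_along(l1), seq_along(l2)),
    eigenvalue = c(l1, l2),
    prop_within_level = c(if (length(l1)) l1 / sum(l1),
                          if (length(l2)) l2 / sum(l2)),
    prop_total = c(l1, l2) / total)
  attr(out, "rho") <- if (length(l1)) sum(l1) / total else NA_real_
  if (!length(l2)) attr(out, "rho") <- 1
  out
}

#' @export
print.mfpca_model <- function(x, ...) {
  cat("Two-level functional PCA fit\n")
  cat(sprintf("  grid length T = %d, rows = %d, subjects = %d\n",
              x$T, nrow(x$index), nrow(x$scores1)))
  cat(sprintf("  N1 = %d (level-1 shares: %s)\n", x$N1,
              paste(sprintf("%.1f%%", 100 * x$pve1), collapse = ", ")))
  cat(sprintf("  N2 = %d (level-2 shares: %s)\n", x$N2,
              paste(sprintf("%.1f%%", 100 * x$pve2), collapse = ", ")))
  cat(sprintf("  level-1 share of total variance rho = %.1f%%\n",
              100 * x$rho))
  cat(sprintf("  sigma2 = %.4g%s\n", x$sigma2,
              if (x$smoothed) " (smoothed surfaces)" else ""))
  invisible(x)
}
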