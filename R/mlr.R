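# Multiple linear regression with the QSPR validation battery.
#
# The response is the (signed) log10 of the initial hydrogenation rate r0;
# descriptors enter untransformed. Internal validation uses leave-one-out
# (PRESS via the hat-diagonal identity), bootstrap out-of-bag prediction,
# and Y-randomization; external validation uses held-out rows.

# fast OLS workhorse: intercept-augmented design, QR once
ols_stats <- function(X, y) {
  Xa <- cbind(`(Intercept)` = 1, X)
  qr_ <- qr(Xa)
  if (qr_$rank < ncol(Xa)) {
    dep <- colnames(Xa)[qr_$pivot[seq.int(qr_$rank + 1L, ncol(Xa))]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  coef <- qr.coef(qr_, y)
  fitted <- as.numeric(Xa %*% coef)
  e <- y - fitted
  n <- length(y); p <- ncol(Xa)
  Q <- qr.Q(qr_)
  h <- rowSums(Q^2)
  sst <- sum((y - mean(y))^2)
  sse <- sum(e^2)
  r2 <- 1 - sse / sst
  s2 <- sse / (n - p)
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(diag(XtXinv) * s2)
  names(se) <- colnames(Xa)
  list(coef = coef, se = se, residuals = e, fitted = fitted, hat = h,
       r2 = r2, s = sqrt(s2), sse = sse, sst = sst, n = n, k = p - 1L,
       XtXinv = XtXinv)
}

#' Fit an ordinary least squares QSPR model with intercept
#'
#' @param X numeric matrix of descriptors, one column per predictor.
#' @param y numeric response (log10 initial rate).
#' @return object of class `"mlr_fit"`: coefficients with standard errors,
#'   `R2`, residual standard error `s`, `F` with `(k, n-k-1)` degrees of
#'   freedom, residuals, fitted values and the hat diagonal.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("X and y sizes disagree")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("X and y must be finite, no missing values")
  if (any(apply(X, 2L, stats::sd) == 0)) {
    stop("constant descriptor column(s): ",
         paste(colnames(X)[apply(X, 2L, stats::sd) == 0], collapse = ", "))
  }
  st <- ols_stats(X, y)
  k <- st$k; n <- st$n
  Fstat <- (st$r2 / k) / ((1 - st$r2) / (n - k - 1L))
  structure(
    list(coefficients = st$coef, se = st$se, R2 = st$r2, s = st$s,
         F = Fstat, df = c(k, n - k - 1L), residuals = st$residuals,
         fitted = st$fitted, hat = st$hat, n = n, k = k,
         SSE = st$sse, SST = st$sst, XtXinv = st$XtXinv, X = X, y = y),
    class = "mlr_fit"
  )
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat("<mlr_fit> n =", x$n, " k =", x$k, "\n")
  tab <- cbind(coefficient = x$coefficients, se = x$se)
  print(round(tab, 4))
  cat(sprintf("R2 = %.3f; s = %.3f; F(%d,%d) = %.1f\n",
              x$R2, x$s, x$df[1], x$df[2], x$F))
  invisible(x)
}

#' Predict from a fitted MLR model
#' @param object an `mlr_fit`.
#' @param newdata matrix with the training columns.
#' @param ... unused.
#' @export
predict.mlr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(cbind(1, newdata) %*% object$coefficients)
}

#' Descriptor importance as absolute t-statistics and percent shares
#'
#' importance_j = |b_j / se_j| for each non-intercept coefficient;
#' the share is each importance as a percentage of their sum. A zero
#' standard error yields an infinite importance (flagged, not an error).
#'
#' @param fit an `mlr_fit`.
#' @return data frame with `term`, `importance`, `share_pct`.
#' @export
descriptor_importance <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  b <- fit$coefficients[-1L]
  se <- fit$se[-1L]
  imp <- abs(b / se)
  data.frame(term = names(b), importance = unname(imp),
             share_pct = unname(100 * imp / sum(imp)))
}

#' Leave-one-out cross-validated Q^2
#'
#' Uses the PRESS identity e_i / (1 - h_i) on a single fit, which equals the
#' n explicit leave-one-out refits exactly.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @return Q2_LOO = 1 - PRESS / SST.
#' @export
q2_loo <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 2L) stop("leave-one-out needs n > k + 2 (n = ", n, ", k = ", k, ")")
  st <- ols_stats(X, y)
  if (any(st$hat >= 1 - 1e-12)) stop("degenerate leverage (h = 1): observation fully determines its own fit")
  press <- sum((st$residuals / (1 - st$hat))^2)
  1 - press / st$sst
}

#' External-validation Q^2 against held-out rows
#'
#' Q2_EXT = 1 - sum((y_test - yhat)^2) / sum((y_test - mean(y_train))^2).
#'
#' @param fit an `mlr_fit` trained on the training rows.
#' @param X_test,y_test held-out data.
#' @export
q2_ext <- function(fit, X_test, y_test) {
  yhat <- predict(fit, X_test)
  1 - sum((y_test - yhat)^2) / sum((y_test - mean(fit$y))^2)
}

#' Bootstrap out-of-bag Q^2
#'
#' Draws `B` case resamples with replacement, refits on each, and predicts
#' the rows left out of the resample. The out-of-bag squared errors are
#' pooled and compared to the response variance:
#' Q2_BOO = 1 - mean(oob squared error) / (SST / (n - 1)).
#' Resamples with fewer than k + 2 distinct rows (or with no out-of-bag
#' rows) are skipped and counted.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param B number of resamples (the study used 500).
#' @param seed integer seed.
#' @return list with `q2_boo`, per-resample `resamples`, and `n_skipped`.
#' @export
bootstrap_q2 <- function(X, y, B = 500L, seed = 20250430L) {
  if (B < 1L) stop("B must be >= 1")
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  set.seed(seed)
  var_y <- sum((y - mean(y))^2) / (n - 1L)
  oob_se <- numeric(0)
  per <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (length(unique(idx)) < k + 2L || !length(oob)) {
      skipped <- skipped + 1L
      next
    }
    st <- tryCatch(ols_stats(X[idx, , drop = FALSE], y[idx]),
                   error = function(e) NULL)
    if (is.null(st)) { skipped <- skipped + 1L; next }
    yhat <- as.numeric(cbind(1, X[oob, , drop = FALSE]) %*% st$coef)
    se_b <- (y[oob] - yhat)^2
    oob_se <- c(oob_se, se_b)
    per[b] <- 1 - mean(se_b) / var_y
  }
  list(q2_boo = 1 - mean(oob_se) / var_y, resamples = per[!is.na(per)],
       n_skipped = skipped)
}

#' Y-randomization (response scrambling) null distribution
#'
#' Permutes the response `R` times, refits each time, and records R^2 and
#' Q2_LOO. Under permutation the expected R^2 is k / (n - 1), so a sound
#' model's true R^2 should sit far in the upper tail.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param R number of permutations (the study used 5000).
#' @param seed integer seed.
#' @return list with `mean_r2`, `max_r2`, `mean_q2`, the raw `r2` and `q2`
#'   vectors, and `true_r2_percentile` (share of null R^2 below the
#'   unpermuted fit's R^2).
#' @export
y_randomization <- function(X, y, R = 5000L, seed = 20250430L) {
  if (R < 1L) stop("R must be >= 1")
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(seed)
  r2 <- numeric(R); q2 <- numeric(R)
  for (r in seq_len(R)) {
    yp <- y[sample.int(n)]
    st <- ols_stats(X, yp)
    r2[r] <- st$r2
    press <- sum((st$residuals / (1 - st$hat))^2)
    q2[r] <- 1 - press / st$sst
  }
  true_r2 <- ols_stats(X, y)$r2
  list(mean_r2 = mean(r2), max_r2 = max(r2), mean_q2 = mean(q2),
       r2 = r2, q2 = q2, true_r2 = true_r2,
       true_r2_percentile = mean(r2 < true_r2))
}

#' Residual diagnostics: normality, autocorrelation, collinearity
#'
#' Shapiro-Wilk W on the residuals (Royston approximation via
#' [stats::shapiro.test()]); Durbin-Watson d = sum((e_t - e_{t-1})^2) /
#' sum(e_t^2) with a two-sided permutation p-value (the residual order is
#' permuted `n_perm` times and |d - 2| compared); VIF_j = 1 / (1 - R2_j)
#' from the auxiliary regression of column j on the others.
#'
#' @param fit an `mlr_fit`.
#' @param n_perm permutations for the Durbin-Watson p-value.
#' @param seed integer seed.
#' @return list with `shapiro_w`, `shapiro_p`, `dw_d`, `dw_p`, `vif`.
#' @export
residual_diagnostics <- function(fit, n_perm = 10000L, seed = 20250430L) {
  stopifnot(inherits(fit, "mlr_fit"))
  e <- fit$residuals
  sw <- stats::shapiro.test(e)
  if (stats::sd(e) == 0) {
    dw <- NA_real_; dw_p <- NA_real_
  } else {
    dw_stat <- function(x) sum(diff(x)^2) / sum(x^2)
    dw <- dw_stat(e)
    set.seed(seed)
    dev <- abs(dw - 2)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (abs(dw_stat(e[sample.int(length(e))]) - 2) >= dev) hits <- hits + 1L
    }
    dw_p <- (hits + 1L) / (n_perm + 1L)
  }
  X <- fit$X
  vif <- vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1L) return(1)
    r2j <- ols_stats(X[, -j, drop = FALSE], X[, j])$r2
    1 / (1 - r2j)
  }, numeric(1))
  names(vif) <- colnames(X)
  list(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       dw_d = dw, dw_p = dw_p, vif = vif)
}

#' Full validation report for a fitted model
#'
#' Bundles leave-one-out, bootstrap, Y-randomization, residual diagnostics
#' and (when test rows are given) external validation.
#'
#' @param X,y training data.
#' @param X_test,y_test optional held-out data.
#' @param B bootstrap resamples.
#' @param R Y-randomization permutations.
#' @param seed integer seed.
#' @export
validation_report <- function(X, y, X_test = NULL, y_test = NULL,
                              B = 500L, R = 5000L, seed = 20250430L) {
  fit <- fit_mlr(X, y)
  boo <- bootstrap_q2(X, y, B = B, seed = seed)
  yr <- y_randomization(X, y, R = R, seed = seed)
  diag <- residual_diagnostics(fit, seed = seed)
  out <- list(
    fit = fit,
    q2_loo = q2_loo(X, y),
    q2_boo = boo$q2_boo,
    y_randomization = list(mean_r2 = yr$mean_r2, mean_q2 = yr$mean_q2,
                           true_r2_percentile = yr$true_r2_percentile),
    diagnostics = diag
  )
  if (!is.null(X_test)) out$q2_ext <- q2_ext(fit, X_test, y_test)
  out
}
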