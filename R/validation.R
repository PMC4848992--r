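# Model-quality statistics: R2, RMSE, F statistics, leave-one-out Q2,
# external-test statistics and Y-randomization.

#' Squared correlation coefficient
#'
#' `R2` as the squared Pearson correlation between observed and predicted
#' values — the convention that reproduces the external-test statistics of
#' the reference study exactly from its printed prediction columns.
#'
#' @param y,yhat numeric vectors of equal length (n >= 3), non-constant.
#' @return a value in `[0, 1]`.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 3L) stop("need at least 3 observations")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(y, yhat)^2
}

#' Root-mean-square error
#'
#' Population form `sqrt(mean((y - yhat)^2))`; this is the convention that
#' reproduces the training and test RMSE of the reference study from its
#' printed prediction columns (the `n - p - 1` form does not).
#'
#' @param y,yhat numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  sqrt(mean((y - yhat)^2))
}

#' F statistic of a regression from its R2
#'
#' `(R2/p) / ((1 - R2)/(n - p - 1))`.
#'
#' @param r2 coefficient of determination in `[0, 1)` (`Inf` returned at 1).
#' @param n number of observations (> p + 1).
#' @param p number of predictors.
#' @return the F statistic.
#' @export
f_statistic <- function(r2, n, p) {
  stopifnot(r2 >= 0, r2 <= 1, n > p + 1)
  if (r2 == 1) return(Inf)
  (r2 / p) / ((1 - r2) / (n - p - 1))
}

#' Upper-tail critical value of the F distribution
#'
#' @param alpha upper-tail probability in (0, 1).
#' @param df1,df2 degrees of freedom (>= 1).
#' @return the `1 - alpha` quantile of `F(df1, df2)`.
#' @export
f_critical <- function(alpha, df1, df2) {
  stopifnot(alpha > 0, alpha < 1, df1 >= 1, df2 >= 1)
  stats::qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Leave-one-out cross-validated Q2
#'
#' For each row i the model with the fixed column set is refitted on the
#' remaining n-1 rows and row i is predicted; `Q2 = 1 - PRESS/SST` with SST
#' about the full-sample mean, and `rmse_loo = sqrt(PRESS/n)`. Computed via
#' the exact hat-matrix identity `e_i / (1 - h_i)` for the leave-one-out
#' residuals.
#'
#' @param X numeric matrix or data frame of descriptors.
#' @param y numeric response.
#' @return a list with `q2` and `rmse_loo`.
#' @export
q2_loo <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2L) stop("need n > p + 2 for leave-one-out")
  fit <- stats::lm.fit(cbind(1, X), y)
  if (fit$rank < p + 1L) stop("rank-deficient descriptor matrix")
  Q <- qr.Q(fit$qr)
  h <- rowSums(Q^2)
  if (any(h > 1 - 1e-10))
    stop("leave-one-out undefined: deleting row ",
         which.max(h), " makes the fit singular")
  e_loo <- fit$residuals / (1 - h)
  press <- sum(e_loo^2)
  sst <- sum((y - mean(y))^2)
  list(q2 = 1 - press / sst, rmse_loo = sqrt(press / n))
}

#' Y-randomization (response scrambling) test
#'
#' Shuffles the response k times (seeded), refits OLS on the fixed selected
#' descriptor set for each shuffle, and records the training R2 and the
#' leave-one-out Q2. A sound model shows shuffled R2 values near the null
#' expectation p/(n-1) and Q2 values near or below zero.
#'
#' @param X numeric matrix or data frame of the selected descriptors.
#' @param y numeric response.
#' @param k number of randomization runs (>= 1).
#' @param seed integer RNG seed.
#' @return a list with `runs` (data frame with columns `r2`, `q2`) and
#'   `seed`.
#' @export
y_randomization <- function(X, y, k = 10L, seed = 1L) {
  stopifnot(k >= 1L)
  X <- as.matrix(X)
  if (stats::sd(y) == 0) stop("response is constant; R2 undefined")
  runs <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(k), function(i) {
      ys <- sample(y)
      m <- fit_ols(X, ys)
      data.frame(r2 = m$r2, q2 = q2_loo(X, ys)$q2)
    }))
  })
  list(runs = runs, seed = seed)
}

#' Assemble a validation report
#'
#' Collects every statistic reported for model quality: training R2/RMSE,
#' F statistic and critical value, LOO Q2 (when the descriptor matrix is
#' supplied), and external-test R2/RMSE.
#'
#' @param y_train,pred_train training responses and predictions.
#' @param y_test,pred_test test responses and predictions (optional).
#' @param p number of model descriptors (for the F statistics).
#' @param X_train optional training descriptor matrix; enables Q2_LOO.
#' @param alpha upper-tail probability for the F critical value
#'   (default 0.005).
#' @return a list of class `validation_report`.
#' @export
validation_report <- function(y_train, pred_train, y_test = NULL,
                              pred_test = NULL, p, X_train = NULL,
                              alpha = 0.005) {
  n <- length(y_train)
  r2tr <- r_squared(y_train, pred_train)
  rep <- list(
    n_train = n, n_test = length(y_test), p = p,
    r2_train = r2tr,
    rmse_train = rmse(y_train, pred_train),
    f_stat = f_statistic(r2tr, n, p),
    f_critical = f_critical(alpha, p, n - p - 1),
    q2_loo = NA_real_, rmse_loo = NA_real_,
    r2_test = NA_real_, rmse_test = NA_real_
  )
  if (!is.null(X_train)) {
    loo <- q2_loo(X_train, y_train)
    rep$q2_loo <- loo$q2; rep$rmse_loo <- loo$rmse_loo
  }
  if (!is.null(y_test)) {
    rep$r2_test <- r_squared(y_test, pred_test)
    rep$rmse_test <- rmse(y_test, pred_test)
  }
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("train (n=%d): R2 = %.3f  RMSE = %.3f  F = %.3f (crit %.2f)\n",
              x$n_train, x$r2_train, x$rmse_train, x$f_stat, x$f_critical))
  if (!is.na(x$q2_loo))
    cat(sprintf("LOO: Q2 = %.3f  RMSE = %.3f\n", x$q2_loo, x$rmse_loo))
  if (!is.na(x$r2_test))
    cat(sprintf("test (n=%d): R2 = %.3f  RMSE = %.3f\n",
                x$n_test, x$r2_test, x$rmse_test))
  invisible(x)
}
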