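# Ordinary least squares, stepwise descriptor selection, collinearity
# diagnostics and prediction with the fixed published coefficient set.

#' Fit an ordinary least-squares model with intercept
#'
#' Wraps `stats::lm` and reports the statistics used throughout the QSAR
#' workflow: coefficients with standard errors, standardized coefficients
#' (`b_j * sd(x_j) / sd(y)`), the squared correlation `r2`, the population
#' root-mean-square error `rmse = sqrt(SSE/n)` and the F statistic.
#'
#' @param X numeric matrix or data frame of descriptors (n x p).
#' @param y numeric response of length n.
#' @return an object of class `mlr_model`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 1L) stop("need n > p + 1 observations")
  if (qr(cbind(1, X))$rank < p + 1L) {
    # name the offending columns for the error message
    qx <- qr(cbind(1, X))
    dep <- colnames(X)[setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)] - 1L)]
    stop("descriptor matrix is rank deficient",
         if (length(dep)) paste0(" (dependent: ",
                                 paste(dep, collapse = ", "), ")"))
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  cf <- summary(fit)$coefficients
  res <- stats::residuals(fit)
  sse <- sum(res^2); sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  model <- list(
    descriptor_names = colnames(X),
    coefficients = stats::coef(fit)[-1],
    se = cf[-1, 2],
    intercept = unname(stats::coef(fit)[1]),
    intercept_se = cf[1, 2],
    std_coefficients = stats::coef(fit)[-1] *
      apply(X, 2, stats::sd) / stats::sd(y),
    n_train = n, p = p,
    r2 = r2,
    rmse = sqrt(sse / n),
    f_stat = f_statistic(r2, n, p),
    fitted = stats::fitted(fit),
    residuals = res,
    lm = fit
  )
  class(model) <- "mlr_model"
  model
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("Multiple linear regression:", x$p, "descriptors, n =", x$n_train, "\n")
  tab <- data.frame(coefficient = x$coefficients, se = x$se,
                    standardized = x$std_coefficients)
  print(round(tab, 4))
  cat(sprintf("intercept %.4f (se %.4f)\n", x$intercept, x$intercept_se))
  cat(sprintf("R2 = %.4f  RMSE = %.4f  F = %.3f\n", x$r2, x$rmse, x$f_stat))
  invisible(x)
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  predict_mlr(object$coefficients, object$intercept, newdata)
}

#' Predict activity from a fixed linear coefficient vector
#'
#' @param coefficients named numeric coefficient vector.
#' @param intercept scalar intercept.
#' @param descriptors numeric vector (length p), matrix, or data frame with
#'   columns matching the coefficient names.
#' @return predicted value(s): `intercept + descriptors %*% coefficients`.
#' @export
predict_mlr <- function(coefficients, intercept, descriptors) {
  if (is.data.frame(descriptors)) descriptors <- as.matrix(descriptors)
  if (is.null(dim(descriptors)))
    descriptors <- matrix(descriptors, nrow = 1,
                          dimnames = list(NULL, names(descriptors)))
  if (ncol(descriptors) != length(coefficients))
    stop("descriptor vector length (", ncol(descriptors),
         ") does not match coefficient vector (", length(coefficients), ")")
  if (!is.null(colnames(descriptors)) && !is.null(names(coefficients)) &&
      all(names(coefficients) %in% colnames(descriptors)))
    descriptors <- descriptors[, names(coefficients), drop = FALSE]
  drop(descriptors %*% coefficients + intercept)
}

#' The reference five-descriptor model for the AAD FXR series
#'
#' The fixed coefficient set of the published stepwise-MLR model of the
#' anthranilic-acid partial FXR agonist series (trained on 31 compounds):
#' pEC50 = 0.016 ASA + 14.001 RPC- - 0.049 SlogP_VSA2 + 0.362 b_rotN +
#' 0.318 opr_leadlike - 9.717. Useful with [predict_mlr()]; note that
#' descriptor values from different descriptor engines differ, so
#' predictions on engine-computed descriptors approximate, not reproduce,
#' the reference values.
#'
#' @return a list with `name`, `coefficients` (named), `se`, `intercept`,
#'   `intercept_se`.
#' @export
aad_reference_mlr <- function() {
  list(
    name = "aad-fxr-swmlr",
    coefficients = c(ASA = 0.016, RPC_neg = 14.001, SlogP_VSA2 = -0.049,
                     b_rotN = 0.362, opr_leadlike = 0.318),
    se = c(ASA = 0.002, RPC_neg = 4.041, SlogP_VSA2 = 0.0175,
           b_rotN = 0.158, opr_leadlike = 0.276),
    intercept = -9.717,
    intercept_se = 2.221
  )
}

# partial-F p-value for adding/removing one column
.partial_f_p <- function(rss_small, rss_big, n, p_big) {
  df2 <- n - p_big - 1L
  if (df2 <= 0L) return(1)
  f <- (rss_small - rss_big) / (rss_big / df2)
  stats::pf(max(f, 0), 1, df2, lower.tail = FALSE)
}

.rss_of <- function(X, y, cols) {
  if (!length(cols)) return(sum((y - mean(y))^2))
  sum(stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)$residuals^2)
}

#' Stepwise descriptor selection by partial-F tests
#'
#' Classical forward/backward stepwise regression: repeatedly add the
#' candidate whose partial-F p-value is smallest and below `alpha_enter`,
#' then drop any included descriptor whose p-value exceeds `alpha_remove`,
#' until the set stabilizes. Ties break deterministically by column order.
#'
#' @param X numeric matrix or data frame of candidate descriptors.
#' @param y numeric response.
#' @param alpha_enter p-value threshold to enter (default 0.05).
#' @param alpha_remove p-value threshold to stay (default 0.10);
#'   must be >= `alpha_enter`.
#' @param max_steps safety bound on iterations.
#' @return a list with `selected` (column names), `model` (an `mlr_model`
#'   fitted on the final set, or NULL when the selection is empty).
#' @export
stepwise_select <- function(X, y, alpha_enter = 0.05, alpha_remove = 0.10,
                            max_steps = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(alpha_enter <= alpha_remove, nrow(X) > 2L)
  n <- nrow(X); p <- ncol(X)
  sel <- integer(0)
  for (step in seq_len(max_steps)) {
    changed <- FALSE
    # forward
    cand <- setdiff(seq_len(p), sel)
    if (n - (length(sel) + 1L) - 1L <= 0L) cand <- integer(0)  # keep df > 0
    if (length(cand)) {
      rss0 <- .rss_of(X, y, sel)
      pv <- vapply(cand, function(j)
        .partial_f_p(rss0, .rss_of(X, y, c(sel, j)), n, length(sel) + 1L),
        1.0)
      best <- which(pv < alpha_enter)
      if (length(best)) {
        j <- cand[best[which.min(pv[best])]]
        sel <- c(sel, j)
        changed <- TRUE
      }
    }
    # backward
    repeat {
      if (length(sel) == 0L) break
      rss_full <- .rss_of(X, y, sel)
      pv <- vapply(seq_along(sel), function(k)
        .partial_f_p(.rss_of(X, y, sel[-k]), rss_full, n, length(sel)),
        1.0)
      worst <- which.max(pv)
      if (pv[worst] > alpha_remove) {
        sel <- sel[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sel <- sort(sel)
  model <- if (length(sel))
    fit_ols(X[, sel, drop = FALSE], y) else NULL
  list(selected = colnames(X)[sel], model = model)
}

#' Pairwise correlations and variance inflation factors
#'
#' The VIF of descriptor j is `1 / (1 - R_j^2)` where `R_j^2` is the
#' coefficient of determination of descriptor j regressed on all others;
#' computed here from the diagonal of the inverse correlation matrix.
#'
#' @param X numeric matrix or data frame (n x p, p >= 2), non-constant
#'   columns.
#' @return a list with `correlation_matrix` (p x p) and `vif` (named,
#'   each >= 1).
#' @export
collinearity_report <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least two descriptors")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  C <- stats::cor(X)
  vif <- diag(solve(C))
  names(vif) <- colnames(X)
  list(correlation_matrix = C, vif = vif)
}
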