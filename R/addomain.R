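# Applicability-domain analysis: hat-matrix leverages, the warning
# leverage h*, standardized residuals and Williams-plot data.

#' Hat-matrix leverages for training and query compounds
#'
#' `h_i = x_i' (X'X)^-1 x_i` with an intercept column prepended to both the
#' training matrix and the query rows. For the training rows this is the
#' diagonal of the hat matrix; for external compounds the training
#' `(X'X)^-1` is reused, the standard applicability-domain practice.
#'
#' @param X_train numeric matrix/data frame of training descriptors (n x m).
#' @param X_query rows to evaluate (defaults to the training matrix).
#' @return numeric vector of leverages.
#' @export
leverages <- function(X_train, X_query = X_train) {
  X <- cbind(1, as.matrix(X_train))
  Q <- cbind(1, as.matrix(X_query))
  if (ncol(Q) != ncol(X)) stop("query and training column mismatch")
  xtx <- crossprod(X)
  inv <- tryCatch(chol2inv(chol(xtx)),
                  error = function(e) stop("X'X is singular"))
  rowSums((Q %*% inv) * Q)
}

#' Warning leverage threshold h*
#'
#' `h* = 3 (m + 1) / n`, with m the number of model descriptors and n the
#' number of training compounds.
#'
#' @param m number of model descriptors (>= 1).
#' @param n number of training compounds (> m).
#' @return the threshold.
#' @export
warning_leverage <- function(m, n) {
  stopifnot(m >= 1, n > m)
  3 * (m + 1) / n
}

#' Standardized residuals
#'
#' `(y - yhat) / s`, where `s` is the training RMSE (population form). The
#' conventional Y-outlier cut-off is |standardized residual| > 3.
#'
#' @param y,yhat observed and predicted values.
#' @param s positive scale (training RMSE).
#' @return numeric vector.
#' @export
standardized_residuals <- function(y, yhat, s) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0) stop("s must be > 0")
  (y - yhat) / s
}

#' Williams-plot report (leverage vs standardized residual)
#'
#' One record per compound, train and test: leverage against the training
#' descriptor space, standardized residual against the training RMSE, and
#' the outlier flags (`x_outlier` iff leverage > h*, `y_outlier` iff
#' |standardized residual| > 3).
#'
#' @param desc descriptor data frame (row names = compound ids) restricted
#'   to the model descriptors.
#' @param y named or ordered numeric activities (same order as `desc`).
#' @param yhat predicted activities (same order).
#' @param split character vector `"train"`/`"test"` per compound.
#' @param s optional training RMSE; computed from the training rows when
#'   omitted.
#' @return a list of class `leverage_report`: `table` (data frame with id,
#'   leverage, std_residual, role, x_outlier, y_outlier) and `h_star`.
#' @export
williams_report <- function(desc, y, yhat, split = rep("train", length(y)),
                            s = NULL) {
  desc <- as.data.frame(desc)
  stopifnot(nrow(desc) == length(y), length(y) == length(yhat),
            length(split) == length(y), all(split %in% c("train", "test")))
  tr <- split == "train"
  if (!any(tr)) stop("no training compounds")
  if (is.null(s)) s <- rmse(y[tr], yhat[tr])
  h <- leverages(desc[tr, , drop = FALSE], desc)
  hs <- warning_leverage(ncol(desc), sum(tr))
  sr <- standardized_residuals(y, yhat, s)
  tab <- data.frame(
    id = rownames(desc), leverage = h, std_residual = sr, role = split,
    x_outlier = h > hs, y_outlier = abs(sr) > 3,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(table = tab, h_star = hs, s = s), class = "leverage_report")
}

#' @export
print.leverage_report <- function(x, ...) {
  cat("Applicability domain: h* =", round(x$h_star, 3), "\n")
  flagged <- x$table[x$table$x_outlier | x$table$y_outlier, ]
  if (nrow(flagged)) {
    cat("flagged compounds:\n"); print(flagged, row.names = FALSE)
  } else cat("no X or Y outliers\n")
  invisible(x)
}

#' Williams plot
#'
#' @param report a `leverage_report`.
#' @return a ggplot object: leverage vs standardized residual, h* and the
#'   +-3 sigma limits drawn, train and test compounds distinguished.
#' @export
plot_williams <- function(report) {
  tab <- report$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$leverage,
                                    y = .data$std_residual,
                                    shape = .data$role)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = report$h_star, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dotted") +
    ggplot2::labs(x = "leverage", y = "standardized residual",
                  shape = NULL) +
    ggplot2::theme_bw()
}

#' Experimental-vs-predicted scatter plot
#'
#' @param y,yhat observed and predicted activities.
#' @param split optional train/test labels.
#' @return a ggplot object with the identity line.
#' @export
plot_pred_scatter <- function(y, yhat, split = NULL) {
  d <- data.frame(y = y, yhat = yhat,
                  role = if (is.null(split)) "train" else split)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$y, y = .data$yhat,
                                  shape = .data$role)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "experimental pEC50", y = "predicted pEC50",
                  shape = NULL) +
    ggplot2::theme_bw()
}
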