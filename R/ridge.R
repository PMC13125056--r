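#' Configuration of the ridge encoding models
#'
#' @param lambdas Regularization grid; default 30 logarithmically spaced
#'   values from 1e-5 to 1e15, sorted ascending.
#' @param include_ols If `TRUE`, an unpenalized least-squares fit
#'   (lambda = 0, via the pseudoinverse) is added to the grid as the
#'   reference model.
#' @return A list of class `encoding_config`.
#' @export
encoding_config <- function(lambdas = 10^seq(-5, 15, length.out = 30),
                            include_ols = FALSE) {
  if (any(lambdas <= 0)) stop("lambda grid values must be > 0")
  lambdas <- sort(lambdas)
  if (include_ols) lambdas <- c(0, lambdas)
  structure(list(lambdas = lambdas, include_ols = include_ols),
            class = "encoding_config")
}

#' Fit a multivariate ridge regression in closed form
#'
#' Centers predictors and responses and solves
#' `beta = (X'X + lambda I)^{-1} X'Y`; the intercept places the fit through
#' the response means at the predictor means. `lambda = 0` gives the
#' least-squares solution (via the pseudoinverse when X is rank-deficient).
#'
#' @param x Predictor matrix (samples x predictors).
#' @param y Response matrix or vector (samples x targets).
#' @param lambda Non-negative ridge penalty.
#' @return A `ridge_model` with `beta` (predictors x targets), `intercept`
#'   (length targets) and `lambda`.
#' @export
fit_ridge <- function(x, y, lambda) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0) {
    stop("lambda must be a single non-negative number")
  }
  if (anyNA(x) || anyNA(y)) stop("NaN/NA in inputs")
  xm <- colMeans(x); ym <- colMeans(y)
  xc <- sweep(x, 2, xm); yc <- sweep(y, 2, ym)
  s <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * max(s$d, 0)
  shrink <- if (lambda == 0) ifelse(s$d > tol, 1 / s$d, 0) else
    s$d / (s$d^2 + lambda)
  beta <- s$v %*% (shrink * crossprod(s$u, yc))
  dimnames(beta) <- list(colnames(x), colnames(y))
  structure(
    list(beta = beta, intercept = as.numeric(ym - crossprod(beta, xm)),
         lambda = lambda, x_mean = xm),
    class = "ridge_model"
  )
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$beta)) stop("predictor count mismatch")
  sweep(newdata %*% object$beta, 2, object$intercept, `+`)
}

#' @export
print.ridge_model <- function(x, ...) {
  cat("<ridge_model> ", nrow(x$beta), " predictors -> ", ncol(x$beta),
      " targets, lambda=", signif(x$lambda, 3), "\n", sep = "")
  invisible(x)
}

# Validation predictions for every lambda on the grid, via one SVD of the
# centered training predictors. Returns a list of prediction matrices.
ridge_grid_predictions <- function(x_train, y_train, x_new, lambdas) {
  xm <- colMeans(x_train); ym <- colMeans(y_train)
  xc <- sweep(x_train, 2, xm); yc <- sweep(y_train, 2, ym)
  s <- svd(xc)
  uty <- crossprod(s$u, yc)
  xnc <- sweep(x_new, 2, xm)
  xnv <- xnc %*% s$v
  tol <- max(dim(xc)) * .Machine$double.eps * max(s$d, 0)
  lapply(lambdas, function(l) {
    shrink <- if (l == 0) ifelse(s$d > tol, 1 / s$d, 0) else s$d / (s$d^2 + l)
    sweep(xnv %*% (shrink * uty), 2, ym, `+`)
  })
}

#' Select the ridge penalty on a validation split
#'
#' Fits the training data at every grid value, predicts the validation
#' responses, and scores each fit by the Pearson correlation between
#' predicted and true responses averaged over all response columns
#' (channels x timepoints, or components). Returns the grid value with the
#' highest mean correlation; ties go to the smaller lambda. Validation
#' columns with zero variance contribute r = 0 (with a warning).
#'
#' @param x_train,y_train Training predictors and responses.
#' @param x_val,y_val Validation predictors and responses.
#' @param lambdas Penalty grid (default from [encoding_config()]).
#' @return A list of class `lambda_selection`: the selected `lambda` and a
#'   tibble `curve` of mean validation correlation per grid value.
#' @export
select_lambda <- function(x_train, y_train, x_val, y_val,
                          lambdas = encoding_config()$lambdas) {
  if (length(lambdas) == 0) stop("empty lambda grid")
  lambdas <- sort(lambdas)
  x_train <- as.matrix(x_train); y_train <- as.matrix(y_train)
  x_val <- as.matrix(x_val); y_val <- as.matrix(y_val)
  preds <- ridge_grid_predictions(x_train, y_train, x_val, lambdas)
  warned <- FALSE
  score <- vapply(preds, function(p) {
    r <- col_pearson(p, y_val)
    if (anyNA(r)) {
      if (!warned) {
        warning("constant validation or prediction column(s); treating r as 0")
        warned <<- TRUE
      }
      r[is.na(r)] <- 0
    }
    mean(r)
  }, numeric(1))
  best <- which.max(score)  # first maximum = smallest lambda on ties
  structure(
    list(lambda = lambdas[best],
         curve = tibble::tibble(lambda = lambdas, mean_r = score)),
    class = "lambda_selection"
  )
}

#' Variance-weighted average of component correlations
#'
#' `sum(w * r) / sum(w)`: each component's correlation weighted by its
#' explained variance, so components carrying more variance dominate the
#' summary. Equal weights reduce to the arithmetic mean.
#'
#' @param r Per-component correlations.
#' @param weights Non-negative weights (explained variances).
#' @return The weighted mean correlation.
#' @export
weighted_correlation <- function(r, weights) {
  if (length(r) != length(weights)) stop("r and weights differ in length")
  if (any(weights < 0)) stop("weights must be non-negative")
  sum(weights * r) / sum(weights)
}
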