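#' Fit a centered linear PCA on a training matrix
#'
#' Centered, unscaled principal component analysis with a deterministic sign
#' convention: within each component the loading of largest absolute value is
#' made positive, so stored models are comparable across runs.
#'
#' @param x Training matrix (samples x predictors).
#' @param n_components Number of components to retain;
#'   must satisfy `n_components <= min(nrow(x) - 1, ncol(x))`.
#' @return A `pca_model` with orthonormal `loadings` (predictors x
#'   components), the training `mean`, and per-component `explained_variance`
#'   (non-increasing).
#' @export
fit_pca <- function(x, n_components) {
  x <- as.matrix(x)
  if (n_components > min(nrow(x) - 1L, ncol(x))) {
    stop("n_components exceeds min(n_samples - 1, n_predictors)")
  }
  if (all(abs(sweep(x, 2, colMeans(x))) < .Machine$double.eps * 100)) {
    stop("constant matrix: zero variance, PCA undefined")
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  load <- p$rotation[, seq_len(n_components), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  structure(
    list(loadings = load, mean = p$center,
         explained_variance = p$sdev[seq_len(n_components)]^2,
         n_components = as.integer(n_components)),
    class = "pca_model"
  )
}

#' Project a matrix onto a fitted PCA
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param x Matrix with the same predictor count the model was fitted on.
#' @return Scores matrix (samples x components): `(x - train mean) %*% loadings`.
#' @export
apply_pca <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$loadings)) {
    stop("predictor count does not match the fitted PCA")
  }
  sweep(x, 2, model$mean) %*% model$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", nrow(x$loadings), " predictors -> ", x$n_components,
      " components; cumulative variance ",
      round(sum(x$explained_variance), 3), "\n", sep = "")
  invisible(x)
}
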