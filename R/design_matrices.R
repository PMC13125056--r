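#' Prepare per-feature predictor matrices for encoding models
#'
#' Turns raw annotations into the design matrices used by all encoding
#' models. Per feature: (video mode) average over frames, then flatten, then
#' reduce high-dimensional features (native dimension above `n_components`)
#' with a centered PCA fitted on the training split only; low-dimensional
#' features (skeleton: 28 predictors, action: one per category) keep their
#' native dimensions. All splits are projected onto the train-fitted
#' components, so no test or validation information leaks into the predictors.
#'
#' @param annotations An `annotation_set` from [simulate_annotations()].
#' @param design The matching stimulus design.
#' @param n_components Maximum predictor count after PCA (default 100).
#' @return A `feature_design_matrices` object: per feature, `train`,
#'   `validation` and `test` matrices (stimuli x predictors), the fitted
#'   `pca_model` (or `NULL` when PCA was skipped), and per-split stimulus ids.
#' @export
prepare_design_matrices <- function(annotations, design, n_components = 100L) {
  stopifnot(inherits(annotations, "annotation_set"))
  if (!all(c("train", "test", "validation") %in% as.character(design$split))) {
    stop("design is missing a split")
  }
  if (nrow(design) != length(annotations$stimulus_id)) {
    stop("annotations do not cover the design")
  }
  split_rows <- lapply(c(train = "train", validation = "validation", test = "test"),
                       function(s) which(design$split == s))

  prep_feature <- function(f) {
    M <- f$data
    if (annotations$mode == "video") {
      if (length(dim(M)) != 3) stop("video mode requires a frame axis")
      M <- apply(M, c(1, 3), mean)  # frame average; flattening order unchanged
    }
    D <- ncol(M)
    n_train <- length(split_rows$train)
    use_pca <- D > n_components
    if (use_pca) {
      k <- min(n_components, n_train - 1L, D)
      pca <- fit_pca(M[split_rows$train, , drop = FALSE], k)
      mats <- lapply(split_rows, function(r) apply_pca(pca, M[r, , drop = FALSE]))
    } else {
      pca <- NULL
      mats <- lapply(split_rows, function(r) M[r, , drop = FALSE])
    }
    c(mats, list(pca = pca, n_predictors = ncol(mats$train)))
  }

  feats <- purrr::map(annotations$features, prep_feature)
  structure(
    list(features = feats,
         stimulus_id = lapply(split_rows, function(r) design$stimulus_id[r]),
         mode = annotations$mode, n_components = as.integer(n_components)),
    class = "feature_design_matrices"
  )
}

#' @export
print.feature_design_matrices <- function(x, ...) {
  cat("<feature_design_matrices> mode=", x$mode, "\n", sep = "")
  for (nm in names(x$features)) {
    f <- x$features[[nm]]
    cat(sprintf("  %-14s %d predictors (%s), splits %d/%d/%d\n", nm,
                f$n_predictors, if (is.null(f$pca)) "native" else "PCA",
                nrow(f$train), nrow(f$validation), nrow(f$test)))
  }
  invisible(x)
}
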