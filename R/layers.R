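#' Layered-activation model for simulated network responses
#'
#' Describes a stand-in for activations extracted from eight residual blocks
#' of a feedforward vision network. Each feature f contributes
#' `g_{f,l} * (a_f(s)' Q_f)` to layer l, where `g_{f,l}` is a unimodal
#' Gaussian tuning curve over the layer index peaking at the feature's planted
#' peak layer, plus i.i.d. unit noise.
#'
#' @param layers Layer labels in network order (default the eight residual
#'   blocks "1.0" .. "4.1").
#' @param features Feature names; must match the annotation set.
#' @param peak_layer Planted peak layer per feature (label or index).
#' @param tuning_width SD of the layer tuning curve, in layer-index units.
#' @param units_per_layer Units per simulated layer (must be >= 1).
#' @param noise_scale SD of the additive unit noise.
#' @return A list of class `layer_model_spec`.
#' @export
layer_model_spec <- function(
    layers = c("1.0", "1.1", "2.0", "2.1", "3.0", "3.1", "4.0", "4.1"),
    features = c("edges", "reflectance", "lighting", "world_normals",
                 "scene_depth", "skeleton", "action"),
    peak_layer = c("1.0", "2.0", "2.1", "3.0", "3.1", "4.0", "4.1"),
    tuning_width = 0.75,
    units_per_layer = 60L,
    noise_scale = 0.5) {
  if (units_per_layer < 1) stop("units_per_layer must be >= 1")
  if (is.character(peak_layer)) {
    peak_idx <- match(peak_layer, layers)
  } else {
    peak_idx <- as.integer(peak_layer)
  }
  if (anyNA(peak_idx) || any(peak_idx < 1) || any(peak_idx > length(layers))) {
    stop("planted peak layer outside the layer range")
  }
  structure(
    list(layers = layers, features = features,
         peak_idx = setNames(peak_idx, features),
         tuning_width = tuning_width,
         units_per_layer = as.integer(units_per_layer),
         noise_scale = noise_scale),
    class = "layer_model_spec"
  )
}

#' Simulate layered network activations with planted feature peaks
#'
#' @param design Stimulus design from [make_design()].
#' @param annotations Matching `annotation_set`.
#' @param spec A [layer_model_spec()].
#' @param seed Integer seed.
#' @return A `layer_activation_set`: per layer, a stimuli x units activation
#'   matrix, in network order.
#' @export
simulate_layer_activations <- function(design, annotations,
                                       spec = layer_model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "layer_model_spec"))
  set.seed(seed)
  S <- nrow(design)
  U <- spec$units_per_layer
  # per-feature unit signal: standardized projection of the flattened
  # (frame-averaged) annotation into unit space
  unit_sig <- purrr::map(setNames(spec$features, spec$features), function(fname) {
    f <- annotations$features[[fname]]
    if (is.null(f)) stop("annotations missing feature: ", fname)
    M <- f$data
    if (annotations$mode == "video") M <- apply(M, c(1, 3), mean)
    Q <- matrix(rnorm(ncol(M) * U), ncol(M), U) / sqrt(ncol(M))
    X <- scale(M %*% Q)
    X[is.nan(X)] <- 0
    X
  })
  acts <- purrr::map(setNames(seq_along(spec$layers), spec$layers), function(l) {
    A <- matrix(0, S, U)
    for (fname in spec$features) {
      g <- exp(-(l - spec$peak_idx[[fname]])^2 / (2 * spec$tuning_width^2))
      A <- A + g * unit_sig[[fname]]
    }
    A + spec$noise_scale * matrix(rnorm(S * U), S, U)
  })
  structure(
    list(activations = acts, layers = spec$layers,
         stimulus_id = design$stimulus_id, spec = spec, seed = seed),
    class = "layer_activation_set"
  )
}

#' @export
print.layer_activation_set <- function(x, ...) {
  cat("<layer_activation_set> ", length(x$layers), " layers (",
      paste(x$layers, collapse = ", "), "), ",
      nrow(x$activations[[1]]), " stimuli x ", ncol(x$activations[[1]]),
      " units\n", sep = "")
  invisible(x)
}

#' Reduce layer activations with a train-fitted PCA retaining >= 90% variance
#'
#' Per layer, fits a centered PCA on the training stimuli and keeps the
#' smallest number of components whose cumulative explained variance reaches
#' `var_threshold`; all splits are projected onto those components. The kept
#' components' explained variances serve as weights for the variance-weighted
#' encoding accuracy of [encode_layers()].
#'
#' @param raw A `layer_activation_set` (or any named list of stimuli x units
#'   matrices covering the design).
#' @param design The matching stimulus design.
#' @param var_threshold Cumulative explained-variance threshold (default 0.9).
#' @return A `layer_activations` object: per layer, `train`/`validation`/`test`
#'   score matrices and `explained_variance` weights.
#' @export
prepare_layer_activations <- function(raw, design, var_threshold = 0.9) {
  acts <- if (inherits(raw, "layer_activation_set")) raw$activations else raw
  split_rows <- lapply(c(train = "train", validation = "validation", test = "test"),
                       function(s) which(design$split == s))
  layers <- purrr::map(acts, function(M) {
    kmax <- min(length(split_rows$train) - 1L, ncol(M))
    pca <- fit_pca(M[split_rows$train, , drop = FALSE], kmax)
    cum <- cumsum(pca$explained_variance) / sum(pca$explained_variance)
    k <- which(cum >= var_threshold)[1]
    pca$loadings <- pca$loadings[, seq_len(k), drop = FALSE]
    pca$explained_variance <- pca$explained_variance[seq_len(k)]
    pca$n_components <- k
    out <- lapply(split_rows, function(r) apply_pca(pca, M[r, , drop = FALSE]))
    c(out, list(explained_variance = pca$explained_variance, pca = pca))
  })
  structure(
    list(layers = layers, layer_labels = names(acts),
         stimulus_id = lapply(split_rows, function(r) design$stimulus_id[r]),
         var_threshold = var_threshold),
    class = "layer_activations"
  )
}

#' @export
print.layer_activations <- function(x, ...) {
  cat("<layer_activations> ", length(x$layers), " layers, components: ",
      paste(vapply(x$layers, function(l) ncol(l$train), 1L), collapse = ", "),
      " (>= ", round(100 * x$var_threshold), "% train variance)\n", sep = "")
  invisible(x)
}
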