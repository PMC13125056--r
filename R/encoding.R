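#' Time-resolved EEG encoding accuracy per feature
#'
#' For every feature: selects one ridge penalty on the validation split (mean
#' Pearson correlation over all channels and timepoints), refits on the
#' training split at that penalty, predicts the repetition-averaged test
#' responses, and correlates predicted with true responses across test
#' stimuli within every (channel, timepoint) cell. Responses of every split
#' are stimulus means over that split's repetitions; the test set is never
#' touched during penalty selection.
#'
#' @param design_matrices A `feature_design_matrices` from
#'   [prepare_design_matrices()].
#' @param epochs A whitened `eeg_epochs` containing all three splits.
#' @param config An [encoding_config()].
#' @return An `eeg_encoding` object: `accuracy` (tibble of channel-averaged
#'   correlation per feature and timepoint), `surfaces` (per feature, the
#'   channels x timepoints correlation matrix), and `lambda` (selected
#'   penalty per feature).
#' @export
encode_eeg <- function(design_matrices, epochs, config = encoding_config()) {
  stopifnot(inherits(design_matrices, "feature_design_matrices"),
            inherits(epochs, "eeg_epochs"))
  C <- dim(epochs$data)[2]; Tn <- dim(epochs$data)[3]
  resp <- lapply(c(train = "train", validation = "validation", test = "test"),
                 function(s) split_stimulus_means(epochs, s))
  align <- function(split) {
    m <- resp[[split]]
    rows <- match(design_matrices$stimulus_id[[split]], m$stimulus_id)
    if (anyNA(rows)) stop("design matrices and epochs disagree on stimuli")
    m$mean[rows, , drop = FALSE]
  }
  Y <- lapply(c(train = "train", validation = "validation", test = "test"), align)

  feats <- names(design_matrices$features)
  surfaces <- list()
  lambda_tbl <- tibble::tibble(feature = character(), lambda = numeric())
  acc <- list()
  for (fname in feats) {
    f <- design_matrices$features[[fname]]
    sel <- select_lambda(f$train, Y$train, f$validation, Y$validation,
                         lambdas = config$lambdas)
    fit <- fit_ridge(f$train, Y$train, sel$lambda)
    r <- col_pearson(predict(fit, f$test), Y$test)
    r[is.na(r)] <- 0
    surf <- matrix(r, C, Tn, dimnames = list(epochs$channels, NULL))
    surfaces[[fname]] <- surf
    lambda_tbl <- dplyr::bind_rows(lambda_tbl,
      tibble::tibble(feature = fname, lambda = sel$lambda))
    acc[[fname]] <- tibble::tibble(feature = fname, time_ms = epochs$time_ms,
                                   r = colMeans(surf))
  }
  structure(
    list(accuracy = dplyr::bind_rows(acc), surfaces = surfaces,
         lambda = lambda_tbl, time_ms = epochs$time_ms,
         channels = epochs$channels, config = config),
    class = "eeg_encoding"
  )
}

#' @export
print.eeg_encoding <- function(x, ...) {
  cat("<eeg_encoding> ", length(x$surfaces), " features x ",
      length(x$time_ms), " timepoints\n", sep = "")
  peaks <- dplyr::summarise(
    dplyr::group_by(x$accuracy, .data$feature),
    peak_ms = .data$time_ms[which.max(.data$r)], peak_r = max(.data$r))
  print(peaks)
  invisible(x)
}

#' Layer-wise encoding accuracy per feature
#'
#' For every (feature, layer): selects one ridge penalty on the validation
#' activations, refits on the training split, predicts the test-set
#' principal-component scores, correlates per component, and summarizes the
#' layer with the variance-weighted mean of the component correlations
#' ([weighted_correlation()]).
#'
#' @param design_matrices A `feature_design_matrices`.
#' @param layer_activations A `layer_activations` from
#'   [prepare_layer_activations()].
#' @param config An [encoding_config()].
#' @return A `layer_encoding` object: `accuracy` (tibble of weighted
#'   correlation per feature and layer), `detail` (per-component
#'   correlations and weights) and `lambda`.
#' @export
encode_layers <- function(design_matrices, layer_activations,
                          config = encoding_config()) {
  stopifnot(inherits(design_matrices, "feature_design_matrices"),
            inherits(layer_activations, "layer_activations"))
  layers <- layer_activations$layer_labels
  feats <- names(design_matrices$features)
  acc <- list(); detail <- list(); lam <- list()
  for (fname in feats) {
    f <- design_matrices$features[[fname]]
    for (lname in layers) {
      l <- layer_activations$layers[[lname]]
      if (is.null(l$explained_variance)) {
        stop("layer activations missing explained-variance weights")
      }
      sel <- select_lambda(f$train, l$train, f$validation, l$validation,
                           lambdas = config$lambdas)
      fit <- fit_ridge(f$train, l$train, sel$lambda)
      r <- col_pearson(predict(fit, f$test), l$test)
      r[is.na(r)] <- 0
      w <- l$explained_variance
      acc[[paste(fname, lname)]] <- tibble::tibble(
        feature = fname, layer = lname,
        accuracy = weighted_correlation(r, w))
      detail[[paste(fname, lname)]] <- tibble::tibble(
        feature = fname, layer = lname, component = seq_along(r),
        r = r, weight = w)
      lam[[paste(fname, lname)]] <- tibble::tibble(
        feature = fname, layer = lname, lambda = sel$lambda)
    }
  }
  out_acc <- dplyr::mutate(dplyr::bind_rows(acc),
                           layer = factor(.data$layer, levels = layers))
  structure(
    list(accuracy = out_acc, detail = dplyr::bind_rows(detail),
         lambda = dplyr::bind_rows(lam), layers = layers, config = config),
    class = "layer_encoding"
  )
}

#' @export
print.layer_encoding <- function(x, ...) {
  cat("<layer_encoding> ", length(unique(x$accuracy$feature)), " features x ",
      length(x$layers), " layers\n", sep = "")
  peaks <- dplyr::summarise(
    dplyr::group_by(x$accuracy, .data$feature),
    peak_layer = as.character(.data$layer[which.max(.data$accuracy)]),
    peak_r = max(.data$accuracy))
  print(peaks)
  invisible(x)
}

#' Split-half noise ceiling of stimulus-evoked EEG responses
#'
#' Per repetition: the trials of every stimulus are split into two random
#' halves; stimulus-wise mean responses of each half are correlated across
#' stimuli within every (channel, timepoint) cell. Half-vs-half correlations
#' give the lower bound, half-vs-all the upper bound; both are averaged over
#' `n_reps` random groupings.
#'
#' @param epochs An `eeg_epochs` object.
#' @param split Split to use (default `"test"`, the most-repeated split).
#' @param n_reps Number of random half-splits (default 100).
#' @param seed Integer seed.
#' @return A `noise_ceiling` object with `lower` and `upper`
#'   channels x timepoints matrices and a channel-averaged `summary` tibble.
#' @export
noise_ceiling <- function(epochs, split = "test", n_reps = 100L, seed = 1L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- which(epochs$trial_table$split == split)
  if (length(idx) == 0) stop("missing split: ", split)
  sid <- epochs$trial_table$stimulus_id[idx]
  reps <- table(sid)
  if (any(reps < 2)) stop("every stimulus needs >= 2 repetitions")
  if (any(reps %% 2 != 0)) stop("repetition counts must be even")
  d <- dim(epochs$data)
  C <- d[2]; Tn <- d[3]
  flat <- epochs$data[idx, , , drop = FALSE]
  dim(flat) <- c(length(idx), C * Tn)
  all_mean <- rowsum(flat, sid) / as.vector(reps[order(as.integer(names(reps)))])
  stim_rows <- split(seq_along(sid), sid)

  set.seed(seed)
  low <- matrix(0, C, Tn); up <- matrix(0, C, Tn)
  for (i in seq_len(n_reps)) {
    half1 <- unlist(lapply(stim_rows, function(r) sample(r, length(r) / 2)))
    in1 <- seq_along(sid) %in% half1
    m1 <- rowsum(flat[in1, , drop = FALSE], sid[in1])
    m2 <- rowsum(flat[!in1, , drop = FALSE], sid[!in1])
    n1 <- as.vector(table(sid[in1]))
    m1 <- m1 / n1
    m2 <- m2 / as.vector(table(sid[!in1]))
    r_low <- col_pearson(m1, m2)
    r_up <- col_pearson(m1, all_mean)
    r_low[is.na(r_low)] <- 0; r_up[is.na(r_up)] <- 0
    low <- low + matrix(r_low, C, Tn)
    up <- up + matrix(r_up, C, Tn)
  }
  low <- low / n_reps; up <- up / n_reps
  structure(
    list(lower = low, upper = up, time_ms = epochs$time_ms,
         channels = epochs$channels, n_reps = n_reps,
         summary = tibble::tibble(time_ms = epochs$time_ms,
                                  lower = colMeans(low),
                                  upper = colMeans(up))),
    class = "noise_ceiling"
  )
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat("<noise_ceiling> ", x$n_reps, " half-splits; peak lower=",
      round(max(x$summary$lower), 3), ", upper=",
      round(max(x$summary$upper), 3), "\n", sep = "")
  invisible(x)
}
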