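#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an EEG encoding result into one row per feature and timepoint
#'
#' @param x An `eeg_encoding` object.
#' @param ... Unused.
#' @return A tibble with `feature`, `time_ms`, `r`.
#' @method tidy eeg_encoding
#' @export
tidy.eeg_encoding <- function(x, ...) x$accuracy

#' Per-feature summary of an EEG encoding result
#'
#' @param x An `eeg_encoding` object.
#' @param ... Unused.
#' @return A tibble with one row per feature: peak latency, peak correlation
#'   and the selected ridge penalty.
#' @method glance eeg_encoding
#' @export
glance.eeg_encoding <- function(x, ...) {
  peaks <- dplyr::summarise(
    dplyr::group_by(x$accuracy, .data$feature),
    peak_ms = .data$time_ms[which.max(.data$r)],
    peak_r = max(.data$r), .groups = "drop")
  dplyr::left_join(peaks, x$lambda, by = "feature")
}

#' @method tidy layer_encoding
#' @export
tidy.layer_encoding <- function(x, ...) x$accuracy

#' @method glance layer_encoding
#' @export
glance.layer_encoding <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$accuracy, .data$feature),
    peak_layer = as.character(.data$layer[which.max(.data$accuracy)]),
    peak_index = which.max(.data$accuracy),
    peak_r = max(.data$accuracy), .groups = "drop")
}

#' @method tidy noise_ceiling
#' @export
tidy.noise_ceiling <- function(x, ...) x$summary

#' @method tidy hierarchy_correlation
#' @export
tidy.hierarchy_correlation <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rho", "p_value", "n_features",
                                 "n_permutations", "exact")])
}

#' @method glance hierarchy_correlation
#' @export
glance.hierarchy_correlation <- function(x, ...) tidy.hierarchy_correlation(x)

#' @method tidy ridge_model
#' @export
tidy.ridge_model <- function(x, ...) {
  beta <- x$beta
  tibble::tibble(
    term = rep(rownames(beta) %||% paste0("x", seq_len(nrow(beta))),
               times = ncol(beta)),
    target = rep(colnames(beta) %||% paste0("y", seq_len(ncol(beta))),
                 each = nrow(beta)),
    estimate = as.vector(beta))
}

#' @method glance ridge_model
#' @export
glance.ridge_model <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_predictors = nrow(x$beta),
                 n_targets = ncol(x$beta))
}

#' Plot feature encoding time courses
#'
#' @param object An `eeg_encoding` object.
#' @param ... Unused.
#' @return A ggplot: channel-averaged encoding correlation over time, one
#'   line per feature, with stimulus onset marked.
#' @method autoplot eeg_encoding
#' @export
autoplot.eeg_encoding <- function(object, ...) {
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(x = .data$time_ms, y = .data$r,
                               colour = .data$feature)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from stimulus onset (ms)",
                  y = "Encoding accuracy (Pearson r)", colour = "Feature") +
    ggplot2::theme_minimal()
}

#' Plot layer-wise encoding curves
#'
#' @param object A `layer_encoding` object.
#' @param ... Unused.
#' @return A ggplot of variance-weighted encoding accuracy per layer and
#'   feature.
#' @method autoplot layer_encoding
#' @export
autoplot.layer_encoding <- function(object, ...) {
  ggplot2::ggplot(object$accuracy,
                  ggplot2::aes(x = .data$layer, y = .data$accuracy,
                               colour = .data$feature,
                               group = .data$feature)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Network layer", y = "Encoding accuracy (weighted r)",
                  colour = "Feature") +
    ggplot2::theme_minimal()
}

#' Plot a pairwise decoding time course
#'
#' @param object A `decoding_timecourse` tibble from [decode_subject()].
#' @param ... Unused.
#' @return A ggplot of decoding accuracy over time with the 50% chance line.
#' @method autoplot decoding_timecourse
#' @export
autoplot.decoding_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = attr(object, "chance") %||% 50,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from stimulus onset (ms)",
                  y = "Pairwise decoding accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Plot noise-ceiling bounds over time
#'
#' @param object A `noise_ceiling` object.
#' @param ... Unused.
#' @return A ggplot with the channel-averaged lower/upper bounds as a ribbon.
#' @method autoplot noise_ceiling
#' @export
autoplot.noise_ceiling <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$time_ms)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed") +
    ggplot2::labs(x = "Time from stimulus onset (ms)",
                  y = "Split-half correlation") +
    ggplot2::theme_minimal()
}
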