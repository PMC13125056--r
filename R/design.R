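#' Specify how a factorial stimulus set is split into train/test/validation
#'
#' The split mirrors a common generalization-oriented design: a subset of
#' rooms is held out entirely from training, and the held-out rooms are shared
#' between the test and validation sets but seen from disjoint camera
#' viewpoints (half of the cameras each).
#'
#' @param n_holdout_rooms Number of rooms reserved for test + validation
#'   (default 5 of 20).
#' @param n_test_cameras Number of cameras assigned to the test set within the
#'   held-out rooms; the remaining cameras go to validation (default 2 of 4).
#' @return A list of class `design_split_spec`.
#' @export
design_split_spec <- function(n_holdout_rooms = 5L, n_test_cameras = 2L) {
  structure(
    list(n_holdout_rooms = as.integer(n_holdout_rooms),
         n_test_cameras = as.integer(n_test_cameras)),
    class = "design_split_spec"
  )
}

#' Build a full factorial stimulus design with split labels
#'
#' Creates one row per combination of room, action, character and camera
#' (default 20 x 6 x 3 x 4 = 1440 stimuli) and assigns each stimulus to the
#' train, test or validation split. Training contains all stimuli from the
#' non-held-out rooms (all cameras); stimuli from held-out rooms are divided
#' between test and validation by camera, so test/validation rooms never occur
#' in training and test/validation share rooms but not viewpoints.
#'
#' @param n_rooms,n_actions,n_characters,n_cameras Factor level counts.
#' @param split_spec A [design_split_spec()].
#' @param seed Integer seed controlling which rooms/cameras are held out.
#' @return A tibble with columns `stimulus_id`, `room`, `action`, `character`,
#'   `camera`, `split`.
#' @examples
#' d <- make_design(seed = 1)
#' table(d$split)
#' @export
make_design <- function(n_rooms = 20L, n_actions = 6L, n_characters = 3L,
                        n_cameras = 4L, split_spec = design_split_spec(),
                        seed = 1L) {
  if (any(c(n_rooms, n_actions, n_characters, n_cameras) < 1)) {
    stop("all factor level counts must be >= 1")
  }
  if (split_spec$n_holdout_rooms >= n_rooms && n_rooms > 1) {
    stop("split_spec requests at least as many held-out rooms as exist")
  }
  if (split_spec$n_holdout_rooms > n_rooms) {
    stop("split_spec requests more held-out rooms than exist")
  }
  design <- tidyr::expand_grid(
    room = factor(paste0("room", seq_len(n_rooms)),
                  levels = paste0("room", seq_len(n_rooms))),
    action = factor(paste0("action", seq_len(n_actions)),
                    levels = paste0("action", seq_len(n_actions))),
    character = factor(paste0("char", seq_len(n_characters)),
                       levels = paste0("char", seq_len(n_characters))),
    camera = factor(paste0("cam", seq_len(n_cameras)),
                    levels = paste0("cam", seq_len(n_cameras)))
  )
  design <- dplyr::mutate(design, stimulus_id = dplyr::row_number(),
                          .before = 1)

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  picks <- withr_seed({
    holdout_rooms <- if (split_spec$n_holdout_rooms > 0 && n_rooms > 1) {
      sample(levels(design$room), split_spec$n_holdout_rooms)
    } else character(0)
    test_cameras <- if (n_cameras > 1) {
      sample(levels(design$camera), min(split_spec$n_test_cameras, n_cameras - 1L))
    } else character(0)
    list(holdout_rooms = holdout_rooms, test_cameras = test_cameras)
  })

  design <- dplyr::mutate(
    design,
    split = dplyr::case_when(
      !(.data$room %in% picks$holdout_rooms) ~ "train",
      .data$camera %in% picks$test_cameras ~ "test",
      TRUE ~ "validation"
    ),
    split = factor(.data$split, levels = c("train", "test", "validation"))
  )
  attr(design, "holdout_rooms") <- picks$holdout_rooms
  attr(design, "test_cameras") <- picks$test_cameras
  design
}

#' Arithmetic of the rapid serial presentation sequence
#'
#' Computes the timing of one presentation sequence: `n_trials` stimuli of
#' `stimulus_ms` each followed by `iti_ms` of inter-trial interval, plus a
#' response window. With the defaults (10 trials of 300 ms + 100 ms ITI and a
#' 2 s response period) a sequence has 4 s of presentation time and lasts 6 s.
#'
#' @param n_trials Trials per sequence.
#' @param stimulus_ms Stimulus duration (ms).
#' @param iti_ms Inter-trial interval (ms).
#' @param response_s Response window (s).
#' @return A one-row tibble with `presentation_s` and `sequence_s`.
#' @export
sequence_timing <- function(n_trials = 10L, stimulus_ms = 300, iti_ms = 100,
                            response_s = 2) {
  presentation_s <- n_trials * (stimulus_ms + iti_ms) / 1000
  tibble::tibble(
    n_trials = n_trials,
    trial_ms = stimulus_ms + iti_ms,
    presentation_s = presentation_s,
    sequence_s = presentation_s + response_s
  )
}
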