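#' Default configuration of a full synthetic encoding run
#'
#' All stage parameters in one serializable list: the factorial design and
#' its split, annotation and forward-model parameters, layer model, predictor
#' preparation (100 PCA components for high-dimensional features, 90%
#' variance for layer activations), decoding geometry (bin size 5, 6 folds),
#' the 30-value ridge penalty grid, noise-ceiling repetitions (100), and
#' inference settings (10000 permutations and bootstraps, alpha = 0.05).
#' The decoding stage runs on a subset of stimuli and timepoints by default
#' to stay desk-scale; set `decoding$n_stimuli = NULL` for all pairs.
#'
#' @param seed Master seed; each stage consumes its own substream via
#'   [fan_seed()].
#' @param mode `"image"` or `"video"`.
#' @param n_subjects Number of simulated subjects (independent noise and
#'   sensor mixing, shared design and annotations).
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, mode = "image", n_subjects = 5L) {
  structure(list(
    seed = as.integer(seed), mode = mode, n_subjects = as.integer(n_subjects),
    design = list(n_rooms = 20L, n_actions = 6L, n_characters = 3L,
                  n_cameras = 4L, n_holdout_rooms = 5L, n_test_cameras = 2L),
    annotations = list(map_height = 36L, map_width = 27L, latent_rank = 12L,
                       rho = 0.1, pixel_noise = 0.1, n_frames = 9L,
                       frame_jitter = 0.2),
    forward = list(
      tau_ms = list(edges = 80, reflectance = 120, lighting = 160,
                    world_normals = 180, scene_depth = 200, skeleton = 260,
                    action = 420),
      sigma_ms = 25, amplitude = 1, latent_rank = 5L, n_channels = 19L,
      time_from = -400, time_to = 980, time_step = 20,
      reps = list(train = 5L, test = 30L, validation = 5L),
      noise_corr = 0.5, noise_scale = 3, ar1_phi = 0),
    layers = list(
      labels = c("1.0", "1.1", "2.0", "2.1", "3.0", "3.1", "4.0", "4.1"),
      peak_layer = list(edges = "1.0", reflectance = "2.0", lighting = "2.1",
                        world_normals = "3.0", scene_depth = "3.1",
                        skeleton = "4.0", action = "4.1"),
      tuning_width = 0.75, units_per_layer = 60L, noise_scale = 0.5),
    prep = list(n_components = 100L, var_threshold = 0.9),
    decoding = list(bin_size = 5L, n_folds = 6L, n_repeats = 2L,
                    n_stimuli = 8L, time_stride = 2L),
    encoding = list(lambda_log10_min = -5, lambda_log10_max = 15,
                    lambda_n = 30L, include_ols = FALSE),
    ceiling = list(n_reps = 100L),
    inference = list(n_perm = 10000L, n_boot = 10000L, alpha = 0.05)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' `read_config(write_config(cfg, path))` reproduces the configuration.
#'
#' @param config A `run_config` list.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

# Build the stage objects implied by a config.
config_specs <- function(config) {
  fw <- config$forward
  feats <- names(fw$tau_ms)
  list(
    split = design_split_spec(config$design$n_holdout_rooms,
                              config$design$n_test_cameras),
    annotation = annotation_spec(
      features = default_feature_set(
        map_dim = c(config$annotations$map_height, config$annotations$map_width),
        n_actions = config$design$n_actions),
      latent_rank = config$annotations$latent_rank,
      rho = config$annotations$rho,
      pixel_noise = config$annotations$pixel_noise,
      n_frames = config$annotations$n_frames,
      frame_jitter = config$annotations$frame_jitter),
    forward = forward_model_spec(
      features = feats, tau_ms = unlist(fw$tau_ms), sigma_ms = fw$sigma_ms,
      amplitude = fw$amplitude, latent_rank = fw$latent_rank,
      n_channels = fw$n_channels,
      time_ms = seq(fw$time_from, fw$time_to, by = fw$time_step),
      reps = unlist(fw$reps), noise_corr = fw$noise_corr,
      noise_scale = fw$noise_scale, ar1_phi = fw$ar1_phi),
    layer = layer_model_spec(
      layers = config$layers$labels, features = feats,
      peak_layer = unlist(config$layers$peak_layer),
      tuning_width = config$layers$tuning_width,
      units_per_layer = config$layers$units_per_layer,
      noise_scale = config$layers$noise_scale),
    encoding = encoding_config(
      lambdas = 10^seq(config$encoding$lambda_log10_min,
                       config$encoding$lambda_log10_max,
                       length.out = config$encoding$lambda_n),
      include_ols = isTRUE(config$encoding$include_ols))
  )
}

#' Simulate a complete experiment (design, annotations, EEG, activations)
#'
#' One call to the whole generator: factorial design with splits, per-
#' stimulus annotations, one set of epoched EEG per subject (each subject
#' gets independent sensor mixing and noise), and layered network
#' activations.
#'
#' @param config A [default_config()]-style `run_config`.
#' @return A `scene_experiment` list: `design`, `annotations`, `subjects`
#'   (list of `eeg_epochs`), `activations`, `config`.
#' @export
simulate_experiment <- function(config = default_config()) {
  sp <- config_specs(config)
  design <- make_design(config$design$n_rooms, config$design$n_actions,
                        config$design$n_characters, config$design$n_cameras,
                        split_spec = sp$split,
                        seed = fan_seed(config$seed, "design"))
  ann <- simulate_annotations(design, sp$annotation, mode = config$mode,
                              seed = fan_seed(config$seed, "annotations"))
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    simulate_eeg(design, ann, sp$forward,
                 seed = fan_seed(config$seed, "subjects", i))
  })
  acts <- simulate_layer_activations(design, ann, sp$layer,
                                     seed = fan_seed(config$seed, "layers"))
  structure(list(design = design, annotations = ann, subjects = subjects,
                 activations = acts, config = config),
            class = "scene_experiment")
}

#' Validate the internal consistency of a simulated experiment
#'
#' Checks the container invariants: full factorial design, disjoint and
#' exhaustive splits, annotations covering every stimulus, trial tables
#' referencing existing stimuli, a strictly increasing uniform time axis,
#' and consistent channel/stimulus dimensions.
#'
#' @param x A `scene_experiment` from [simulate_experiment()].
#' @return A tibble with one row per check: `check`, `pass`, `detail`.
#' @export
validate_experiment <- function(x) {
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = name, pass = pass, detail = detail)
  }
  d <- x$design
  combos <- nrow(dplyr::distinct(d[, c("room", "action", "character", "camera")]))
  n_expected <- nlevels(d$room) * nlevels(d$action) * nlevels(d$character) *
    nlevels(d$camera)
  add("design_factorial", combos == nrow(d) && nrow(d) == n_expected,
      paste0(nrow(d), " stimuli"))
  add("splits_exhaustive", !anyNA(d$split) &&
        all(levels(d$split) == c("train", "test", "validation")))
  train_rooms <- unique(d$room[d$split == "train"])
  held <- unique(d$room[d$split != "train"])
  add("holdout_rooms_unseen", nrow(d) == 1 ||
        length(intersect(train_rooms, held)) == 0,
      paste0(length(held), " held-out rooms"))
  ann_ok <- all(vapply(x$annotations$features, function(f) {
    n <- if (length(dim(f$data)) == 3) dim(f$data)[1] else nrow(f$data)
    n == nrow(d)
  }, logical(1)))
  add("annotations_cover_design", ann_ok &&
        identical(x$annotations$stimulus_id, d$stimulus_id))
  for (i in seq_along(x$subjects)) {
    ep <- x$subjects[[i]]
    tt_ok <- all(ep$trial_table$stimulus_id %in% d$stimulus_id)
    steps <- diff(ep$time_ms)
    grid_ok <- all(steps > 0) && max(abs(steps - steps[1])) < 1e-9
    add(paste0("subject", i, "_trials_reference_design"), tt_ok)
    add(paste0("subject", i, "_uniform_time_grid"), grid_ok,
        paste0(length(ep$time_ms), " points"))
    add(paste0("subject", i, "_dims"),
        all(dim(ep$data) == c(nrow(ep$trial_table), length(ep$channels),
                              length(ep$time_ms))))
  }
  act_ok <- all(vapply(x$activations$activations,
                       function(m) nrow(m) == nrow(d), logical(1)))
  add("activations_cover_design", act_ok)
  dplyr::bind_rows(checks)
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Executes simulate, predictor preparation, multivariate noise
#' normalization, pairwise decoding, EEG and layer encoding, noise ceilings,
#' group statistics and the hierarchy correlation, writing plain-text
#' results (CSV/JSON) plus a manifest into `out_dir`. Stage outputs are
#' cached under `out_dir/cache`, so a rerun with `resume = TRUE` resumes
#' after the last completed stage.
#'
#' @param config A `run_config` from [default_config()].
#' @param out_dir Output directory (created if missing).
#' @param resume Reuse cached stage outputs when present (default TRUE).
#' @return Invisibly, a list with all stage results and the manifest tibble.
#' @export
run_pipeline <- function(config = default_config(), out_dir, resume = TRUE) {
  dir.create(file.path(out_dir, "cache"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  stage <- function(name, fun) {
    cache <- file.path(out_dir, "cache", paste0(name, ".rds"))
    t0 <- proc.time()[["elapsed"]]
    if (resume && file.exists(cache)) {
      value <- readRDS(cache)
      status <- "cached"
    } else {
      value <- tryCatch(fun(), error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      })
      saveRDS(value, cache)
      status <- "complete"
    }
    manifest[[name]] <<- tibble::tibble(
      stage = name, status = status,
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    value
  }
  sp <- config_specs(config)
  alpha <- config$inference$alpha

  exper <- stage("simulate", function() simulate_experiment(config))
  prep <- stage("prep", function() {
    list(dm = prepare_design_matrices(exper$annotations, exper$design,
                                      n_components = config$prep$n_components),
         acts = prepare_layer_activations(exper$activations, exper$design,
                                          var_threshold = config$prep$var_threshold))
  })
  white <- stage("mvnn", function() {
    lapply(exper$subjects, function(ep) mvnn(baseline_correct(ep)))
  })
  decode <- stage("decode", function() {
    dcfg <- config$decoding
    test_ids <- sort(exper$design$stimulus_id[exper$design$split == "test"])
    stimuli <- if (is.null(dcfg$n_stimuli)) test_ids else
      test_ids[unique(round(seq(1, length(test_ids),
                                length.out = min(dcfg$n_stimuli, length(test_ids)))))]
    times <- exper$subjects[[1]]$time_ms
    if (!is.null(dcfg$time_stride) && dcfg$time_stride > 1) {
      times <- times[seq(1, length(times), by = dcfg$time_stride)]
    }
    curves <- lapply(seq_along(white), function(i) {
      decode_subject(white[[i]], bin_size = dcfg$bin_size,
                     n_folds = dcfg$n_folds, n_repeats = dcfg$n_repeats,
                     stimuli = stimuli, times = times,
                     seed = fan_seed(config$seed, "decode", i))
    })
    list(curves = curves,
         group = tibble::tibble(time_ms = curves[[1]]$time_ms,
                                accuracy = rowMeans(sapply(curves, `[[`, "accuracy"))))
  })
  enc <- stage("encode_eeg", function() {
    lapply(white, function(ep) encode_eeg(prep$dm, ep, sp$encoding))
  })
  ceil <- stage("ceiling", function() {
    lapply(seq_along(white), function(i) {
      noise_ceiling(white[[i]], n_reps = config$ceiling$n_reps,
                    seed = fan_seed(config$seed, "ceiling", i))
    })
  })
  layer_enc <- stage("encode_layers", function() {
    encode_layers(prep$dm, prep$acts, sp$encoding)
  })
  stats <- stage("stats", function() {
    feats <- names(prep$dm$features)
    time_ms <- white[[1]]$time_ms
    curves_by_feature <- lapply(setNames(feats, feats), function(f) {
      do.call(rbind, lapply(enc, function(e) {
        e$accuracy$r[e$accuracy$feature == f]
      }))
    })
    sign_tests <- dplyr::bind_rows(lapply(feats, function(f) {
      st <- sign_permutation_test(curves_by_feature[[f]], chance = 0,
                                  n_perm = config$inference$n_perm,
                                  alpha = alpha,
                                  seed = fan_seed(config$seed, "stats"))
      dplyr::mutate(st, feature = f, time_ms = time_ms, .before = 1)
    }))
    peaks <- dplyr::bind_rows(lapply(feats, function(f) {
      pe <- bootstrap_peak_ci(curves_by_feature[[f]], grid = time_ms,
                              n_boot = config$inference$n_boot,
                              seed = fan_seed(config$seed, "stats"))
      dplyr::mutate(tibble::as_tibble(pe), feature = f, .before = 1)
    }))
    list(sign_tests = sign_tests, peaks = peaks,
         curves_by_feature = curves_by_feature)
  })
  hier <- stage("hierarchy", function() {
    feats <- names(prep$dm$features)
    lat <- setNames(stats$peaks$peak, stats$peaks$feature)[feats]
    layer_peaks <- vapply(feats, function(f) {
      sub <- layer_enc$accuracy[layer_enc$accuracy$feature == f, ]
      which.max(sub$accuracy)
    }, numeric(1))
    hierarchy_correlation(lat, layer_peaks,
                          seed = fan_seed(config$seed, "hierarchy"))
  })

  # plain-text results
  readr_write <- function(x, file) utils::write.csv(x, file.path(out_dir, file),
                                                    row.names = FALSE)
  readr_write(exper$design, "design.csv")
  readr_write(decode$group, "decoding_timecourse.csv")
  readr_write(dplyr::bind_rows(lapply(seq_along(enc), function(i) {
    dplyr::mutate(enc[[i]]$accuracy, subject = i, .before = 1)
  })), "encoding_timecourses.csv")
  readr_write(layer_enc$accuracy, "layer_curves.csv")
  readr_write(dplyr::bind_rows(lapply(seq_along(ceil), function(i) {
    dplyr::mutate(ceil[[i]]$summary, subject = i, .before = 1)
  })), "noise_ceiling.csv")
  readr_write(stats$sign_tests, "stats_encoding.csv")
  readr_write(stats$peaks, "peaks.csv")
  jsonlite::write_json(
    list(rho = hier$rho, p_value = hier$p_value,
         n_permutations = hier$n_permutations,
         seed = config$seed, mode = config$mode),
    file.path(out_dir, "hierarchy.json"), auto_unbox = TRUE, digits = NA)
  write_config(config, file.path(out_dir, "config.yaml"))

  manifest_tbl <- dplyr::bind_rows(manifest)
  files <- setdiff(list.files(out_dir, full.names = TRUE), file.path(out_dir, "cache"))
  files <- files[!dir.exists(files)]
  hashes <- tibble::tibble(file = basename(files),
                           md5 = as.vector(tools::md5sum(files)))
  jsonlite::write_json(list(stages = manifest_tbl, outputs = hashes),
                       file.path(out_dir, "manifest.json"), digits = NA)

  invisible(list(experiment = exper, prep = prep, whitened = white,
                 decoding = decode, encoding = enc, ceiling = ceil,
                 layer_encoding = layer_enc, stats = stats, hierarchy = hier,
                 manifest = manifest_tbl))
}
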