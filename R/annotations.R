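#' Default feature set of a simulated visual-scene experiment
#'
#' Seven per-stimulus ground-truth annotations spanning the low- to high-level
#' feature spectrum: edge maps, reflectance, lighting, world normals, scene
#' depth (pixel maps), a 14-joint 2-D body skeleton, and a one-hot action
#' identity vector. Map resolution defaults to 36 x 27 so that desk-scale PCA
#' remains cheap; the shape *classes*, not the sizes, are contractual.
#'
#' @param map_dim Height x width of the simulated pixel maps.
#' @param n_actions Number of action categories (one-hot length).
#' @return Named list of feature descriptors (`class`, `shape`).
#' @export
default_feature_set <- function(map_dim = c(36L, 27L), n_actions = 6L) {
  gray <- function() list(class = "grayscale_map", shape = as.integer(map_dim))
  col <- function() list(class = "color_map", shape = c(as.integer(map_dim), 3L))
  list(
    edges = gray(),
    reflectance = col(),
    lighting = col(),
    world_normals = col(),
    scene_depth = gray(),
    skeleton = list(class = "skeleton", shape = c(14L, 2L)),
    action = list(class = "one_hot", shape = as.integer(n_actions))
  )
}

#' Parameters of the synthetic annotation generator
#'
#' Continuous features are generated from per-stimulus latent factors mapped
#' into the declared array shape through fixed random projections, plus i.i.d.
#' pixel noise. All continuous features share one latent factor with weight
#' `rho`, so inter-feature correlation is controllable (`rho = 0` gives
#' independent features). In video mode each stimulus carries `n_frames`
#' frames whose latents are jittered by `frame_jitter`.
#'
#' @param features Feature descriptors, see [default_feature_set()].
#' @param latent_rank Latent dimensionality per feature.
#' @param rho Cross-feature latent mixing coefficient in `[0, 1)`.
#' @param pixel_noise SD of i.i.d. noise added to each array element.
#' @param n_frames Frames per stimulus in video mode.
#' @param frame_jitter SD of the per-frame latent jitter (video mode).
#' @return A list of class `annotation_spec`.
#' @export
annotation_spec <- function(features = default_feature_set(), latent_rank = 12L,
                            rho = 0.1, pixel_noise = 0.1, n_frames = 9L,
                            frame_jitter = 0.2) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  structure(
    list(features = features, latent_rank = as.integer(latent_rank), rho = rho,
         pixel_noise = pixel_noise, n_frames = as.integer(n_frames),
         frame_jitter = frame_jitter),
    class = "annotation_spec"
  )
}

#' Simulate ground-truth annotations for every stimulus
#'
#' @param design Stimulus design from [make_design()].
#' @param spec An [annotation_spec()].
#' @param mode `"image"` (one array per stimulus) or `"video"` (adds a frame
#'   axis with small inter-frame jitter).
#' @param seed Integer seed; identical seeds give bit-identical annotations.
#' @return An `annotation_set`: per feature, a stimuli x predictors matrix
#'   (image mode) or stimuli x frames x predictors array (video mode) of
#'   row-major flattened arrays, with the original shape stored alongside.
#' @export
simulate_annotations <- function(design, spec = annotation_spec(),
                                 mode = c("image", "video"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(design), nrow(design) >= 1)
  set.seed(seed)
  S <- nrow(design)
  L <- spec$latent_rank
  n_frames <- if (mode == "video") spec$n_frames else 1L
  shared <- matrix(rnorm(S * L), S, L)

  simulate_feature <- function(fname, fspec) {
    D <- prod(fspec$shape)
    if (fspec$class == "one_hot") {
      lev <- as.integer(design$action)
      if (length(fspec$shape) != 1) stop("one_hot shape must be scalar")
      n_act <- fspec$shape
      if (max(lev) > n_act) stop("design has more actions than one_hot length")
      data <- matrix(0, S, n_act)
      data[cbind(seq_len(S), lev)] <- 1
      if (mode == "video") { # action identity is constant across frames
        data <- aperm(array(rep(data, n_frames), c(S, n_act, n_frames)),
                      c(1, 3, 2))
      }
      return(list(class = fspec$class, shape = fspec$shape, data = data))
    }
    if (!fspec$class %in% c("grayscale_map", "color_map", "skeleton")) {
      stop("unknown feature shape class: ", fspec$class)
    }
    own <- matrix(rnorm(S * L), S, L)
    U <- sqrt(spec$rho) * shared + sqrt(1 - spec$rho) * own
    B <- matrix(rnorm(L * D), L, D) / sqrt(L)
    if (mode == "image") {
      data <- U %*% B + spec$pixel_noise * matrix(rnorm(S * D), S, D)
    } else {
      data <- array(0, c(S, n_frames, D))
      for (f in seq_len(n_frames)) {
        Uf <- U + spec$frame_jitter * matrix(rnorm(S * L), S, L)
        data[, f, ] <- Uf %*% B + spec$pixel_noise * matrix(rnorm(S * D), S, D)
      }
    }
    list(class = fspec$class, shape = fspec$shape, data = data)
  }

  feats <- purrr::imap(spec$features, function(fs, nm) simulate_feature(nm, fs))
  structure(
    list(features = feats, stimulus_id = design$stimulus_id, mode = mode,
         n_frames = n_frames, spec = spec, seed = seed),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", length(x$stimulus_id), " stimuli, mode=", x$mode,
      if (x$mode == "video") paste0(" (", x$n_frames, " frames)"), "\n", sep = "")
  for (nm in names(x$features)) {
    f <- x$features[[nm]]
    cat(sprintf("  %-14s %s [%s]\n", nm, f$class,
                paste(f$shape, collapse = "x")))
  }
  invisible(x)
}

#' Retrieve one stimulus' annotation in its native array shape
#'
#' @param x An `annotation_set`.
#' @param feature Feature name.
#' @param stimulus Stimulus index (row of the design).
#' @param frame Frame index (video mode only; `NULL` returns the frame stack).
#' @return An array with the feature's native shape.
#' @export
get_annotation <- function(x, feature, stimulus, frame = NULL) {
  f <- x$features[[feature]]
  if (is.null(f)) stop("unknown feature: ", feature)
  unflatten <- function(v) {
    if (length(f$shape) == 1) return(as.numeric(v))
    aperm(array(v, rev(f$shape)), rev(seq_along(f$shape)))
  }
  if (x$mode == "image") return(unflatten(f$data[stimulus, ]))
  if (is.null(frame)) {
    frames <- lapply(seq_len(x$n_frames), function(fr) unflatten(f$data[stimulus, fr, ]))
    return(frames)
  }
  unflatten(f$data[stimulus, frame, ])
}

#' Flatten an annotation array into a 1-D predictor vector
#'
#' Row-major order with the trailing (RGB / coordinate) axis varying fastest,
#' i.e. element `(h, w, c)` lands at position `((h-1)*W + (w-1))*C + c`.
#'
#' @param x A numeric vector, matrix or array.
#' @return A numeric vector of length `prod(dim(x))`.
#' @examples
#' flatten_annotation(matrix(1:4, 2, 2, byrow = TRUE)) # 1 2 3 4
#' @export
flatten_annotation <- function(x) {
  if (!is.numeric(x) && !is.logical(x)) stop("unrecognized annotation shape")
  if (is.null(dim(x))) return(as.numeric(x))
  as.numeric(as.vector(aperm(x, rev(seq_along(dim(x))))))
}

#' Average a stack of per-frame annotation arrays
#'
#' @param frames A list of identically shaped arrays, or an array whose first
#'   dimension indexes frames.
#' @return The element-wise mean, with the frame axis dropped.
#' @export
average_frames <- function(frames) {
  if (is.list(frames)) {
    if (length(frames) < 1) stop("need at least one frame")
    dims <- lapply(frames, dim)
    if (length(unique(vapply(frames, length, 1L))) != 1 ||
        length(unique(vapply(dims, function(d) paste(d %||% 0, collapse = "x"), ""))) != 1) {
      stop("frame shapes differ")
    }
    out <- Reduce(`+`, frames) / length(frames)
    return(out)
  }
  d <- dim(frames)
  if (is.null(d)) stop("need a frame axis")
  if (length(d) == 2) return(colMeans(frames))
  apply(frames, seq_along(d)[-1], mean)
}

#' One-hot encode an action label
#'
#' @param action Integer label in `1:n_actions`, or a factor level.
#' @param n_actions Number of categories (default 6).
#' @return A 0/1 vector of length `n_actions` with a single 1.
#' @export
encode_action <- function(action, n_actions = 6L) {
  if (is.factor(action)) action <- as.integer(action)
  if (length(action) != 1 || is.na(action) || action < 1 || action > n_actions) {
    stop("action label out of range")
  }
  out <- numeric(n_actions)
  out[action] <- 1
  out
}

#' Canny edge detection
#'
#' Standard four-stage Canny detector: Gaussian smoothing, Sobel gradient
#' magnitude/direction, non-maximum suppression along the quantized gradient
#' direction, and two-threshold hysteresis. Thresholds are expressed as
#' fractions of the maximum gradient magnitude.
#'
#' @param img A 2-D numeric matrix (grayscale image).
#' @param low_thresh,high_thresh Hysteresis thresholds in `[0, 1]` relative to
#'   the maximum gradient magnitude, `low_thresh <= high_thresh`.
#' @param sigma Gaussian smoothing SD in pixels.
#' @return A binary (0/1) matrix of the same size as `img`.
#' @export
canny_edges <- function(img, low_thresh = 0.1, high_thresh = 0.3, sigma = 1) {
  if (!is.matrix(img)) stop("img must be a 2-D matrix")
  if (low_thresh < 0 || low_thresh > high_thresh) stop("thresholds out of order")
  H <- nrow(img); W <- ncol(img)

  # separable Gaussian blur with edge replication
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2)); k <- k / sum(k)
  conv1d <- function(M, along_rows) {
    A <- if (along_rows) M else t(M)
    n <- ncol(A)
    out <- matrix(0, nrow(A), n)
    for (i in seq_along(k)) {
      off <- i - half - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[i] * A[, idx, drop = FALSE]
    }
    if (along_rows) out else t(out)
  }
  sm <- conv1d(conv1d(img, TRUE), FALSE)

  pad <- function(M) { # replicate-pad by one pixel
    M2 <- rbind(M[1, , drop = FALSE], M, M[nrow(M), , drop = FALSE])
    cbind(M2[, 1, drop = FALSE], M2, M2[, ncol(M2), drop = FALSE])
  }
  P <- pad(sm)
  at <- function(dr, dc) P[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  # Sobel kernels; rows = y (downward), cols = x
  gx <- (at(-1, 1) + 2 * at(0, 1) + at(1, 1)) -
        (at(-1, -1) + 2 * at(0, -1) + at(1, -1))
  gy <- (at(1, -1) + 2 * at(1, 0) + at(1, 1)) -
        (at(-1, -1) + 2 * at(-1, 0) + at(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(0, H, W))

  # gradient direction modulo pi, quantized to 4 sectors
  ang <- atan2(gy, gx) %% pi
  sector <- round(ang / (pi / 4)) %% 4  # 0: +x, 1: +x+y, 2: +y, 3: -x+y

  Pm <- pad(mag)
  atm <- function(dr, dc) Pm[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  pairs <- list(`0` = list(c(0, 1), c(0, -1)), `1` = list(c(1, 1), c(-1, -1)),
                `2` = list(c(1, 0), c(-1, 0)), `3` = list(c(1, -1), c(-1, 1)))
  for (s in 0:3) {
    m <- sector == s
    p <- pairs[[as.character(s)]]
    n1[m] <- atm(p[[1]][1], p[[1]][2])[m]
    n2[m] <- atm(p[[2]][1], p[[2]][2])[m]
  }
  nms <- mag
  nms[mag < n1 | mag < n2] <- 0

  hi <- high_thresh * max(mag); lo <- low_thresh * max(mag)
  strong <- nms >= hi
  weak <- nms >= lo & !strong
  # hysteresis: grow strong set into 8-connected weak pixels until fixed point
  repeat {
    Ps <- pad(strong)
    nb <- matrix(FALSE, H, W)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- nb | Ps[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    }
    grow <- weak & nb
    if (!any(grow)) break
    strong <- strong | grow
    weak <- weak & !grow
  }
  mode(strong) <- "numeric"
  strong
}
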