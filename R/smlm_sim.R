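#' Uniform random emitter field
#'
#' Emitter count drawn as Poisson(density * area), positions i.i.d. uniform
#' over a square ROI. Coordinates are in nm.
#'
#' @param roi_nm ROI edge length (nm).
#' @param density emitters per nm^2.
#' @param seed optional RNG seed (otherwise the current RNG stream is used).
#' @return an `emitter_field` data.frame with columns `x`, `y` (nm).
#' @export
gen_uniform_emitters <- function(roi_nm, density, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(density >= 0, roi_nm > 0)
  n <- rpois(1, density * roi_nm^2)
  out <- data.frame(x = runif(n, 0, roi_nm), y = runif(n, 0, roi_nm))
  structure(out, structure_label = "uniform", roi_nm = roi_nm,
            class = c("emitter_field", "data.frame"))
}

#' Star-shaped emitter field
#'
#' Uniform points at the requested density, rejection-sampled into the
#' alternating angular wedges of a Siemens-star disk centered in the ROI
#' (even wedges of `n_wedges` total are kept, radius at most half the ROI).
#' Poisson thinning preserves the requested density inside the accepted
#' region.
#'
#' @inheritParams gen_uniform_emitters
#' @param n_wedges even total number of angular wedges (default 16, i.e. an
#'   8-pointed star).
#' @export
gen_star_emitters <- function(roi_nm, density, n_wedges = 16L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_wedges %% 2 == 0, n_wedges >= 2)
  n <- rpois(1, density * roi_nm^2)
  x <- runif(n, 0, roi_nm); y <- runif(n, 0, roi_nm)
  keep <- in_star(x, y, roi_nm, n_wedges)
  out <- data.frame(x = x[keep], y = y[keep])
  structure(out, structure_label = "star", roi_nm = roi_nm,
            n_wedges = n_wedges,
            class = c("emitter_field", "data.frame"))
}

#' @rdname gen_star_emitters
#' @param x,y coordinates to test (nm).
#' @export
in_star <- function(x, y, roi_nm, n_wedges = 16L) {
  cx <- roi_nm / 2
  dx <- x - cx; dy <- y - cx
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) %% (2 * pi)
  wedge <- floor(theta / (2 * pi / n_wedges))
  r <= roi_nm / 2 & wedge %% 2 == 0
}

#' 3D ring-pair emitter field
#'
#' Two rings of the given diameter separated along z, emitters uniform along
#' each circumference at a linear density given per pixel unit of contour
#' length (count per ring drawn as Poisson). Mimics a DNA-PAINT labeled
#' nanorod whose center and ends are visible.
#'
#' @param diameter_nm ring diameter (nm).
#' @param separation_nm z separation between ring planes (nm).
#' @param density_per_px emitters per pixel unit of contour length.
#' @param center length-3 ring-pair center (nm).
#' @param pixel_size_nm lateral pixel size defining the contour-length unit.
#' @param seed optional RNG seed.
#' @return an `emitter_field` data.frame with columns `x`, `y`, `z` (nm).
#' @export
gen_ring_pair_3d <- function(diameter_nm = 40, separation_nm = 80,
                             density_per_px = 1000,
                             center = c(0, 0, 0), pixel_size_nm = 100,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  radius <- diameter_nm / 2
  circ_px <- pi * diameter_nm / pixel_size_nm
  one_ring <- function(zc) {
    n <- rpois(1, density_per_px * circ_px)
    th <- runif(n, 0, 2 * pi)
    data.frame(x = center[1] + radius * cos(th),
               y = center[2] + radius * sin(th),
               z = zc)
  }
  out <- rbind(one_ring(center[3] - separation_nm / 2),
               one_ring(center[3] + separation_nm / 2))
  structure(out, structure_label = "ring_pair",
            diameter_nm = diameter_nm, separation_nm = separation_nm,
            class = c("emitter_field", "data.frame"))
}

#' @rdname gen_ring_pair_3d
#' @param n_pairs number of ring pairs.
#' @param roi_nm ROI edge length for the random pair centers (nm).
#' @export
gen_multi_ring_3d <- function(n_pairs = 10, roi_nm = 2000,
                              diameter_nm = 40, separation_nm = 80,
                              density_per_px = 1000, pixel_size_nm = 100,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  margin <- diameter_nm
  centers <- cbind(runif(n_pairs, margin, roi_nm - margin),
                   runif(n_pairs, margin, roi_nm - margin), 0)
  out <- do.call(rbind, lapply(seq_len(n_pairs), function(i)
    gen_ring_pair_3d(diameter_nm, separation_nm, density_per_px,
                     center = centers[i, ], pixel_size_nm = pixel_size_nm)))
  structure(out, structure_label = "multi_ring",
            class = c("emitter_field", "data.frame"))
}

#' Blinking traces from exponential on/off kinetics
#'
#' Each emitter alternates between off and on states: off durations are
#' exponential with rate `K_on` (the off-to-on switching rate per frame), on
#' durations exponential with rate `K_off`. Emitters start off at a random
#' phase. The stationary on fraction is `K_on / (K_on + K_off)` and the
#' expected number of blinking events per emitter over `n_frames` is
#' approximately `n_frames * K_on * K_off / (K_on + K_off)`.
#'
#' @param n_emitters number of emitters.
#' @param n_frames trace length (frames); on intervals are clipped to
#'   `[0, n_frames]`.
#' @param K_on,K_off switching rates (per frame). Defaults 0.0005 and 1.
#' @param seed optional RNG seed.
#' @return a `blink_traces` data.frame with columns `emitter`, `t_on`,
#'   `t_off` (fractional frame times, one row per on-interval) and attribute
#'   `n_emitters`.
#' @export
gen_blink_traces <- function(n_emitters, n_frames, K_on = 5e-4, K_off = 1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(K_on > 0, K_off > 0)
  out <- gen_blink_events_cpp(as.integer(n_emitters), n_frames, K_on, K_off)
  structure(out, n_emitters = as.integer(n_emitters), n_frames = n_frames,
            K_on = K_on, K_off = K_off,
            class = c("blink_traces", "data.frame"))
}

#' Switching rate that yields a target mean number of blinking events
#'
#' Inverts the renewal-theory expectation
#' `lambda = n_frames * K_on * K_off / (K_on + K_off)` for `K_on`.
#'
#' @param lambda_ target expected blinking events per emitter.
#' @param n_frames trace length (frames).
#' @param K_off on-to-off rate (per frame).
#' @export
kon_for_lambda <- function(lambda_, n_frames, K_off = 1) {
  stopifnot(lambda_ > 0, lambda_ < n_frames * K_off)
  lambda_ * K_off / (n_frames * K_off - lambda_)
}

#' Expected number of blinking-event pairs per emitter
#'
#' With the event count per emitter Poisson with mean `lambda_`, the expected
#' number of unordered event pairs is
#' `sum_k P(k; lambda) * choose(k, 2) = lambda^2 / 2`.
#'
#' @param lambda_ expected blinking events per emitter.
#' @export
expected_pairs <- function(lambda_) {
  stopifnot(all(lambda_ >= 0))
  lambda_^2 / 2
}

#' Drift curves: constant rate, polynomial, and smooth spline
#'
#' Cumulative drift offsets per frame, in nm, anchored at zero for the
#' polynomial kinds. `gen_drift_constant` is a per-frame rate,
#' `gen_drift_polynomial` is `alpha * f + beta * f^2` per axis, and
#' `gen_drift_spline` draws a Poisson number of nodes (redrawn below 4),
#' spreads them over the frame range with jittered spacing around
#' `n_frames / (n_nodes + 1)`, assigns node values uniform in
#' `[-amplitude, amplitude]` and interpolates with a natural cubic spline —
#' emulating slow, smoothly oscillating mechanical drift.
#'
#' @param n_frames number of frames; curves cover frames `0..n_frames-1`.
#' @param rate_nm_per_frame per-axis drift rate (nm/frame), length 2 or 3.
#' @return a `drift_curve` data.frame with columns `frame`, `x`, `y`
#'   (and `z` for length-3 input).
#' @export
gen_drift_constant <- function(n_frames, rate_nm_per_frame) {
  f <- seq_len(n_frames) - 1
  out <- data.frame(frame = f)
  dims <- c("x", "y", "z")[seq_along(rate_nm_per_frame)]
  for (j in seq_along(dims)) out[[dims[j]]] <- rate_nm_per_frame[j] * f
  structure(out, kind = "constant", class = c("drift_curve", "data.frame"))
}

#' @rdname gen_drift_constant
#' @param alpha linear coefficients (nm/frame), one per axis.
#' @param beta quadratic coefficients (nm/frame^2), one per axis.
#' @export
gen_drift_polynomial <- function(n_frames, alpha, beta = 0) {
  beta <- rep_len(beta, length(alpha))
  f <- seq_len(n_frames) - 1
  out <- data.frame(frame = f)
  dims <- c("x", "y", "z")[seq_along(alpha)]
  for (j in seq_along(dims))
    out[[dims[j]]] <- alpha[j] * f + beta[j] * f^2
  structure(out,
            kind = if (all(beta == 0)) "linear" else "quadratic",
            class = c("drift_curve", "data.frame"))
}

#' @rdname gen_drift_constant
#' @param mean_nodes mean of the Poisson node count per axis.
#' @param amplitude_nm node values are uniform in `[-amplitude, amplitude]`.
#' @param ndim number of axes (2 or 3).
#' @param seed optional RNG seed.
#' @export
gen_drift_spline <- function(n_frames, mean_nodes = 35, amplitude_nm = 100,
                             ndim = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(amplitude_nm > 0, mean_nodes >= 1)
  f <- seq_len(n_frames) - 1
  out <- data.frame(frame = f)
  dims <- c("x", "y", "z")[seq_len(ndim)]
  nodes <- list()
  for (d in dims) {
    # redraw when the interpolant overshoots 1.5x the node range, so the
    # generated curves honor the documented amplitude
    repeat {
      n_nodes <- 0L
      while (n_nodes < 4L) n_nodes <- rpois(1, mean_nodes)
      w <- runif(n_nodes - 1, 0.5, 1.5)  # jittered inter-node spacings
      node_f <- c(0, cumsum(w) / sum(w) * (n_frames - 1))
      node_v <- runif(n_nodes, -amplitude_nm, amplitude_nm)
      curve <- splinefun(node_f, node_v, method = "natural")(f)
      if (max(abs(curve)) <= 1.5 * amplitude_nm) break
    }
    out[[d]] <- curve
    nodes[[d]] <- data.frame(frame = node_f, value = node_v)
  }
  structure(out, kind = "spline", nodes = nodes,
            amplitude_nm = amplitude_nm,
            class = c("drift_curve", "data.frame"))
}

#' Render localizations from emitters, blinking traces and a drift curve
#'
#' Produces one localization for every (emitter, frame) in which the
#' emitter's on-interval overlaps the frame: position = true position +
#' cumulative drift at that frame + Gaussian scatter (per axis; `sigma` may
#' be a vector to emulate anisotropic localization precision, e.g. a larger
#' axial sigma for fitted 3D data). Frame and dataset indices are assigned
#' by chunking the global frame sequence into `frames_per_dataset`.
#'
#' @param field an `emitter_field` (nm).
#' @param traces a [gen_blink_traces()] result for `nrow(field)` emitters.
#' @param drift a `drift_curve` covering all frames (nm), or NULL for none.
#' @param noise_sigma_nm localization scatter sigma (nm), scalar or one
#'   value per axis; 0 for noiseless localizations.
#' @param frames_per_dataset frames per dataset chunk.
#' @param pixel_size_nm lateral pixel size for the output table.
#' @param seed optional RNG seed.
#' @return list with `table` (a [loc_table()], pixels) and `truth`
#'   (data.frame with per-row emitter id, true position and true drift, nm).
#' @export
render_localizations <- function(field, traces, drift = NULL,
                                 noise_sigma_nm = 10,
                                 frames_per_dataset = 1000L,
                                 pixel_size_nm = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ndim <- if ("z" %in% names(field)) 3L else 2L
  dims <- c("x", "y", "z")[seq_len(ndim)]
  n_frames <- attr(traces, "n_frames")
  if (!is.null(drift)) {
    stopifnot(nrow(drift) >= n_frames)
    for (d in dims) if (!d %in% names(drift))
      stop("drift curve lacks axis ", d)
  }
  sigma <- rep_len(noise_sigma_nm, ndim)

  # frames covered by each on-interval [t_on, t_off)
  f_start <- pmax(floor(traces$t_on), 0)
  f_end <- pmin(ceiling(traces$t_off - 1e-12) - 1, n_frames - 1)
  n_cov <- pmax(f_end - f_start + 1, 0)
  keep <- n_cov > 0
  emitter <- rep(traces$emitter[keep], n_cov[keep])
  frame <- sequence(n_cov[keep]) - 1L + rep(f_start[keep], n_cov[keep])

  pos <- as.matrix(as.data.frame(field)[dims])[emitter, , drop = FALSE]
  truth <- data.frame(emitter = emitter)
  for (j in seq_len(ndim)) truth[[paste0("true_", dims[j])]] <- pos[, j]
  if (!is.null(drift)) {
    dr <- as.matrix(as.data.frame(drift)[dims])[frame + 1L, , drop = FALSE]
    pos <- pos + dr
    for (j in seq_len(ndim)) truth[[paste0("drift_", dims[j])]] <- dr[, j]
  }
  for (j in seq_len(ndim))
    if (sigma[j] > 0) pos[, j] <- pos[, j] + rnorm(length(frame), 0, sigma[j])

  tab <- loc_table(x = pos[, 1] / pixel_size_nm,
                   y = pos[, 2] / pixel_size_nm,
                   z = if (ndim == 3) pos[, 3] / pixel_size_nm else NULL,
                   frame = frame %% frames_per_dataset,
                   dataset = frame %/% frames_per_dataset,
                   pixel_size_nm = pixel_size_nm,
                   frames_per_dataset = as.integer(frames_per_dataset))
  truth$global_frame <- frame
  list(table = tab, truth = truth)
}

#' Synthetic brightfield scene and z-stack
#'
#' A smooth random texture of many small signed-amplitude 3D Gaussian blobs
#' on a constant bright baseline — emulating the fine transmitted-light
#' contrast of a cell, with intensity fluctuating both above and below the
#' background. The field is sampled analytically on the voxel grid, so
#' fractional shifts of the scene are exact, providing sub-voxel ground
#' truth for registration tests.
#'
#' @param shape stack dimensions (ny, nx, nz).
#' @param n_blobs number of Gaussian blobs.
#' @param pixel_size_nm,z_step_nm voxel geometry (nm).
#' @param seed optional RNG seed.
#' @return a `bf_scene` list of blob parameters and geometry.
#' @export
gen_brightfield_scene <- function(shape = c(32, 32, 21), n_blobs = 2000,
                                  pixel_size_nm = 100, z_step_nm = 50,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ext <- c(shape[1] * pixel_size_nm, shape[2] * pixel_size_nm,
           shape[3] * z_step_nm)
  structure(list(
    cx = runif(n_blobs, 0, ext[2]), cy = runif(n_blobs, 0, ext[1]),
    cz = runif(n_blobs, 0, ext[3]),
    sxy = runif(n_blobs, 0.8, 1.6) * pixel_size_nm,
    sz = runif(n_blobs, 0.8, 1.6) * z_step_nm,
    amp = runif(n_blobs, -1, 1),
    baseline = 10,
    shape = shape, pixel_size_nm = pixel_size_nm, z_step_nm = z_step_nm),
    class = "bf_scene")
}

#' @rdname gen_brightfield_scene
#' @param scene a `bf_scene`.
#' @param offset_nm apparent sample offset (dx, dy, dz) in nm: features at
#'   position p in the reference appear at p + offset.
#' @param noise_sd additive Gaussian intensity noise (fraction of baseline).
#' @export
render_brightfield <- function(scene, offset_nm = c(0, 0, 0), noise_sd = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sh <- scene$shape
  xs <- (seq_len(sh[2]) - 1) * scene$pixel_size_nm
  ys <- (seq_len(sh[1]) - 1) * scene$pixel_size_nm
  zs <- (seq_len(sh[3]) - 1) * scene$z_step_nm
  v <- array(scene$baseline, sh)
  for (b in seq_along(scene$amp)) {
    gx <- exp(-(xs - scene$cx[b] - offset_nm[1])^2 / (2 * scene$sxy[b]^2))
    gy <- exp(-(ys - scene$cy[b] - offset_nm[2])^2 / (2 * scene$sxy[b]^2))
    gz <- exp(-(zs - scene$cz[b] - offset_nm[3])^2 / (2 * scene$sz[b]^2))
    v <- v + scene$amp[b] * outer(outer(gy, gx), gz)
  }
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd * scene$baseline)
  image_stack(v, pixel_size_nm = scene$pixel_size_nm,
              z_step_nm = scene$z_step_nm)
}

#' @rdname gen_brightfield_scene
#' @param shift_nm ground-truth apparent sample shift of the returned stack.
#' @export
gen_brightfield_stack <- function(shape = c(48, 48, 21), n_blobs = 40,
                                  shift_nm = c(0, 0, 0), noise_sd = 0,
                                  pixel_size_nm = 100, z_step_nm = 50,
                                  seed = NULL) {
  scene <- gen_brightfield_scene(shape, n_blobs, pixel_size_nm, z_step_nm,
                                 seed = seed)
  st <- render_brightfield(scene, offset_nm = shift_nm, noise_sd = noise_sd)
  attr(st, "true_shift_nm") <- shift_nm
  attr(st, "scene") <- scene
  st
}

#' Simulated microscope stage for registration tests
#'
#' Implements the stage contract used by [register_iterative()]: holds an
#' apparent sample offset, renders a brightfield stack from a shared scene at
#' that offset on `acquire_stack()`, and on `move_by(dx, dy, dz)` changes the
#' offset by the commanded amount scaled by `(1 - move_error)`, emulating an
#' imperfect positioner.
#'
#' @param scene a [gen_brightfield_scene()] result.
#' @param offset_nm initial apparent sample offset (nm).
#' @param move_error fractional move error (0 = perfect moves).
#' @param noise_sd acquisition intensity noise (fraction of baseline).
#' @return list with functions `acquire_stack()`, `move_by(dx, dy, dz)` and
#'   `offset()` (the current true offset, for tests).
#' @export
simulated_stage <- function(scene, offset_nm = c(0, 0, 0), move_error = 0,
                            noise_sd = 0) {
  offset <- as.numeric(offset_nm)
  list(
    acquire_stack = function()
      render_brightfield(scene, offset_nm = offset, noise_sd = noise_sd),
    move_by = function(dx, dy, dz) {
      offset <<- offset + c(dx, dy, dz) * (1 - move_error)
      invisible(offset)
    },
    offset = function() offset)
}
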