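#' Error between an estimated drift model and the true drift curve
#'
#' Evaluates the fitted model at every global frame and compares it to the
#' true cumulative drift curve. Both curves are anchored to zero at global
#' frame 0 before comparison, since the algorithm cannot observe an absolute
#' offset. All frames are weighted equally.
#'
#' @param model a [drift_model()].
#' @param true_curve a `drift_curve` (nm) covering at least the model's
#'   frame range.
#' @param frames_per_dataset frames per dataset; defaults to the model's.
#' @return a `drift_error` list: per-axis `rmse`, `max_abs`, `mean`, `sd`
#'   (nm), pooled Euclidean `rmse_pooled` (nm), per-axis `rate_error`
#'   (nm/frame, least-squares slope of the error curve) and the per-frame
#'   `error` matrix.
#' @export
drift_error <- function(model, true_curve,
                        frames_per_dataset = model$frames_per_dataset) {
  est <- drift_curve_from_model(model, frames_per_dataset, units = "nm")
  dims <- model$dims
  for (d in dims) if (!d %in% names(true_curve))
    stop("true curve lacks axis ", d)
  if (max(est$frame) > max(true_curve$frame))
    stop("true curve does not cover the model's frame range")
  tr <- true_curve[match(est$frame, true_curve$frame), dims, drop = FALSE]
  if (anyNA(tr)) stop("true curve does not cover the model's frame range")
  em <- as.matrix(est[dims])
  tm <- as.matrix(tr)
  em <- sweep(em, 2, em[1, ])
  tm <- sweep(tm, 2, tm[1, ])
  err <- em - tm
  colnames(err) <- dims
  rate <- apply(err, 2, function(e) unname(coef(lm(e ~ est$frame))[2]))
  structure(list(
    rmse = sqrt(colMeans(err^2)),
    max_abs = apply(abs(err), 2, max),
    mean = colMeans(err),
    sd = apply(err, 2, sd),
    rmse_pooled = sqrt(mean(rowSums(err^2))),
    rate_error = rate,
    error = err, frame = est$frame), class = "drift_error")
}

#' @export
print.drift_error <- function(x, ...) {
  cat("<drift_error> per-axis RMSE (nm):",
      paste(sprintf("%s=%.3g", names(x$rmse), x$rmse), collapse = " "),
      sprintf("| max |err| %.3g nm | pooled RMSE %.3g nm\n",
              max(x$max_abs), x$rmse_pooled))
  invisible(x)
}

#' Overall drift rate recovered by a fitted model
#'
#' Least-squares slope, per axis, of the modeled drift curve over all global
#' frames — the recovered constant drift rate in constant-drift studies.
#'
#' @param model a [drift_model()].
#' @param frames_per_dataset frames per dataset; defaults to the model's.
#' @return named per-axis rate (nm/frame).
#' @export
recovered_rate <- function(model,
                           frames_per_dataset = model$frames_per_dataset) {
  est <- drift_curve_from_model(model, frames_per_dataset, units = "nm")
  vapply(model$dims, function(d)
    unname(coef(lm(est[[d]] ~ est$frame))[2]), numeric(1))
}

#' Simulate one uniform-field dataset and correct it (intra only)
#'
#' One `n_frames`-frame dataset of emitters uniform over a square ROI with
#' exponential blinking tuned to `lambda` expected events per emitter,
#' Gaussian localization scatter, and linear drift; corrected with a
#' degree-1 intra fit (a single dataset has no inter fit).
#'
#' @param n_emitters number of emitters.
#' @param lambda expected blinking events per emitter over the dataset.
#' @param roi_nm ROI edge (nm).
#' @param n_frames frames in the dataset.
#' @param alpha linear drift rates (nm/frame), length 2.
#' @param noise_sigma_nm localization scatter (nm).
#' @param pixel_size_nm lateral pixel size (nm).
#' @param params a [cost_params()].
#' @param seed RNG seed.
#' @return list with `model`, `truth_curve`, `err` (a [drift_error()]),
#'   `n_locs`, `pairs` (realized blinking-event pair count).
#' @export
sim_intra_study <- function(n_emitters = 1e5, lambda = 0.45,
                            roi_nm = 25600, n_frames = 1000,
                            alpha = c(0.05, 0.02), noise_sigma_nm = 10,
                            pixel_size_nm = 100, params = cost_params(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  field <- gen_uniform_emitters(roi_nm, n_emitters / roi_nm^2)
  traces <- gen_blink_traces(nrow(field), n_frames,
                             K_on = kon_for_lambda(lambda, n_frames),
                             K_off = 1)
  curve <- gen_drift_polynomial(n_frames, alpha)
  sim <- render_localizations(field, traces, curve,
                              noise_sigma_nm = noise_sigma_nm,
                              frames_per_dataset = n_frames,
                              pixel_size_nm = pixel_size_nm)
  fit <- drift_correct_knn(sim$table, params = params)
  ev <- tabulate(traces$emitter, nbins = nrow(field))
  list(model = fit$model, truth_curve = curve,
       err = drift_error(fit$model, curve),
       n_locs = nrow(sim$table), pairs = sum(choose(ev, 2)))
}

#' Recovery of an imposed constant drift rate vs emitter density
#'
#' For each density, emitters are placed (star-confined or uniform) in the
#' ROI, blink over `n_datasets` datasets of `frames_per_dataset` frames under
#' a constant drift, and the full kNN correction (intra + sequential inter,
#' initialized from accumulated drift since no registration is emulated) is
#' run; the recovered rate is the least-squares slope of the modeled drift
#' curve. Replicate seeds are derived from `seed`.
#'
#' @param densities emitter densities (per nm^2).
#' @param n_reps replicates per density.
#' @param domain `"star"` or `"uniform"`.
#' @param roi_nm ROI edge (nm).
#' @param n_datasets,frames_per_dataset acquisition layout.
#' @param rate true drift rate (nm/frame), length 2.
#' @param lambda expected blinking events per emitter per dataset.
#' @param noise_sigma_nm localization scatter (nm).
#' @param pixel_size_nm lateral pixel size (nm).
#' @param params a [cost_params()].
#' @param seed base RNG seed.
#' @return data.frame, one row per (density, replicate): emitters per
#'   dataset, recovered rate and rate error per axis (nm/frame).
#' @export
rate_recovery_study <- function(densities = 1e-4, n_reps = 20,
                                domain = c("star", "uniform"),
                                roi_nm = 6400, n_datasets = 5,
                                frames_per_dataset = 1000,
                                rate = c(0.3, 0.4), lambda = 1.28,
                                noise_sigma_nm = 10, pixel_size_nm = 100,
                                params = cost_params(), seed = 1) {
  domain <- match.arg(domain)
  n_frames <- n_datasets * frames_per_dataset
  rows <- list()
  for (di in seq_along(densities)) {
    for (r in seq_len(n_reps)) {
      set.seed(seed + 7919L * di + r)
      field <- if (domain == "star")
        gen_star_emitters(roi_nm, densities[di])
      else gen_uniform_emitters(roi_nm, densities[di])
      traces <- gen_blink_traces(
        nrow(field), n_frames,
        K_on = kon_for_lambda(lambda, frames_per_dataset), K_off = 1)
      curve <- gen_drift_constant(n_frames, rate)
      sim <- render_localizations(field, traces, curve,
                                  noise_sigma_nm = noise_sigma_nm,
                                  frames_per_dataset = frames_per_dataset,
                                  pixel_size_nm = pixel_size_nm)
      fit <- drift_correct_knn(sim$table, params = params,
                               registration_used = FALSE)
      rr <- recovered_rate(fit$model)
      rows[[length(rows) + 1L]] <- data.frame(
        density = densities[di], rep = r, n_emitters = nrow(field),
        rate_x = rr["x"], rate_y = rr["y"],
        err_x = rr["x"] - rate[1], err_y = rr["y"] - rate[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Drift-curve RMSE versus number of blinking-event pairs
#'
#' Reproduces the pairs-RMSE study: single 1000-frame datasets of uniform
#' emitters over a 25,600 nm square ROI under linear drift
#' alpha = (0.05, 0.02) nm/frame, sweeping either `lambda` at fixed
#' `n_emitters` or `n_emitters` at fixed `lambda`; records the RMSE between
#' estimated and true drift curves against the realized pair count
#' `lambda^2/2 * N_e`.
#'
#' @param mode `"lambda"` or `"n_emitters"`: which quantity `values` sweeps.
#' @param values swept values.
#' @param fixed the fixed quantity's value (`n_emitters` when sweeping
#'   lambda, `lambda` when sweeping emitters).
#' @param n_reps replicates per value.
#' @param seed base RNG seed.
#' @inheritParams sim_intra_study
#' @return data.frame, one row per (value, replicate), with expected and
#'   realized pair counts, per-axis and mean per-axis RMSE (nm).
#' @export
pairs_sweep <- function(mode = c("lambda", "n_emitters"), values,
                        fixed = if (mode == "lambda") 1e5 else 0.2,
                        n_reps = 5, roi_nm = 25600, n_frames = 1000,
                        alpha = c(0.05, 0.02), noise_sigma_nm = 10,
                        params = cost_params(), seed = 1) {
  mode <- match.arg(mode)
  rows <- list()
  for (vi in seq_along(values)) {
    lam <- if (mode == "lambda") values[vi] else fixed
    ne <- if (mode == "lambda") fixed else values[vi]
    for (r in seq_len(n_reps)) {
      st <- sim_intra_study(n_emitters = ne, lambda = lam, roi_nm = roi_nm,
                            n_frames = n_frames, alpha = alpha,
                            noise_sigma_nm = noise_sigma_nm, params = params,
                            seed = seed + 104729L * vi + r)
      rows[[length(rows) + 1L]] <- data.frame(
        value = values[vi], rep = r, lambda = lam, n_emitters = ne,
        pairs_expected = expected_pairs(lam) * ne, pairs = st$pairs,
        rmse_x = st$err$rmse["x"], rmse_y = st$err$rmse["y"],
        rmse_mean = mean(st$err$rmse), rmse_pooled = st$err$rmse_pooled)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 3D two-ring benchmark under smooth spline drift
#'
#' Two 40 nm rings separated along z, linear emitter density 1000 per pixel
#' of contour length, exponential blinking (K_on = 0.0005, K_off = 1 per
#' frame), noiseless localizations at the true blink positions, smooth
#' cubic-spline drift per axis, split into datasets of
#' `frames_per_dataset` frames; full 3D correction with accumulated-drift
#' inter initialization.
#'
#' @param n_datasets,frames_per_dataset acquisition layout.
#' @param mean_nodes,amplitude_nm spline drift parameters. Both default to
#'   the reference conditions of ~35 nodes and +/-100 nm per 50,000 frames,
#'   scaled proportionally to the covered frames so the node spacing and the
#'   per-frame steepness of the drift are preserved at smaller scale.
#' @param separation_nm ring separation (nm).
#' @param density_per_px emitters per pixel of ring contour.
#' @param pixel_size_nm lateral pixel size (nm).
#' @param params a [cost_params()].
#' @param seed RNG seed.
#' @return list with `model`, `truth_curve`, `err` (a [drift_error()]) and
#'   `n_locs`.
#' @export
sim_ring3d_study <- function(n_datasets = 20, frames_per_dataset = 500,
                             mean_nodes = NULL, amplitude_nm = NULL,
                             separation_nm = 80, density_per_px = 1000,
                             pixel_size_nm = 100, params = cost_params(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_frames <- n_datasets * frames_per_dataset
  if (is.null(mean_nodes)) mean_nodes <- max(4, round(35 * n_frames / 50000))
  if (is.null(amplitude_nm)) amplitude_nm <- 100 * n_frames / 50000
  field <- gen_ring_pair_3d(diameter_nm = 40, separation_nm = separation_nm,
                            density_per_px = density_per_px,
                            center = c(500, 500, 200),
                            pixel_size_nm = pixel_size_nm)
  traces <- gen_blink_traces(nrow(field), n_frames, K_on = 5e-4, K_off = 1)
  curve <- gen_drift_spline(n_frames, mean_nodes = mean_nodes,
                            amplitude_nm = amplitude_nm, ndim = 3)
  sim <- render_localizations(field, traces, curve, noise_sigma_nm = 0,
                              frames_per_dataset = frames_per_dataset,
                              pixel_size_nm = pixel_size_nm)
  fit <- drift_correct_knn(sim$table, params = params,
                           registration_used = FALSE)
  list(model = fit$model, truth_curve = curve,
       err = drift_error(fit$model, curve), n_locs = nrow(sim$table))
}

#' Effect of re-segmenting an acquisition into different dataset sizes
#'
#' Runs the drift correction once per requested chunk size (via the internal
#' re-segmentation) and summarizes either the drift-curve error against a
#' known truth or, absent truth, the final mean thresholded-NN cost per
#' localization.
#'
#' @param table a [loc_table()].
#' @param chunk_list frames-per-dataset values to try.
#' @param true_curve optional `drift_curve` (nm) for error metrics.
#' @param params a [cost_params()].
#' @param registration_used passed to [drift_correct_knn()].
#' @return data.frame, one row per chunk size.
#' @export
segmentation_sweep <- function(table, chunk_list, true_curve = NULL,
                               params = cost_params(),
                               registration_used = FALSE) {
  rows <- lapply(chunk_list, function(chunk) {
    fit <- drift_correct_knn(table, params = params,
                             registration_used = registration_used,
                             frames_per_dataset = chunk)
    row <- data.frame(frames_per_dataset = chunk,
                      n_datasets = length(fit$model$intra))
    if (!is.null(true_curve)) {
      err <- drift_error(fit$model, true_curve)
      row$rmse_mean <- mean(err$rmse)
      row$rmse_pooled <- err$rmse_pooled
      row$max_abs <- max(err$max_abs)
    } else {
      pts <- coord_matrix(fit$table)
      row$mean_cost <- thresholded_nnd_sum(pts, pts, params$l_intra,
                                           exclude_self = TRUE) / nrow(pts)
    }
    row
  })
  do.call(rbind, rows)
}
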