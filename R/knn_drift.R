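#' Cost-function parameters for kNN drift correction
#'
#' `l_intra` and `l_inter` are the saturation thresholds of the nearest-
#' neighbor cost (in pixels): neighbor distances beyond the threshold
#' contribute exactly the threshold, de-emphasizing pairings unlikely to come
#' from the same emitter. Defaults are 1 px within a dataset and 2 px between
#' datasets. The intra-dataset model is a polynomial in frame number of
#' degree `intra_degree` (default linear); the inter-dataset model is always
#' a constant shift.
#'
#' @param l_intra intra-dataset threshold (pixels).
#' @param l_inter inter-dataset threshold (pixels).
#' @param intra_degree polynomial degree of the intra-dataset drift model.
#' @param maxiter maximum simplex iterations per fit.
#' @param tol relative convergence tolerance of the simplex optimizer.
#' @return a list of class `cost_params`.
#' @export
cost_params <- function(l_intra = 1, l_inter = 2, intra_degree = 1L,
                        maxiter = 2000L, tol = 1e-9) {
  stopifnot(l_intra > 0, l_inter > 0, intra_degree >= 1)
  structure(list(l_intra = l_intra, l_inter = l_inter,
                 intra_degree = as.integer(intra_degree),
                 maxiter = as.integer(maxiter), tol = tol),
            class = "cost_params")
}

#' Thresholded sum of nearest-neighbor distances (sumNND)
#'
#' Computes `sum_i min(d_i, l)` where `d_i` is the Euclidean distance from
#' query point i to its nearest neighbor in the reference set. With
#' `exclude_self = TRUE` the query and reference are the same point set and
#' each point's own entry is excluded from its search by row identity (not by
#' distance, so coincident distinct points still pair). Distances are found
#' with an exact threshold-aware spatial index built on the reference set.
#'
#' @param query,reference numeric matrices (n x 2 or n x 3), pixels. The
#'   reference may instead be a prebuilt index from [nn_reference_index()].
#' @param l saturation threshold (pixels).
#' @param exclude_self logical; self-mode as described above.
#' @return the cost (pixels); 0 for an empty query, `n * l` when every
#'   query saturates (e.g. self-mode with fewer than 2 points).
#' @export
thresholded_nnd_sum <- function(query, reference, l, exclude_self = FALSE) {
  query <- as.matrix(query)
  if (nrow(query) == 0) return(0)
  qids <- seq_len(nrow(query))
  if (inherits(reference, "nn_reference_index")) {
    if (exclude_self)
      stop("self-mode requires the raw reference point set")
    if (abs(reference$l - l) > 1e-12)
      stop("prebuilt index threshold differs from l")
    return(nn_grid_cost_cpp(reference$ptr, query, qids, FALSE))
  }
  reference <- as.matrix(reference)
  rids <- seq_len(nrow(reference))
  if (exclude_self && !identical(dim(query), dim(reference)))
    stop("self-mode requires query and reference to be the same point set")
  nnd_cost_cpp(query, reference, l, qids, rids, exclude_self)
}

#' Build a reusable nearest-neighbor index over a reference point set
#'
#' The inter-dataset fits query every dataset against the corrected first
#' dataset, so that reference is indexed once and reused across all cost
#' evaluations.
#'
#' @param reference numeric matrix (n x 2 or n x 3), pixels.
#' @param l saturation threshold the index is built for (pixels).
#' @export
nn_reference_index <- function(reference, l) {
  reference <- as.matrix(reference)
  structure(list(ptr = nn_grid_build_cpp(reference, l,
                                         seq_len(nrow(reference))),
                 l = l, n = nrow(reference), dim = ncol(reference)),
            class = "nn_reference_index")
}

#' Project localizations to t = 0 under a polynomial drift model
#'
#' `corrected = observed - sum_p a_p f^p` per dimension; the constant term
#' is fixed at zero so frame 0 is the anchor.
#'
#' @param positions n x ndim matrix (pixels).
#' @param frames frame numbers (0-based).
#' @param coeffs P x ndim matrix of polynomial coefficients
#'   (pixels/frame^p), row p = degree p.
#' @export
project_to_t0 <- function(positions, frames, coeffs) {
  positions <- as.matrix(positions)
  coeffs <- as.matrix(coeffs)
  out <- positions
  for (p in seq_len(nrow(coeffs)))
    out <- out - outer(frames^p, coeffs[p, ])
  out
}

#' Intra-dataset cost: dispersion of t = 0-projected localizations
#'
#' Thresholded NN sum of the projected set against itself with
#' self-exclusion. A good drift model moves the localizations as a group, so
#' repeated blinks of an emitter collapse and the sum shrinks; the spatial
#' index is rebuilt per evaluation since every point moves with the
#' coefficients.
#'
#' @inheritParams project_to_t0
#' @param l_intra saturation threshold (pixels).
#' @export
intra_cost <- function(positions, frames, coeffs, l_intra = 1) {
  proj <- project_to_t0(positions, frames, coeffs)
  thresholded_nnd_sum(proj, proj, l_intra, exclude_self = TRUE)
}

#' Inter-dataset cost: target unshifted onto the corrected first dataset
#'
#' Thresholded NN sum of `target + shift` queried against the fixed
#' reference (no self-exclusion). If the only difference between datasets is
#' a constant offset and the model is accurate, this sum is zero.
#'
#' @param ref_index a prebuilt [nn_reference_index()] over the corrected
#'   first dataset, or a raw point matrix.
#' @param target n x ndim matrix of intra-corrected target positions.
#' @param shift length-ndim shift applied to the target (pixels).
#' @param l_inter saturation threshold (pixels); taken from the index when
#'   one is supplied.
#' @export
inter_cost <- function(ref_index, target, shift, l_inter = 2) {
  target <- as.matrix(target)
  if (nrow(target) == 0) return(0)
  shifted <- sweep(target, 2, shift, "+")
  if (inherits(ref_index, "nn_reference_index"))
    l_inter <- ref_index$l
  thresholded_nnd_sum(shifted, ref_index, l_inter, exclude_self = FALSE)
}

# Derivative-free simplex minimization (fminsearch-equivalent Nelder-Mead).
# Returns best-so-far with a convergence flag; never worse than the initial
# guess.
simplex_minimize <- function(fn, x0, maxiter = 2000L, tol = 1e-9) {
  f0 <- fn(x0)
  res <- tryCatch(
    pracma::fminsearch(fn, x0, maxiter = maxiter, tol = tol),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$fmin) || res$fmin > f0)
    return(list(x = x0, value = f0, init_value = f0, converged = FALSE,
                evals = 0L))
  list(x = res$xmin, value = res$fmin, init_value = f0,
       converged = is.null(res$errmess) || !nzchar(res$errmess %||% ""),
       evals = res$count %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the intra-dataset polynomial drift of one dataset
#'
#' Minimizes [intra_cost()] over the polynomial coefficients with a
#' derivative-free simplex search started at zero. Internally the
#' coefficients are rescaled to displacement-at-last-frame units so all
#' search directions have comparable magnitude regardless of degree.
#'
#' @param positions n x ndim matrix (pixels).
#' @param frames 0-based frame numbers within the dataset.
#' @param degree polynomial degree P (default 1).
#' @param l_intra saturation threshold (pixels).
#' @param maxiter,tol simplex control.
#' @return list with `coeffs` (P x ndim matrix), `cost`, `init_cost`,
#'   `converged` and `evals`.
#' @export
fit_intra <- function(positions, frames, degree = 1L, l_intra = 1,
                      maxiter = 2000L, tol = 1e-9) {
  positions <- as.matrix(positions)
  ndim <- ncol(positions)
  P <- as.integer(degree)
  zero <- matrix(0, P, ndim, dimnames = list(NULL, colnames(positions)))
  if (nrow(positions) < 2) {
    warning("fewer than 2 localizations; returning zero drift")
    return(list(coeffs = zero, cost = nrow(positions) * l_intra,
                init_cost = nrow(positions) * l_intra,
                converged = TRUE, evals = 0L))
  }
  fmax <- max(max(frames), 1)
  unscale <- function(b) {
    co <- matrix(b, P, ndim)
    co / matrix(fmax^seq_len(P), P, ndim)
  }
  fn <- function(b) intra_cost(positions, frames, unscale(b), l_intra)
  res <- simplex_minimize(fn, rep(0, P * ndim), maxiter = maxiter, tol = tol)
  co <- unscale(res$x)
  dimnames(co) <- dimnames(zero)
  list(coeffs = co, cost = res$value, init_cost = res$init_value,
       converged = res$converged, evals = res$evals)
}

#' Fit the constant inter-dataset shift of one dataset
#'
#' Minimizes [inter_cost()] over the shift that unshifts the target dataset
#' onto the corrected first dataset. The initial guess is zero when
#' brightfield registration was used during acquisition, or minus the
#' accumulated drift of the previously corrected datasets otherwise.
#'
#' @inheritParams inter_cost
#' @param init_shift starting shift (pixels).
#' @param maxiter,tol simplex control.
#' @return list with `shift`, `cost`, `init_cost`, `converged`, `evals`.
#' @export
fit_inter <- function(ref_index, target, init_shift = NULL, l_inter = 2,
                      maxiter = 2000L, tol = 1e-9) {
  target <- as.matrix(target)
  ndim <- ncol(target)
  if (is.null(init_shift)) init_shift <- rep(0, ndim)
  if (nrow(target) < 1) {
    warning("empty target dataset; returning initial shift")
    return(list(shift = init_shift, cost = 0, init_cost = 0,
                converged = TRUE, evals = 0L))
  }
  if (!inherits(ref_index, "nn_reference_index"))
    ref_index <- nn_reference_index(ref_index, l_inter)
  fn <- function(s) inter_cost(ref_index, target, s)
  res <- simplex_minimize(fn, init_shift, maxiter = maxiter, tol = tol)
  list(shift = res$x, cost = res$value, init_cost = res$init_value,
       converged = res$converged, evals = res$evals)
}

#' Fiducial-free kNN drift correction of a localization table
#'
#' The full post-processing procedure: (1) fit an intra-dataset polynomial
#' drift model per dataset by minimizing the thresholded NN-distance sum of
#' the t = 0-projected localizations; (2) apply the intra corrections;
#' (3) register datasets 1..D-1 in sequence against the corrected first
#' dataset with a constant shift each, initialized at zero when brightfield
#' registration was used or at the accumulated end-of-dataset drift
#' otherwise. The total modeled drift at (dataset d, frame f) is
#' `inter[d] + sum_p a_p[d] f^p`, and the corrected table is exactly
#' `observed - model` rowwise.
#'
#' @param table a [loc_table()].
#' @param params a [cost_params()].
#' @param registration_used was brightfield registration performed between
#'   datasets during acquisition? Controls the inter-fit initial guess.
#' @param frames_per_dataset optional re-segmentation override: the table is
#'   internally reorganized into datasets of this many frames, corrected,
#'   and the results reassembled into the original dataset scheme.
#' @return list with `table` (corrected [loc_table()]) and `model`
#'   (a [drift_model()] in the working segmentation scheme).
#' @export
drift_correct_knn <- function(table, params = cost_params(),
                              registration_used = TRUE,
                              frames_per_dataset = NULL) {
  validate_loc_table(table)
  mapping <- NULL
  work <- table
  if (!is.null(frames_per_dataset)) {
    rs <- resegment(table, frames_per_dataset)
    work <- rs$table
    mapping <- rs$mapping
  }
  dims <- coord_cols(work)
  D <- n_datasets(work)
  pts <- coord_matrix(work)
  idx_by_ds <- split(seq_len(nrow(work)), work$dataset)
  fpd <- attr(work, "frames_per_dataset")
  if (is.null(fpd)) fpd <- max(work$frame) + 1L

  intra <- vector("list", D)
  fit_info <- vector("list", D)
  last_frame <- numeric(D)
  for (d in seq_len(D)) {
    rows <- idx_by_ds[[d]]
    fit <- fit_intra(pts[rows, , drop = FALSE], work$frame[rows],
                     degree = params$intra_degree, l_intra = params$l_intra,
                     maxiter = params$maxiter, tol = params$tol)
    if (!fit$converged)
      warning(sprintf("intra fit for dataset %d did not converge", d - 1L))
    intra[[d]] <- fit$coeffs
    fit_info[[d]] <- list(phase = "intra", cost = fit$cost,
                          init_cost = fit$init_cost,
                          converged = fit$converged, evals = fit$evals)
    last_frame[d] <- if (!is.null(fpd)) fpd - 1 else max(work$frame[rows])
  }

  corrected <- pts
  for (d in seq_len(D)) {
    rows <- idx_by_ds[[d]]
    corrected[rows, ] <- project_to_t0(pts[rows, , drop = FALSE],
                                       work$frame[rows], intra[[d]])
  }

  inter <- matrix(0, D, length(dims), dimnames = list(NULL, dims))
  if (D > 1) {
    ref <- nn_reference_index(corrected[idx_by_ds[[1]], , drop = FALSE],
                              params$l_inter)
    for (d in 2:D) {
      rows <- idx_by_ds[[d]]
      if (length(rows) < 1) next
      init <- if (registration_used) rep(0, length(dims)) else {
        prev_end <- inter[d - 1, ] +
          vapply(seq_along(dims), function(j)
            sum(intra[[d - 1]][, j] * last_frame[d - 1]^
                  seq_len(nrow(intra[[d - 1]]))), numeric(1))
        -prev_end
      }
      fit <- fit_inter(ref, corrected[rows, , drop = FALSE],
                       init_shift = init, l_inter = params$l_inter,
                       maxiter = params$maxiter, tol = params$tol)
      if (!fit$converged)
        warning(sprintf("inter fit for dataset %d did not converge", d - 1L))
      inter[d, ] <- -fit$shift
      fit_info[[d]]$inter <- list(cost = fit$cost, init_cost = fit$init_cost,
                                  converged = fit$converged,
                                  evals = fit$evals)
    }
  }

  model <- drift_model(intra, inter, dims = dims,
                       frames_per_dataset = fpd,
                       pixel_size_nm = attr(work, "pixel_size_nm"),
                       fit_info = fit_info)
  drift <- predict(model, work$dataset, work$frame)
  out <- work
  out[dims] <- as.data.frame(pts - drift)
  if (!is.null(mapping)) out <- reassemble(out, mapping)
  list(table = out, model = model)
}

#' Cost-function landscape over a parameter grid
#'
#' Evaluates the intra- or inter-dataset cost on a dense grid of candidate
#' values of the two lateral parameters (linear drift rate per frame for
#' `which = "intra"`, constant shift for `which = "inter"`), for
#' visualization of the funnel-shaped landscape the optimizer descends.
#' Non-varied dimensions are held at zero.
#'
#' @param table a [loc_table()].
#' @param which `"intra"` (cost of dataset `dataset` vs itself) or
#'   `"inter"` (dataset `dataset` vs corrected dataset 0 positions in
#'   `reference`).
#' @param x_grid,y_grid numeric vectors of candidate parameter values
#'   (pixels/frame for intra, pixels for inter).
#' @param dataset 0-based dataset index examined.
#' @param params a [cost_params()].
#' @param reference for `which = "inter"`: matrix of corrected dataset-0
#'   positions (defaults to dataset 0 of `table`, uncorrected).
#' @return list of class `cost_landscape` with `x_grid`, `y_grid` and a
#'   cost `matrix` (rows follow `x_grid`).
#' @export
cost_landscape <- function(table, which = c("intra", "inter"),
                           x_grid, y_grid, dataset = 0L,
                           params = cost_params(), reference = NULL) {
  which <- match.arg(which)
  rows <- table$dataset == dataset
  pts <- coord_matrix(table)[rows, , drop = FALSE]
  frames <- table$frame[rows]
  ndim <- ncol(pts)
  cost <- matrix(NA_real_, length(x_grid), length(y_grid))
  if (which == "intra") {
    for (i in seq_along(x_grid)) for (j in seq_along(y_grid)) {
      co <- matrix(0, 1, ndim)
      co[1, 1] <- x_grid[i]; co[1, 2] <- y_grid[j]
      cost[i, j] <- intra_cost(pts, frames, co, params$l_intra)
    }
    n_query <- nrow(pts); l <- params$l_intra
  } else {
    if (is.null(reference))
      reference <- coord_matrix(table)[table$dataset == 0, , drop = FALSE]
    ref <- nn_reference_index(reference, params$l_inter)
    for (i in seq_along(x_grid)) for (j in seq_along(y_grid)) {
      s <- rep(0, ndim)
      s[1] <- x_grid[i]; s[2] <- y_grid[j]
      cost[i, j] <- inter_cost(ref, pts, s)
    }
    n_query <- nrow(pts); l <- params$l_inter
  }
  structure(list(which = which, x_grid = x_grid, y_grid = y_grid,
                 cost = cost, n_query = n_query, l = l),
            class = "cost_landscape")
}

#' @export
print.cost_landscape <- function(x, ...) {
  mi <- arrayInd(which.min(x$cost), dim(x$cost))
  cat(sprintf(
    "<cost_landscape> %s, %d x %d grid, min %.4g at (%.4g, %.4g)\n",
    x$which, length(x$x_grid), length(x$y_grid), min(x$cost),
    x$x_grid[mi[1]], x$y_grid[mi[2]]))
  invisible(x)
}
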