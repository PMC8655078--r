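#' Construct a brightfield z-stack
#'
#' @param voxels 3D intensity array in (y, x, z) order with at least 3
#'   slices (the sub-voxel z fit needs 3 points).
#' @param z_positions physical z of each slice (nm), strictly increasing and
#'   uniformly spaced; defaults to `0, z_step_nm, ...`.
#' @param pixel_size_nm lateral sampling (nm/pixel).
#' @param z_step_nm axial sampling (nm/slice).
#' @return an `image_stack` object.
#' @export
image_stack <- function(voxels, z_positions = NULL, pixel_size_nm = 100,
                        z_step_nm = 50) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  nz <- dim(voxels)[3]
  if (nz < 3) stop("a z-stack needs at least 3 slices")
  if (!all(is.finite(voxels))) stop("non-finite intensities in stack")
  if (is.null(z_positions)) z_positions <- (seq_len(nz) - 1) * z_step_nm
  dz <- diff(z_positions)
  if (any(dz <= 0) || any(abs(dz - dz[1]) > 1e-6 * dz[1]))
    stop("z positions must be strictly increasing and uniformly spaced")
  structure(list(voxels = voxels, z_positions = z_positions,
                 pixel_size_nm = pixel_size_nm, z_step_nm = dz[1]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d x %d x %d (y,x,z), %g nm/px, %g nm z-step\n",
              d[1], d[2], d[3], x$pixel_size_nm, x$z_step_nm))
  invisible(x)
}

#' Scale each slice of a z-stack by its pixel sum
#'
#' Removes slice-to-slice intensity differences (e.g. from illumination
#' changes with z) that would otherwise bias the z location of the
#' cross-correlation maximum. After scaling, every slice sums to 1.
#'
#' @param stack an [image_stack()].
#' @export
normalize_slices <- function(stack) {
  v <- stack$voxels
  sums <- apply(v, 3, sum)
  if (any(sums == 0)) stop("cannot normalize a slice whose pixel sum is zero")
  stack$voxels <- sweep(v, 3, sums, "/")
  stack
}

#' Whiten a z-stack
#'
#' `(stack - mean(stack)) / (stdev(stack) * sqrt(N - 1))` with mean/stdev over
#' the whole stack and N the total voxel count — equivalently division by
#' `sqrt(max(stack x-corr stack))`, so the whitened stack's full zero-padded
#' autocorrelation peaks at exactly 1 and cross-correlation values are
#' comparable across stacks.
#'
#' @param stack an [image_stack()].
#' @export
whiten_stack <- function(stack) {
  v <- stack$voxels
  s <- sd(as.vector(v))
  if (s == 0) stop("cannot whiten a constant stack")
  stack$voxels <- (v - mean(v)) / (s * sqrt(length(v) - 1))
  stack
}

#' Overlap-count volume: full cross-correlation of ones with itself
#'
#' Each element counts the voxels overlapping at that lag in a full (linear,
#' zero-padded) cross-correlation of two arrays of the given shape; it is the
#' separable product of triangular profiles, with value N (the total voxel
#' count) at zero lag.
#'
#' @param shape integer vector of array dimensions (y, x, z).
#' @return array of dimensions `2 * shape - 1`.
#' @export
ones_overlap <- function(shape) {
  tri <- function(n) if (n == 1) 1 else c(seq_len(n), rev(seq_len(n - 1)))
  ty <- tri(shape[1]); tx <- tri(shape[2]); tz <- tri(shape[3])
  outer(outer(ty, tx), tz)
}

# Full linear cross-correlation c(k) = sum_i a(i) b(i + k) via zero-padded
# FFTs, returned on the ordered lag grid -(n-1)..(n-1) per dimension.
xcorr3_full <- function(a, b) {
  n <- dim(a)
  L <- 2L * n - 1L
  A <- array(0, L); A[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])] <- a
  B <- array(0, L); B[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])] <- b
  cc <- Re(fft(Conj(fft(A)) * fft(B), inverse = TRUE)) / prod(L)
  ix <- lapply(seq_len(3), function(j)
    ((-(n[j] - 1):(n[j] - 1)) %% L[j]) + 1L)
  cc[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' Overlap-scaled full 3D cross-correlation of two prepared stacks
#'
#' Computes the full (linear, zero-padded — not circular) cross-correlation
#' of `ref` and `new` via FFTs and multiplies elementwise by
#' `max(ones x-corr ones) / (ones x-corr ones)`, removing the bias toward
#' small lags caused by the shrinking overlap at large lags. Both inputs are
#' expected to be slice-normalized and whitened already. Lags where the
#' overlap is below 10% of the voxel count are masked out of the subsequent
#' peak search, since the overlap scaling inflates the variance there.
#'
#' @param ref,new [image_stack()]s of equal shape.
#' @return list of class `xcorr_volume` with the scaled correlation array
#'   (dimensions `2*dim - 1`, zero lag at the center), the valid-overlap
#'   mask and the input shape.
#' @export
scaled_xcorr3 <- function(ref, new) {
  if (!identical(dim(ref$voxels), dim(new$voxels)))
    stop("stacks must have identical shapes")
  n <- dim(ref$voxels)
  cc <- xcorr3_full(ref$voxels, new$voxels)
  ov <- ones_overlap(n)
  structure(list(cc = cc * (max(ov) / ov), mask = ov >= 0.1 * max(ov),
                 shape = n), class = "xcorr_volume")
}

#' Sub-voxel peak location of a correlation volume
#'
#' Finds the maximum voxel (within the valid-overlap mask) and refines each
#' coordinate independently by fitting a second-order polynomial to the 3
#' correlation values along the line through the maximum in that dimension;
#' the vertex offset is `(c_r - c_l) / (2 * (2*c_m - c_l - c_r))`. If the
#' maximum sits on a volume border in some dimension, or the 3-point
#' neighborhood has no downward curvature, the integer lag is returned for
#' that dimension with a warning.
#'
#' @param vol an `xcorr_volume` from [scaled_xcorr3()].
#' @return list with `lag` (named dx, dy, dz; voxels, sub-voxel) and
#'   `peak_value` (correlation at the maximum voxel).
#' @export
subpixel_peak <- function(vol) {
  cc <- vol$cc
  cc_search <- cc
  cc_search[!vol$mask] <- -Inf
  mi <- arrayInd(which.max(cc_search), dim(cc))[1, ]
  lag <- numeric(3)
  for (j in 1:3) {
    i <- mi[j]
    if (i <= 1 || i >= dim(cc)[j]) {
      warning("correlation maximum on volume border in dimension ", j,
              "; using integer lag")
      off <- 0
    } else {
      idx <- function(k) { m <- mi; m[j] <- k; cc[matrix(m, 1)] }
      cl <- idx(i - 1); cm <- idx(i); cr <- idx(i + 1)
      den <- 2 * (2 * cm - cl - cr)
      if (den <= .Machine$double.eps * max(abs(c(cl, cm, cr)), 1)) {
        warning("flat 3-point neighborhood in dimension ", j,
                "; using integer lag")
        off <- 0
      } else off <- (cr - cl) / den
    }
    lag[j] <- (mi[j] - vol$shape[j]) + off
  }
  # array order is (y, x, z); report as (dx, dy, dz)
  list(lag = c(dx = lag[2], dy = lag[1], dz = lag[3]),
       peak_value = cc[matrix(mi, 1)])
}

#' Register a brightfield z-stack against a reference once
#'
#' Pipeline: per-slice sum scaling, whitening, overlap-scaled full 3D
#' cross-correlation, sub-voxel quadratic peak fit. Sign convention:
#' a positive shift means the sample appears moved by +shift in the new
#' stack, so the stage should move by -shift to realign.
#'
#' @param ref_stack,new_stack [image_stack()]s of equal shape and sampling.
#' @return list of class `registration_result` with `shift_nm`
#'   (named dx, dy, dz), `peak_value`, `iterations` and `converged`.
#' @export
register_once <- function(ref_stack, new_stack) {
  if (!identical(dim(ref_stack$voxels), dim(new_stack$voxels)))
    stop("stacks must have identical shapes")
  r <- whiten_stack(normalize_slices(ref_stack))
  w <- whiten_stack(normalize_slices(new_stack))
  pk <- subpixel_peak(scaled_xcorr3(r, w))
  shift <- c(dx = unname(pk$lag["dx"]) * ref_stack$pixel_size_nm,
             dy = unname(pk$lag["dy"]) * ref_stack$pixel_size_nm,
             dz = unname(pk$lag["dz"]) * ref_stack$z_step_nm)
  structure(list(shift_nm = shift, peak_value = pk$peak_value,
                 iterations = list(shift), converged = NA),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> shift (%.2f, %.2f, %.2f) nm, peak %.4f%s\n",
    x$shift_nm["dx"], x$shift_nm["dy"], x$shift_nm["dz"], x$peak_value,
    if (isTRUE(x$converged)) sprintf(", converged in %d iteration(s)",
                                     length(x$iterations))
    else if (isFALSE(x$converged)) ", NOT converged" else ""))
  invisible(x)
}

#' Iterative registration loop against a stage
#'
#' Acquire a stack, register it against the reference, move the stage by the
#' negated shift, and repeat until the measured movement falls below the
#' tolerances (5 nm laterally, 50 nm axially by default) or `max_iter` is
#' reached.
#'
#' @param ref_stack the reference [image_stack()].
#' @param stage a stage interface as returned by [simulated_stage()]:
#'   a list with `acquire_stack()` and `move_by(dx, dy, dz)` (nm).
#' @param tol_xy_nm,tol_z_nm convergence tolerances (nm).
#' @param max_iter maximum number of register-and-move iterations.
#' @return a `registration_result` whose `iterations` holds every per-pass
#'   shift and whose `shift_nm` is the final measured shift.
#' @export
register_iterative <- function(ref_stack, stage, tol_xy_nm = 5,
                               tol_z_nm = 50, max_iter = 10L) {
  iterations <- list()
  converged <- FALSE
  res <- NULL
  for (it in seq_len(max_iter)) {
    res <- register_once(ref_stack, stage$acquire_stack())
    iterations[[it]] <- res$shift_nm
    stage$move_by(-res$shift_nm["dx"], -res$shift_nm["dy"],
                  -res$shift_nm["dz"])
    if (all(abs(res$shift_nm[c("dx", "dy")]) < tol_xy_nm) &&
        abs(res$shift_nm["dz"]) < tol_z_nm) {
      converged <- TRUE
      break
    }
  }
  structure(list(shift_nm = res$shift_nm, peak_value = res$peak_value,
                 iterations = iterations, converged = converged),
            class = "registration_result")
}

#' Read / write a z-stack as multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per z-slice. Intensities are stored rescaled to `[0, 1]`;
#' the affine scaling and the z/pixel geometry are recorded in a JSON sidecar
#' (default: same path with extension `.json`) so the stack round-trips.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path.
#' @param sidecar JSON sidecar path.
#' @export
write_image_stack <- function(stack, path,
                              sidecar = paste0(path, ".json")) {
  v <- stack$voxels
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(v)[3]), function(k) (v[, , k] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(z_positions = stack$z_positions,
                            pixel_size_nm = stack$pixel_size_nm,
                            z_step_nm = stack$z_step_nm,
                            intensity_offset = lo, intensity_scale = scale),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, sidecar = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  v <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) v[, , k] <- pages[[k]]
  v <- v * meta$intensity_scale + meta$intensity_offset
  image_stack(v, z_positions = meta$z_positions,
              pixel_size_nm = meta$pixel_size_nm,
              z_step_nm = meta$z_step_nm)
}
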