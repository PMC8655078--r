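#' Drift model: per-dataset polynomial plus inter-dataset constant shift
#'
#' Holds, per dataset and spatial dimension, the intra-dataset polynomial
#' coefficients `a_1..a_P` over frame number (pixels/frame^p, constant term
#' fixed at zero so the model passes through the dataset's first frame) and
#' the constant inter-dataset offset (pixels, zero for dataset 0). Total
#' modeled drift at (dataset d, frame f) is
#' `inter[d] + sum_p a_p[d] * f^p` per dimension.
#'
#' @param intra list with one `P x ndim` coefficient matrix per dataset.
#' @param inter `D x ndim` matrix of constant shifts (pixels).
#' @param dims character vector of dimension names, `c("x","y")` or
#'   `c("x","y","z")`.
#' @param frames_per_dataset frames per dataset (scalar, if known).
#' @param pixel_size_nm lateral pixel size (nm), for unit conversion.
#' @param fit_info optional per-dataset optimizer diagnostics.
#' @return a `drift_model` object.
#' @export
drift_model <- function(intra, inter, dims, frames_per_dataset = NULL,
                        pixel_size_nm = 100, fit_info = NULL) {
  stopifnot(length(intra) == nrow(inter), ncol(inter) == length(dims))
  if (any(abs(inter[1, ]) > 0))
    stop("inter-dataset shift of dataset 0 must be zero")
  structure(list(intra = intra, inter = inter, dims = dims,
                 intra_degree = nrow(intra[[1]]),
                 frames_per_dataset = frames_per_dataset,
                 pixel_size_nm = pixel_size_nm, fit_info = fit_info),
            class = "drift_model")
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf(
    "<drift_model> %d dataset(s), intra degree %d, dims [%s], %g nm/px\n",
    length(x$intra), x$intra_degree, paste(x$dims, collapse = ","),
    x$pixel_size_nm))
  invisible(x)
}

#' Evaluate the modeled drift at localization positions
#'
#' @param object a [drift_model()].
#' @param dataset,frame equal-length vectors of 0-based indices.
#' @param ... unused.
#' @return matrix (length(frame) x ndim) of drift offsets in pixels.
#' @export
predict.drift_model <- function(object, dataset, frame, ...) {
  n <- length(frame)
  out <- matrix(0, n, length(object$dims),
                dimnames = list(NULL, object$dims))
  for (d in sort(unique(dataset))) {
    sel <- dataset == d
    f <- frame[sel]
    co <- object$intra[[d + 1L]]
    acc <- matrix(rep(object$inter[d + 1L, ], each = sum(sel)), ncol = ncol(out))
    for (p in seq_len(nrow(co)))
      acc <- acc + outer(f^p, co[p, ])
    out[sel, ] <- acc
  }
  out
}

#' Evaluate the modeled drift curve over all frames
#'
#' @param model a [drift_model()].
#' @param frames_per_dataset frames per dataset; defaults to the value stored
#'   in the model.
#' @param units `"pixels"` or `"nm"`.
#' @return data.frame with global `frame` and one drift column per dimension.
#' @export
drift_curve_from_model <- function(model,
                                   frames_per_dataset =
                                     model$frames_per_dataset,
                                   units = c("pixels", "nm")) {
  units <- match.arg(units)
  if (is.null(frames_per_dataset))
    stop("frames per dataset unknown; supply frames_per_dataset")
  fpd <- as.integer(frames_per_dataset)
  D <- length(model$intra)
  dataset <- rep(seq_len(D) - 1L, each = fpd)
  frame <- rep(seq_len(fpd) - 1L, times = D)
  drift <- predict(model, dataset, frame)
  if (units == "nm") drift <- drift * model$pixel_size_nm
  out <- data.frame(frame = dataset * fpd + frame)
  out[model$dims] <- as.data.frame(drift)
  out
}

#' Serialize / restore a drift model as JSON
#'
#' @param model a [drift_model()].
#' @param path JSON file path.
#' @export
write_drift_model <- function(model, path) {
  obj <- list(intra_degree = model$intra_degree,
              pixel_size_nm = model$pixel_size_nm,
              dims = model$dims,
              frames_per_dataset = model$frames_per_dataset,
              datasets = lapply(seq_along(model$intra), function(i) {
                list(intra_coeffs = model$intra[[i]],
                     inter_shift = model$inter[i, ])
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_drift_model
#' @export
read_drift_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dims <- unlist(obj$dims)
  ndim <- length(dims)
  intra <- lapply(obj$datasets, function(d)
    matrix(unlist(d$intra_coeffs), ncol = ndim, byrow = TRUE,
           dimnames = list(NULL, dims)))
  inter <- do.call(rbind, lapply(obj$datasets, function(d)
    unlist(d$inter_shift)))
  colnames(inter) <- dims
  fpd <- obj$frames_per_dataset
  if (is.null(fpd) || length(fpd) == 0) fpd <- NULL else fpd <- unlist(fpd)
  drift_model(intra, inter, dims = dims, frames_per_dataset = fpd,
              pixel_size_nm = unlist(obj$pixel_size_nm))
}
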