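#' Construct a localization table
#'
#' The working container of the package: one row per localization with lateral
#' coordinates `x`, `y` (and `z` for 3D tables) in **pixels**, a 0-based
#' `frame` index within its dataset and a 0-based `dataset` index. A dataset
#' is a contiguous block of frames acquired between registration events.
#' Internal canonical units are pixels because the nearest-neighbor
#' thresholds are naturally expressed in pixels; nanometer conversion happens
#' only at I/O boundaries via `pixel_size_nm`. The axial coordinate `z` is
#' expressed in the same lateral pixel unit so that the Euclidean
#' nearest-neighbor metric and its thresholds are isotropic.
#'
#' @param x,y lateral coordinates (pixels).
#' @param z optional axial coordinate (pixels, lateral pixel unit).
#' @param frame integer frame index within the dataset (0-based).
#' @param dataset integer dataset index (0-based, contiguous from 0).
#' @param pixel_size_nm physical lateral pixel size (nm/pixel).
#' @param frames_per_dataset number of frames per dataset, if uniform and
#'   known (needed to re-segment multi-dataset tables).
#' @param extra optional data.frame of passthrough columns (e.g. photons).
#' @return a `loc_table` data.frame.
#' @export
loc_table <- function(x, y, z = NULL, frame, dataset = 0L,
                      pixel_size_nm = 100, frames_per_dataset = NULL,
                      extra = NULL) {
  n <- length(x)
  frame <- as.integer(round(frame))
  dataset <- as.integer(round(rep_len(dataset, n)))
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(z)) df$z <- as.numeric(z)
  df$frame <- frame
  df$dataset <- dataset
  if (!is.null(extra)) df <- cbind(df, extra)
  attr(df, "pixel_size_nm") <- pixel_size_nm
  attr(df, "frames_per_dataset") <- frames_per_dataset
  class(df) <- c("loc_table", "data.frame")
  validate_loc_table(df)
  df
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, %s, %d dataset(s), %g nm/px\n",
              nrow(x), if (is_3d(x)) "3D" else "2D",
              n_datasets(x), attr(x, "pixel_size_nm")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

validate_loc_table <- function(t) {
  cols <- coord_cols(t)
  for (cc in c(cols, "frame", "dataset"))
    if (!cc %in% names(t)) stop("missing required column: ", cc)
  if (nrow(t) == 0) return(invisible(t))
  if (!all(is.finite(as.matrix(t[cols]))))
    stop("non-finite coordinates in localization table")
  if (any(t$frame < 0) || any(t$dataset < 0))
    stop("frame and dataset indices must be >= 0")
  ds <- sort(unique(t$dataset))
  if (!identical(as.integer(ds), seq_len(length(ds)) - 1L))
    stop("dataset indices must form a contiguous range starting at 0")
  invisible(t)
}

#' @rdname loc_table
#' @param table a `loc_table`.
#' @export
is_3d <- function(table) "z" %in% names(table)

coord_cols <- function(table) if (is_3d(table)) c("x", "y", "z") else c("x", "y")

n_datasets <- function(table)
  if (nrow(table) == 0) 0L else max(table$dataset) + 1L

coord_matrix <- function(table)
  as.matrix(as.data.frame(table)[coord_cols(table)])

#' Read a localization table from CSV
#'
#' Expects a header row with columns `x,y[,z],frame,dataset` plus optional
#' passthrough columns (`photons`, `bg`, `precision`, ...). Columns named
#' `x_nm`/`y_nm`/`z_nm` are accepted as nm-unit coordinates regardless of
#' `units_on_disk`. Coordinates are converted to pixels on read.
#'
#' @param path CSV file path.
#' @param pixel_size_nm lateral pixel size used for nm/pixel conversion.
#' @param units_on_disk units of the coordinate columns: `"nm"` or `"pixels"`.
#' @param frame_base 0 or 1: value of the first frame/dataset index on disk.
#' @return a [loc_table()].
#' @export
read_localizations <- function(path, pixel_size_nm = 100,
                               units_on_disk = c("nm", "pixels"),
                               frame_base = 0L) {
  units_on_disk <- match.arg(units_on_disk)
  stopifnot(pixel_size_nm > 0)
  if (!file.exists(path)) stop("cannot open file: ", path)
  raw <- read.csv(path, check.names = FALSE)
  nm_named <- all(c("x_nm", "y_nm") %in% names(raw))
  if (nm_named) {
    names(raw)[names(raw) == "x_nm"] <- "x"
    names(raw)[names(raw) == "y_nm"] <- "y"
    names(raw)[names(raw) == "z_nm"] <- "z"
    units_on_disk <- "nm"
  }
  for (cc in c("x", "y", "frame"))
    if (!cc %in% names(raw)) stop("missing required column: ", cc)
  if (!"dataset" %in% names(raw)) raw$dataset <- frame_base
  has_z <- "z" %in% names(raw)
  if (has_z && anyNA(raw$z)) {
    if (all(is.na(raw$z))) {
      raw$z <- NULL
      has_z <- FALSE
    } else stop("mixed z presence: some rows have z, others do not")
  }
  scale <- if (units_on_disk == "nm") 1 / pixel_size_nm else 1
  extra <- raw[setdiff(names(raw), c("x", "y", "z", "frame", "dataset"))]
  if (ncol(extra) == 0) extra <- NULL
  loc_table(x = raw$x * scale, y = raw$y * scale,
            z = if (has_z) raw$z * scale else NULL,
            frame = raw$frame - frame_base,
            dataset = raw$dataset - frame_base,
            pixel_size_nm = pixel_size_nm, extra = extra)
}

#' Write a localization table to CSV
#'
#' @param table a [loc_table()].
#' @param path output path.
#' @param units_on_disk coordinate units to write: `"nm"` or `"pixels"`.
#' @export
write_localizations <- function(table, path,
                                units_on_disk = c("nm", "pixels")) {
  units_on_disk <- match.arg(units_on_disk)
  out <- as.data.frame(table)
  scale <- if (units_on_disk == "nm") attr(table, "pixel_size_nm") else 1
  for (cc in coord_cols(table)) out[[cc]] <- out[[cc]] * scale
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-segment a localization table into fixed-size datasets
#'
#' Reorganizes the global frame sequence (global frame =
#' `dataset * original_frames_per_dataset + frame`) into consecutive chunks
#' of `frames_per_dataset` frames, renumbering `dataset` and `frame`
#' accordingly. A mapping is returned so [reassemble()] can restore the
#' original scheme exactly after drift correction.
#'
#' @param table a [loc_table()].
#' @param frames_per_dataset requested chunk size (frames).
#' @param original_frames_per_dataset frames per dataset in the input
#'   scheme; defaults to the table's `frames_per_dataset` attribute. Only
#'   required when the table holds more than one dataset.
#' @return list with elements `table` (re-segmented) and `mapping`.
#' @export
resegment <- function(table, frames_per_dataset,
                      original_frames_per_dataset =
                        attr(table, "frames_per_dataset")) {
  stopifnot(frames_per_dataset >= 1)
  if (n_datasets(table) > 1 && is.null(original_frames_per_dataset))
    stop("original frames per dataset unknown; supply ",
         "original_frames_per_dataset")
  orig <- if (is.null(original_frames_per_dataset)) 0L
          else as.integer(original_frames_per_dataset)
  global <- table$dataset * orig + table$frame
  mapping <- list(dataset = table$dataset, frame = table$frame,
                  frames_per_dataset = attr(table, "frames_per_dataset"))
  out <- table
  out$dataset <- as.integer(global %/% frames_per_dataset)
  out$frame <- as.integer(global %% frames_per_dataset)
  attr(out, "frames_per_dataset") <- as.integer(frames_per_dataset)
  list(table = out, mapping = mapping)
}

#' @rdname resegment
#' @param mapping the mapping returned by [resegment()].
#' @export
reassemble <- function(table, mapping) {
  out <- table
  out$dataset <- mapping$dataset
  out$frame <- mapping$frame
  attr(out, "frames_per_dataset") <- mapping$frames_per_dataset
  out
}

#' Merge repeated localizations of one emitter across consecutive frames
#'
#' Greedy frame-connection: localizations in nearby frames (gap at most
#' `max_gap_frames`) and within `radius_px` of a running cluster centroid are
#' merged into a single localization at the unweighted centroid of the merged
#' inputs, with `frame` set to the first frame of the run. Within each frame,
#' candidate merges are committed nearest-first; each cluster absorbs at most
#' one localization per frame. Passthrough columns keep the first member's
#' values; a column `n_merged` counts members.
#'
#' @param table a [loc_table()].
#' @param radius_px merge radius (pixels).
#' @param max_gap_frames maximum allowed gap between consecutive members.
#' @return a [loc_table()] with at most as many rows as the input.
#' @export
connect_frames <- function(table, radius_px, max_gap_frames = 0L) {
  stopifnot(radius_px > 0, max_gap_frames >= 0)
  if (nrow(table) == 0) return(table)
  cols <- coord_cols(table)
  pieces <- lapply(split(seq_len(nrow(table)), table$dataset), function(idx) {
    connect_one_dataset(as.data.frame(table)[idx, , drop = FALSE],
                        cols, radius_px, max_gap_frames)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$dataset, out$frame), , drop = FALSE]
  attr(out, "pixel_size_nm") <- attr(table, "pixel_size_nm")
  attr(out, "frames_per_dataset") <- attr(table, "frames_per_dataset")
  class(out) <- c("loc_table", "data.frame")
  out
}

connect_one_dataset <- function(df, cols, radius, max_gap) {
  df <- df[order(df$frame), , drop = FALSE]
  pts <- as.matrix(df[cols])
  # clusters: coordinate sums for the output centroid; candidate matching is
  # against the most recent member so pairwise-linked chains stay one run
  cl_sum <- matrix(0, 0, length(cols))
  cl_head <- matrix(0, 0, length(cols))
  cl_n <- integer(0)
  cl_last <- integer(0)
  cl_first_row <- integer(0)
  for (f in sort(unique(df$frame))) {
    rows <- which(df$frame == f)
    active <- which(cl_last >= f - max_gap - 1L & cl_last < f)
    taken_cl <- rep(FALSE, length(cl_n))
    taken_row <- rep(FALSE, length(rows))
    if (length(active) > 0) {
      head_pos <- cl_head[active, , drop = FALSE]
      d2 <- outer(rowSums(pts[rows, , drop = FALSE]^2),
                  rowSums(head_pos^2), "+") -
        2 * pts[rows, , drop = FALSE] %*% t(head_pos)
      cand <- which(d2 <= radius^2 + 1e-12, arr.ind = TRUE)
      if (length(cand) > 0) {
        ord <- order(d2[cand])
        for (k in ord) {
          r <- cand[k, 1]; c <- active[cand[k, 2]]
          if (taken_row[r] || taken_cl[c]) next
          taken_row[r] <- TRUE; taken_cl[c] <- TRUE
          cl_sum[c, ] <- cl_sum[c, ] + pts[rows[r], ]
          cl_head[c, ] <- pts[rows[r], ]
          cl_n[c] <- cl_n[c] + 1L
          cl_last[c] <- f
        }
      }
    }
    for (r in which(!taken_row)) {
      cl_sum <- rbind(cl_sum, pts[rows[r], ])
      cl_head <- rbind(cl_head, pts[rows[r], ])
      cl_n <- c(cl_n, 1L)
      cl_last <- c(cl_last, f)
      cl_first_row <- c(cl_first_row, rows[r])
    }
  }
  out <- df[cl_first_row, , drop = FALSE]
  out[cols] <- cl_sum / cl_n
  out$n_merged <- cl_n
  out
}
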