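# Independent oracles used across test files; deliberately naive so they
# stay independent of the implementation paths they check.

# O(n^2) thresholded nearest-neighbor sum.
brute_nnd_sum <- function(query, reference, l, exclude_self = FALSE) {
  query <- as.matrix(query)
  reference <- as.matrix(reference)
  if (nrow(query) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(query))) {
    d <- sqrt(rowSums(
      (reference - matrix(query[i, ], nrow(reference), ncol(reference),
                          byrow = TRUE))^2))
    if (exclude_self) d <- d[-i]
    total <- total + min(c(d, l))
  }
  total
}

# Direct sliding-window full cross-correlation with overlap scaling.
brute_scaled_xcorr3 <- function(a, b) {
  n <- dim(a)
  out <- array(0, 2 * n - 1)
  N <- prod(n)
  for (ky in -(n[1] - 1):(n[1] - 1))
    for (kx in -(n[2] - 1):(n[2] - 1))
      for (kz in -(n[3] - 1):(n[3] - 1)) {
        iy <- max(1, 1 - ky):min(n[1], n[1] - ky)
        ix <- max(1, 1 - kx):min(n[2], n[2] - kx)
        iz <- max(1, 1 - kz):min(n[3], n[3] - kz)
        s <- sum(a[iy, ix, iz] * b[iy + ky, ix + kx, iz + kz])
        cnt <- length(iy) * length(ix) * length(iz)
        out[ky + n[1], kx + n[2], kz + n[3]] <- s * N / cnt
      }
  out
}

# Small noiseless field where every emitter blinks in several known frames.
make_duplicated_emitters <- function(n_emitters = 150, n_blinks = 4,
                                     n_frames = 400, roi_px = 60,
                                     rate_px_frame = c(0.003, 0.004),
                                     seed = 42) {
  set.seed(seed)
  em <- matrix(runif(n_emitters * 2, 0, roi_px), ncol = 2)
  frames <- sample(0:(n_frames - 1), n_emitters * n_blinks, replace = TRUE)
  pos <- em[rep(seq_len(n_emitters), each = n_blinks), ] +
    outer(frames, rate_px_frame)
  list(positions = pos, frames = frames, rate = rate_px_frame,
       emitter = rep(seq_len(n_emitters), each = n_blinks))
}

# Quick blinking localization table in pixels (uniform 2D field, nm inputs).
quick_sim <- function(n_emitters, lambda, n_frames = 1000, roi_nm = 25600,
                      alpha = c(0.05, 0.02), sigma = 10,
                      frames_per_dataset = n_frames, seed = 1) {
  set.seed(seed)
  field <- gen_uniform_emitters(roi_nm, n_emitters / roi_nm^2)
  traces <- gen_blink_traces(nrow(field), n_frames,
                             K_on = kon_for_lambda(lambda, n_frames))
  curve <- gen_drift_polynomial(n_frames, alpha)
  sim <- render_localizations(field, traces, curve, noise_sigma_nm = sigma,
                              frames_per_dataset = frames_per_dataset)
  sim$curve <- curve
  sim$traces <- traces
  sim
}

coords_of <- function(tab)
  as.matrix(as.data.frame(tab)[, intersect(c("x", "y", "z"), names(tab))])
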