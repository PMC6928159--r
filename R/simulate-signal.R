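# Rician magnitude of a noise-free signal s at Gaussian channel noise sigma
.rician <- function(s, sigma) {
  n <- length(s)
  sqrt((s + sigma * rnorm(n))^2 + (sigma * rnorm(n))^2)
}

#' Simulate the diffusion-weighted signal of one voxel
#'
#' Evaluates the forward DKI model for a known ground-truth tensor and,
#' optionally, corrupts it with Rician noise: the magnitude of the
#' noise-free signal plus complex Gaussian channel noise of standard
#' deviation sigma = S0 / snr.
#'
#' @param truth a [tensor_fit()] holding the ground-truth S0, D and W.
#' @param scheme a [gradient_scheme()].
#' @param snr signal-to-noise ratio at b = 0 (S0 / sigma); `NULL` for a
#'   noise-free signal, in which case the output equals
#'   [predict_signal()] exactly.
#' @param seed optional integer seed for the noise draws.
#' @return numeric signal vector.
#' @export
simulate_voxel_signal <- function(truth, scheme, snr = NULL, seed = NULL) {
  if (truth$s0 <= 0) abort("S0 must be positive")
  s <- predict_signal(truth, scheme)
  if (is.null(snr)) return(s)
  if (snr <= 0) abort("snr must be positive")
  if (!is.null(seed)) set.seed(seed)
  .rician(s, truth$s0 / snr)
}

#' Simulate a tube phantom of a nerve segment
#'
#' Builds a 4-D diffusion-weighted volume of a straight cylindrical nerve
#' along the slice (third) axis: voxels inside the tube carry signals
#' simulated from their slice's ground-truth tensor, voxels outside carry
#' pure background noise (the Rician magnitude of zero signal). Slices are
#' labeled proximal / injury / distal by [label_slices()].
#'
#' @param slice_truths list of [tensor_fit()] objects, one per slice.
#' @param radius tube radius in voxels (> 0).
#' @param matrix_size in-plane matrix size (the volume is
#'   `matrix_size x matrix_size x n_slices`).
#' @param scheme a [gradient_scheme()].
#' @param injury_start,injury_end 0-based inclusive slice interval of the
#'   injury zone (see [label_slices()]).
#' @param snr b = 0 signal-to-noise ratio; `NULL` for noise-free.
#' @param seed integer seed.
#' @return list with `image` (4-D array), `mask` (3-D 0/1 array),
#'   `labels` (character vector per slice) and `scheme`.
#' @export
simulate_nerve_volume <- function(slice_truths, radius, matrix_size = 8,
                                  scheme, injury_start, injury_end,
                                  snr = NULL, seed = 1) {
  n_slices <- length(slice_truths)
  labels <- label_slices(n_slices, injury_start, injury_end)
  if (radius <= 0 || matrix_size < 2 * radius) {
    abort("tube radius must be positive and fit inside the matrix")
  }
  ctr <- (matrix_size + 1) / 2
  xy <- expand.grid(x = seq_len(matrix_size), y = seq_len(matrix_size))
  inside <- (xy$x - ctr)^2 + (xy$y - ctr)^2 <= radius^2
  if (!any(inside)) abort("tube mask is empty: radius too small for the voxel grid")

  mask <- array(0L, c(matrix_size, matrix_size, n_slices))
  for (z in seq_len(n_slices)) {
    mask[cbind(xy$x[inside], xy$y[inside], z)] <- 1L
  }
  m <- n_acquisitions(scheme)
  image <- array(0, c(matrix_size, matrix_size, n_slices, m))
  set.seed(seed)
  s0_ref <- mean(vapply(slice_truths, function(t) t$s0, numeric(1)))
  sigma <- if (is.null(snr)) 0 else s0_ref / snr
  for (z in seq_len(n_slices)) {
    clean <- predict_signal(slice_truths[[z]], scheme)
    for (v in which(inside)) {
      sig <- if (sigma > 0) .rician(clean, sigma) else clean
      image[xy$x[v], xy$y[v], z, ] <- sig
    }
    for (v in which(!inside)) {
      image[xy$x[v], xy$y[v], z, ] <- if (sigma > 0) .rician(rep(0, m), sigma) else 0
    }
  }
  list(image = image, mask = mask, labels = labels, scheme = scheme)
}
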