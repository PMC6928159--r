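#' Gradient schemes
#'
#' A gradient scheme records, per acquisition, the diffusion weighting
#' (b-value, s/mm^2) and the unit gradient direction (zero vector for b = 0
#' acquisitions). It is the acquisition-side contract shared by the forward
#' signal model, the tensor estimator and the simulator.
#'
#' @param bvalues numeric vector of b-values in s/mm^2, one per acquisition.
#' @param directions numeric matrix, one row per acquisition, of gradient
#'   directions. Rows for nonzero b must have unit Euclidean norm; rows for
#'   b = 0 must be the zero vector.
#' @param delta,Delta optional pulse duration / diffusion time (ms), carried
#'   as annotation only.
#'
#' @return An object of class `gradient_scheme`: a list with elements
#'   `bvalues`, `directions` and `meta`.
#' @export
gradient_scheme <- function(bvalues, directions, delta = NULL, Delta = NULL) {
  bvalues <- as.numeric(bvalues)
  directions <- as.matrix(directions)
  if (nrow(directions) != length(bvalues)) {
    abort(sprintf("gradient table mismatch: %d b-values vs %d directions",
                  length(bvalues), nrow(directions)))
  }
  if (ncol(directions) != 3L) abort("directions must be 3-vectors")
  if (any(bvalues < 0)) abort("b-values must be nonnegative")
  nz <- bvalues > 0
  if (!any(!nz)) abort("scheme must contain at least one b = 0 acquisition")
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms[nz] - 1) > 1e-12)) {
    abort("all nonzero-b directions must have unit norm (tolerance 1e-12)")
  }
  directions[!nz, ] <- 0
  structure(
    list(bvalues = bvalues, directions = directions,
         meta = list(delta = delta, Delta = Delta)),
    class = "gradient_scheme"
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  ub <- sort(unique(x$bvalues))
  cat("<gradient_scheme> ", length(x$bvalues), " acquisitions\n", sep = "")
  cat("  b-values (s/mm^2): ", paste(ub, collapse = ", "),
      "  (", sum(x$bvalues == 0), " x b=0)\n", sep = "")
  invisible(x)
}

#' Number of acquisitions in a scheme
#' @param scheme a [gradient_scheme()].
#' @return integer count.
#' @export
n_acquisitions <- function(scheme) length(scheme$bvalues)

# Electrostatic-repulsion refinement of antipodally symmetric points on the
# unit sphere: gradient descent on sum_{i<j} 1/d(+-xi, +-xj).
.repulse_directions <- function(n, seed, n_iter = 200, step0 = 0.1) {
  set.seed(seed)
  x <- matrix(rnorm(3 * n), ncol = 3)
  x <- x / sqrt(rowSums(x^2))
  step <- step0
  energy <- function(p) {
    e <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d1 <- sqrt(sum((p[i, ] - p[j, ])^2))
      d2 <- sqrt(sum((p[i, ] + p[j, ])^2))
      e <- e + 1 / max(d1, 1e-9) + 1 / max(d2, 1e-9)
    }
    e
  }
  e_old <- energy(x)
  for (it in seq_len(n_iter)) {
    g <- matrix(0, n, 3)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dv <- x[i, ] - x[j, ]; sv <- x[i, ] + x[j, ]
      d1 <- max(sqrt(sum(dv^2)), 1e-9); d2 <- max(sqrt(sum(sv^2)), 1e-9)
      g[i, ] <- g[i, ] - dv / d1^3 - sv / d2^3
      g[j, ] <- g[j, ] + dv / d1^3 - sv / d2^3
    }
    xn <- x - step * g
    xn <- xn / sqrt(rowSums(xn^2))
    e_new <- energy(xn)
    if (e_new < e_old) {
      x <- xn; e_old <- e_new; step <- step * 1.1
    } else {
      step <- step / 2
      if (step < 1e-8) break
    }
  }
  x
}

#' Generate an acquisition scheme with near-uniform directions
#'
#' Builds a multi-shell scheme in the style of a two-shell nerve protocol
#' (e.g. b = 2000 and 4000 s/mm^2, 20 directions, plus b = 0): a seeded
#' random set of directions is refined by electrostatic repulsion (with
#' antipodal symmetry) and repeated on every shell, with `n_b0` unweighted
#' acquisitions prepended.
#'
#' @param n_dirs number of gradient directions (>= 6 for diffusion-tensor
#'   identifiability; >= 15 recommended when kurtosis is estimated).
#' @param bvalues nonzero b-values in s/mm^2, one shell per value.
#' @param n_b0 number of b = 0 acquisitions prepended.
#' @param seed integer seed; the scheme is deterministic given the seed.
#' @return a [gradient_scheme()] with `n_b0 + n_dirs * length(bvalues)`
#'   acquisitions.
#' @examples
#' sch <- make_gradient_scheme(20, c(2000, 4000), n_b0 = 1, seed = 7)
#' n_acquisitions(sch)  # 41
#' @export
make_gradient_scheme <- function(n_dirs, bvalues, n_b0 = 1, seed = 1) {
  if (n_dirs < 6) {
    abort(sprintf(
      "n_dirs = %d is below the minimum of 6 directions required to identify the diffusion tensor",
      n_dirs))
  }
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) == 0 || any(bvalues <= 0)) {
    abort("bvalues must be a nonempty vector of positive b-values")
  }
  dirs <- .repulse_directions(n_dirs, seed = seed)
  b <- c(rep(0, n_b0), rep(bvalues, each = n_dirs))
  d <- rbind(matrix(0, n_b0, 3),
             do.call(rbind, replicate(length(bvalues), dirs, simplify = FALSE)))
  gradient_scheme(b, d)
}

#' Read and write FSL-style gradient tables
#'
#' `read_bval_bvec()` reads a space-separated 1-row `.bval` and 3-row `.bvec`
#' pair into a [gradient_scheme()]; `write_bval_bvec()` is its inverse.
#' Direction norms deviating from 1 by less than 1e-3 are renormalized;
#' larger deviations are an error.
#'
#' @param bval_path,bvec_path file paths.
#' @param scheme a [gradient_scheme()] (for writing).
#' @param b0_threshold b-values below this (s/mm^2) are treated as b = 0.
#' @return `read_bval_bvec()` returns a [gradient_scheme()];
#'   `write_bval_bvec()` returns the paths invisibly.
#' @export
read_bval_bvec <- function(bval_path, bvec_path, b0_threshold = 50) {
  b <- scan(bval_path, what = numeric(), quiet = TRUE)
  v <- as.matrix(read.table(bvec_path))
  if (nrow(v) != 3L) abort("bvec file must have exactly 3 rows")
  if (ncol(v) != length(b)) {
    abort(sprintf("gradient table mismatch: %d b-values vs %d b-vectors",
                  length(b), ncol(v)))
  }
  d <- t(v)
  b[b < b0_threshold] <- 0
  nz <- b > 0
  norms <- sqrt(rowSums(d^2))
  bad <- nz & abs(norms - 1) >= 1e-3
  if (any(bad)) {
    abort(sprintf("b-vector %d has norm %.4f (deviation >= 1e-3)",
                  which(bad)[1], norms[which(bad)[1]]))
  }
  d[nz, ] <- d[nz, , drop = FALSE] / norms[nz]
  gradient_scheme(b, d)
}

#' @rdname read_bval_bvec
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(sprintf("%.17g", scheme$bvalues), collapse = " "), bval_path)
  v <- t(scheme$directions)
  lines <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(lines, bvec_path)
  invisible(c(bval_path, bvec_path))
}
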