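#' Construct a tensor fit object
#'
#' Container for the 22 parameters of the DKI signal representation: the
#' unweighted signal S0, the symmetric diffusion tensor D (um^2/ms) and the
#' 15 unique elements of the fully symmetric kurtosis tensor W.
#'
#' @param s0 positive unweighted signal.
#' @param D symmetric 3x3 diffusion tensor.
#' @param W 15 unique kurtosis elements (default all zero, i.e. a pure
#'   Gaussian tensor model).
#' @param diagnostics optional list of fit diagnostics.
#' @return object of class `tensor_fit`.
#' @export
tensor_fit <- function(s0, D, W = numeric(15), diagnostics = list()) {
  if (s0 <= 0) abort("S0 must be positive")
  D <- as.matrix(D)
  d6 <- matrix_to_d6(D)   # validates symmetry
  W <- as.numeric(W)
  if (length(W) != 15) abort("W must have 15 unique elements")
  lam <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  structure(
    list(s0 = s0, D = d6_to_matrix(d6), W = W,
         diagnostics = c(diagnostics,
                         list(negative_eigenvalues = any(lam < 0)))),
    class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  sc <- dti_scalars(x$D)
  cat("<tensor_fit>  S0 =", signif(x$s0, 5), "\n")
  cat(sprintf("  FA %.4f  MD %.4f  AD %.4f  RD %.4f (um^2/ms)\n",
              sc$fa, sc$md, sc$ad, sc$rd))
  if (isTRUE(x$diagnostics$kurtosis_undefined)) {
    cat("  kurtosis tensor undefined (MD <= 0)\n")
  }
  invisible(x)
}

#' Predict diffusion-weighted signals from a tensor fit
#'
#' Evaluates the standard log-quadratic DKI representation
#' ln S(b, n) = ln S0 - b D_app(n) + (b^2/6) MD^2 sum n_i n_j n_k n_l W_ijkl,
#' where D_app(n) = n' D n. The b^2 term equals (b^2/6) D_app^2 K_app by the
#' definition of apparent kurtosis. b = 0 acquisitions return S0 exactly.
#'
#' @param fit a [tensor_fit()].
#' @param scheme a [gradient_scheme()]; b-values in s/mm^2 are converted to
#'   ms/um^2 internally.
#' @return numeric signal vector, one entry per acquisition.
#' @examples
#' sch <- gradient_scheme(c(0, 2000), rbind(c(0, 0, 0), c(1, 0, 0)))
#' predict_signal(tensor_fit(1, diag(c(1.5, 0.5, 0.5))), sch)  # 1, exp(-3)
#' @export
predict_signal <- function(fit, scheme) {
  b <- .b_internal(scheme$bvalues)
  n <- scheme$directions
  nz <- b > 0
  dapp <- .d_app(fit$D, n)
  if (any(dapp[nz] <= 0)) {
    abort("apparent diffusivity is nonpositive along an acquisition direction (degenerate tensor)")
  }
  md <- mean(diag(fit$D))
  w4 <- .w4_contract(fit$W, n)
  lns <- log(fit$s0) - b * dapp + (b^2 / 6) * md^2 * w4
  s <- exp(lns)
  s[!nz] <- fit$s0
  s
}

#' Design matrix of the linearized DKI model
#'
#' One row per acquisition, 22 columns in fixed order: intercept (ln S0);
#' the 6 diffusion-tensor columns -b * m_ij n_i n_j with multiplicities
#' (1,1,1,2,2,2) for (xx, yy, zz, xy, xz, yz); the 15 kurtosis columns
#' +(b^2/6) * m_ijkl n_i n_j n_k n_l with multinomial multiplicities
#' (1,1,1,4,4,4,4,4,4,6,6,6,12,12,12) for the unique index patterns. The
#' kurtosis block multiplies MD^2 * W, so the raw linear parameters are
#' (ln S0, D_6, MD^2 W_15).
#'
#' @param scheme a [gradient_scheme()].
#' @return numeric matrix, `n_acquisitions(scheme)` x 22.
#' @export
build_design_matrix <- function(scheme) {
  b <- .b_internal(scheme$bvalues)
  n <- scheme$directions
  d_block <- cbind(n[, 1]^2, n[, 2]^2, n[, 3]^2,
                   n[, 1] * n[, 2], n[, 1] * n[, 3], n[, 2] * n[, 3])
  d_block <- sweep(d_block, 2, .D_MULT, `*`)
  w_block <- sweep(.w15_monomials(n), 2, .W_MULT, `*`)
  X <- cbind(1, -b * d_block, (b^2 / 6) * w_block)
  colnames(X) <- c("lnS0", paste0("D.", .D_NAMES), paste0("W.", .W_NAMES))
  X
}

#' Weighted linear least-squares tensor estimation
#'
#' Two-pass WLLS on the log signal: pass 1 is ordinary least squares on
#' ln S, subsequent passes reweight each acquisition by the squared signal
#' predicted from the previous pass (the standard heteroscedasticity
#' correction for log-transformed Rician-corrupted magnitudes). The kurtosis
#' block of the linear model estimates MD^2 * W; W is recovered by dividing
#' by the squared mean diffusivity of the fitted D. Nonpositive signals are
#' clamped to `eps_frac * max(signal)` before the log and flagged.
#'
#' No positivity constraints are imposed: negative eigenvalues or a
#' nonpositive MD are flagged in `diagnostics`, not projected away. When
#' MD <= 0 the kurtosis tensor is undefined and W is returned as NA.
#'
#' @param signals positive signal vector, one per acquisition.
#' @param scheme a [gradient_scheme()] with at least 22 acquisitions whose
#'   design matrix has full column rank.
#' @param n_pass number of WLLS passes (1 = plain OLS; default 2).
#' @param eps_frac clamping floor for nonpositive signals, as a fraction of
#'   the maximum signal.
#' @return a [tensor_fit()] whose `diagnostics` carry the weighted residual
#'   norm, the design condition number, and flags (`clamped_signals`,
#'   `kurtosis_undefined`, `negative_eigenvalues`).
#' @export
fit_wlls <- function(signals, scheme, n_pass = 2, eps_frac = 1e-6) {
  signals <- as.numeric(signals)
  m <- n_acquisitions(scheme)
  if (length(signals) != m) {
    abort(sprintf("signal length %d does not match scheme with %d acquisitions",
                  length(signals), m))
  }
  if (m < 22) {
    abort(sprintf("DKI estimation needs >= 22 acquisitions, got %d", m))
  }
  X <- build_design_matrix(scheme)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    missing_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf(
      "design matrix is rank deficient (rank %d of %d); unidentifiable columns: %s",
      qrX$rank, ncol(X), paste(missing_cols, collapse = ", ")))
  }
  clamped <- signals <= 0
  floor_val <- eps_frac * max(signals)
  if (any(clamped)) signals[clamped] <- floor_val
  y <- log(signals)

  beta <- qr.coef(qrX, y)
  if (n_pass > 1) {
    for (pass in 2:n_pass) {
      w <- exp(X %*% beta)^2
      fitw <- stats::lm.wfit(X, y, w = as.numeric(w))
      beta <- fitw$coefficients
    }
  }
  resid <- y - as.numeric(X %*% beta)
  w_final <- if (n_pass > 1) as.numeric(exp(X %*% beta)^2) else rep(1, m)

  beta <- unname(beta)
  s0 <- exp(beta[1])
  D <- d6_to_matrix(beta[2:7])
  md <- mean(diag(D))
  kurt_undef <- md <= 0
  W <- if (kurt_undef) rep(NA_real_, 15) else as.numeric(beta[8:22]) / md^2
  sv <- svd(X, nu = 0, nv = 0)$d
  tensor_fit(
    s0, D, ifelse(is.na(W), 0, W),
    diagnostics = list(
      residual_norm = sqrt(sum(w_final * resid^2)),
      condition_number = sv[1] / sv[length(sv)],
      clamped_signals = sum(clamped),
      kurtosis_undefined = kurt_undef)
  ) -> fit
  if (kurt_undef) fit$W <- rep(NA_real_, 15)
  fit
}

#' All scalar indices of a tensor fit
#'
#' Convenience wrapper combining [dti_scalars()] and [kurtosis_scalars()]
#' into a one-row tibble.
#'
#' @param fit a [tensor_fit()].
#' @inheritParams kurtosis_scalars
#' @return one-row tibble with columns fa, md, ad, rd, mk, ak, rk,
#'   e1_defined, kurtosis_undefined.
#' @export
scalar_indices <- function(fit, n_mk = 256, n_rk = 64) {
  sc <- dti_scalars(fit$D)
  kurt_undef <- isTRUE(fit$diagnostics$kurtosis_undefined) || anyNA(fit$W)
  if (kurt_undef) {
    ks <- list(mk = NA_real_, ak = NA_real_, rk = NA_real_)
  } else {
    ks <- kurtosis_scalars(fit$D, fit$W, n_mk = n_mk, n_rk = n_rk)
  }
  tibble(fa = sc$fa, md = sc$md, ad = sc$ad, rd = sc$rd,
         mk = ks$mk, ak = ks$ak, rk = ks$rk,
         e1_defined = sc$e1_defined, kurtosis_undefined = kurt_undef)
}

#' Voxel-wise tensor fitting over a masked 4-D volume
#'
#' Fits the DKI model in every voxel of `mask` and assembles one 3-D map
#' per scalar index. Voxels whose fit fails (error, or undefined kurtosis)
#' carry NA in the affected maps and are marked in the flag map.
#'
#' @param image 4-D array (x, y, z, acquisition).
#' @param mask 3-D logical/0-1 array of voxels to fit.
#' @param scheme a [gradient_scheme()]; the number of acquisitions must
#'   equal `dim(image)[4]`.
#' @param ... passed to [fit_wlls()] and [scalar_indices()].
#' @return object of class `dki_maps`: list with `maps` (named list of 3-D
#'   arrays fa, md, ad, rd, mk, ak, rk), `flags` (3-D integer array: 0 ok,
#'   1 kurtosis undefined, 2 fit error, NA outside mask) and `n_fit`.
#' @export
fit_volume <- function(image, mask, scheme, ...) {
  di <- dim(image)
  if (length(di) != 4) abort("image must be a 4-D array")
  if (!identical(di[1:3], dim(mask)[1:3])) {
    abort(sprintf("image spatial dims (%s) do not match mask dims (%s)",
                  paste(di[1:3], collapse = "x"),
                  paste(dim(mask), collapse = "x")))
  }
  if (di[4] != n_acquisitions(scheme)) {
    abort(sprintf("image has %d volumes but scheme has %d acquisitions",
                  di[4], n_acquisitions(scheme)))
  }
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask is empty")

  index_names <- c("fa", "md", "ad", "rd", "mk", "ak", "rk")
  maps <- lapply(index_names, function(i) array(NA_real_, di[1:3]))
  names(maps) <- index_names
  flags <- array(NA_integer_, di[1:3])

  dots <- list(...)
  fit_args <- dots[intersect(names(dots), c("n_pass", "eps_frac"))]
  sc_args <- dots[intersect(names(dots), c("n_mk", "n_rk"))]

  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]; k <- idx[v, 3]
    sig <- image[i, j, k, ]
    res <- tryCatch({
      fit <- do.call(fit_wlls, c(list(signals = sig, scheme = scheme), fit_args))
      do.call(scalar_indices, c(list(fit = fit), sc_args))
    }, error = function(e) NULL)
    if (is.null(res)) {
      flags[i, j, k] <- 2L
      next
    }
    flags[i, j, k] <- if (res$kurtosis_undefined) 1L else 0L
    for (nm in index_names) maps[[nm]][i, j, k] <- res[[nm]]
  }
  structure(list(maps = maps, flags = flags, n_fit = nrow(idx)),
            class = "dki_maps")
}

#' @export
print.dki_maps <- function(x, ...) {
  cat("<dki_maps> ", x$n_fit, " fitted voxels; ",
      sum(x$flags > 0, na.rm = TRUE), " flagged\n", sep = "")
  invisible(x)
}
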