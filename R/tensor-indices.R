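# Unique-element conventions for the symmetric tensors.
#
# D (rank 2, symmetric): 6 unique elements, order xx, yy, zz, xy, xz, yz,
# multiplicities 1,1,1,2,2,2.
#
# W (rank 4, fully symmetric): 15 unique elements. Order and multinomial
# multiplicity 4!/(a! b! c!) for x-count a, y-count b, z-count c:
#   xxxx yyyy zzzz (1) | xxxy xxxz xyyy yyyz xzzz yzzz (4)
#   xxyy xxzz yyzz (6) | xxyz xyyz xyzz (12)
.W_POWERS <- rbind(
  c(4,0,0), c(0,4,0), c(0,0,4),
  c(3,1,0), c(3,0,1), c(1,3,0), c(0,3,1), c(1,0,3), c(0,1,3),
  c(2,2,0), c(2,0,2), c(0,2,2),
  c(2,1,1), c(1,2,1), c(1,1,2)
)
.W_MULT <- apply(.W_POWERS, 1, function(p) factorial(4) / prod(factorial(p)))
.W_NAMES <- apply(.W_POWERS, 1, function(p)
  paste0(strrep("x", p[1]), strrep("y", p[2]), strrep("z", p[3])))

.D_NAMES <- c("xx", "yy", "zz", "xy", "xz", "yz")
.D_MULT <- c(1, 1, 1, 2, 2, 2)

# D as symmetric 3x3 <-> 6-vector in .D_NAMES order
d6_to_matrix <- function(d6) {
  m <- matrix(0, 3, 3)
  m[1, 1] <- d6[1]; m[2, 2] <- d6[2]; m[3, 3] <- d6[3]
  m[1, 2] <- m[2, 1] <- d6[4]
  m[1, 3] <- m[3, 1] <- d6[5]
  m[2, 3] <- m[3, 2] <- d6[6]
  m
}

matrix_to_d6 <- function(D) {
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D)))) {
    abort("diffusion tensor must be symmetric")
  }
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

# monomials n_x^a n_y^b n_z^c for each of the 15 unique W patterns,
# for a matrix of direction rows
.w15_monomials <- function(dirs) {
  dirs <- rbind(dirs)
  sapply(seq_len(15), function(k) {
    p <- .W_POWERS[k, ]
    dirs[, 1]^p[1] * dirs[, 2]^p[2] * dirs[, 3]^p[3]
  })
}

# full contraction sum_ijkl n_i n_j n_k n_l W_ijkl via multiplicities
.w4_contract <- function(w15, dirs) {
  mono <- .w15_monomials(dirs)
  as.numeric(mono %*% (.W_MULT * w15))
}

# apparent diffusivity n' D n for direction rows
.d_app <- function(D, dirs) {
  dirs <- rbind(dirs)
  unname(rowSums((dirs %*% D) * dirs))
}

#' An isotropic kurtosis tensor
#'
#' Returns the 15 unique elements of the fully symmetric rank-4 tensor whose
#' apparent kurtosis equals `k0` along every direction when the diffusion
#' tensor is isotropic: W = k0/3 * (delta_ij delta_kl + delta_ik delta_jl +
#' delta_il delta_jk) symmetrized.
#'
#' @param k0 the direction-independent apparent kurtosis.
#' @return numeric vector of 15 unique W elements.
#' @export
isotropic_kurtosis <- function(k0) {
  w <- numeric(15)
  names(w) <- .W_NAMES
  w[c("xxxx", "yyyy", "zzzz")] <- k0
  w[c("xxyy", "xxzz", "yyzz")] <- k0 / 3
  w
}

#' Diffusion-tensor scalar indices
#'
#' Eigen-decomposes a symmetric diffusion tensor and returns the standard
#' DTI scalars. Eigenvalues are sorted descending (lambda1 >= lambda2 >=
#' lambda3), so AD = lambda1 and RD = (lambda2 + lambda3)/2 and AD >= RD by
#' construction; MD = (AD + 2 RD)/3 exactly.
#'
#' @param D symmetric 3x3 diffusion tensor (um^2/ms).
#' @return list with `fa`, `md`, `ad`, `rd`, the principal eigenvector `e1`
#'   (unit 3-vector), `e1_defined` (FALSE when lambda1 and lambda2 are
#'   degenerate to within 1e-9 * MD) and `zero_tensor` flag.
#' @examples
#' dti_scalars(diag(c(1.5, 0.5, 0.5)))$fa  # 0.603
#' @export
dti_scalars <- function(D) {
  ev <- eigen(D, symmetric = TRUE)
  lam <- ev$values                      # descending
  md <- mean(lam)
  ad <- lam[1]
  rd <- (lam[2] + lam[3]) / 2
  ss <- sum(lam^2)
  zero <- ss <= 0
  fa <- if (zero) 0 else sqrt(1.5 * sum((lam - md)^2) / ss)
  e1_defined <- !zero && (lam[1] - lam[2]) >= 1e-9 * abs(md)
  list(fa = fa, md = md, ad = ad, rd = rd,
       e1 = ev$vectors[, 1], e1_defined = e1_defined, zero_tensor = zero)
}

#' Fractional anisotropy of a cylindrically symmetric tensor from RD/AD
#'
#' For eigenvalues (AD, RD, RD) the fractional anisotropy depends only on
#' the ratio r = RD/AD:  FA = (1 - r) / sqrt(1 + 2 r^2).  The map is
#' strictly decreasing on [0, Inf): r = 0 (stick) gives FA = 1, r = 1
#' (isotropy) gives FA = 0, and r > 1 (oblate) gives a negative value,
#' returned as-is.
#'
#' @param ratio RD/AD, nonnegative; vectorized.
#' @return FA values (same length as `ratio`).
#' @examples
#' fa_from_ratio(0.40)  # 0.5222
#' @export
fa_from_ratio <- function(ratio) {
  if (any(ratio < 0)) abort("RD/AD ratio must be nonnegative")
  (1 - ratio) / sqrt(1 + 2 * ratio^2)
}

#' Apparent kurtosis along a direction
#'
#' K_app(n) = (MD^2 / D_app(n)^2) * sum_ijkl n_i n_j n_k n_l W_ijkl, the
#' directional kurtosis of the standard DKI signal representation. Even in
#' n, so K_app(n) = K_app(-n).
#'
#' @param D symmetric 3x3 diffusion tensor.
#' @param W 15 unique kurtosis-tensor elements (see [isotropic_kurtosis()]
#'   for the element order).
#' @param n unit direction 3-vector, or a matrix of direction rows.
#' @return apparent kurtosis value(s).
#' @export
apparent_kurtosis <- function(D, W, n) {
  n <- rbind(n)
  dapp <- .d_app(D, n)
  if (any(dapp <= 0)) {
    abort("apparent diffusivity is nonpositive along a requested direction (degenerate tensor)")
  }
  md <- mean(diag(D))
  unname((md^2 / dapp^2) * .w4_contract(W, n))
}

# deterministic near-uniform spherical design: Fibonacci lattice
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# orthonormal basis of the plane perpendicular to unit vector e1
.perp_basis <- function(e1) {
  a <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * e1) * e1
  u <- u / sqrt(sum(u^2))
  v <- c(e1[2] * u[3] - e1[3] * u[2],
         e1[3] * u[1] - e1[1] * u[3],
         e1[1] * u[2] - e1[2] * u[1])
  list(u = u, v = v)
}

#' Mean, axial and radial kurtosis
#'
#' Defined by numerical averaging of the apparent kurtosis: MK over a fixed
#' deterministic spherical design (`n_mk` Fibonacci-lattice directions), AK
#' along the principal diffusion eigenvector, RK over `n_rk` equally spaced
#' directions in the perpendicular plane. The circular RK average is exact
#' for the degree-4 integrand once `n_rk` >= 5, so enlarging `n_rk` does not
#' change RK beyond roundoff.
#'
#' @inheritParams apparent_kurtosis
#' @param n_mk number of spherical-design directions for MK (default 256).
#' @param n_rk number of in-plane directions for RK (default 64).
#' @return list with `mk`, `ak`, `rk` and `e1_defined` (when FALSE, AK/RK
#'   were computed with an arbitrary axis of the degenerate eigenspace).
#' @export
kurtosis_scalars <- function(D, W, n_mk = 256, n_rk = 64) {
  sc <- dti_scalars(D)
  e1 <- sc$e1
  mk <- mean(apparent_kurtosis(D, W, .fibonacci_sphere(n_mk)))
  ak <- as.numeric(apparent_kurtosis(D, W, e1))
  pb <- .perp_basis(e1)
  th <- 2 * pi * (seq_len(n_rk) - 1) / n_rk
  perp <- outer(cos(th), pb$u) + outer(sin(th), pb$v)
  rk <- mean(apparent_kurtosis(D, W, perp))
  list(mk = mk, ak = ak, rk = rk, e1_defined = sc$e1_defined)
}
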