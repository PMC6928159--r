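test_that("forward signal matches hand-evaluated attenuation", {
  ft <- tensor_fit(1, diag(c(1.5, 0.5, 0.5)))
  sch <- gradient_scheme(c(0, 2000, 2000),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  s <- predict_signal(ft, sch)
  expect_equal(s[1], 1)                    # b = 0 returns S0 exactly
  expect_equal(s[2], exp(-3))              # b = 2 ms/um^2 along x: exp(-2*1.5)
  expect_equal(s[3], exp(-1))              # along y: exp(-2*0.5)
})

test_that("isotropic tensor with isotropic kurtosis is direction independent", {
  d <- 0.9; k0 <- 0.7; b <- 2.5
  ft <- tensor_fit(1.3, d * diag(3), isotropic_kurtosis(k0))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  sch <- gradient_scheme(c(0, rep(1000 * b, 3)), rbind(c(0, 0, 0), dirs))
  s <- predict_signal(ft, sch)[2:4]
  expected <- 1.3 * exp(-b * d + b^2 * d^2 * k0 / 6)
  expect_equal(s, rep(expected, 3), tolerance = 1e-14)
})

test_that("design matrix rows implement the linearized model", {
  sch <- gradient_scheme(c(0, 2000), rbind(c(0, 0, 0), c(1, 0, 0)))
  X <- build_design_matrix(sch)
  expect_equal(dim(X), c(2L, 22L))
  expect_equal(X[1, ], c(1, rep(0, 21)), ignore_attr = TRUE)
  # b = 2 ms/um^2 along x: only the Dxx column carries -b, only Wxxxx +b^2/6
  expect_equal(unname(X[2, "D.xx"]), -2)
  expect_equal(unname(X[2, setdiff(paste0("D.", c("yy", "zz", "xy", "xz", "yz")),
                                   character(0))]),
               rep(0, 5))
  expect_equal(unname(X[2, "W.xxxx"]), 4 / 6)
  expect_equal(sum(abs(X[2, 9:22])), 0)
})

test_that("two-shell 41-acquisition design has full column rank", {
  X <- build_design_matrix(protocol_scheme())
  expect_equal(qr(X)$rank, 22)
})

test_that("WLLS recovers random ground-truth tensors from noise-free signals", {
  sch <- protocol_scheme()
  set.seed(101)
  for (i in 1:10) {
    truth <- rand_truth()
    fit <- fit_wlls(predict_signal(truth, sch), sch)
    expect_lt(max(abs(fit$D - truth$D)), 1e-8)
    expect_lt(max(abs(fit$W - truth$W)), 1e-6)
    expect_equal(fit$s0, truth$s0, tolerance = 1e-8)
  }
})

test_that("constant signals give a zero tensor with kurtosis flagged undefined", {
  sch <- protocol_scheme()
  fit <- fit_wlls(rep(2, n_acquisitions(sch)), sch)
  expect_lt(max(abs(fit$D)), 1e-10)
  expect_true(fit$diagnostics$kurtosis_undefined)
  expect_true(all(is.na(fit$W)))
})

test_that("WLLS pass count is irrelevant when weights are constant", {
  # constant predicted signals make every weight equal, so the reweighted
  # pass must reproduce plain OLS
  sch <- protocol_scheme()
  sig <- rep(1.7, n_acquisitions(sch))
  f1 <- fit_wlls(sig, sch, n_pass = 1)
  f2 <- fit_wlls(sig, sch, n_pass = 2)
  expect_equal(f1$D, f2$D, tolerance = 1e-12)
  expect_equal(f1$s0, f2$s0, tolerance = 1e-12)
})

test_that("rank-deficient and undersized designs are refused", {
  sch1 <- make_gradient_scheme(20, 2000, n_b0 = 2, seed = 1)  # one shell
  sig <- rep(1, n_acquisitions(sch1))
  expect_error(fit_wlls(sig, sch1), "rank deficient")
  sch2 <- make_gradient_scheme(8, c(2000, 4000), n_b0 = 1, seed = 1)
  expect_error(fit_wlls(rep(1, 17), sch2), "22")
})

test_that("nonpositive signals are clamped and flagged, not fatal", {
  sch <- protocol_scheme()
  truth <- tensor_fit(1, diag(c(1.5, 0.5, 0.5)))
  sig <- predict_signal(truth, sch)
  sig[5] <- 0
  fit <- fit_wlls(sig, sch)
  expect_equal(fit$diagnostics$clamped_signals, 1)
})

test_that("Monte-Carlo FA error at SNR 30 stays small", {
  sch <- protocol_scheme()
  truth <- tensor_fit(1, diag(c(1.5, 0.5, 0.5)), isotropic_kurtosis(0.6))
  truth_fa <- dti_scalars(truth$D)$fa
  set.seed(55)
  err <- replicate(500, {
    sig <- simulate_voxel_signal(truth, sch, snr = 30)
    abs(dti_scalars(fit_wlls(sig, sch)$D)$fa - truth_fa)
  })
  expect_lt(median(err), 0.05)
})

test_that("DTI scalars match the closed-form prolate case", {
  sc <- dti_scalars(diag(c(1.5, 0.5, 0.5)))
  expect_equal(sc$ad, 1.5)
  expect_equal(sc$rd, 0.5)
  expect_equal(sc$md, (1.5 + 0.5 + 0.5) / 3)
  lam <- c(1.5, 0.5, 0.5); md <- mean(lam)
  expect_equal(sc$fa, sqrt(1.5 * sum((lam - md)^2) / sum(lam^2)))
  expect_equal(dti_scalars(0.8 * diag(3))$fa, 0)
  expect_equal(dti_scalars(0.8 * diag(3))$md, 0.8)
  expect_equal(dti_scalars(diag(c(1, 0, 0)))$fa, 1)
  zero <- dti_scalars(matrix(0, 3, 3))
  expect_equal(zero$fa, 0)
  expect_true(zero$zero_tensor)
})

test_that("MD identity and AD >= RD hold on random tensors", {
  set.seed(7)
  for (i in 1:50) {
    sc <- dti_scalars(rand_truth()$D)
    expect_equal(sc$md, (sc$ad + 2 * sc$rd) / 3, tolerance = 1e-12)
    expect_gte(sc$ad, sc$rd)
    expect_true(sc$fa >= 0 && sc$fa <= 1)
  }
})

test_that("FA from the RD/AD ratio has the stated limits and monotonicity", {
  expect_equal(fa_from_ratio(0), 1)
  expect_equal(fa_from_ratio(1), 0)
  g <- fa_from_ratio(seq(0, 2, by = 0.01))
  expect_true(all(diff(g) < 0))
  expect_lt(fa_from_ratio(1.5), 0)   # oblate ratios yield negative values
  expect_error(fa_from_ratio(-0.1), "nonnegative")
})

test_that("cylindrically symmetric eigen-FA equals the ratio formula", {
  for (r in seq(0, 1, by = 0.05)) {
    D <- diag(c(1.2, 1.2 * r, 1.2 * r))
    expect_equal(dti_scalars(D)$fa, fa_from_ratio(r), tolerance = 1e-12)
  }
})

test_that("apparent kurtosis is even in n and isotropy-consistent", {
  expect_equal(apparent_kurtosis(diag(3) * 0.8, isotropic_kurtosis(1),
                                 c(0.6, -0.64, 0.48)), 1, tolerance = 1e-12)
  expect_equal(apparent_kurtosis(diag(c(1.5, 0.5, 0.5)), numeric(15),
                                 c(1, 0, 0)), 0)
  set.seed(12)
  truth <- rand_truth()
  n <- rnorm(3); n <- n / sqrt(sum(n^2))
  expect_equal(apparent_kurtosis(truth$D, truth$W, n),
               apparent_kurtosis(truth$D, truth$W, -n), tolerance = 1e-14)
})

test_that("kurtosis scalars reduce correctly and RK quadrature is exact", {
  ks <- kurtosis_scalars(diag(3) * 1.1, isotropic_kurtosis(0.8))
  expect_equal(c(ks$mk, ks$ak, ks$rk), rep(0.8, 3), tolerance = 1e-10)
  expect_false(ks$e1_defined)
  ks0 <- kurtosis_scalars(diag(c(1.5, 0.6, 0.5)), numeric(15))
  expect_equal(c(ks0$mk, ks0$ak, ks0$rk), c(0, 0, 0))
  set.seed(21)
  truth <- rand_truth()
  rk_64 <- kurtosis_scalars(truth$D, truth$W, n_rk = 64)$rk
  rk_4096 <- kurtosis_scalars(truth$D, truth$W, n_rk = 4096)$rk
  expect_lt(abs(rk_64 - rk_4096), 1e-10)
})

test_that("signal model is covariant under b rescaling", {
  sch <- protocol_scheme()
  set.seed(31)
  truth <- rand_truth()
  c_scale <- 2.5
  sch2 <- gradient_scheme(sch$bvalues * c_scale, sch$directions)
  truth2 <- tensor_fit(truth$s0, truth$D / c_scale, truth$W)
  expect_equal(predict_signal(truth, sch), predict_signal(truth2, sch2),
               tolerance = 1e-12)
})

test_that("volume fitting reproduces a noise-free phantom slice by slice", {
  sch <- protocol_scheme()
  truths <- list(tensor_fit(1, diag(c(1.5, 0.5, 0.5)), isotropic_kurtosis(0.5)),
                 tensor_fit(1, diag(c(1.0, 0.7, 0.7)), isotropic_kurtosis(0.9)))
  vol <- simulate_nerve_volume(truths, radius = 1.6, matrix_size = 5,
                               scheme = sch, injury_start = 0, injury_end = 0,
                               snr = NULL, seed = 1)
  maps <- fit_volume(vol$image, vol$mask, sch)
  for (z in 1:2) {
    truth_fa <- dti_scalars(truths[[z]]$D)$fa
    vals <- maps$maps$fa[, , z][vol$mask[, , z] > 0]
    expect_equal(vals, rep(truth_fa, length(vals)), tolerance = 1e-8)
  }
  # conservation: every masked voxel is either finite or flagged
  n_masked <- sum(vol$mask > 0)
  n_finite <- sum(is.finite(maps$maps$fa[vol$mask > 0]))
  n_flagged <- sum(maps$flags[vol$mask > 0] > 0)
  expect_equal(n_finite + sum(maps$flags[vol$mask > 0] == 2), n_masked)
  expect_equal(maps$n_fit, n_masked)
})

test_that("volume fitting validates shapes and masks", {
  sch <- protocol_scheme()
  img <- array(1, c(4, 4, 2, n_acquisitions(sch)))
  expect_error(fit_volume(img, array(0, c(4, 4, 2)), sch), "empty")
  expect_error(fit_volume(img, array(1, c(3, 4, 2)), sch), "4x4x2")
  expect_error(fit_volume(array(1, c(4, 4, 2, 10)), array(1, c(4, 4, 2)), sch),
               "10")
})
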