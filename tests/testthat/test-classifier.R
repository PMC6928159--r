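test_that("two-point geometry gives the perpendicular bisector", {
  pts <- tibble::tibble(ad = c(1.5, 1.5, 1.499, 1.501),
                        rd = c(0.3, 0.5, 0.3, 0.5),
                        recovered = c(TRUE, FALSE, TRUE, FALSE))
  b <- fit_boundary(pts)
  expect_equal(b$slope * 1.5 + b$intercept, 0.4, tolerance = 1e-3)
  expect_lt(abs(b$slope), 0.05)
  expect_equal(b$training_accuracy, 1)
})

test_that("single-class input cannot define a boundary", {
  pts <- tibble::tibble(ad = c(1, 2, 3), rd = c(0.2, 0.3, 0.4),
                        recovered = c(TRUE, TRUE, TRUE))
  expect_error(fit_boundary(pts), "cannot define boundary")
  expect_error(fit_boundary(tibble::tibble(ad = 1, rd = 1)), "columns")
})

test_that("slope/intercept are consistent with the weight vector and side labels", {
  pts <- simulate_boundary_points(25, seed = 4)
  b <- fit_boundary(pts)
  expect_equal(b$slope, -b$w["ad"] / b$w["rd"], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(b$intercept, -b$offset / b$w["rd"], tolerance = 1e-12,
               ignore_attr = TRUE)
  # geometric side test: positive decision value iff below the line
  f <- decision_values(b, pts)
  below <- pts$rd < b$slope * pts$ad + b$intercept
  expect_equal(f > 0, below)
  # recovered points are the ones below the line
  expect_equal(below, pts$recovered)
})

test_that("separable training data are classified perfectly at the max margin", {
  pts <- simulate_boundary_points(20, margin = 0.1, symmetric = TRUE, seed = 3)
  b <- fit_boundary(pts)
  expect_equal(b$training_accuracy, 1)
  oracle <- max_margin_oracle(pts$ad, pts$rd, pts$recovered)
  expect_gte(b$margin, (1 - 1e-3) * oracle$margin)
})

test_that("bootstrap is deterministic, stratified and tight on well-separated clusters", {
  pts <- simulate_boundary_points(25, margin = 0.15, clearance_sd = 0.02,
                                  symmetric = TRUE, seed = 6)
  bs1 <- bootstrap_boundary(pts, n_boot = 200, seed = 9)
  bs2 <- bootstrap_boundary(pts, n_boot = 200, seed = 9)
  expect_identical(bs1$slope_sd, bs2$slope_sd)
  expect_identical(bs1$samples, bs2$samples)
  expect_lt(bs1$slope_sd, 0.05)
  expect_equal(bs1$n_failed, 0)          # stratification keeps both classes
  expect_error(bootstrap_boundary(pts, n_boot = 1), "at least 2")
})

test_that("Platt calibration matches closed-form symmetric solutions", {
  f <- c(rep(-1, 10), rep(1, 10))
  y <- rep(c(FALSE, TRUE), each = 10)
  pm <- fit_platt(f, y)
  expect_equal(pm$B, 0, tolerance = 1e-6)
  expect_equal(predict(pm, 0), 0.5, tolerance = 1e-6)
  # at the positive margin the probability equals the smoothed target 11/12
  expect_equal(predict(pm, 1), 11 / 12, tolerance = 1e-3)
  expect_lt(pm$A, 0)
  # sigmoid limits
  expect_equal(predict(pm, 1e6), 1)
  expect_equal(predict(pm, -1e6), 0, tolerance = 1e-12)
  expect_error(fit_platt(f, rep(TRUE, 20)), "both classes")
})

test_that("Platt parameters agree with a brute-force likelihood grid search", {
  set.seed(14)
  f <- c(rnorm(15, -1.2, 0.7), rnorm(15, 1.0, 0.7))
  y <- rep(c(FALSE, TRUE), each = 15)
  pm <- fit_platt(f, y)
  oracle <- platt_grid_oracle(f, y)
  expect_equal(pm$A, unname(oracle["A"]), tolerance = 1e-3)
  expect_equal(pm$B, unname(oracle["B"]), tolerance = 1e-3)
})

test_that("recovery probabilities are monotone along a crossing ray", {
  pts <- simulate_boundary_points(20, seed = 2)
  b <- fit_boundary(pts)
  pm <- fit_platt(decision_values(b, pts), pts$recovered)
  ray <- tibble::tibble(ad = rep(1.4, 41),
                        rd = seq(0.2, 0.9, length.out = 41))
  out <- recovery_probability(ray, b, pm)
  expect_true(all(diff(out$probability) < 0))  # RD up = away from recovery
  expect_true(all(out$probability > 0 & out$probability < 1))
  expect_error(recovery_probability(tibble::tibble(ad = 1, rd = NA_real_), b, pm),
               "finite")
})

test_that("a record on the boundary of balanced training gets probability 0.5", {
  pts <- simulate_boundary_points(15, symmetric = TRUE, seed = 8)
  b <- fit_boundary(pts)
  # balanced, exactly sign-symmetric decision values: the calibrated sigmoid
  # must be centered, so a record on the line scores probability one half
  d <- abs(decision_values(b, pts[pts$recovered, ]))
  pm <- fit_platt(c(d, -d), rep(c(TRUE, FALSE), each = length(d)))
  on_line <- tibble::tibble(ad = 1.35, rd = b$slope * 1.35 + b$intercept)
  out <- recovery_probability(on_line, b, pm)
  expect_equal(out$decision, 0, tolerance = 1e-12)
  expect_equal(out$probability, 0.5, tolerance = 1e-6)
})

test_that("FA threshold conversion uses the slope only and flags the intercept", {
  pts <- simulate_boundary_points(25, symmetric = TRUE, seed = 5)
  b <- fit_boundary(pts)
  bs <- bootstrap_boundary(pts, n_boot = 100, seed = 5)
  fa <- fa_threshold(b, bs)
  expect_equal(fa$threshold, fa_from_ratio(b$slope))
  expect_equal(fa$ignored_intercept, b$intercept)
  expect_true(is.finite(fa$sd) && fa$sd > 0)
  # invariance under positive rescaling of (w, offset)
  b2 <- b; b2$w <- 10 * b$w; b2$offset <- 10 * b$offset
  b2$slope <- -b2$w["ad"] / b2$w["rd"]
  expect_equal(fa_threshold(b2)$threshold, fa$threshold, ignore_attr = TRUE)
  b_neg <- b; b_neg$slope <- -0.2
  expect_error(fa_threshold(b_neg), "negative")
})

test_that("classify_study separates week-4 cohorts and summarizes per nerve", {
  st <- simulate_study(study_config(seed = 1))
  model <- suppressMessages(
    train_recovery_model(st$slices, n_boot = 100, seed = 1))
  kept <- suppressMessages(filter_outliers(st$slices))$kept
  cl <- classify_study(kept, model$boundary, model$platt)
  w4 <- dplyr::filter(cl$assessments, week == 4, region == "distal")
  expect_true(all(w4$probability[w4$cohort == "crush"] > 0.5))
  expect_true(all(w4$probability[w4$cohort == "cut_repair"] < 0.5))
  # week-12 cut_repair nerves split into both calls (half assigned recovered)
  n12 <- dplyr::filter(cl$nerves, week == 12, cohort == "cut_repair")
  expect_setequal(unique(n12$call), c("recovered", "non_recovered"))
  calls <- n12$call[match(st$truth$animal[st$truth$cohort == "cut_repair" &
                                            st$truth$week == 12], n12$animal)]
  truth12 <- st$truth$recovered[st$truth$cohort == "cut_repair" & st$truth$week == 12]
  expect_equal(calls == "recovered", truth12)
  # empty input passes through
  empty <- classify_study(kept[0, ], model$boundary, model$platt)
  expect_equal(nrow(empty$assessments), 0)
  # a nerve with only proximal records is not assessable
  prox_only <- dplyr::filter(kept, animal == kept$animal[1], region == "proximal")
  cl2 <- classify_study(prox_only, model$boundary, model$platt)
  expect_false(cl2$nerves$assessable[1])
  expect_true(is.na(cl2$nerves$call[1]))
})

test_that("predicted probabilities are calibrated on held-out data", {
  # noisy, overlapping clusters; train on half, bin the other half
  set.seed(33)
  n <- 1000
  ad <- rnorm(n, 1.35, 0.15)
  offset <- rnorm(n, 0, 0.15)
  truth_line <- 0.40 * ad - 0.03
  recovered <- offset < 0
  pts <- tibble::tibble(ad = ad, rd = truth_line + offset, recovered = recovered)
  train <- pts[1:500, ]; test <- pts[501:1000, ]
  b <- fit_boundary(train)
  pm <- fit_platt(decision_values(b, train), train$recovered)
  out <- recovery_probability(test, b, pm)
  bins <- cut(out$probability, breaks = seq(0, 1, by = 0.2), include.lowest = TRUE)
  emp <- tapply(test$recovered, bins, mean)
  emp <- emp[!is.na(emp)]
  expect_true(all(diff(emp) >= 0))
})

test_that("tidy and glance expose the boundary in broom form", {
  st <- simulate_study(study_config(seed = 2))
  model <- suppressMessages(train_recovery_model(st$slices, n_boot = 50, seed = 2))
  td <- tidy(model)
  expect_equal(td$term, c("slope", "intercept", "fa_threshold"))
  expect_true(all(is.finite(td$estimate)))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(model)
  expect_equal(gl$training_accuracy, 1)
  expect_s3_class(autoplot(model$boundary), "ggplot")
  expect_s3_class(autoplot(st), "ggplot")
})
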