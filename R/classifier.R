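#' Fit the linear recovery boundary in the RD-vs-AD plane
#'
#' Trains a linear soft-margin support-vector machine on per-slice (AD, RD)
#' means with a recovered / non-recovered label and reports the decision
#' boundary as a line `RD = slope * AD + intercept` in physical units
#' (um^2/ms): features are not standardized, and a large cost parameter
#' (default C = 100) approximates the hard-margin separator appropriate for
#' linearly separable clusters. The underlying weight vector is sign-fixed
#' so a positive decision value means the recovered side; equivalently,
#' records with `RD < slope * AD + intercept` are on the recovered side.
#'
#' @param data tibble with numeric columns `ad`, `rd` and logical
#'   `recovered`.
#' @param cost SVM cost parameter C.
#' @return object of class `recovery_boundary`: `slope`, `intercept`,
#'   weight vector `w` (named ad/rd), `offset`, `cost`, `n`,
#'   `training_accuracy`, `margin` (geometric margin over correctly
#'   classified training points), and the training `data`.
#' @export
fit_boundary <- function(data, cost = 100) {
  req <- c("ad", "rd", "recovered")
  if (!all(req %in% names(data))) {
    abort(sprintf("data must have columns: %s", paste(req, collapse = ", ")))
  }
  y <- as.logical(data$recovered)
  if (length(unique(y)) < 2) {
    abort("cannot define boundary: both recovered and non-recovered points are required")
  }
  if (sum(y) < 2 || sum(!y) < 2) {
    abort("need at least 2 points per class")
  }
  X <- cbind(ad = data$ad, rd = data$rd)
  fit <- e1071::svm(X, factor(y, levels = c(FALSE, TRUE)),
                    type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  names(w) <- c("ad", "rd")
  offset <- -fit$rho
  f <- as.numeric(X %*% w) + offset
  # fix sign: positive decision value = recovered side
  if (mean(f[y]) < mean(f[!y])) {
    w <- -w; offset <- -offset; f <- -f
  }
  if (abs(w["rd"]) < 1e-12) {
    abort("degenerate boundary: vertical in the RD-vs-AD plane (w_rd = 0)")
  }
  correct <- (f > 0) == y
  margin <- min(abs(f[correct])) / sqrt(sum(w^2))
  structure(
    list(slope = unname(-w["ad"] / w["rd"]),
         intercept = unname(-offset / w["rd"]),
         w = w, offset = offset, cost = cost, n = nrow(data),
         training_accuracy = mean(correct), margin = margin,
         data = tibble(ad = data$ad, rd = data$rd, recovered = y)),
    class = "recovery_boundary")
}

#' @export
print.recovery_boundary <- function(x, ...) {
  cat(sprintf("<recovery_boundary> RD = %.4f * AD + %.4f\n", x$slope, x$intercept))
  cat(sprintf("  n = %d, C = %g, training accuracy %.1f%%, margin %.4f\n",
              x$n, x$cost, 100 * x$training_accuracy, x$margin))
  if (!is.null(x$slope_sd)) {
    cat(sprintf("  bootstrap SD: slope %.4f, intercept %.4f (n_boot = %d)\n",
                x$slope_sd, x$intercept_sd, x$n_boot))
  }
  invisible(x)
}

#' Signed decision values of a boundary
#'
#' @param boundary a [fit_boundary()] result.
#' @param data tibble with `ad`, `rd`.
#' @return numeric decision values; positive = recovered side.
#' @export
decision_values <- function(boundary, data) {
  if (!all(c("ad", "rd") %in% names(data))) abort("data must have 'ad' and 'rd' columns")
  if (any(!is.finite(data$ad)) || any(!is.finite(data$rd))) {
    abort("ad/rd must be finite to compute decision values")
  }
  as.numeric(cbind(data$ad, data$rd) %*% boundary$w) + boundary$offset
}

#' Bootstrap uncertainty of the recovery boundary
#'
#' Resamples the training records with replacement, stratified within each
#' class (so every resample retains both classes), refits the SVM, and
#' returns the standard deviations of the slope and intercept over the
#' resampled fits together with the bootstrap sample table.
#'
#' @param data training tibble as for [fit_boundary()].
#' @param n_boot number of bootstrap resamples (>= 2; default 1000).
#' @param seed integer seed.
#' @param cost SVM cost parameter.
#' @return list with `slope_sd`, `intercept_sd`, `samples` (tibble of
#'   per-resample slope/intercept), `n_boot`, `n_failed`.
#' @export
bootstrap_boundary <- function(data, n_boot = 1000, seed = 1, cost = 100) {
  if (n_boot < 2) abort("n_boot must be at least 2")
  y <- as.logical(data$recovered)
  idx_pos <- which(y); idx_neg <- which(!y)
  set.seed(seed)
  slopes <- rep(NA_real_, n_boot); intercepts <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    take <- c(sample(idx_pos, length(idx_pos), replace = TRUE),
              sample(idx_neg, length(idx_neg), replace = TRUE))
    bfit <- tryCatch(fit_boundary(data[take, , drop = FALSE], cost = cost),
                     error = function(e) NULL)
    if (!is.null(bfit)) {
      slopes[b] <- bfit$slope; intercepts[b] <- bfit$intercept
    }
  }
  ok <- is.finite(slopes)
  list(slope_sd = sd(slopes[ok]), intercept_sd = sd(intercepts[ok]),
       samples = tibble(slope = slopes[ok], intercept = intercepts[ok]),
       n_boot = n_boot, n_failed = sum(!ok))
}

#' Convert the boundary slope to a fractional-anisotropy threshold
#'
#' Under the cylindrically symmetric tensor assumption a zero-offset linear
#' RD/AD boundary corresponds to a unique FA threshold,
#' FA = (1 - slope) / sqrt(1 + 2 slope^2). The fitted intercept is ignored
#' by design (the zero-offset assumption); it is reported back so the
#' approximation can be judged. The threshold SD is propagated as the SD of
#' the converted bootstrap slopes.
#'
#' @param boundary a [fit_boundary()] result with nonnegative slope.
#' @param bootstrap optional [bootstrap_boundary()] result for SD
#'   propagation.
#' @return list with `threshold`, `sd` (NA without bootstrap samples),
#'   `slope`, `ignored_intercept`.
#' @export
fa_threshold <- function(boundary, bootstrap = NULL) {
  if (boundary$slope < 0) {
    abort(sprintf("boundary slope %.3f is negative; the FA conversion requires RD/AD >= 0",
                  boundary$slope))
  }
  thr_sd <- NA_real_
  if (!is.null(bootstrap)) {
    sl <- bootstrap$samples$slope
    neg <- sl < 0
    if (any(neg)) {
      warn(sprintf("dropping %d bootstrap slopes < 0 from FA threshold SD", sum(neg)))
      sl <- sl[!neg]
    }
    thr_sd <- sd(fa_from_ratio(sl))
  }
  list(threshold = fa_from_ratio(boundary$slope), sd = thr_sd,
       slope = boundary$slope, ignored_intercept = boundary$intercept)
}

#' Recovery probability of slice records
#'
#' Computes each record's signed decision value under the boundary, its
#' Platt-calibrated probability of recovery, and the side label
#' (`recovered` iff f > 0; records exactly on the boundary are labeled by
#' probability >= 0.5).
#'
#' @param records tibble with finite `ad`, `rd` (and any metadata columns,
#'   which are carried through).
#' @param boundary a [fit_boundary()] result.
#' @param platt a [fit_platt()] result.
#' @return the input tibble with added columns `decision`, `probability`,
#'   `side`.
#' @export
recovery_probability <- function(records, boundary, platt) {
  f <- decision_values(boundary, records)
  p <- predict(platt, f)
  dplyr::mutate(records, decision = f, probability = p,
                side = ifelse(f > 0 | (f == 0 & p >= 0.5),
                              "recovered", "non_recovered"))
}

#' Assess every slice record and summarize per nerve
#'
#' Applies [recovery_probability()] to all records, then reduces the distal
#' records of each nerve (animal) to a per-nerve summary: the mean recovery
#' probability over its distal slices, the fraction of distal slices on the
#' recovered side, and a nerve-level call (`recovered` iff mean probability
#' exceeds `call_threshold`). Nerves with no distal records are retained
#' with `assessable = FALSE` and an NA call.
#'
#' @inheritParams recovery_probability
#' @param call_threshold mean-probability cutoff for the nerve-level call.
#' @return list with `assessments` (per-record) and `nerves` (per-animal
#'   summary: `animal`, `cohort`, `week`, `n_distal`, `mean_probability`,
#'   `fraction_recovered_side`, `assessable`, `call`).
#' @export
classify_study <- function(records, boundary, platt, call_threshold = 0.5) {
  if (nrow(records) == 0) {
    return(list(assessments = records,
                nerves = tibble(animal = character(), cohort = character(),
                                week = numeric(), n_distal = integer(),
                                mean_probability = numeric(),
                                fraction_recovered_side = numeric(),
                                assessable = logical(), call = character())))
  }
  assessments <- recovery_probability(records, boundary, platt)
  nerves <- assessments |>
    dplyr::group_by(.data$animal, .data$cohort, .data$week) |>
    dplyr::summarise(
      n_distal = sum(.data$region == "distal"),
      mean_probability = ifelse(n_distal > 0,
                                mean(.data$probability[.data$region == "distal"]),
                                NA_real_),
      fraction_recovered_side = ifelse(n_distal > 0,
                                       mean(.data$side[.data$region == "distal"] == "recovered"),
                                       NA_real_),
      .groups = "drop") |>
    dplyr::mutate(
      assessable = .data$n_distal > 0,
      call = dplyr::case_when(
        !.data$assessable ~ NA_character_,
        .data$mean_probability > call_threshold ~ "recovered",
        TRUE ~ "non_recovered"))
  list(assessments = assessments, nerves = nerves)
}

#' Train the full recovery model from a slice-record table
#'
#' The end-to-end training rule: take the distal week-4 records of the
#' crush (label: recovered) and cut_repair (label: non-recovered) cohorts,
#' apply the outlier filter, fit the SVM boundary, bootstrap its
#' uncertainty, calibrate Platt probabilities on the training decision
#' values, and convert the slope to an FA threshold.
#'
#' @param records slice-record tibble (e.g. `simulate_study(...)$slices`).
#' @param cost SVM cost parameter C.
#' @param n_boot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @param filter_training apply the outlier rules to the training set.
#' @param training_week endpoint week whose distal records form the
#'   training set.
#' @return object of class `recovery_model`: `boundary` (with bootstrap
#'   SDs attached), `platt`, `fa` (from [fa_threshold()]), `bootstrap`,
#'   `n_training`, `n_excluded`.
#' @export
train_recovery_model <- function(records, cost = 100, n_boot = 1000, seed = 1,
                                 filter_training = TRUE, training_week = 4) {
  train <- dplyr::filter(records, .data$week == training_week,
                         .data$region == "distal",
                         .data$cohort %in% c("crush", "cut_repair"))
  n_excluded <- 0L
  if (filter_training && all(c("rd", "rk") %in% names(train))) {
    fl <- filter_outliers(train)
    n_excluded <- nrow(fl$excluded)
    train <- fl$kept
  }
  train <- dplyr::mutate(train, recovered = .data$cohort == "crush")
  boundary <- fit_boundary(train, cost = cost)
  boot <- bootstrap_boundary(train, n_boot = n_boot, seed = seed, cost = cost)
  boundary$slope_sd <- boot$slope_sd
  boundary$intercept_sd <- boot$intercept_sd
  boundary$n_boot <- boot$n_boot
  platt <- fit_platt(decision_values(boundary, train), train$recovered)
  structure(
    list(boundary = boundary, platt = platt,
         fa = fa_threshold(boundary, boot), bootstrap = boot,
         n_training = nrow(train), n_excluded = n_excluded),
    class = "recovery_model")
}

#' @export
print.recovery_model <- function(x, ...) {
  b <- x$boundary
  cat(sprintf("<recovery_model> boundary RD = %.3f (+/- %.3f) * AD + %.3f (+/- %.3f)\n",
              b$slope, b$slope_sd %||% NA, b$intercept, b$intercept_sd %||% NA))
  cat(sprintf("  FA threshold %.4f +/- %.4f (intercept %.3f ignored by the zero-offset assumption)\n",
              x$fa$threshold, x$fa$sd, x$fa$ignored_intercept))
  cat(sprintf("  trained on %d distal week-4 slice records (%d excluded as outliers)\n",
              x$n_training, x$n_excluded))
  invisible(x)
}
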