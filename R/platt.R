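#' Platt sigmoid calibration with smoothed targets
#'
#' Fits the sigmoid P(recovered | f) = 1 / (1 + exp(A f + B)) to classifier
#' decision values by maximizing the regularized Platt likelihood with
#' smoothed targets t+ = (N+ + 1)/(N+ + 2) for the positive class and
#' t- = 1/(N- + 2) for the negative class, via Newton iteration with
#' backtracking line search. The target smoothing keeps the problem
#' well-posed even when the classes are fully separable in `f` -- the
#' situation in which plain logistic regression degenerates.
#'
#' @param decision_values numeric vector of signed decision values (positive
#'   = recovered side).
#' @param recovered logical vector, `TRUE` for the recovered class.
#' @param max_iter maximum Newton iterations.
#' @param tol gradient infinity-norm convergence tolerance.
#' @return object of class `platt_model` with elements `A`, `B` (A < 0 on
#'   any data where larger f means more likely recovered), `n_pos`,
#'   `n_neg`, `n_iter`, `converged`.
#' @examples
#' pm <- fit_platt(c(-1, -1, 1, 1), c(FALSE, FALSE, TRUE, TRUE))
#' predict(pm, 0)  # 0.5 by symmetry
#' @export
fit_platt <- function(decision_values, recovered, max_iter = 100, tol = 1e-5) {
  f <- as.numeric(decision_values)
  y <- as.logical(recovered)
  if (length(f) != length(y)) abort("decision values and labels differ in length")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to calibrate probabilities")
  }
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y, hi, lo)

  obj <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  fval <- obj(A, B)
  sigma <- 1e-12  # Hessian ridge
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- p * q
    h11 <- sum(f * f * d1) + sigma
    h22 <- sum(d1) + sigma
    h21 <- sum(f * d1)
    d2 <- t - p
    g1 <- sum(f * d2)
    g2 <- sum(d2)
    if (max(abs(g1), abs(g2)) < tol) { converged <- TRUE; break }
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    ok <- FALSE
    while (step >= 1e-10) {
      newA <- A + step * dA; newB <- B + step * dB
      newf <- obj(newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf; ok <- TRUE; break
      }
      step <- step / 2
    }
    if (!ok) break  # line search failed; gradient is effectively flat
  }
  if (!converged && it >= max_iter) {
    abort(sprintf(
      "Platt calibration did not converge after %d iterations (|grad| = %.2e, A = %.3g, B = %.3g)",
      max_iter, max(abs(g1), abs(g2)), A, B))
  }
  structure(list(A = A, B = B, n_pos = n_pos, n_neg = n_neg,
                 n_iter = it, converged = converged),
            class = "platt_model")
}

#' @export
print.platt_model <- function(x, ...) {
  cat(sprintf("<platt_model> P(recovered|f) = 1/(1 + exp(%.4g f + %.4g))\n",
              x$A, x$B))
  cat(sprintf("  fitted on %d recovered / %d non-recovered; %d Newton steps\n",
              x$n_pos, x$n_neg, x$n_iter))
  invisible(x)
}

#' @param object a `platt_model`.
#' @param newdata decision values to calibrate.
#' @param ... unused.
#' @rdname fit_platt
#' @export
predict.platt_model <- function(object, newdata, ...) {
  fApB <- object$A * newdata + object$B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}
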