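# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the max-margin oracle enumerates support sets instead of
# solving the SVM dual, the BH oracle applies the step-up definition
# literally, and the Platt oracle is a refined grid search on the likelihood.

# 2-D hard-margin separator by support-set enumeration: the optimum is
# determined by either a cross-class pair (perpendicular bisector) or two
# same-class points plus one opposite point (midline).
max_margin_oracle <- function(ad, rd, y) {
  X <- cbind(ad, rd)
  pos <- which(y); neg <- which(!y)
  best <- list(margin = -Inf)
  eval_cand <- function(w, b) {
    nw <- sqrt(sum(w^2)); if (nw < 1e-12) return(invisible())
    f <- (X %*% w + b) / nw
    for (sgn in c(1, -1)) {
      fs <- sgn * f
      if (all(fs[pos] > 0) && all(fs[neg] < 0)) {
        m <- min(abs(fs))
        if (m > best$margin) best <<- list(margin = m, w = sgn * w / nw, b = sgn * b / nw)
      }
    }
  }
  for (i in pos) for (j in neg) {
    w <- X[i, ] - X[j, ]; mid <- (X[i, ] + X[j, ]) / 2
    eval_cand(w, -sum(w * mid))
  }
  n <- nrow(X)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (y[i] != y[j]) next
    d <- X[j, ] - X[i, ]
    w <- c(-d[2], d[1])
    opp <- if (y[i]) neg else pos
    for (k in opp) {
      mid <- (X[i, ] + X[k, ]) / 2
      eval_cand(w, -sum(w * mid))
    }
  }
  best
}

# literal Benjamini-Hochberg step-up: sort ascending, take running minima of
# p_(j) * m / j from the largest rank down, map back to input order
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run <- Inf
  for (j in m:1) {
    run <- min(run, ps[j] * m / j)
    adj[j] <- min(run, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Platt negative log-likelihood with smoothed targets (same objective the
# fitter minimizes, evaluated independently on a refined grid)
platt_nll <- function(A, B, f, y) {
  n_pos <- sum(y); n_neg <- sum(!y)
  t <- ifelse(y, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  fApB <- A * f + B
  sum(ifelse(fApB >= 0,
             t * fApB + log1p(exp(-fApB)),
             (t - 1) * fApB + log1p(exp(fApB))))
}

platt_grid_oracle <- function(f, y, a_range = c(-20, 0), b_range = c(-5, 5)) {
  best <- c(A = mean(a_range), B = mean(b_range))
  half_a <- diff(a_range) / 2
  half_b <- diff(b_range) / 2
  for (round in 1:6) {
    As <- seq(best["A"] - half_a, best["A"] + half_a, length.out = 41)
    Bs <- seq(best["B"] - half_b, best["B"] + half_b, length.out = 41)
    vals <- outer(As, Bs, Vectorize(function(a, b) platt_nll(a, b, f, y)))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(A = As[ix[1]], B = Bs[ix[2]])
    half_a <- half_a / 10
    half_b <- half_b / 10
  }
  best
}

# random positive-definite diffusion tensor and kurtosis tensor, drawn from
# the currently seeded generator
rand_truth <- function(s0_range = c(0.8, 3), lam_range = c(0.3, 1.8)) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  lam <- sort(runif(3, lam_range[1], lam_range[2]), decreasing = TRUE)
  D <- Q %*% diag(lam) %*% t(Q)
  W <- rnorm(15, 0, 0.25)
  W[1:3] <- abs(W[1:3]) + 0.3
  tensor_fit(runif(1, s0_range[1], s0_range[2]), D, W)
}

# reference 41-acquisition two-shell scheme shared across tests
protocol_scheme <- function() make_gradient_scheme(20, c(2000, 4000), n_b0 = 1, seed = 7)
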