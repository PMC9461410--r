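# Independent oracles. These deliberately avoid the code paths they check.

# sliding-window mean, plain loop
oracle_moving_average <- function(v, window = 5L) {
  half <- (window - 1L) %/% 2L
  n <- length(v)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(v[i])) next
    w <- v[max(1, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (length(w)) out[i] <- sum(w) / length(w)
  }
  out
}

# beta quantile by root-finding on the regularized incomplete beta function
oracle_beta_quantile <- function(p, a, b) {
  stats::uniroot(function(x) stats::pbeta(x, a, b) - p,
                 interval = c(0, 1), tol = 1e-12)$root
}

# Welch statistic from the textbook formulas, scalar arithmetic only
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- sum(x) / nx; my <- sum(y) / ny
  vx <- sum((x - mx)^2) / (nx - 1); vy <- sum((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

# ML fit of the random-intercept panel model by GLS with the variance
# ratio profiled out numerically: for a given ratio r = s_u^2/s_e^2 the
# covariance of participant i's stacked residuals is s_e^2 (I + r J), so
# beta_hat(r) is GLS and the profile log-likelihood has a closed form.
# Independent of lme4.
oracle_panel_ml <- function(panel) {
  ids <- unique(panel$participant_id)
  X <- cbind(1, panel$post72, panel$y_lag, panel$age, panel$no_condition,
             panel$male)
  y <- panel$y
  n <- length(y)
  idx <- split(seq_len(n), panel$participant_id)
  prof <- function(r) {
    # GLS via the Sherman-Morrison form of (I + r J)^-1
    XtX <- matrix(0, ncol(X), ncol(X)); Xty <- numeric(ncol(X))
    logdet <- 0; yy <- 0
    parts <- list()
    for (ix in idx) {
      Xi <- X[ix, , drop = FALSE]; yi <- y[ix]; Ti <- length(ix)
      w <- r / (1 + r * Ti)
      sx <- colSums(Xi); sy <- sum(yi)
      XtX <- XtX + crossprod(Xi) - w * tcrossprod(sx)
      Xty <- Xty + crossprod(Xi, yi) - w * sx * sy
      logdet <- logdet + log(1 + r * Ti)
      parts[[length(parts) + 1]] <- list(Xi = Xi, yi = yi, w = w,
                                         sx = sx, sy = sy)
    }
    beta <- solve(XtX, Xty)
    rss <- 0
    for (p in parts) {
      ei <- p$yi - p$Xi %*% beta
      rss <- rss + sum(ei^2) - p$w * sum(ei)^2
    }
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
    list(ll = ll, beta = beta, s2e = s2, s2u = r * s2)
  }
  opt <- stats::optimize(function(lr) -prof(exp(lr))$ll,
                         interval = c(-12, 6), tol = 1e-9)
  prof(exp(opt$minimum))
}
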