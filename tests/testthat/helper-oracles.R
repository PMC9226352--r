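# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# sort-and-interpolate quantile with plotting positions p(k) = (k-1)/(n-1)
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  if (n == 1L) return(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_iqr <- function(x) oracle_quantile(x, 0.75) - oracle_quantile(x, 0.25)

# from-scratch Pearson correlation (direct covariance/variance formula)
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# normal-equations OLS
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

oracle_euler <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

# best rigid-fit RMSD by coarse-to-fine search over Euler angles, refined
# down to (below) 0.1 degree steps; translation handled by centroid match
oracle_grid_rmsd <- function(P, Q, final_step_deg = 0.1) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  eval_rmsd <- function(a, b, c) {
    R <- oracle_euler(a, b, c)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  step <- 15 * pi / 180
  centre <- c(0, 0, 0)
  span <- pi
  best <- c(0, 0, 0)
  best_val <- Inf
  repeat {
    grid <- seq(-span, span, by = step)
    for (a in centre[1] + grid) for (b in centre[2] + grid) for (c in centre[3] + grid) {
      v <- eval_rmsd(a, b, c)
      if (v < best_val) { best_val <- v; best <- c(a, b, c) }
    }
    if (step <= final_step_deg * pi / 180) break
    centre <- best
    span <- 2 * step
    step <- step / 4
  }
  best_val
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply an independent random rigid transform to every frame
rigid_scramble <- function(ens) {
  out <- ens
  for (f in seq_len(dim(ens$coords)[1])) {
    R <- random_rotation()
    t <- rnorm(3, 0, 20)
    out$coords[f, , ] <- sweep(ens$coords[f, , ] %*% t(R), 2, t, `+`)
  }
  out
}

# Fisher-z 95% confidence band around a target correlation at sample size n
fisher_band <- function(rho, n) {
  z <- atanh(rho) + c(-1, 1) * 1.96 / sqrt(n - 3)
  tanh(z)
}
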