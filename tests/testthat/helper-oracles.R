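# Independent oracles, kept deliberately separate from the package code
# paths they check.

# Natural cubic spline interpolation through (xk, yk) via the classical
# tridiagonal system for the knot second derivatives (natural boundary
# conditions M_1 = M_n = 0), evaluated piecewise; linear continuation
# beyond the boundary knots.
ncs_interpolate <- function(xk, yk, xout) {
  n <- length(xk)
  stopifnot(n >= 3L, !is.unsorted(xk), length(yk) == n)
  h <- diff(xk)
  # Thomas algorithm for M_2..M_{n-1}
  m <- n - 2L
  a <- h[1:(m)]                       # sub-diagonal entries h_{i-1}
  b <- 2 * (h[1:m] + h[2:(m + 1L)])   # diagonal
  cc <- h[2:(m + 1L)]                 # super-diagonal
  d <- 6 * ((yk[3:n] - yk[2:(n - 1L)]) / h[2:(m + 1L)] -
              (yk[2:(n - 1L)] - yk[1:(n - 2L)]) / h[1:m])
  if (m > 1L) {
    for (i in 2:m) {
      w <- a[i] / b[i - 1L]
      b[i] <- b[i] - w * cc[i - 1L]
      d[i] <- d[i] - w * d[i - 1L]
    }
  }
  M_int <- numeric(m)
  M_int[m] <- d[m] / b[m]
  if (m > 1L) {
    for (i in (m - 1L):1L) {
      M_int[i] <- (d[i] - cc[i] * M_int[i + 1L]) / b[i]
    }
  }
  M <- c(0, M_int, 0)

  eval_one <- function(x) {
    if (x <= xk[1]) {
      slope <- (yk[2] - yk[1]) / h[1] - h[1] * M[2] / 6
      return(yk[1] + slope * (x - xk[1]))
    }
    if (x >= xk[n]) {
      slope <- (yk[n] - yk[n - 1L]) / h[n - 1L] + h[n - 1L] * M[n - 1L] / 6
      return(yk[n] + slope * (x - xk[n]))
    }
    i <- findInterval(x, xk, rightmost.closed = TRUE)
    hi <- h[i]
    M[i] * (xk[i + 1L] - x)^3 / (6 * hi) +
      M[i + 1L] * (x - xk[i])^3 / (6 * hi) +
      (yk[i] / hi - M[i] * hi / 6) * (xk[i + 1L] - x) +
      (yk[i + 1L] / hi - M[i + 1L] * hi / 6) * (x - xk[i])
  }
  vapply(xout, eval_one, numeric(1))
}
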