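## Internal numerical helpers.

## Symmetric pseudo-inverse with relative eigenvalue truncation.
.pinv <- function(M, tol = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  if (!any(keep))
    stop("matrix is singular beyond pseudo-inverse tolerance")
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

## Analytic signal via the frequency-domain Hilbert transformer.
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Analytic signal of every row of a matrix (batched Hilbert transform).
.analyticRows <- function(X) {
  n <- ncol(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  FT <- stats::mvfft(t(X)) * h
  t(stats::mvfft(FT, inverse = TRUE)) / n
}

## Wrap angles to [-pi, pi).
.wrapPhase <- function(x) ((x + pi) %% (2 * pi)) - pi

.crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

## Fix the sign of an orientation so its first non-negligible component is
## positive (source polarity is unobservable in the external field).
.fixSign <- function(v, tol = 1e-12) {
  i <- which(abs(v) > tol)
  if (length(i) == 0) return(v)
  if (v[i[1]] < 0) -v else v
}

.checkBand <- function(band, fs) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] > fs / 2)
    stop(sprintf("invalid band [%g, %g] Hz for fs = %g Hz",
                 band[1], band[2], fs))
  invisible(band)
}
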