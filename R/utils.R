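# Internal numeric helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs against the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed; kept below 2^31 - 1 (R integers are 32-bit).
subSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 100003 * as.numeric(k)) %% 2147483647L)
}

# Zero-phase application of a linear-phase (odd-length, symmetric) FIR filter.
# One forward pass with group-delay compensation and reflection padding, so the
# designed magnitude response applies once (not squared as with filtfilt).
firApply <- function(x, h) {
  stopifnot(length(h) %% 2 == 1)
  if (is.matrix(x)) return(apply(x, 2, firApply, h = h))
  n <- length(x)
  pad <- min(length(h), n - 1)
  xe <- c(2 * x[1] - rev(x[seq_len(pad) + 1]), x,
          2 * x[n] - rev(x[n - seq_len(pad)]))
  y <- signal::fftfilt(h, xe)
  d <- (length(h) - 1) / 2
  y[pad + d + seq_len(n)]
}

# Hamming-window FIR designs. Order is even (odd length) for integer group delay.
firHighpass <- function(srate, cutoff, order) {
  if (order %% 2 == 1) order <- order + 1
  signal::fir1(order, cutoff / (srate / 2), type = "high",
               window = signal::hamming(order + 1))
}

firLowpass <- function(srate, cutoff, order = 256) {
  if (order %% 2 == 1) order <- order + 1
  signal::fir1(order, cutoff / (srate / 2), type = "low",
               window = signal::hamming(order + 1))
}

firBandpass <- function(srate, lo, hi, order = 128) {
  if (order %% 2 == 1) order <- order + 1
  signal::fir1(order, c(lo, hi) / (srate / 2), type = "pass",
               window = signal::hamming(order + 1))
}

# Magnitude of the analytic signal (FFT method); x vector or time-by-channel
# matrix.
hilbertEnvelope <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, hilbertEnvelope))
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * w, inverse = TRUE) / n)
}

# Centered boxcar smoothing with edge shrinkage.
boxcarSmooth <- function(x, k) {
  if (k <= 1) return(x)
  if (is.matrix(x)) return(apply(x, 2, boxcarSmooth, k = k))
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- floor(k / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Legendre polynomials P_1..P_nmax at x (vector), by the Bonnet recurrence.
# Returns length(x) x nmax matrix.
legendreP <- function(nmax, x) {
  out <- matrix(0, length(x), nmax)
  pm2 <- rep(1, length(x))        # P_0
  pm1 <- x                        # P_1
  out[, 1] <- pm1
  if (nmax >= 2) {
    for (n in 2:nmax) {
      p <- ((2 * n - 1) * x * pm1 - (n - 1) * pm2) / n
      out[, n] <- p
      pm2 <- pm1
      pm1 <- p
    }
  }
  out
}

# Decimation by block averaging; `factor` consecutive samples are averaged.
# Acts along the last dimension of a trials x channels x time array, or along
# a vector. Built-in anti-aliasing is the boxcar average itself.
blockDecimate <- function(x, factor) {
  if (factor == 1) return(x)
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    nt <- floor(d[3] / factor)
    y <- x[, , seq_len(nt * factor), drop = FALSE]
    dim(y) <- c(d[1] * d[2], factor, nt)
    out <- colMeans(aperm(y, c(2, 1, 3)))
    dim(out) <- c(d[1], d[2], nt)
    return(out)
  }
  nt <- floor(length(x) / factor)
  colMeans(matrix(x[seq_len(nt * factor)], factor, nt))
}

# Rank-based (Mann-Whitney) AUC of `score` for positive class `pos` (logical).
rankAUC <- function(score, pos) {
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Gaussian bump used as a temporal response kernel, unit peak amplitude.
gaussKernel <- function(times, peak, width) {
  exp(-0.5 * ((times - peak) / width)^2)
}

# Indices of `times` (ms) inside [win[1], win[2]].
timeIndex <- function(times, win) {
  which(times >= win[1] - 1e-9 & times <= win[2] + 1e-9)
}
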