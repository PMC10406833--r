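# Spherical-spline scalp interpolation (order-4 splines, Legendre expansion),
# following the classic g-function formulation: g(cos) =
# (1/4pi) sum_n (2n+1) / (n (n+1))^m P_n(cos), truncated at n_terms.

splineG <- function(cosang, m = 4, n_terms = 50) {
  P <- legendreP(n_terms, pmin(pmax(cosang, -1), 1))
  n <- seq_len(n_terms)
  w <- (2 * n + 1) / (n * (n + 1))^m
  as.numeric(P %*% w) / (4 * pi)
}

# Interpolate bad-channel time courses from good channels for one epoch.
# dataGood: good-channels x time matrix; returns bad-channels x time.
splineInterpolateMatrix <- function(dataGood, goodNames, badNames, montage,
                                    m = 4, n_terms = 50, lambda = 1e-5) {
  gi <- match(goodNames, montage$channel)
  bi <- match(badNames, montage$channel)
  if (anyNA(gi) || anyNA(bi))
    stop("channels without montage positions", call. = FALSE)
  P <- as.matrix(montage[, c("x", "y", "z")])
  cosGG <- tcrossprod(P[gi, , drop = FALSE])
  cosBG <- P[bi, , drop = FALSE] %*% t(P[gi, , drop = FALSE])
  ng <- length(gi)
  G <- matrix(splineG(as.numeric(cosGG), m, n_terms), ng, ng)
  Gb <- matrix(splineG(as.numeric(cosBG), m, n_terms), length(bi), ng)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(dataGood, 0)
  sol <- solve(A, rhs)
  C <- sol[seq_len(ng), , drop = FALSE]
  d <- sol[ng + 1, ]
  out <- Gb %*% C
  sweep(out, 2, d, "+")
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed scalp channels, in every epoch, by the order-4
#' spherical-spline estimate from the remaining scalp channels (Legendre
#' expansion truncated at 50 terms, ridge regularization 1e-5). Reference
#' and EOG channels cannot be interpolated. The fit is linear in the data
#' and exactly reproduces a constant field.
#'
#' @param epochs an \code{\linkS4class{EpochSet}}.
#' @param bad_channels character vector of scalp channel names.
#' @param m spline order (4).
#' @param n_terms Legendre truncation (50).
#' @return the \code{EpochSet} with interpolated channels and a log entry.
#' @export
splineInterpolate <- function(epochs, bad_channels, m = 4, n_terms = 50) {
  scalp <- scalpChannels()
  if (!all(bad_channels %in% scalp))
    stop("bad set must be scalp channels (references excluded)",
         call. = FALSE)
  if (length(bad_channels) > 0.25 * length(scalp))
    stop("refusing to interpolate more than 25% of scalp channels",
         call. = FALSE)
  montage <- standardMontage()
  good <- setdiff(scalp, bad_channels)
  gi <- match(good, epochs@channels)
  bi <- match(bad_channels, epochs@channels)
  for (tr in seq_len(dim(epochs@data)[1])) {
    epochs@data[tr, bi, ] <- splineInterpolateMatrix(
      epochs@data[tr, gi, , drop = TRUE], good, bad_channels, montage,
      m = m, n_terms = n_terms)
  }
  epochs@log <- c(epochs@log,
                  list(interpolated = list(channels = bad_channels)))
  epochs
}
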