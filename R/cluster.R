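# Cluster-based sign-flip permutation tests (time courses and 2-D grids),
# paired tests and cross-subject correlations.

tStat <- function(d) {
  # one-sample t per column of a subjects x points matrix; columns that are
  # identically zero (no effect, no variance) score t = 0, while non-zero
  # constant differences are degenerate and yield Inf for the caller to
  # reject.
  n <- nrow(d)
  m <- colMeans(d)
  s <- sqrt(pmax((colMeans(d^2) - m^2) * n / (n - 1), 0))
  se <- s / sqrt(n)
  t <- ifelse(s == 0, ifelse(abs(m) < 1e-12, 0, Inf * sign(m)), m / se)
  list(t = t, sd = s, n = n)
}

# Contiguous 1-D clusters of same-signed supra-threshold t; returns a
# data.frame with start/end indices and mass (sum of t).
clusters1d <- function(t, tcrit) {
  lab <- sign(t) * (abs(t) > tcrit)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values != 0)
  if (!length(i))
    return(data.frame(start = integer(0), end = integer(0),
                      mass = numeric(0)))
  data.frame(start = starts[i], end = ends[i],
             mass = vapply(i, function(k)
               sum(t[starts[k]:ends[k]]), numeric(1)))
}

maxMass1d <- function(t, tcrit) {
  cl <- clusters1d(t, tcrit)
  if (!nrow(cl)) 0 else max(abs(cl$mass))
}

# 4-connected components of a logical matrix by iterative label propagation
# (vectorized pmin over shifted copies). Returns an integer label matrix.
label4 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  big <- nr * nc + 1L
  L <- matrix(big, nr, nc)
  L[mask] <- lab[mask]
  repeat {
    Lp <- L
    up <- rbind(L[-1, , drop = FALSE], rep(big, nc))
    dn <- rbind(rep(big, nc), L[-nr, , drop = FALSE])
    lf <- cbind(L[, -1, drop = FALSE], rep(big, nr))
    rt <- cbind(rep(big, nr), L[, -nc, drop = FALSE])
    L <- pmin(L, up, dn, lf, rt)
    L[!mask] <- big
    if (identical(L, Lp)) break
  }
  out <- matrix(0L, nr, nc)
  out[mask] <- as.integer(factor(L[mask]))
  out
}

clusters2d <- function(t, tcrit) {
  res <- list()
  for (sg in c(1, -1)) {
    mask <- sg * t > tcrit
    lab <- label4(mask)
    k <- max(lab)
    if (k > 0) for (j in seq_len(k)) {
      cells <- which(lab == j)
      res[[length(res) + 1]] <- list(cells = cells, mass = sum(t[cells]))
    }
  }
  res
}

maxMass2d <- function(t, tcrit) {
  cl <- clusters2d(t, tcrit)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
}

permNull <- function(d, tcrit, nPerm, maxMassFun, seed) {
  n <- nrow(d)
  msq <- colMeans(d^2)      # invariant under sign flips; the mean is not
  withSeed(seed, {
    vapply(seq_len(nPerm), function(p) {
      sg <- sample(c(-1, 1), n, replace = TRUE)
      mp <- as.numeric(crossprod(sg, d)) / n
      vp <- pmax(msq - mp^2, 0) * n / (n - 1)
      tp <- ifelse(vp == 0, 0, mp / sqrt(vp / n))
      maxMassFun(tp, tcrit)
    }, numeric(1))
  })
}

#' Cluster-based permutation test on time courses
#'
#' Tests subject-level curves against a scalar reference (one-sample, e.g.
#' AUC against chance 0.5) or a second curve set (paired). Per-timepoint t
#' statistics are thresholded at the two-sided cluster-forming level;
#' contiguous same-signed supra-threshold runs form clusters with mass =
#' sum of t; the null distribution of the maximum absolute cluster mass is
#' built from random sign flips of the subject-level differences; each
#' observed cluster's p is its rank in that null.
#'
#' @param curves subjects x timepoints matrix, or an
#'   \code{\linkS4class{AUCTimecourse}}.
#' @param reference scalar chance level, or a matching matrix/
#'   \code{AUCTimecourse} for a paired test.
#' @param times time stamps (taken from the object when available).
#' @param n_permutations sign-flip iterations (1024).
#' @param alpha cluster significance level (0.05).
#' @param cluster_alpha two-sided cluster-forming p threshold (0.05).
#' @param seed integer seed for the permutation draw.
#' @return a \code{\linkS4class{ClusterResult}}; the cluster table reports
#'   start/end in ms when times are known, otherwise in samples.
#' @export
clusterPermTime <- function(curves, reference = 0.5, times = NULL,
                            n_permutations = 1024, alpha = 0.05,
                            cluster_alpha = 0.05, seed = 1L) {
  if (is(curves, "AUCTimecourse")) {
    if (is.null(times)) times <- curves@times
    curves <- curves@auc
  }
  type <- "onesample"
  if (is(reference, "AUCTimecourse")) reference <- reference@auc
  if (is.matrix(reference)) {
    stopifnot(dim(reference) == dim(curves))
    d <- curves - reference
    type <- "paired"
  } else {
    d <- curves - reference
  }
  n <- nrow(d)
  if (n < 6) stop("need at least 6 subjects", call. = FALSE)
  st <- tStat(d)
  if (any(is.infinite(st$t) | is.nan(st$t)))
    stop("degenerate input: constant non-zero differences", call. = FALSE)
  tcrit <- stats::qt(1 - cluster_alpha / 2, n - 1)
  obs <- clusters1d(st$t, tcrit)
  null <- permNull(d, tcrit, n_permutations, maxMass1d, seed)
  p <- vapply(obs$mass, function(m)
    (1 + sum(null >= abs(m))) / (n_permutations + 1), numeric(1))
  cl <- data.frame(start = if (is.null(times)) obs$start
                   else times[obs$start],
                   end = if (is.null(times)) obs$end else times[obs$end],
                   mass = obs$mass, p = p)
  cl <- cl[order(cl$p, -abs(cl$mass)), , drop = FALSE]
  rownames(cl) <- NULL
  new("ClusterResult", clusters = cl, nPermutations = n_permutations,
      alpha = alpha, type = type, tCrit = tcrit, stat = st$t)
}

#' Cluster-based permutation test on 2-D maps
#'
#' Same scheme as \code{\link{clusterPermTime}} with 4-connected components
#' over a grid (e.g. per-subject gaze density difference maps against 0).
#'
#' @param maps subjects x rows x cols array of per-subject maps, or a list
#'   of matrices.
#' @param reference scalar reference (0).
#' @param n_permutations,alpha,cluster_alpha,seed as in
#'   \code{\link{clusterPermTime}}.
#' @return a \code{\linkS4class{ClusterResult}} whose cluster table carries
#'   a \code{cells} list-column of grid indices.
#' @export
clusterPerm2d <- function(maps, reference = 0, n_permutations = 1024,
                          alpha = 0.05, cluster_alpha = 0.05, seed = 1L) {
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    maps <- aperm(array(unlist(maps), c(dims, length(maps))), c(3, 1, 2))
  }
  d <- dim(maps)
  n <- d[1]
  if (n < 6) stop("need at least 6 subjects", call. = FALSE)
  flat <- matrix(maps, n, d[2] * d[3]) - reference
  if (all(flat == 0))
    return(new("ClusterResult",
               clusters = data.frame(mass = numeric(0), p = numeric(0)),
               nPermutations = n_permutations, alpha = alpha,
               type = "onesample", tCrit = NA_real_,
               stat = matrix(0, d[2], d[3])))
  sds <- tStat(flat)$sd
  ok <- sds > 0
  tmap <- matrix(0, d[2], d[3])
  tflat <- rep(0, d[2] * d[3])
  tfull <- tStat(flat[, ok, drop = FALSE])$t
  tflat[ok] <- tfull
  tmap[] <- tflat
  tcrit <- stats::qt(1 - cluster_alpha / 2, n - 1)
  obs <- clusters2d(tmap, tcrit)
  mm2 <- function(tvec, tc) {
    tm <- matrix(0, d[2], d[3])
    tm[ok] <- tvec
    maxMass2d(tm, tc)
  }
  null <- permNull(flat[, ok, drop = FALSE], tcrit, n_permutations, mm2,
                   seed)
  cl <- data.frame(mass = vapply(obs, `[[`, numeric(1), "mass"),
                   p = vapply(obs, function(o)
                     (1 + sum(null >= abs(o$mass))) /
                       (n_permutations + 1), numeric(1)))
  cl$cells <- lapply(obs, `[[`, "cells")
  cl <- cl[order(cl$p, -abs(cl$mass)), , drop = FALSE]
  rownames(cl) <- NULL
  new("ClusterResult", clusters = cl, nPermutations = n_permutations,
      alpha = alpha, type = "onesample", tCrit = tcrit, stat = tmap)
}

#' Pearson correlation of two per-subject summaries
#'
#' @param a,b numeric vectors, one value per subject (paired).
#' @return list with \code{r}, \code{p} (two-sided), \code{n}.
#' @export
corrAcrossSubjects <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need at least 3 subjects", call. = FALSE)
  ct <- stats::cor.test(a[ok], b[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Significant clusters at the configured level
#'
#' @param x a \code{\linkS4class{ClusterResult}}.
#' @return the rows of the cluster table with \code{p <= alpha}.
#' @export
significantClusters <- function(x) {
  x@clusters[x@clusters$p <= x@alpha, , drop = FALSE]
}
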