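## Inferential statistics on spectra: cluster-based frequency randomization,
## jackknife pseudo-value peak estimation, topography similarity.

## Maximal contiguous runs of supra-threshold |t| of one sign.
## Returns a data.frame of clusters (start/end index, size, sign, mass).
find_clusters <- function(tvals, t_crit) {
  state <- ifelse(is.finite(tvals) & abs(tvals) > t_crit, sign(tvals), 0)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  data.frame(start = starts[keep], end = ends[keep],
             size = r$lengths[keep], sign = r$values[keep],
             mass = vapply(which(keep), function(i) {
               sum(abs(tvals[starts[i]:ends[i]]))
             }, 0))
}

#' Cluster-based randomization test across frequencies
#'
#' Paired two-tailed t-tests at each frequency; contiguous frequencies with
#' `p < cluster_alpha` and a common sign form clusters; each observed
#' cluster's size (number of grid frequencies; optionally summed |t| mass)
#' is compared against the null distribution of the maximal cluster size
#' obtained by randomizing condition labels — realized as sign flips of the
#' within-subject differences, since conditions are paired within subject.
#' When the `2^n` sign patterns do not exceed `n_perm`, they are enumerated
#' exhaustively. Cluster p-values are `(1 + #(null >= observed)) / (n + 1)`.
#'
#' @param a,b subjects x frequencies matrices for the two conditions,
#'   matched by row (subject). Frequencies where any subject's difference is
#'   missing are excluded from cluster formation.
#' @param freqs_hz optional frequency labels for reporting.
#' @param n_perm number of randomizations.
#' @param cluster_alpha per-frequency cluster-forming threshold.
#' @param statistic `"size"` (cluster extent in grid steps) or `"mass"`
#'   (summed |t|).
#' @param seed RNG seed for the Monte-Carlo case.
#' @return object of class `cluster_test`: data.frame `clusters`
#'   (`start_hz`, `end_hz`, `size`, `sign`, `p`), `t` (per-frequency),
#'   `t_crit`, `n_perm_used`, `exhaustive`.
#' @export
cluster_randomization_test <- function(a, b, freqs_hz = NULL,
                                       n_perm = 10000, cluster_alpha = 0.01,
                                       statistic = c("size", "mass"),
                                       seed = NULL) {
  statistic <- match.arg(statistic)
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b))) {
    stop("`a` and `b` must be subjects x frequencies matrices of equal size",
         call. = FALSE)
  }
  n <- nrow(a)
  if (n < 5L) stop("need >= 5 paired subjects", call. = FALSE)
  d <- a - b
  ok <- apply(is.finite(d), 2, all)
  if (is.null(freqs_hz)) freqs_hz <- seq_len(ncol(d))

  t_of <- function(dd) {
    m <- colMeans(dd)
    s <- apply(dd, 2, stats::sd)
    ifelse(s > 0, m / (s / sqrt(n)), 0)
  }
  tvals <- rep(NA_real_, ncol(d))
  tvals[ok] <- t_of(d[, ok, drop = FALSE])
  t_crit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  obs <- find_clusters(tvals, t_crit)

  exhaustive <- 2^n <= n_perm
  signs <- if (exhaustive) {
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t(m)
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                           n, n_perm))
  }
  n_used <- ncol(signs)

  dok <- d[, ok, drop = FALSE]
  ss <- colSums(dok^2)
  M <- crossprod(signs, dok) / n                 # n_used x F means
  V <- sweep(-(n * M^2), 2, ss, "+") / (n - 1)    # per-perm variances
  Tm <- M / sqrt(pmax(V, 0) / n)
  Tm[!is.finite(Tm)] <- 0

  null_max <- vapply(seq_len(n_used), function(i) {
    cl <- find_clusters(Tm[i, ], t_crit)
    if (!nrow(cl)) 0 else max(cl[[statistic]])
  }, 0)

  if (nrow(obs)) {
    obs$p <- vapply(obs[[statistic]], function(s0) {
      (1 + sum(null_max >= s0)) / (n_used + 1)
    }, 0)
    obs$start_hz <- freqs_hz[obs$start]
    obs$end_hz <- freqs_hz[obs$end]
  } else {
    obs$p <- numeric(0)
    obs$start_hz <- numeric(0)
    obs$end_hz <- numeric(0)
  }
  structure(list(clusters = obs, t = tvals, t_crit = t_crit,
                 freqs_hz = freqs_hz, n_perm_used = n_used,
                 exhaustive = exhaustive, cluster_alpha = cluster_alpha,
                 statistic = statistic),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster randomization test (%s statistic, %d randomizations%s)\n",
              x$statistic, x$n_perm_used,
              if (x$exhaustive) ", exhaustive" else ""))
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf("  %s cluster %.2f-%.2f Hz (size %d): p = %.4g\n",
                  if (cl$sign > 0) "positive" else "negative",
                  cl$start_hz, cl$end_hz, cl$size, cl$p))
    }
  }
  invisible(x)
}

## Peak of a spectrum within a band, with parabolic interpolation between
## adjacent grid points in log2-frequency. direction = "min" finds troughs.
spectrum_peak_hz <- function(values, freqs_hz, band_hz,
                             direction = c("max", "min")) {
  direction <- match.arg(direction)
  v <- if (direction == "min") -values else values
  lf <- log2(freqs_hz)
  idx <- which(freqs_hz >= band_hz[1] & freqs_hz <= band_hz[2] &
                 is.finite(v))
  if (length(idx) < 2L || diff(range(v[idx])) == 0) return(NA_real_)
  i <- idx[which.max(v[idx])]
  if (i > min(idx) && i < max(idx)) {
    y0 <- v[i - 1L]; y1 <- v[i]; y2 <- v[i + 1L]
    denom <- y0 - 2 * y1 + y2
    offset <- if (denom < 0) 0.5 * (y0 - y2) / denom else 0
    offset <- max(-0.5, min(0.5, offset))
    step <- lf[i + 1L] - lf[i]
    return(2^(lf[i] + offset * step))
  }
  2^lf[i]
}

#' Jackknife pseudo-values of a group statistic
#'
#' For a statistic `theta` computed over subjects (rows), the pseudo-values
#' are `p_i = n * theta(all) - (n - 1) * theta(without i)`. For a statistic
#' linear in subjects their mean equals the full-sample statistic; for
#' non-linear statistics they provide a bias-corrected estimate and a
#' standard error.
#'
#' @param x subjects x variables matrix.
#' @param statistic function taking a subjects x variables matrix and
#'   returning a scalar.
#' @return numeric vector of per-subject pseudo-values.
#' @export
jackknife_pseudo_values <- function(x, statistic) {
  n <- nrow(x)
  theta_full <- statistic(x)
  loo <- vapply(seq_len(n), function(i) {
    statistic(x[-i, , drop = FALSE])
  }, 0)
  n * theta_full - (n - 1) * loo
}

#' Jackknife pseudo-value estimate of an effect's peak frequency
#'
#' The peak of the group-mean effect spectrum within a band is a non-linear
#' group statistic; its standard error is obtained from jackknife
#' pseudo-values `p_i = n * theta_full - (n - 1) * theta_(-i)` where
#' `theta_(-i)` is the peak with subject `i` left out. Peaks are localized
#' on the log2-frequency grid with parabolic interpolation (sub-grid
#' resolution) and reported in Hz.
#'
#' @param effect subjects x frequencies matrix of effect spectra (e.g.
#'   percent power change).
#' @param freqs_hz grid frequencies.
#' @param band_hz frequency band to search.
#' @param direction `"max"` for a positive-effect peak, `"min"` for a
#'   negative one.
#' @return object of class `peak_estimate`: `peak_hz` (pseudo-value mean),
#'   `sem_hz`, `pseudo_values`, `theta_full`, `band_hz`, `flat` flag.
#' @export
jackknife_peak <- function(effect, freqs_hz, band_hz,
                           direction = c("max", "min")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(effect), nrow(effect) >= 3L)
  n <- nrow(effect)
  theta_full <- spectrum_peak_hz(colMeans(effect, na.rm = TRUE), freqs_hz,
                                 band_hz, direction)
  if (!is.finite(theta_full)) {
    return(structure(list(peak_hz = NA_real_, sem_hz = NA_real_,
                          pseudo_values = rep(NA_real_, n),
                          theta_full = NA_real_, band_hz = band_hz,
                          flat = TRUE),
                     class = "peak_estimate"))
  }
  pv <- jackknife_pseudo_values(effect, function(m) {
    spectrum_peak_hz(colMeans(m, na.rm = TRUE), freqs_hz, band_hz,
                     direction)
  })
  structure(list(peak_hz = mean(pv), sem_hz = stats::sd(pv) / sqrt(n),
                 pseudo_values = pv, theta_full = theta_full,
                 band_hz = band_hz, flat = FALSE),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  if (x$flat) {
    cat("Peak estimate: flat spectrum in band, peak undefined\n")
  } else {
    cat(sprintf("Peak frequency %.2f +/- %.2f Hz (jackknife SEM, band %g-%g Hz)\n",
                x$peak_hz, x$sem_hz, x$band_hz[1], x$band_hz[2]))
  }
  invisible(x)
}

#' Compare two pseudo-value peak-frequency estimates
#'
#' Paired (default) or two-sample t-test on the jackknife pseudo-values.
#'
#' @param pe1,pe2 [jackknife_peak()] results.
#' @param paired whether the same subjects underlie both estimates.
#' @return the `htest` from [stats::t.test()].
#' @export
compare_peaks <- function(pe1, pe2, paired = TRUE) {
  if (pe1$flat || pe2$flat) stop("peak undefined for a flat spectrum",
                                 call. = FALSE)
  if (paired && length(pe1$pseudo_values) != length(pe2$pseudo_values)) {
    stop("paired comparison needs equal subject counts", call. = FALSE)
  }
  stats::t.test(pe1$pseudo_values, pe2$pseudo_values, paired = paired)
}

#' Topography-similarity randomization test
#'
#' Tests whether the spatial topography of an effect differs between two
#' drugs. Statistic: mean of the within-drug average pairwise cross-subject
#' correlations minus the between-drug average pairwise correlation; the
#' null distribution is obtained by randomly permuting the drug labels of
#' the pooled topographies. One-sided p-value.
#'
#' @param topo1,topo2 subjects x channels matrices (same channel set).
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return object of class `topo_test`: `r_within` (length 2), `r_between`,
#'   `statistic`, `p`, `n_perm`.
#' @export
topography_similarity_test <- function(topo1, topo2, n_perm = 10000,
                                       seed = NULL) {
  stopifnot(is.matrix(topo1), is.matrix(topo2),
            ncol(topo1) == ncol(topo2))
  n1 <- nrow(topo1); n2 <- nrow(topo2)
  if (n1 < 3L || n2 < 3L) stop("need >= 3 subjects per drug", call. = FALSE)
  pool <- rbind(topo1, topo2)
  sds <- apply(pool, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance topographies excluded from correlations")
  }
  C <- suppressWarnings(stats::cor(t(pool)))
  diag(C) <- NA
  stat_of <- function(idx1) {
    idx2 <- setdiff(seq_len(n1 + n2), idx1)
    rw1 <- mean(C[idx1, idx1], na.rm = TRUE)
    rw2 <- mean(C[idx2, idx2], na.rm = TRUE)
    rb <- mean(C[idx1, idx2], na.rm = TRUE)
    c(stat = mean(c(rw1, rw2)) - rb, rw1 = rw1, rw2 = rw2, rb = rb)
  }
  obs <- stat_of(seq_len(n1))
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stat_of(sample(n1 + n2, n1))[["stat"]]
  }, 0))
  structure(list(r_within = c(obs[["rw1"]], obs[["rw2"]]),
                 r_between = obs[["rb"]], statistic = obs[["stat"]],
                 p = (1 + sum(null >= obs[["stat"]])) / (n_perm + 1),
                 n_perm = n_perm),
            class = "topo_test")
}

#' @export
print.topo_test <- function(x, ...) {
  cat(sprintf("Topography similarity: r_within = %.3f/%.3f, r_between = %.3f\n",
              x$r_within[1], x$r_within[2], x$r_between))
  cat(sprintf("  statistic = %.3f, one-sided p = %.4g (%d permutations)\n",
              x$statistic, x$p, x$n_perm))
  invisible(x)
}
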