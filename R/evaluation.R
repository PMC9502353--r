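#' Dynamic time warping alignment
#'
#' Classic dynamic-programming alignment of two value sequences with local
#' cost `|a_i - b_j|`, steps (i-1,j), (i,j-1), (i-1,j-1) with unit weights,
#' boundary-to-boundary, and no windowing constraint. Ties prefer the
#' diagonal during backtracking.
#'
#' @param a,b Non-empty numeric vectors.
#' @return A list with `distance` (accumulated cost of the optimal path) and
#'   `path`, a two-column integer matrix of matched (i, j) index pairs.
#' @export
dtw_align <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  n <- length(a)
  m <- length(b)
  if (!n || !m) stop("dtw_align requires non-empty inputs")
  cost <- abs(outer(a, b, "-"))
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    Di <- D[i, ]          # row i (prefix lengths i-1)
    Dc <- D[i + 1L, ]
    for (j in seq_len(m)) {
      Dc[j + 1L] <- cost[i, j] + min(Di[j], Di[j + 1L], Dc[j])
    }
    D[i + 1L, ] <- Dc
  }
  # backtrack, diagonal preferred on ties
  path <- matrix(0L, n + m, 2L)
  k <- n + m
  i <- n; j <- m
  repeat {
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    diag_ <- D[i, j]
    up <- D[i, j + 1L]
    left <- D[i + 1L, j]
    if (i > 1L && j > 1L && diag_ <= up && diag_ <= left) {
      i <- i - 1L; j <- j - 1L
    } else if (i > 1L && (j == 1L || up <= left)) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    k <- k - 1L
  }
  list(distance = D[n + 1L, m + 1L], path = path[k:(n + m), , drop = FALSE])
}

#' Pearson correlation over DTW-matched pairs
#'
#' Correlates the values matched along a warping path; every path pair
#' contributes once.
#'
#' @param a,b Numeric vectors as passed to [dtw_align()].
#' @param path Two-column index matrix from [dtw_align()].
#' @return Pearson `r`, or `NA` (with a warning) when either matched side
#'   has zero variance.
#' @export
aligned_pearson <- function(a, b, path) {
  av <- a[path[, 1L]]
  bv <- b[path[, 2L]]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    warning("zero variance along the alignment; correlation undefined")
    return(NA_real_)
  }
  stats::cor(av, bv)
}

#' Relative root-mean-square error between variability series
#'
#' `100 * sqrt(sum((PRV_i - HRV_i)^2) / sum(HRV_i^2))`, in percent, with the
#' HRV as reference.
#'
#' @param prv,hrv Equal-length [uniform_variability()] series at the same
#'   rate (plain numeric vectors are also accepted).
#' @return RRMSE in percent.
#' @export
rrmse <- function(prv, hrv) {
  pv <- if (inherits(prv, "uniform_variability")) prv$values else as.numeric(prv)
  hv <- if (inherits(hrv, "uniform_variability")) hrv$values else as.numeric(hrv)
  if (inherits(prv, "uniform_variability") &&
      inherits(hrv, "uniform_variability") && prv$fs_v != hrv$fs_v)
    stop("series rates differ")
  if (length(pv) != length(hv)) stop("series lengths differ")
  den <- sum(hv ^ 2)
  if (den == 0) stop("all-zero reference series")
  100 * sqrt(sum((pv - hv) ^ 2) / den)
}

#' Root-mean-square of per-participant RRMSE values
#'
#' `sqrt(sum(RRMSE_i^2) / N)` across participants.
#'
#' @param per_participant Non-empty numeric vector of RRMSE values (%).
#' @return mRRMSE in percent.
#' @export
mrrmse <- function(per_participant) {
  x <- as.numeric(per_participant)
  if (!length(x)) stop("empty input")
  sqrt(mean(x ^ 2))
}

#' Welch power spectral density of a variability series
#'
#' Averaged modified periodograms: Hamming-tapered segments of
#' `window_s * fs_v` samples, hop equal to the segment length minus
#' `overlap_samples`, per-segment constant detrending, one-sided density
#' normalization (integrating the PSD over frequency approximates the
#' series variance).
#'
#' @param series A [uniform_variability()] at least one segment long.
#' @param window_s Segment length in seconds (default 30).
#' @param overlap_samples Overlap between consecutive segments in samples
#'   (default 25).
#' @return A list of class `psd_estimate` with `freqs` (Hz) and `power`
#'   (s^2/Hz).
#' @export
welch_psd <- function(series, window_s = 30, overlap_samples = 25) {
  stopifnot(inherits(series, "uniform_variability"))
  fs <- series$fs_v
  x <- series$values
  seg_len <- round(window_s * fs)
  if (length(x) < seg_len) stop("series shorter than one Welch segment")
  hop <- max(1L, seg_len - as.integer(overlap_samples))
  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  taper <- 0.54 - 0.46 * cos(2 * pi * (seq_len(seg_len) - 1L) / (seg_len - 1L))
  u <- sum(taper ^ 2)
  nf <- seg_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    # taper-weighted demeaning zeroes the DC bin exactly
    seg <- (seg - sum(seg * taper) / sum(taper)) * taper
    spec <- Mod(stats::fft(seg)[seq_len(nf)]) ^ 2 / (fs * u)
    spec[2:(nf - 1L)] <- 2 * spec[2:(nf - 1L)]
    if (seg_len %% 2L == 1L) spec[nf] <- 2 * spec[nf]
    acc <- acc + spec
  }
  structure(list(freqs = (seq_len(nf) - 1L) * fs / seg_len,
                 power = acc / length(starts)),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  pk <- which.max(x$power)
  cat(sprintf("psd_estimate: %d bins up to %g Hz, peak at %g Hz\n",
              length(x$freqs), max(x$freqs), x$freqs[pk]))
  invisible(x)
}

#' Assemble a PRV-vs-HRV comparison report
#'
#' DTW distance and aligned Pearson correlation on the raw (unequal-length)
#' interval duration sequences, plus RRMSE on the uniformly resampled
#' series.
#'
#' @param prv_raw,hrv_raw [interval_series()] objects (raw PRV/HRV).
#' @param prv_u,hrv_u Length-matched [uniform_variability()] series.
#' @return A list of class `comparison_report` with fields `rrmse` (%),
#'   `dtw_distance` (s), `pearson_r`, `n_ref`, `n_test`.
#' @export
compare_variability <- function(prv_raw, hrv_raw, prv_u, hrv_u) {
  stopifnot(inherits(prv_raw, "interval_series"),
            inherits(hrv_raw, "interval_series"))
  al <- dtw_align(prv_raw$durations, hrv_raw$durations)
  r <- aligned_pearson(prv_raw$durations, hrv_raw$durations, al$path)
  structure(list(rrmse = rrmse(prv_u, hrv_u),
                 dtw_distance = al$distance,
                 pearson_r = r,
                 n_ref = length(hrv_raw$durations),
                 n_test = length(prv_raw$durations)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(paste0("comparison_report: RRMSE = %.2f%%, DTW = %.3f s, ",
                     "r = %.3f (n_test = %d, n_ref = %d)\n"),
              x$rrmse, x$dtw_distance, x$pearson_r, x$n_test, x$n_ref))
  invisible(x)
}
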