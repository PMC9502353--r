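# Orthonormal wavelet filter bank. Coefficients are the standard published
# values for the Daubechies least-asymmetric family (sym4) and the first
# Coiflet (coif1), stored at double precision.
wavelet_filters <- function(wavelet) {
  lo <- switch(wavelet,
    sym4 = c(-0.075765714789273325, -0.02963552764599851,
              0.49761866763201545,   0.80373875180591614,
              0.29785779560527736,  -0.099219543576847216,
             -0.012603967262037833,  0.032223100604042702),
    coif1 = c(-0.015655728135791993, -0.07273261951252645,
               0.38486484686485778,   0.85257202021160039,
               0.33789766245748182,  -0.07273261951252645),
    stop("unknown wavelet: ", wavelet,
         " (supported: sym4, coif1)"))
  L <- length(lo)
  # quadrature mirror: h_l = (-1)^l g_{L-1-l}
  hi <- rev(lo) * (-1) ^ (seq_len(L) - 1)
  list(lo = lo, hi = hi)
}

# x circularly delayed by s samples: y[t] = x[(t - s) mod N]
circ_shift <- function(x, s) {
  n <- length(x)
  s <- s %% n
  if (s == 0) return(x)
  c(x[(n - s + 1):n], x[1:(n - s)])
}

#' Maximal-overlap discrete wavelet transform
#'
#' Undecimated dyadic decomposition with circular (periodic) boundary
#' handling. Every detail level and the final approximation keep the input
#' length, so the transform is shift-invariant and reconstruction from all
#' components is exact to numerical precision.
#'
#' @param signal A [uniform_signal()].
#' @param wavelet `"sym4"` or `"coif1"`.
#' @param levels Number of decomposition levels,
#'   `<= floor(log2(length(signal)))`.
#' @return An object of class `wavelet_decomposition` with fields `details`
#'   (list of length `levels`, each a numeric vector of input length),
#'   `approximation`, `wavelet`, `fs`, `t0`, `n`.
#' @export
modwt <- function(signal, wavelet = "sym4", levels = 4) {
  stopifnot(inherits(signal, "uniform_signal"))
  x <- signal$values
  n <- length(x)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  if (levels > floor(log2(n)))
    stop(sprintf("too many levels (%d) for signal length %d", levels, n))
  f <- wavelet_filters(wavelet)
  # rescaled filters give an energy-preserving undecimated transform
  g <- f$lo / sqrt(2)
  h <- f$hi / sqrt(2)
  details <- vector("list", levels)
  v <- x
  for (j in seq_len(levels)) {
    step <- 2L ^ (j - 1L)
    w_j <- numeric(n)
    v_j <- numeric(n)
    for (l in seq_along(g)) {
      shifted <- circ_shift(v, (l - 1L) * step)
      w_j <- w_j + h[l] * shifted
      v_j <- v_j + g[l] * shifted
    }
    details[[j]] <- w_j
    v <- v_j
  }
  structure(list(details = details, approximation = v,
                 wavelet = wavelet, fs = signal$fs, t0 = signal$t0, n = n),
            class = "wavelet_decomposition")
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("wavelet_decomposition: %s, %d levels, n = %d, fs = %g Hz\n",
              x$wavelet, length(x$details), x$n, x$fs))
  invisible(x)
}

#' Inverse maximal-overlap transform from selected components
#'
#' Linear in the kept components: reconstructing from disjoint level sets
#' and summing equals reconstructing from their union. Keeping everything
#' returns the original signal; keeping nothing returns zero.
#'
#' @param decomp A [modwt()] result.
#' @param keep_details Integer vector of detail levels to keep (subset of
#'   `1:L`).
#' @param keep_approximation Keep the level-L approximation?
#' @return A [uniform_signal()].
#' @export
reconstruct <- function(decomp, keep_details = seq_along(decomp$details),
                        keep_approximation = TRUE) {
  stopifnot(inherits(decomp, "wavelet_decomposition"))
  L <- length(decomp$details)
  keep_details <- as.integer(keep_details)
  if (length(keep_details) && (any(keep_details < 1L) ||
                               any(keep_details > L)))
    stop("keep_details must be within 1..", L)
  f <- wavelet_filters(decomp$wavelet)
  g <- f$lo / sqrt(2)
  h <- f$hi / sqrt(2)
  n <- decomp$n
  v <- if (keep_approximation) decomp$approximation else numeric(n)
  for (j in L:1) {
    step <- 2L ^ (j - 1L)
    w <- if (j %in% keep_details) decomp$details[[j]] else numeric(n)
    v_prev <- numeric(n)
    for (l in seq_along(g)) {
      # adjoint of the analysis step: advance instead of delay
      v_prev <- v_prev + g[l] * circ_shift(v, -(l - 1L) * step) +
                         h[l] * circ_shift(w, -(l - 1L) * step)
    }
    v <- v_prev
  }
  uniform_signal(v, fs = decomp$fs, t0 = decomp$t0)
}

#' Nominal frequency band of a dyadic decomposition level
#'
#' Detail level `j` passes `[fs / 2^(j+1), fs / 2^j]`; the approximation
#' after `L` levels passes `[0, fs / 2^(L+1)]`.
#'
#' @param fs Sampling rate in Hz.
#' @param level Level index (>= 1).
#' @param kind `"detail"` or `"approximation"`.
#' @return List with `f_lo`, `f_hi` in Hz.
#' @export
band_edges <- function(fs, level, kind = c("detail", "approximation")) {
  kind <- match.arg(kind)
  if (fs <= 0 || level < 1) stop("fs must be > 0 and level >= 1")
  if (kind == "detail")
    list(f_lo = fs / 2 ^ (level + 1), f_hi = fs / 2 ^ level)
  else
    list(f_lo = 0, f_hi = fs / 2 ^ (level + 1))
}

#' Truncate to two decimals for printing band edges
#'
#' Frequency edges are conventionally reported truncated (3.125 prints as
#' 3.12), not rounded.
#' @param x Numeric.
#' @return `x` truncated to two decimals.
#' @export
truncate2 <- function(x) trunc(x * 100) / 100

# Detail levels whose dyadic band overlaps [f_lo, f_hi] at rate fs.
levels_for_band <- function(fs, f_lo, f_hi) {
  j <- 1L
  keep <- integer(0)
  repeat {
    b <- band_edges(fs, j)
    if (b$f_hi <= f_lo) break
    if (b$f_lo < f_hi && b$f_hi > f_lo) keep <- c(keep, j)
    j <- j + 1L
    if (j > 30L) break
  }
  keep
}

#' ECG band filter via wavelet decomposition
#'
#' Decomposes with sym4 (shaped like the QRS complex) and reconstructs
#' without the two finest detail levels (high-frequency noise, 16.25-65 Hz
#' at 130 Hz) and without the approximation (baseline wander below
#' ~0.064 Hz). At 130 Hz this is a 10-level decomposition keeping D3..D10.
#'
#' @param signal ECG as a [uniform_signal()], nominally 130 Hz.
#' @param wavelet Wavelet name (default `"sym4"`).
#' @return Filtered [uniform_signal()].
#' @export
filter_ecg <- function(signal, wavelet = "sym4") {
  stopifnot(inherits(signal, "uniform_signal"))
  fs <- signal$fs
  if (abs(fs - 130) > 5)
    warning(sprintf(
      "filter_ecg tuned for 130 Hz; at fs = %g Hz the dyadic bands shift and level counts are re-derived",
      fs))
  # approximation must sit below ~0.064 Hz; finest kept detail below 16.25 Hz
  L <- ceiling(log2(fs / 0.064)) - 1L
  # drop detail levels lying entirely above 16.25 Hz: fs/2^(j+1) >= 16.25
  n_drop <- max(0L, floor(log2(fs / 16.25) + 1e-9) - 1L)
  if (length(signal$values) < 2 ^ L)
    stop(sprintf("signal too short for %d decomposition levels", L))
  d <- modwt(signal, wavelet = wavelet, levels = L)
  reconstruct(d, keep_details = setdiff(seq_len(L), seq_len(n_drop)),
              keep_approximation = FALSE)
}

#' PPG band filter via wavelet decomposition
#'
#' Decomposes with coif1 (matching the systolic/diastolic pulse shape) and
#' keeps only the detail levels bracketing the useful pulse band
#' 0.78-3.12 Hz (47-187 bpm). At 25 Hz this is a 4-level decomposition
#' keeping D3 and D4.
#'
#' @param signal PPG as a [uniform_signal()], nominally 25 Hz.
#' @param wavelet Wavelet name (default `"coif1"`).
#' @return Filtered [uniform_signal()].
#' @export
filter_ppg <- function(signal, wavelet = "coif1") {
  stopifnot(inherits(signal, "uniform_signal"))
  fs <- signal$fs
  if (abs(fs - 25) > 2)
    warning(sprintf(
      "filter_ppg tuned for 25 Hz; at fs = %g Hz the dyadic bands shift and kept levels are re-derived",
      fs))
  keep <- levels_for_band(fs, 25 / 32, 25 / 8)
  L <- max(keep)
  if (length(signal$values) < 2 ^ L)
    stop(sprintf("signal too short for %d decomposition levels", L))
  d <- modwt(signal, wavelet = wavelet, levels = L)
  reconstruct(d, keep_details = keep, keep_approximation = FALSE)
}
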