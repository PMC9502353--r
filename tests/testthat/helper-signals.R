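# Shared fixtures built in code.

rms <- function(v) sqrt(mean(v ^ 2))

# inner fraction of a vector (drops edge effects)
inner <- function(x, frac = 0.8) {
  n <- length(x)
  lo <- ceiling(n * (1 - frac) / 2)
  x[lo:(n - lo)]
}

make_tone <- function(freq, fs, duration = 60, amp = 1, t0 = 0) {
  t <- seq(0, duration, by = 1 / fs)
  uniform_signal(amp * sin(2 * pi * freq * t), fs = fs, t0 = t0)
}

# brute-force DTW by enumerating all monotone boundary-to-boundary paths
dtw_brute <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    invisible()
  }
  walk(1, 1, 0)
  best
}
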