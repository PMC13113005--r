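# Shared fixtures built in code.

# Reduced-rate study configuration for replicate loops: window statistics,
# not raw sample counts, carry the structure under test.
test_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, sample_rate = 4, ...)
}

# Wrap a bare value vector (with optional times) as an accepted window.
make_window <- function(values, times = seq_along(values) - 1) {
  stream <- tibble::tibble(timestamp = times, mv = values)
  w <- slice_window(stream, end_time = max(times),
                    width = diff(range(times)) + 1, min_samples = 0)
  stopifnot(!is.null(w))
  w
}

# A small paired dataset from a seeded simulated study.
make_test_dataset <- function(seed = 1L, include_peaks = FALSE, ...) {
  st <- simulate_study(test_config(seed = seed, ...))
  build_paired_dataset(st$stream, st$readings, st$era_map,
                       include_peaks = include_peaks)
}

# Brute-force DFT periodogram oracle (O(n^2)); independent of the fft path.
dft_periodogram_oracle <- function(x) {
  m <- length(x)
  x <- x - mean(x)
  ks <- seq_len(floor(m / 2))
  j <- 0:(m - 1)
  vapply(ks, function(k) {
    Mod(sum(x * exp(-2i * pi * k * j / m)))^2 / m
  }, numeric(1))
}

# Brute-force BH step-up oracle following the rule as stated: largest k with
# p_(k) <= k q / m, flag the k smallest.
bh_stepup_oracle <- function(p, m, q) {
  ord <- order(p)
  ps <- p[ord]
  k <- max(c(0, which(ps <= seq_along(ps) * q / m)))
  flags <- logical(length(p))
  if (k > 0) flags[ord[seq_len(k)]] <- TRUE
  flags
}
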