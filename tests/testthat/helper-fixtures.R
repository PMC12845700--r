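# small configurations shared across test files

small_synth <- function(seed = 3, ...) {
  synth_config(n_classes = 3, n_repetitions = 4, motion_duration = 200,
               motion_jitter = 20, rest_duration = 150, rest_jitter = 15,
               boundary_jitter = 15, seed = seed, ...)
}

# brute-force dilated multi-channel cross-correlation + ReLU
conv_oracle <- function(spec, segment) {
  C <- spec$in_channels; k <- spec$k; d <- spec$d; L <- ncol(segment)
  half <- (k - 1) / 2
  out <- matrix(0, spec$n_filters, L)
  for (f in seq_len(spec$n_filters)) {
    for (t in seq_len(L)) {
      acc <- spec$biases[f]
      for (j in seq_len(k)) {
        src <- t + (j - 1 - half) * d
        if (src >= 1 && src <= L)
          for (c in seq_len(C))
            acc <- acc + spec$weights[f, (j - 1) * C + c] * segment[c, src]
      }
      out[f, t] <- max(0, acc)
    }
  }
  out
}

# O(n^2) sample-entropy oracle by explicit template enumeration
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  count <- function(mm) {
    total <- 0
    for (i in 1:(n - m - 1)) {
      for (j in (i + 1):(n - m)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) total <- total + 1
      }
    }
    total
  }
  B <- count(m); A <- count(m + 1)
  if (A <= 0 || B <= 0) return(log((n - m) * (n - m - 1)))
  -log(A / B)
}
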