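#' Zero-phase Butterworth low-pass filter
#'
#' Designs a digital Butterworth low-pass filter and applies it forward and
#' backward (zero phase) so that motion boundaries are not shifted. The
#' pipeline default is a first-order filter with a 1 Hz cutoff, which keeps
#' the sub-1 Hz envelope band carrying the discriminative gesture content.
#'
#' @param x numeric vector.
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order (>= 1).
#' @param fs sampling rate in Hz.
#' @return filtered vector, same length as `x`.
#' @export
lowpass_filter <- function(x, cutoff = 1, order = 1, fs = 100) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie strictly inside (0, fs/2)")
  if (order < 1) stop("order must be >= 1")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding suppresses the forward-backward edge transients
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(6 * fs / cutoff)))
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, ext))
  y[(pad + 1):(pad + n)]
}

# apply lowpass_filter to every channel of a recording
lowpass_recording <- function(rec, cutoff = 1, order = 1) {
  rec$emg <- t(apply(rec$emg, 1, lowpass_filter, cutoff = cutoff,
                     order = order, fs = rec$fs))
  rec
}

#' Cut motion segments from per-sample labels
#'
#' One segment per maximal run of a nonzero label. Sample indices are
#' 1-based and inclusive.
#'
#' @param rec a `recording`.
#' @return list of `motion_segment` objects with `data` (channels x L),
#'   `gesture`, `repetition`, `raw_bounds`, `refined_bounds` (initially
#'   equal to `raw_bounds`).
#' @export
extract_segments <- function(rec) {
  r <- rle(rec$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 0)
  lapply(keep, function(i) {
    on <- starts[i]; off <- ends[i]
    structure(list(data = rec$emg[, on:off, drop = FALSE],
                   gesture = r$values[i],
                   repetition = rec$repetitions[on],
                   raw_bounds = c(on, off),
                   refined_bounds = c(on, off)),
              class = "motion_segment")
  })
}

#' GLR boundary-refinement configuration
#'
#' Rest and motion are modelled as zero-mean Gaussians differing only in
#' variance, fitted on the rectified low-passed signal; a candidate change
#' point is scored by the two-state minus one-state maximized log-likelihood.
#'
#' @param expansion_fraction fraction of the raw segment length added as
#'   search context on each side.
#' @param min_state_len minimum samples per state (>= 2).
#' @param min_stat minimum GLR statistic (2 x log-likelihood gain) for a
#'   channel's detection to be accepted; below it the raw boundary is kept.
#' @param var_floor variance floor guarding the log-likelihood.
#' @return a `glr_config` object.
#' @export
glr_config <- function(expansion_fraction = 0.25, min_state_len = 10,
                       min_stat = 10, var_floor = 1e-12) {
  stopifnot(expansion_fraction >= 0, min_state_len >= 2, var_floor > 0)
  structure(list(expansion_fraction = expansion_fraction,
                 min_state_len = min_state_len, min_stat = min_stat,
                 var_floor = var_floor),
            class = "glr_config")
}

# best single variance change point in x (rectified), states
# [1, c-1] and [c, n]; returns list(change, stat) or NULL if none admissible
glr_scan <- function(x, min_len, var_floor) {
  n <- length(x)
  if (n < 2 * min_len) return(NULL)
  cs <- cumsum(x^2)
  total <- cs[n]
  cand <- (min_len + 1L):(n - min_len + 1L)
  n1 <- cand - 1L
  n2 <- n - n1
  v1 <- cs[cand - 1L] / n1 + var_floor
  v2 <- (total - cs[cand - 1L]) / n2 + var_floor
  ll2 <- -n1 / 2 * log(v1) - n2 / 2 * log(v2)
  ll1 <- -n / 2 * log(total / n + var_floor)
  stat <- 2 * (ll2 - ll1)
  best <- which.max(stat)
  list(change = cand[best], stat = stat[best])
}

#' Refine segment boundaries by multi-channel GLR change-point detection
#'
#' For each channel the onset and offset are located independently by
#' maximizing the two-state variance-change log-likelihood over candidate
#' change points inside a search window expanded around the raw label
#' bounds; channel detections below `min_stat` fall back to the raw bound.
#' Channels are then fused by voting: the earliest detected onset and the
#' latest detected offset become the global refined boundaries. Operates on
#' the rectified signal, so `rec` should already be low-pass filtered.
#'
#' @param rec a `recording` (low-pass filtered).
#' @param seg a `motion_segment` from [extract_segments()].
#' @param cfg a [glr_config()].
#' @param limits optional c(lo, hi) clipping the expanded window (e.g. at
#'   neighbouring segments); defaults to the recording edges.
#' @return the segment with `refined_bounds` set and `data` re-cut from the
#'   refined bounds.
#' @export
refine_boundaries_glr <- function(rec, seg, cfg = glr_config(),
                                  limits = NULL) {
  on <- seg$raw_bounds[1]; off <- seg$raw_bounds[2]
  seg_len <- off - on + 1L
  e <- as.integer(round(cfg$expansion_fraction * seg_len))
  T_total <- ncol(rec$emg)
  lo <- max(1L, on - e); hi <- min(T_total, off + e)
  if (!is.null(limits)) {
    lo <- max(lo, limits[1]); hi <- min(hi, limits[2])
  }
  mid <- as.integer(floor((on + off) / 2))
  n_ch <- nrow(rec$emg)
  onsets <- rep(on, n_ch); offsets <- rep(off, n_ch)
  fell_back <- TRUE
  for (ch in seq_len(n_ch)) {
    x_on <- abs(rec$emg[ch, lo:mid])
    res <- glr_scan(x_on, cfg$min_state_len, cfg$var_floor)
    if (!is.null(res) && res$stat >= cfg$min_stat) {
      onsets[ch] <- lo + res$change - 1L
      fell_back <- FALSE
    }
    x_off <- rev(abs(rec$emg[ch, (mid + 1L):hi]))
    res <- glr_scan(x_off, cfg$min_state_len, cfg$var_floor)
    if (!is.null(res) && res$stat >= cfg$min_stat) {
      offsets[ch] <- hi - res$change + 1L
      fell_back <- FALSE
    }
  }
  if ((hi - lo + 1L) < 2 * cfg$min_state_len) {
    warning("search window shorter than 2*min_state_len; keeping raw bounds")
    refined <- c(on, off)
  } else if (fell_back) {
    refined <- c(on, off)
  } else {
    refined <- c(min(onsets), max(offsets))
  }
  seg$refined_bounds <- refined
  seg$data <- rec$emg[, refined[1]:refined[2], drop = FALSE]
  seg
}

#' Standardize a segment to a fixed window length
#'
#' Shorter segments are zero-padded at the end; longer ones keep their
#' first `L` samples (the onset dynamics carry the gesture).
#'
#' @param seg a `motion_segment`, or a plain channels x T matrix.
#' @param L target length in samples (default 1100).
#' @return same type as the input, with exactly `L` time samples.
#' @export
standardize_length <- function(seg, L = 1100) {
  stopifnot(L >= 1)
  fix <- function(m) {
    nt <- ncol(m)
    if (nt == L) return(m)
    if (nt > L) return(m[, seq_len(L), drop = FALSE])
    cbind(m, matrix(0, nrow(m), L - nt))
  }
  if (inherits(seg, "motion_segment")) {
    seg$data <- fix(seg$data)
    seg
  } else fix(seg)
}

#' Welch power spectral density
#'
#' Hamming-windowed averaged periodogram with 50% segment overlap and a
#' 512-point FFT (the standard diagnostic recipe for sub-5 Hz sEMG
#' envelope spectra). One-sided density scaled so that its integral over
#' frequency approximates the signal variance.
#'
#' @param x numeric vector, length >= `nfft`.
#' @param fs sampling rate in Hz.
#' @param nfft FFT length / window length (default 512).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz, 0..fs/2) and `psd` (power density).
#' @export
welch_psd <- function(x, fs = 100, nfft = 512, overlap = 0.5) {
  n <- length(x)
  if (n < nfft) stop("signal shorter than the analysis window")
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))  # Hamming
  step <- max(1L, as.integer(round(nfft * (1 - overlap))))
  starts <- seq(1L, n - nfft + 1L, by = step)
  U <- sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * w
    X <- fft(seg)
    P <- Mod(X[seq_len(nfft %/% 2 + 1)])^2 / (fs * U)
    P[2:(nfft %/% 2)] <- 2 * P[2:(nfft %/% 2)]      # one-sided
    acc <- acc + P
  }
  list(freq = (0:(nfft %/% 2)) * fs / nfft, psd = acc / length(starts))
}

#' Boundary errors of raw and refined bounds against known truth
#'
#' Matches segments to truth rows by gesture and repetition and reports the
#' absolute onset/offset errors (samples) of the stored label bounds and of
#' the GLR-refined bounds.
#'
#' @param segments list of `motion_segment`s (after refinement).
#' @param truth data frame with `onset`, `offset`, `gesture`, `repetition`.
#' @return data frame with per-segment `raw_err` and `refined_err`
#'   (mean of absolute onset and offset error).
#' @export
boundary_errors <- function(segments, truth) {
  do.call(rbind, lapply(segments, function(sg) {
    row <- truth[truth$gesture == sg$gesture &
                 truth$repetition == sg$repetition, , drop = FALSE]
    if (nrow(row) != 1) return(NULL)
    data.frame(
      gesture = sg$gesture, repetition = sg$repetition,
      raw_err = (abs(sg$raw_bounds[1] - row$onset) +
                 abs(sg$raw_bounds[2] - row$offset)) / 2,
      refined_err = (abs(sg$refined_bounds[1] - row$onset) +
                     abs(sg$refined_bounds[2] - row$offset)) / 2)
  }))
}
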