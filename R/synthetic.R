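#' Synthetic sEMG generator configuration
#'
#' Describes a synthetic multi-channel recording with alternating rest and
#' motion runs. Gesture classes are distinguished by their low-frequency
#' (sub-1 Hz) spectral envelopes, each channel carries a fixed random gain,
#' Gaussian noise is added everywhere, and the stored per-sample labels can
#' be jittered relative to the true activity boundaries so that boundary
#' refinement has something to correct.
#'
#' @param n_classes number of gesture classes (>= 2).
#' @param n_repetitions repetitions of every gesture.
#' @param n_channels electrode channels.
#' @param fs sampling rate in Hz.
#' @param motion_duration mean motion-run length in samples.
#' @param motion_jitter half-range of uniform motion-length jitter (samples).
#' @param rest_duration mean rest-run length in samples.
#' @param rest_jitter half-range of uniform rest-length jitter (samples).
#' @param envelope_band frequency band (Hz) holding the class envelopes.
#' @param channel_gain_spread half-range of per-channel gain around 1.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param boundary_jitter max absolute shift (samples) applied to stored
#'   label boundaries relative to the true activity boundaries.
#' @param seed integer seed; the whole recording is deterministic given it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 8, n_repetitions = 10, n_channels = 10,
                         fs = 100, motion_duration = 500, motion_jitter = 50,
                         rest_duration = 300, rest_jitter = 30,
                         envelope_band = c(0.05, 1),
                         channel_gain_spread = 0.2, noise_sd = 0.1,
                         boundary_jitter = 30, seed = 1L) {
  stopifnot(fs > 0, n_classes >= 2, n_repetitions >= 1, n_channels >= 1,
            noise_sd >= 0, boundary_jitter >= 0,
            channel_gain_spread >= 0)
  if (motion_duration <= 0 || rest_duration <= 0)
    stop("motion_duration and rest_duration must be positive")
  if (envelope_band[1] <= 0 || envelope_band[2] >= fs / 2 ||
      envelope_band[1] >= envelope_band[2])
    stop("envelope_band must lie within (0, fs/2)")
  # label runs must stay separated after jitter
  if (rest_duration - rest_jitter <= 2 * boundary_jitter)
    stop("rest runs too short for the requested boundary_jitter")
  structure(list(n_classes = n_classes, n_repetitions = n_repetitions,
                 n_channels = n_channels, fs = fs,
                 motion_duration = motion_duration,
                 motion_jitter = motion_jitter,
                 rest_duration = rest_duration, rest_jitter = rest_jitter,
                 envelope_band = envelope_band,
                 channel_gain_spread = channel_gain_spread,
                 noise_sd = noise_sd, boundary_jitter = boundary_jitter,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Per-class low-frequency spectral templates
#'
#' Each class gets a distinct dominant frequency on a deterministic grid
#' inside `envelope_band`, plus one to three extra random components with
#' random amplitudes and phases. The motion envelope of a class is the
#' rectified sum of these sinusoids, concentrating the discriminative
#' spectral content below 1 Hz at the defaults.
#'
#' @param n_classes number of classes (>= 2).
#' @param envelope_band frequency band in Hz.
#' @param seed integer seed.
#' @return list of per-class templates with `freqs`, `amps`, `phases` (Hz,
#'   dimensionless, radians).
#' @export
generate_gesture_library <- function(n_classes, envelope_band = c(0.05, 1),
                                     seed = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  stopifnot(envelope_band[1] > 0, envelope_band[2] > envelope_band[1])
  set.seed(as.integer(seed))
  lo <- envelope_band[1]; hi <- envelope_band[2]
  lapply(seq_len(n_classes), function(cl) {
    dom <- lo + (cl - 0.5) / n_classes * (hi - lo)
    n_extra <- sample(1:3, 1)
    list(freqs = c(dom, runif(n_extra, lo, hi)),
         amps = c(1, runif(n_extra, 0.2, 0.6)),
         phases = runif(1 + n_extra, 0, 2 * pi))
  })
}

# rectified sum-of-sinusoids motion envelope at local times t (samples)
class_envelope <- function(template, t, fs) {
  s <- numeric(length(t))
  for (j in seq_along(template$freqs))
    s <- s + template$amps[j] *
      sin(2 * pi * template$freqs[j] * t / fs + template$phases[j])
  abs(s)
}

#' Generate a synthetic recording
#'
#' Builds one continuous recording organised as repetition blocks; within a
#' block every class is executed once, each motion run preceded by a rest
#' run (and a trailing rest closes the block). Motion samples are the class
#' envelope scaled by a fixed per-channel gain and a per-execution amplitude
#' factor, plus Gaussian noise; rest is noise only. Stored labels are
#' shifted from the true boundaries by up to `boundary_jitter` samples.
#'
#' @param config a [synth_config()].
#' @return a `recording`: list with `emg` (channels x T), `fs`, `labels`,
#'   `repetitions` (per-sample, 0 = rest), `truth` (data frame of true
#'   onset/offset/gesture/repetition, 1-based inclusive sample indices) and
#'   `rep_blocks` (sample range of every repetition block).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)
  templates <- generate_gesture_library(cfg$n_classes, cfg$envelope_band,
                                        seed = cfg$seed + 1L)
  gains <- 1 + runif(cfg$n_channels, -1, 1) * cfg$channel_gain_spread

  jit <- function(mean, half) {
    max(2L, as.integer(round(mean + runif(1, -half, half))))
  }
  segs <- list(); cursor <- 0L
  rep_blocks <- matrix(NA_integer_, cfg$n_repetitions, 2)
  for (r in seq_len(cfg$n_repetitions)) {
    block_start <- cursor + 1L
    for (cl in seq_len(cfg$n_classes)) {
      rest_len <- jit(cfg$rest_duration, cfg$rest_jitter)
      mot_len <- jit(cfg$motion_duration, cfg$motion_jitter)
      onset <- cursor + rest_len + 1L
      offset <- onset + mot_len - 1L
      segs[[length(segs) + 1L]] <- list(
        rest_len = rest_len, mot_len = mot_len, onset = onset,
        offset = offset, gesture = cl, repetition = r,
        amp = 1 + rnorm(1, 0, 0.05))
      cursor <- offset
    }
    tail_rest <- jit(cfg$rest_duration, cfg$rest_jitter)
    cursor <- cursor + tail_rest
    rep_blocks[r, ] <- c(block_start, cursor)
  }
  T_total <- cursor

  emg <- matrix(rnorm(cfg$n_channels * T_total, 0, cfg$noise_sd),
                nrow = cfg$n_channels)
  labels <- integer(T_total); reps <- integer(T_total)
  truth <- data.frame(onset = integer(0), offset = integer(0),
                      gesture = integer(0), repetition = integer(0))
  for (sg in segs) {
    idx <- sg$onset:sg$offset
    env <- class_envelope(templates[[sg$gesture]],
                          seq_along(idx) - 1, cfg$fs) * sg$amp
    emg[, idx] <- emg[, idx] + outer(gains, env)
    d_on <- if (cfg$boundary_jitter > 0)
      as.integer(round(runif(1, -cfg$boundary_jitter, cfg$boundary_jitter)))
      else 0L
    d_off <- if (cfg$boundary_jitter > 0)
      as.integer(round(runif(1, -cfg$boundary_jitter, cfg$boundary_jitter)))
      else 0L
    lab_on <- max(1L, sg$onset + d_on)
    lab_off <- min(T_total, sg$offset + d_off)
    labels[lab_on:lab_off] <- sg$gesture
    reps[lab_on:lab_off] <- sg$repetition
    truth <- rbind(truth, data.frame(onset = sg$onset, offset = sg$offset,
                                     gesture = sg$gesture,
                                     repetition = sg$repetition))
  }
  structure(list(emg = emg, fs = cfg$fs, labels = labels,
                 repetitions = reps, truth = truth,
                 rep_blocks = rep_blocks, config = cfg),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples @ %g Hz, %d motion segments\n",
              nrow(x$emg), ncol(x$emg), x$fs,
              if (is.null(x$truth)) sum(rle(x$labels)$values != 0)
              else nrow(x$truth)))
  invisible(x)
}

# keep only the repetition blocks in `reps`, splicing samples and shifting
# truth/block indices accordingly
subset_recording_reps <- function(rec, reps_keep) {
  blocks <- rec$rep_blocks[reps_keep, , drop = FALSE]
  idx <- unlist(lapply(seq_len(nrow(blocks)),
                       function(i) blocks[i, 1]:blocks[i, 2]))
  shift_of <- function(pos) {
    # new index of original sample position (positions must be inside kept blocks)
    match(pos, idx)
  }
  truth <- rec$truth[rec$truth$repetition %in% reps_keep, , drop = FALSE]
  truth$onset <- shift_of(truth$onset)
  truth$offset <- shift_of(truth$offset)
  structure(list(emg = rec$emg[, idx, drop = FALSE], fs = rec$fs,
                 labels = rec$labels[idx], repetitions = rec$repetitions[idx],
                 truth = truth, rep_blocks = NULL, config = rec$config),
            class = "recording")
}

#' Repetition-based train/test benchmark
#'
#' Generates one recording from `config` and splits it by repetition into
#' disjoint train and test recordings. The default held-out repetitions
#' are {2, 5, 10}, the within-subject test protocol used on Ninapro DB1.
#'
#' @param config a [synth_config()].
#' @param test_repetitions repetition ids held out for testing.
#' @return list with `train` and `test` recordings.
#' @export
make_benchmark <- function(config, test_repetitions = c(2, 5, 10)) {
  rec <- generate_recording(config)
  all_reps <- seq_len(config$n_repetitions)
  if (!all(test_repetitions %in% all_reps))
    stop("requested test repetitions absent from the recording")
  train_reps <- setdiff(all_reps, test_repetitions)
  if (length(train_reps) == 0)
    stop("no repetitions left for training")
  train <- subset_recording_reps(rec, train_reps)
  test <- subset_recording_reps(rec, test_repetitions)
  for (part in list(train, test))
    if (length(unique(part$truth$gesture)) < config$n_classes)
      stop("a gesture class is missing from one partition")
  list(train = train, test = test)
}
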