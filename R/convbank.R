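#' Specification of one frozen convolution module
#'
#' A multi-channel dilated 1-D convolution with `n_filters` output filters,
#' "same" zero padding `d*(k-1)/2` (requiring odd `k`), zero biases and
#' Kaiming-Normal weights `N(0, 2/(C_in*k))` frozen at initialization.
#'
#' @param k kernel length (odd).
#' @param d dilation.
#' @param n_filters number of filters (default 256).
#' @param in_channels input channels (default 10).
#' @return a `conv_module_spec` with a `n_filters x (in_channels*k)` weight
#'   matrix (tap-major layout: columns grouped by tap, channels within).
#' @export
conv_module_spec <- function(k, d, n_filters = 256, in_channels = 10) {
  if (k %% 2 == 0) stop("kernel length must be odd for exact same-padding")
  stopifnot(d >= 1, n_filters >= 1, in_channels >= 1)
  W <- matrix(rnorm(n_filters * in_channels * k, 0, sqrt(2 / (in_channels * k))),
              nrow = n_filters)
  structure(list(k = k, d = d, n_filters = n_filters,
                 in_channels = in_channels, weights = W,
                 biases = rep(0, n_filters),
                 padding = d * (k - 1) / 2),
            class = "conv_module_spec")
}

#' Number of frozen parameters of a module (weights + biases)
#' @param spec a `conv_module_spec`.
#' @return integer count `n_filters * (in_channels*k + 1)`.
#' @export
n_params <- function(spec) {
  length(spec$weights) + length(spec$biases)
}

#' Initialize the dual-branch frozen convolution bank
#'
#' Draws independent Kaiming-Normal weights for the raw-signal branch and
#' the IMF branch (identical architecture, separate parameters) from a
#' single seeded random stream, then freezes them. The default multi-scale
#' configuration is (k, d) = (3,1), (5,3), (11,8): local, mid-range and
#' long-range receptive fields.
#'
#' @param configs list of c(k, d) pairs.
#' @param n_filters filters per module (default 256).
#' @param in_channels input channels (default 10).
#' @param seed integer seed; the same seed reproduces the whole bank.
#' @return a `conv_bank` with elements `raw` and `imf` (lists of module
#'   specs), `configs`, `seed`.
#' @export
init_conv_bank <- function(configs = list(c(3, 1), c(5, 3), c(11, 8)),
                           n_filters = 256, in_channels = 10, seed = 42L) {
  for (cf in configs)
    if (cf[1] %% 2 == 0) stop("kernel length must be odd for exact same-padding")
  set.seed(as.integer(seed))
  make_branch <- function() {
    lapply(configs, function(cf)
      conv_module_spec(cf[1], cf[2], n_filters, in_channels))
  }
  structure(list(raw = make_branch(), imf = make_branch(),
                 configs = configs, n_filters = n_filters,
                 in_channels = in_channels, seed = as.integer(seed)),
            class = "conv_bank")
}

#' Dilated multi-channel convolution forward pass
#'
#' Cross-correlation (deep-learning convention, no kernel flip) of a
#' `C_in x L` segment with every filter of the module, summed over input
#' channels, plus bias, followed by ReLU. Same padding keeps the output
#' length at `L`.
#'
#' @param spec a `conv_module_spec`.
#' @param segment `C_in x L` numeric matrix.
#' @return `n_filters x L` activation matrix (post-ReLU).
#' @export
conv_forward <- function(spec, segment) {
  if (nrow(segment) != spec$in_channels)
    stop("segment has ", nrow(segment), " channels; module expects ",
         spec$in_channels)
  L <- ncol(segment); C <- spec$in_channels; k <- spec$k; d <- spec$d
  # im2col: rows grouped by tap (tap-major), matching the weight layout
  Xc <- matrix(0, C * k, L)
  half <- (k - 1) / 2
  for (j in seq_len(k)) {
    off <- (j - 1 - half) * d                     # input index offset
    src <- seq_len(L) + off
    ok <- src >= 1 & src <= L
    rows <- ((j - 1) * C + 1):(j * C)
    Xc[rows, ok] <- segment[, src[ok], drop = FALSE]
  }
  A <- spec$weights %*% Xc + spec$biases
  A[A < 0] <- 0
  A
}

#' GAP and PPV statistics of an activation map
#'
#' GAP is the temporal mean of each filter's activation sequence; PPV is
#' the fraction of strictly positive activations.
#'
#' @param A `n_filters x L` activation matrix.
#' @return list with `gap` and `ppv`, each length `n_filters`.
#' @export
gap_ppv <- function(A) {
  stopifnot(ncol(A) >= 1)
  list(gap = rowMeans(A), ppv = rowMeans(A > 0))
}

#' Extract the fused dual-branch feature vector
#'
#' Per branch and module: convolution forward pass, then the GAP block
#' followed by the PPV block (`2 * n_filters` values per module); modules
#' are concatenated in configuration order, and the raw branch precedes
#' the IMF branch. At the defaults this yields 512 values per module,
#' 1536 per branch and a 3072-dimensional fused vector.
#'
#' @param bank a `conv_bank`.
#' @param raw_seg,imf_seg `C_in x L` standardized segments.
#' @return named numeric feature vector (names encode branch, module,
#'   statistic and filter index).
#' @export
extract_features <- function(bank, raw_seg, imf_seg) {
  for (seg in list(raw_seg, imf_seg))
    if (nrow(seg) != bank$in_channels)
      stop("segment channel count does not match the bank")
  if (ncol(raw_seg) != ncol(imf_seg))
    stop("raw and IMF segments must have equal length")
  one_branch <- function(modules, seg, tag) {
    unlist(lapply(seq_along(modules), function(i) {
      sp <- modules[[i]]
      st <- gap_ppv(conv_forward(sp, seg))
      v <- c(st$gap, st$ppv)
      names(v) <- paste0(tag, "_k", sp$k, "d", sp$d, "_",
                         rep(c("gap", "ppv"), each = sp$n_filters), "_",
                         seq_len(sp$n_filters))
      v
    }))
  }
  c(one_branch(bank$raw, raw_seg, "raw"),
    one_branch(bank$imf, imf_seg, "imf"))
}

#' Select GAP-only, PPV-only or both feature groups by name
#'
#' @param x a named feature vector or a feature matrix with named columns.
#' @param stat `"both"`, `"gap"` or `"ppv"`.
#' @return the subsetted vector/matrix.
#' @export
feature_subset <- function(x, stat = c("both", "gap", "ppv")) {
  stat <- match.arg(stat)
  if (stat == "both") return(x)
  nms <- if (is.matrix(x)) colnames(x) else names(x)
  keep <- grepl(paste0("_", stat, "_"), nms)
  if (is.matrix(x)) x[, keep, drop = FALSE] else x[keep]
}
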