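#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of length-`m` templates
#' within Chebyshev distance `r` (self-matches excluded) and A counts the
#' corresponding length-`m+1` matches. Low values indicate regular,
#' structurally stable series; i.i.d. noise scores high.
#'
#' @param x numeric vector, length > m + 1.
#' @param m embedding dimension (default 2).
#' @param r tolerance; default 0.2 times the standard deviation of `x`.
#' @return entropy in nats. When A or B is zero the (undefined) logarithm
#'   is replaced by the sentinel `log((n-m)*(n-m-1))`, the log of the
#'   reciprocal of the smallest resolvable match ratio.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n <= m + 1) stop("series too short for embedding dimension m")
  if (is.na(r)) r <- 0
  # both counts use the same n - m templates, the standard convention
  # making every (m+1)-match a subset of an m-match
  n_t <- n - m
  count_matches <- function(mm) {
    D <- abs(outer(x[seq_len(n_t)], x[seq_len(n_t)], "-"))
    if (mm > 1)
      for (j in seq_len(mm - 1L))
        D <- pmax(D, abs(outer(x[seq_len(n_t) + j], x[seq_len(n_t) + j], "-")))
    (sum(D <= r) - n_t) / 2                       # exclude self, unordered
  }
  B <- count_matches(m)
  A <- count_matches(m + 1L)
  sentinel <- log((n - m) * (n - m - 1))
  if (A <= 0 || B <= 0) return(sentinel)
  -log(A / B)
}

#' Per-mode selection indicators
#'
#' For each mode: energy ratio `E_i = ||m_i||^2 / sum_j ||m_j||^2`, Pearson
#' correlation `rho_i` with the original signal, and sample entropy `S_i`.
#' Each indicator is min-max normalized across the K modes of the channel;
#' a degenerate range (max = min, including K = 1) maps to 0.5.
#'
#' @param x the original signal.
#' @param modes K x T matrix of modes.
#' @param m,r sample-entropy parameters (see [sample_entropy()]).
#' @return data frame with raw and normalized indicators per mode.
#' @export
compute_indicators <- function(x, modes, m = 2, r = NULL) {
  stopifnot(nrow(modes) >= 1, ncol(modes) == length(x))
  K <- nrow(modes)
  en <- rowSums(modes^2)
  E <- if (sum(en) > 0) en / sum(en) else rep(0, K)
  rho <- vapply(seq_len(K), function(k) {
    if (sd(modes[k, ]) == 0 || sd(x) == 0) {
      warning("constant mode or signal; correlation set to 0")
      return(0)
    }
    cor(modes[k, ], x)
  }, numeric(1))
  S <- vapply(seq_len(K), function(k) {
    xi <- modes[k, ]
    ri <- if (is.null(r)) 0.2 * sd(xi) else r
    sample_entropy(xi, m = m, r = ri)
  }, numeric(1))
  minmax <- function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0.5, length(v)) else (v - min(v)) / rng
  }
  data.frame(mode = seq_len(K), E = E, rho = rho, S = S,
             E_norm = minmax(E), rho_norm = minmax(rho), S_norm = minmax(S))
}

#' Score modes and select the top N
#'
#' `Score_i = w_p * rho'_i + w_e * E_i + w_s * (1 - S'_i)` with weights
#' (0.4, 0.4, 0.2). The energy term uses the min-max normalized `E'_i` by
#' default, consistent with the normalization applied to the other two
#' indicators; set `energy = "raw"` for the unnormalized variant. Modes are
#' ranked by descending score, ties broken by lower mode index.
#'
#' @param ind indicator data frame from [compute_indicators()].
#' @param weights numeric length-3 vector (rho, energy, entropy), must sum
#'   to 1.
#' @param N number of modes to retain (1 <= N <= K).
#' @param energy `"normalized"` (default) or `"raw"`.
#' @return list with `selected` (indices of the top N), `scores` (all K).
#' @export
score_and_select <- function(ind, weights = c(0.4, 0.4, 0.2), N = 1,
                             energy = c("normalized", "raw")) {
  energy <- match.arg(energy)
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  K <- nrow(ind)
  if (N < 1 || N > K) stop("N must lie in [1, K]")
  e_term <- if (energy == "normalized") ind$E_norm else ind$E
  scores <- weights[1] * ind$rho_norm + weights[2] * e_term +
    weights[3] * (1 - ind$S_norm)
  ord <- order(-scores, ind$mode)
  list(selected = ord[seq_len(N)], scores = scores)
}
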