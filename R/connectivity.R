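# Data-driven model inputs: nonlinear-regression association index h2
# (functional coupling), sliding-window signal energy -> node
# excitability, and Pearson dissimilarity between connectivity matrices.

#' Nonlinear association index h2
#'
#' Correlation ratio of a target series on a source series: the range of
#' the source is split into `n_bins` equal-width bins, the piecewise
#' linear regression curve g through the per-bin means of (source,
#' target) is evaluated at every sample, and
#' \deqn{h^2 = 1 - \sum_i (y_i - g(x_i))^2 / \sum_i (y_i - \bar y)^2,}
#' clipped to [0, 1].  h2 captures arbitrary (possibly nonmonotone)
#' dependence of the target on the source and is not symmetric in its
#' arguments.  Empty bins are merged with their nearest nonempty
#' neighbour (they simply contribute no knot).
#'
#' @param x_target series whose variance is to be explained.
#' @param x_source explanatory series (same length).
#' @param n_bins number of equal-width amplitude bins on the source.
#' @return h2 in [0, 1].
#' @examples
#' x <- rnorm(2000)
#' association_index(x^2 + rnorm(2000, sd = 0.05), x)   # close to 1
#' @export
association_index <- function(x_target, x_source, n_bins = 10) {
  stopifnot(length(x_target) == length(x_source), n_bins >= 2)
  if (length(x_target) < 10 * n_bins)
    stop("series too short for ", n_bins, " bins")
  if (var(x_target) == 0) stop("target series has zero variance")
  if (var(x_source) == 0) stop("source series has zero variance")
  edges <- seq(min(x_source), max(x_source), length.out = n_bins + 1)
  bin <- findInterval(x_source, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bx <- tapply(x_source, bin, mean)
  by <- tapply(x_target, bin, mean)
  if (length(bx) < 2) stop("source series collapses into a single bin")
  g <- approx(as.numeric(bx), as.numeric(by), xout = x_source,
              rule = 2)$y
  h2 <- 1 - sum((x_target - g)^2) / sum((x_target - mean(x_target))^2)
  min(max(h2, 0), 1)
}

#' Association matrix of a recording
#'
#' Entry (n, m) is the association index of channel n explained by
#' channel m, computed over a configurable interval of the epoch
#' (default: the whole epoch).  The diagonal is structurally zero and
#' the matrix is in general asymmetric.  Used as the weighted adjacency
#' matrix of the network model for EEG-style data.
#'
#' @param rec a [recording()].
#' @param n_bins bins passed to [association_index()].
#' @param t_start,t_end interval in seconds (defaults: whole epoch).
#' @return N x N matrix with entries in [0, 1], zero diagonal.
#' @export
association_matrix <- function(rec, n_bins = 10, t_start = 0,
                               t_end = NULL) {
  stopifnot(inherits(rec, "recording"))
  n_ch <- nrow(rec$samples)
  if (n_ch < 2) stop("need at least 2 channels")
  n_s <- ncol(rec$samples)
  if (is.null(t_end)) t_end <- n_s / rec$fs
  i0 <- max(1L, floor(t_start * rec$fs) + 1L)
  i1 <- min(n_s, ceiling(t_end * rec$fs))
  seg <- rec$samples[, i0:i1, drop = FALSE]
  A <- matrix(0, n_ch, n_ch, dimnames = list(rec$labels, rec$labels))
  for (n in seq_len(n_ch))
    for (m in seq_len(n_ch))
      if (n != m)
        A[n, m] <- association_index(seg[n, ], seg[m, ], n_bins)
  A
}

#' Pearson dissimilarity between connectivity matrices
#'
#' One minus the Pearson correlation of the vectorised off-diagonal
#' entries; ranges over [0, 2], with 0 for matrices equal up to a
#' positive affine map.
#'
#' @param m1,m2 equal-shape square matrices.
#' @return scalar in [0, 2].
#' @export
pearson_dissimilarity <- function(m1, m2) {
  stopifnot(is.matrix(m1), is.matrix(m2), all(dim(m1) == dim(m2)),
            nrow(m1) == ncol(m1))
  off <- !diag(nrow(m1))
  v1 <- m1[off]; v2 <- m2[off]
  if (var(v1) == 0 || var(v2) == 0)
    stop("off-diagonal entries have zero variance")
  1 - cor(v1, v2)
}

#' Total signal energy per channel over overlapping windows
#'
#' For each channel, the energy \eqn{E^t = \sum x^2} is accumulated over
#' 1-s windows starting at \eqn{t = t_1, t_1 + 0.5, \dots, t_2} (50%
#' overlap, half-open \eqn{[t, t+1)} so overlapping windows never count
#' a sample twice at the shared endpoint), and summed over windows.
#' Computed on the raw signal by default; supplying `band` computes it
#' on the band-passed signal instead.
#'
#' @param rec a [recording()].
#' @param t1,t2 first and last window start, seconds.
#' @param band optional band-pass (Hz pair) applied before squaring.
#' @return named numeric vector of total energies, one per channel, with
#'   the per-window energy matrix in attribute `"windows"`.
#' @export
energy_profile <- function(rec, t1 = 0, t2 = 14, band = NULL) {
  stopifnot(inherits(rec, "recording"), t1 < t2)
  fs <- rec$fs
  n_s <- ncol(rec$samples)
  if ((t2 + 1) * fs > n_s + 1e-9)
    stop("last window [", t2, ", ", t2 + 1, ") exceeds the epoch")
  starts <- seq(t1, t2, by = 0.5)
  X <- rec$samples
  if (!is.null(band)) {
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    X <- t(apply(X, 1, function(v) signal::filtfilt(bf, v)))
  }
  W <- sapply(starts, function(t0) {
    idx <- (floor(t0 * fs) + 1L):(floor((t0 + 1) * fs))
    rowSums(X[, idx, drop = FALSE]^2)
  })
  W <- matrix(W, nrow = nrow(X),
              dimnames = list(rec$labels, paste0("t", starts)))
  E <- rowSums(W)
  attr(E, "windows") <- W
  E
}

#' Excitability profile from channel energies
#'
#' Scales the energy profile affinely to [0.1, 0.2]
#' (\eqn{\hat E = 0.1 + 0.1 (E - \min E)/(\max E - \min E)}) and maps it
#' to node excitability \eqn{\nu_n = 0.3 - \hat E_n}, so the
#' highest-energy channel gets the lowest (most excitable) \eqn{\nu}.
#' A constant energy profile degenerates to \eqn{\hat E \equiv 0.15}
#' with a warning.
#'
#' @param E numeric energy vector (length >= 2).
#' @return list with `E_hat` (in [0.1, 0.2]) and `nu` (in [0.1, 0.2]).
#' @export
excitability_profile <- function(E) {
  stopifnot(is.numeric(E), length(E) >= 2, all(E >= 0))
  rng <- max(E) - min(E)
  if (rng == 0) {
    warning("constant energy profile; using E_hat = 0.15 for all nodes")
    E_hat <- rep(0.15, length(E))
  } else {
    E_hat <- 0.1 + 0.1 * (E - min(E)) / rng
  }
  names(E_hat) <- names(E)
  list(E_hat = E_hat, nu = 0.3 - E_hat)
}
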