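# Recruitment-time geometry and the fast/slow/multi-domino taxonomy.

#' Recruitment pattern from detected onsets
#'
#' Converts per-channel onset times into recruitment times
#' \eqn{t_n = \tau_n - \min(\tau_n)}, the channel order by recruitment,
#' the total recruitment time \eqn{r = \max(t_n)} and the maximum lag
#' \eqn{l}, the largest gap between consecutive ordered recruitment
#' times.
#'
#' @param onsets a `channel_onsets` object or a numeric vector of onset
#'   times in seconds.  All channels must be detected.
#' @return object of class `onset_pattern`: `t`, `order`, `r`, `l`.
#' @examples
#' p <- recruitment_pattern(c(5.0, 5.1, 5.3))
#' c(p$r, p$l)   # 0.3, 0.2
#' @export
recruitment_pattern <- function(onsets) {
  tau <- if (inherits(onsets, "channel_onsets")) onsets$tau else onsets
  stopifnot(is.numeric(tau), length(tau) >= 1)
  if (anyNA(tau))
    stop("onset not detected in all channels; filter the epoch first")
  t_rec <- tau - min(tau)
  ord <- order(t_rec)
  sorted <- t_rec[ord]
  l <- if (length(sorted) > 1) max(diff(sorted)) else 0
  structure(list(t = t_rec, order = ord, r = max(t_rec), l = l),
            class = "onset_pattern")
}

#' @export
print.onset_pattern <- function(x, ...) {
  cat("Onset pattern: r =", signif(x$r, 4), "s, l =", signif(x$l, 4), "s\n")
  invisible(x)
}

#' Linear discriminant boundaries between onset groups
#'
#' Coefficients (intercept, r, l) of the two dividing lines in the
#' (total recruitment time, maximum lag) plane.  The defaults are the
#' published boundaries fitted to the clinical seed set:
#' slow-fast \eqn{L_1 = 2.9644 - 1.5236 r - 16.5419 l} and fast-multi
#' \eqn{L_2 = 31.0766 + 2.301 r - 97.5312 l}.
#'
#' @param c1 length-3 coefficients of L1 (slow-fast line).
#' @param c2 length-3 coefficients of L2 (fast-multi line).
#' @return object of class `lda_boundaries`.
#' @export
lda_boundaries <- function(c1 = c(2.9644, -1.5236, -16.5419),
                           c2 = c(31.0766, 2.301, -97.5312)) {
  stopifnot(length(c1) == 3, length(c2) == 3)
  structure(list(c1 = as.numeric(c1), c2 = as.numeric(c2)),
            class = "lda_boundaries")
}

#' Classify an onset pattern by the discriminant boundaries
#'
#' Evaluates the fast-multi line first: \eqn{L_2 < 0} is multi-domino
#' (multi is defined by the lag feature, so it takes precedence).
#' Otherwise \eqn{L_1 < 0} is slow-domino, else fast-domino.  Boundary
#' ties (L = 0) fall to the fast side.  The sign convention is anchored
#' by unambiguous exemplars of each group: small (r, l) is fast, large r
#' with small l is slow, large l is multi.
#'
#' @param r total recruitment time(s), seconds (vectorised).
#' @param l maximum lag(s), seconds.
#' @param boundaries an [lda_boundaries()] object.
#' @return character vector in `c("fast", "slow", "multi")`.
#' @examples
#' classify_domino(0.2, 0.05)   # "fast"
#' classify_domino(3.0, 0.1)    # "slow"
#' classify_domino(1.0, 0.8)    # "multi"
#' @export
classify_domino <- function(r, l, boundaries = lda_boundaries()) {
  stopifnot(length(r) == length(l), all(r >= 0), all(l >= 0))
  b <- boundaries
  L2 <- b$c2[1] + b$c2[2] * r + b$c2[3] * l
  L1 <- b$c1[1] + b$c1[2] * r + b$c1[3] * l
  ifelse(L2 < 0, "multi", ifelse(L1 < 0, "slow", "fast"))
}

#' Initial threshold grouping of onset patterns
#'
#' The seed rule used before fitting discriminants: a lag of at least
#' 0.4 s makes the pattern multi-domino; otherwise a total recruitment
#' time under 0.5 s is fast-domino and anything longer slow-domino.
#'
#' @inheritParams classify_domino
#' @return character vector in `c("fast", "slow", "multi")`.
#' @export
initial_grouping <- function(r, l) {
  stopifnot(length(r) == length(l), all(r >= 0), all(l >= 0))
  ifelse(l >= 0.4, "multi", ifelse(r < 0.5, "fast", "slow"))
}

#' Refit discriminant boundaries from labelled patterns
#'
#' Fits two pairwise linear discriminants on (r, l) features with equal
#' class priors -- slow vs fast for L1, fast vs multi for L2 -- and
#' returns the boundaries in the same `a + b*r + c*l` form as
#' [lda_boundaries()], oriented so the fast side is positive.
#'
#' If one of the two pairs has no data (e.g. no multi-domino patterns in
#' the batch), the corresponding published default line is kept and the
#' attribute `"refitted"` records which lines were actually fitted.
#'
#' @param r,l numeric feature vectors.
#' @param labels character vector in `c("fast", "slow", "multi")`.
#' @return an [lda_boundaries()] object with attribute `"fits"` holding
#'   the underlying [MASS::lda()] objects and `"refitted"` naming the
#'   lines estimated from the data.
#' @export
fit_lda_boundaries <- function(r, l, labels) {
  stopifnot(length(r) == length(l), length(labels) == length(r))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2 || length(r) < 3)
    stop("need at least 3 points from at least 2 classes")

  pair_line <- function(keep_a, keep_b) {
    sel <- labels %in% c(keep_a, keep_b)
    if (sum(labels[sel] == keep_a) < 2 || sum(labels[sel] == keep_b) < 2)
      return(NULL)
    X <- cbind(r = r[sel], l = l[sel])
    g <- factor(labels[sel], levels = c(keep_a, keep_b))
    fit <- MASS::lda(X, grouping = g, prior = c(0.5, 0.5))
    w <- fit$scaling[, 1]
    mid <- colMeans(fit$means)        # midpoint of projected class means
    a <- -sum(w * mid)
    # orient: keep_a ("fast") side positive
    mu_a <- fit$means[1, ]
    if (a + sum(w * mu_a) < 0) { w <- -w; a <- -a }
    list(coefs = c(a, w[1], w[2]), fit = fit)
  }

  l1 <- pair_line("fast", "slow")
  l2 <- pair_line("fast", "multi")
  if (is.null(l1) && is.null(l2))
    stop("too few points in every class pair")
  defaults <- lda_boundaries()
  out <- lda_boundaries(c1 = if (is.null(l1)) defaults$c1 else l1$coefs,
                        c2 = if (is.null(l2)) defaults$c2 else l2$coefs)
  attr(out, "fits") <- list(L1 = l1$fit, L2 = l2$fit)
  attr(out, "refitted") <- c("L1", "L2")[!c(is.null(l1), is.null(l2))]
  out
}
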