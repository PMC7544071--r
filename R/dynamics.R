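# Intrinsic single-node dynamics: truncated Hopf (Bautin) normal form
#
#   f(z; nu) = (-nu + i*omega) z + 2 z |z|^2 - z |z|^4,  z in C
#
# For 0 < nu < 1 the node is bistable: a stable equilibrium at the origin
# (background state) coexists with a stable limit cycle (seizure state),
# separated by an unstable limit cycle.

#' Drift of a single bistable node
#'
#' Evaluates the deterministic vector field of the truncated Hopf normal
#' form \eqn{f(z;\nu) = (-\nu + i\omega) z + 2 z |z|^2 - z |z|^4}.
#'
#' @param z complex state (vectorised).
#' @param nu node excitability.  Any real value is accepted here; network
#'   simulation restricts to the bistable range (0, 1).
#' @param omega angular frequency of the seizure oscillation.  Transitions
#'   do not depend on the phase, so the default is 0.
#' @return complex velocity, same length as `z`.
#' @examples
#' hopf_drift(1 + 0i, nu = 0.15)   # 0.85
#' @export
hopf_drift <- function(z, nu, omega = 0) {
  if (!is.numeric(z) && !is.complex(z))
    stop("`z` must be numeric or complex")
  z <- as.complex(z)
  if (any(!is.finite(Re(z))) || any(!is.finite(Im(z))))
    stop("`z` must be finite")
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu),
            is.numeric(omega), length(omega) == 1L, is.finite(omega))
  a2 <- Mod(z)^2
  (complex(real = -nu, imaginary = omega)) * z + 2 * z * a2 - z * a2^2
}

#' Radial equilibria of the node model
#'
#' Roots of the radial system \eqn{r' = -\nu r + 2 r^3 - r^5} with their
#' stability.  The origin is always an equilibrium (stable for
#' \eqn{\nu > 0}).  For \eqn{0 < \nu < 1} the nonzero roots
#' \eqn{r^2 = 1 \pm \sqrt{1-\nu}} form the unstable (inner) and stable
#' (outer) limit cycles of the planar system; at \eqn{\nu = 1} they
#' collide in a saddle-node of limit cycles and for \eqn{\nu \le 0} only
#' the outer cycle survives.
#'
#' Stability labels come from the sign of the derivative of the radial
#' velocity at each root; a zero derivative is reported as "degenerate".
#'
#' @param nu excitability (any real scalar).
#' @return data frame with columns `radius`, `stability`.
#' @examples
#' radial_equilibria(0.75)   # radii 0, sqrt(0.5), sqrt(1.5)
#' @export
radial_equilibria <- function(nu) {
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu))
  g_prime <- function(r) -nu + 6 * r^2 - 5 * r^4
  label <- function(d) {
    if (abs(d) < 1e-12) "degenerate" else if (d < 0) "stable" else "unstable"
  }
  radii <- 0
  if (nu <= 1) {
    disc <- sqrt(1 - nu)
    r2 <- c(1 - disc, 1 + disc)
    r2 <- r2[r2 > 0]
    radii <- c(radii, sqrt(unique(r2)))
  }
  out <- data.frame(radius = radii,
                    stability = vapply(radii, function(r) {
                      if (r == 0) {
                        # r = 0: stability of the origin from the linear term
                        if (nu > 0) "stable" else if (nu < 0) "unstable"
                        else "degenerate"
                      } else label(g_prime(r))
                    }, character(1)),
                    stringsAsFactors = FALSE)
  out[order(out$radius), , drop = FALSE]
}

#' Bifurcation points of the node model
#'
#' The equilibrium at the origin loses stability in a subcritical Hopf
#' bifurcation where the real part of the linearisation eigenvalue
#' \eqn{-\nu + i\omega} vanishes; the stable and unstable limit cycles
#' collide in a saddle-node of limit cycles where the discriminant
#' \eqn{1 - \nu} of the nonzero radial roots vanishes.  Both points are
#' located numerically by root finding, which doubles as a consistency
#' check of the analytic bifurcation structure.
#'
#' @return named numeric vector `c(hopf = 0, snlc = 1)`.
#' @export
bifurcation_points <- function() {
  # sign change of the radial drift derivative at r = 0: d/dr(-nu r + ...) = -nu
  hopf <- stats::uniroot(function(nu) -nu, c(-1, 1), tol = 1e-12)$root
  # collision of the nonzero radial roots: discriminant 1 - nu = 0
  snlc <- stats::uniroot(function(nu) 1 - nu, c(0, 2), tol = 1e-12)$root
  c(hopf = hopf, snlc = snlc)
}

#' Bifurcation diagram of the node model over an excitability grid
#'
#' Tabulates all radial equilibria over a grid of `nu` values, suitable
#' for plotting the bistable wedge.  Optionally written as delimited text.
#'
#' @param nu numeric vector of excitability values.
#' @param file optional path; if given the table is written as
#'   tab-separated text.
#' @return data frame with columns `nu`, `radius`, `stability`.
#' @export
bifurcation_diagram <- function(nu = seq(-0.25, 1.25, by = 0.01),
                                file = NULL) {
  rows <- lapply(nu, function(v) {
    eq <- radial_equilibria(v)
    cbind(nu = v, eq)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  out
}
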