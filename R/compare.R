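# Quantitative model-data comparison: scaled recruitment curves, the
# least-squares distance d, grouped bootstrap protocol, Mann-Whitney
# comparisons and parameter sweeps with d / P_V maps.

#' Scale a time vector by its maximum
#'
#' @param v nonnegative numeric vector with `max(v) > 0`.
#' @return `v / max(v)`; the maximum of the result is 1.
#' @export
scale_times <- function(v) {
  stopifnot(is.numeric(v))
  m <- max(v, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop("cannot scale: max(v) is not positive")
  v / m
}

#' Least-squares distance between scaled recruitment curves
#'
#' Sum of squared differences of position-matched entries,
#' \eqn{d = \sum_n (\mathrm{model}_n - \mathrm{data}_n)^2}.  Both inputs
#' are expected on the scaled-to-[0, 1] convention.
#'
#' @param model,data equal-length numeric vectors.
#' @return nonnegative scalar.
#' @export
recruitment_distance <- function(model, data) {
  if (length(model) != length(data))
    stop("model and data vectors differ in length")
  sum((model - data)^2)
}

#' Grouped distance with bootstrap confidence interval
#'
#' The EEG-style comparison protocol: the K realizations are split into
#' `n_groups` consecutive groups (default 20 groups of 50 for K = 1000);
#' in each group the per-node mean recruitment times are computed,
#' ordered, scaled by their maximum, and compared against the sorted,
#' scaled data curve with [recruitment_distance()].  Reported are all
#' group distances, their median, and a seeded percentile bootstrap 95%
#' confidence interval of the median.
#'
#' @param ensemble an `escape_ensemble` run in `all_escape` mode.
#' @param data_times scaled data recruitment curve, sorted ascending.
#' @param n_groups number of groups (K must be divisible).
#' @param n_boot bootstrap resamples for the CI of the median.
#' @param seed RNG seed for the bootstrap.
#' @param ordering `"per_group"` sorts node means within each group
#'   before comparison (electrodes unlabelled); `"global"` keeps node
#'   identity and compares position-matched.
#' @return object of class `comparison_result`: `d_values`, `d_median`,
#'   `ci`, `n_groups`, `group_size`.
#' @export
grouped_distance <- function(ensemble, data_times, n_groups = 20,
                             n_boot = 10000, seed = 1L,
                             ordering = c("per_group", "global")) {
  ordering <- match.arg(ordering)
  stopifnot(inherits(ensemble, "escape_ensemble"))
  tau <- ensemble$tau
  K <- nrow(tau)
  if (K < n_groups) stop("fewer realizations than groups")
  if (K %% n_groups != 0)
    stop("K = ", K, " is not divisible into ", n_groups, " groups")
  gsize <- K %/% n_groups
  data_scaled <- scale_times(data_times)

  t_rec <- sweep(tau, 1, apply(tau, 1, min, na.rm = TRUE), "-")
  d_values <- vapply(seq_len(n_groups), function(g) {
    rows <- ((g - 1) * gsize + 1):(g * gsize)
    Tg <- colMeans(t_rec[rows, , drop = FALSE], na.rm = TRUE)
    if (ordering == "per_group") Tg <- sort(Tg)
    recruitment_distance(scale_times(Tg), data_scaled)
  }, numeric(1))

  med <- stats::median(d_values)
  ci <- local({
    set.seed(seed)
    meds <- replicate(n_boot,
                      stats::median(sample(d_values, replace = TRUE)))
    quantile(meds, c(0.025, 0.975), names = FALSE)
  })
  structure(list(d_values = d_values, d_median = med, ci = ci,
                 n_groups = n_groups, group_size = gsize),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Grouped model-data distance: median d =", signif(x$d_median, 4),
      " 95% CI [", signif(x$ci[1], 4), ",", signif(x$ci[2], 4), "]\n")
  cat("  (", x$n_groups, "groups of", x$group_size, ")\n")
  invisible(x)
}

#' Compare two sets of model-data distances
#'
#' Two-sided Mann-Whitney U test of the null hypothesis that the two
#' sets of d values come from continuous distributions with equal
#' medians.
#'
#' @param d1,d2 nonempty numeric vectors.
#' @return p-value.
#' @export
compare_distance_sets <- function(d1, d2) {
  stopifnot(length(d1) > 0, length(d2) > 0)
  suppressWarnings(
    wilcox.test(d1, d2, alternative = "two.sided", exact = NULL)$p.value)
}

#' Sweep a gradient parameter plane, mapping d and P_V
#'
#' For every grid point, builds the 16-node (or `n_nodes`-node) chain
#' with either an excitability gradient (Eq.-5-style: `nu0` x `dnu`,
#' constant coupling `A_const`) or a coupling gradient (Eq.-6-style:
#' `A0` x `dA`, constant excitability `nu_const`), simulates an
#' ensemble, and records the least-squares distance of the scaled mean
#' recruitment curve to the data together with the ventral-initiation
#' proportion.  Iso-contours of both maps are extracted at the requested
#' levels.
#'
#' @param kind `"excitability"` or `"coupling"`.
#' @param par1,par2 grid vectors: (nu0, dnu) or (A0, dA).
#' @param data scaled data recruitment curve (length `n_nodes`),
#'   position-matched along the chain.
#' @param config a [sim_config()]; `all_escape` mode is required since
#'   both d and P_V come from the same ensembles.
#' @param n_nodes chain length.
#' @param A_const constant coupling for excitability sweeps.
#' @param nu_const constant excitability for coupling sweeps.
#' @param ventral node indices counted as ventral initiation.
#' @param d_levels,pv_levels contour levels.
#' @return object of class `sweep_result` with `d_grid`, `pv_grid`,
#'   `censored_grid`, axes, and `contours` (lists of polylines from
#'   [grDevices::contourLines()]).
#' @export
parameter_sweep <- function(kind = c("excitability", "coupling"),
                            par1, par2, data, config = sim_config(),
                            n_nodes = 16, A_const = 0.1, nu_const = 0.2,
                            ventral = seq_len(n_nodes %/% 2),
                            d_levels = 0.2, pv_levels = 0.86) {
  kind <- match.arg(kind)
  stopifnot(length(data) == n_nodes)
  d_grid <- pv_grid <- cens_grid <-
    matrix(NA_real_, length(par1), length(par2),
           dimnames = list(signif(par1, 8), signif(par2, 8)))
  data_scaled <- scale_times(data)
  for (i in seq_along(par1)) {
    for (j in seq_along(par2)) {
      res <- tryCatch({
        spec <- if (kind == "excitability") {
          network_spec(chain_adjacency(n_nodes, A_const),
                       excitability_gradient(n_nodes, par1[i], par2[j]))
        } else {
          network_spec(chain_adjacency(n_nodes, par1[i], par2[j]),
                       rep(nu_const, n_nodes))
        }
        ens <- simulate_ensemble(spec, config)
        s <- summarize_ensemble(ens, ventral = ventral)
        list(d = recruitment_distance(s$T_hat, data_scaled),
             pv = s$P_V, cens = s$censored_fraction)
      }, error = function(e) e)
      if (!inherits(res, "error")) {
        d_grid[i, j] <- res$d
        pv_grid[i, j] <- res$pv
        cens_grid[i, j] <- res$cens
      }
    }
  }
  contours <- list(
    d = if (all(is.na(d_grid))) list() else
      grDevices::contourLines(par1, par2, d_grid, levels = d_levels),
    pv = if (all(is.na(pv_grid))) list() else
      grDevices::contourLines(par1, par2, pv_grid, levels = pv_levels))
  structure(list(kind = kind, par1 = par1, par2 = par2,
                 d_grid = d_grid, pv_grid = pv_grid,
                 censored_grid = cens_grid, contours = contours),
            class = "sweep_result")
}
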