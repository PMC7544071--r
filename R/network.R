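# Network construction and stochastic ensemble simulation.
#
# The network couples bistable nodes diffusively,
#
#   dz_n = [ f(z_n; nu_n) + beta * sum_m A[n,m] (z_m - z_n) ] dt + alpha dW_n
#
# and the quantity of interest is the first time each node's |z_n|
# exceeds the escape threshold xi, starting from the all-background state
# z = 0.

#' Nearest-neighbour chain adjacency with optional weight gradient
#'
#' Builds the bidirectional chain used for the mEC-style network:
#' \eqn{A_{n,n+1} = A_{n+1,n} = A^0 + (n-1)\,\delta A} for
#' \eqn{n = 1, \dots, N-1}, all other entries zero.  Pairs listed in
#' `severed` have their weights zeroed in both directions, modelling an
#' anatomical cut between the corresponding nodes.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param A0 weight of the first link (nodes 1-2).
#' @param dA per-link increment of the weight gradient.
#' @param severed list of length-2 integer vectors (or a single such
#'   vector); each names an undirected adjacent pair to disconnect.
#' @return `n_nodes` x `n_nodes` numeric matrix.
#' @examples
#' A <- chain_adjacency(16, 0.1)              # homogeneous chain
#' A2 <- chain_adjacency(16, 0.1, severed = c(8, 9))
#' @export
chain_adjacency <- function(n_nodes, A0, dA = 0, severed = NULL) {
  stopifnot(n_nodes >= 2, is.numeric(A0), is.numeric(dA))
  w <- A0 + (seq_len(n_nodes - 1) - 1) * dA
  if (any(w < 0))
    stop("coupling gradient produces negative weights (first at link ",
         which(w < 0)[1], ")")
  A <- matrix(0, n_nodes, n_nodes)
  for (n in seq_len(n_nodes - 1)) {
    A[n, n + 1] <- w[n]
    A[n + 1, n] <- w[n]
  }
  if (!is.null(severed)) {
    if (!is.list(severed)) severed <- list(severed)
    for (p in severed) {
      stopifnot(length(p) == 2)
      A[p[1], p[2]] <- 0
      A[p[2], p[1]] <- 0
    }
  }
  A
}

#' Linear excitability gradient along the chain
#'
#' \eqn{\nu_n = \nu^0 + (n-1)\,\delta\nu}.  All values must stay inside
#' the bistable range (0, 1).
#'
#' @param n_nodes number of nodes.
#' @param nu0 excitability of node 1.
#' @param dnu per-node increment.
#' @return numeric vector of length `n_nodes`.
#' @export
excitability_gradient <- function(n_nodes, nu0, dnu = 0) {
  stopifnot(n_nodes >= 1, is.numeric(nu0), is.numeric(dnu))
  nu <- nu0 + (seq_len(n_nodes) - 1) * dnu
  bad <- which(nu <= 0 | nu >= 1)
  if (length(bad))
    stop("excitability outside (0, 1) at node ", bad[1],
         " (nu = ", signif(nu[bad[1]], 4), ")")
  nu
}

#' Network specification
#'
#' Bundles the coupling matrix, excitability vector and global parameters
#' of the stochastic network model, validating the invariants the
#' simulation relies on: nonnegative weights with a zero diagonal,
#' excitabilities in the bistable range (0, 1), and nonnegative noise and
#' coupling scales.
#'
#' @param A coupling-weight matrix; entry (n, m) is the input weight from
#'   node m to node n.
#' @param nu excitability vector, one value per node, each in (0, 1).
#' @param beta global coupling scale (>= 0); beta = 0 disconnects nodes.
#' @param alpha noise amplitude (>= 0); the study value is 0.05.
#' @param omega shared angular frequency (default 0: escape does not
#'   depend on phase).
#' @return object of class `network_spec`.
#' @export
network_spec <- function(A, nu, beta = 1, alpha = 0.05, omega = 0) {
  A <- as.matrix(A)
  stopifnot(is.numeric(A), nrow(A) == ncol(A), is.numeric(nu))
  if (length(nu) == 1L) nu <- rep(nu, nrow(A))
  if (length(nu) != nrow(A))
    stop("`nu` must have one entry per node")
  if (any(A < 0)) stop("coupling weights must be nonnegative")
  if (any(diag(A) != 0)) stop("self-coupling A[n,n] must be zero")
  if (any(nu <= 0 | nu >= 1))
    stop("all excitabilities must lie in (0, 1) for bistable operation")
  stopifnot(beta >= 0, alpha >= 0, is.finite(omega))
  structure(list(A = A, nu = as.numeric(nu), beta = beta, alpha = alpha,
                 omega = omega, N = nrow(A)),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("Bistable-network specification\n")
  cat("  nodes:", x$N, " links:", sum(x$A != 0) / 2, "\n")
  cat("  nu:   ", paste(signif(range(x$nu), 4), collapse = " - "), "\n")
  cat("  beta:", x$beta, " alpha:", x$alpha, " omega:", x$omega, "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Numerical settings for the stochastic Heun ensemble integration.
#'
#' Noise convention: by default the Wiener process is complex with
#' independent real and imaginary components, each increment distributed
#' Normal(0, h) and multiplied by `alpha`.  A real-component-only
#' convention is selectable for comparison.
#'
#' @param h integration step in model time (study value 1e-3).
#' @param t_max horizon; realizations whose nodes have not all escaped by
#'   `t_max` are censored.
#' @param xi escape threshold on |z| (study value 0.5).
#' @param K number of realizations (study value 1000).
#' @param seed integer seed for the counter-based per-realization RNG.
#' @param stop_mode `"all_escape"` integrates until every node has
#'   crossed (or `t_max`); `"first_escape"` halts at the first crossing
#'   of any node, which is sufficient for initiation-site statistics and
#'   orders of magnitude cheaper.
#' @param noise `"complex"` (default) or `"real"`, see Details.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(h = 1e-3, t_max = 5000, xi = 0.5, K = 1000,
                       seed = 1L, stop_mode = c("all_escape", "first_escape"),
                       noise = c("complex", "real")) {
  stop_mode <- match.arg(stop_mode)
  noise <- match.arg(noise)
  stopifnot(h > 0, t_max > 0, xi > 0, K >= 1)
  seed <- as.integer(seed)
  structure(list(h = h, t_max = t_max, xi = xi, K = as.integer(K),
                 seed = seed, stop_mode = stop_mode, noise = noise),
            class = "sim_config")
}

#' Simulate an ensemble of escape-time realizations
#'
#' Integrates the coupled network with the stochastic Heun
#' predictor-corrector (the deterministic drift is evaluated at the
#' current state and at the Euler predictor; the same Wiener increment is
#' added once per step) from \eqn{z_n(0) = 0}, recording per node the
#' first time \eqn{|z_n| > \xi}.  Each realization uses an independent,
#' reproducible random stream derived from `config$seed` and the
#' realization index, so results do not depend on execution order.
#'
#' @param spec a [network_spec()].
#' @param config a [sim_config()].
#' @return object of class `escape_ensemble` with elements `tau` (K x N
#'   matrix of first-crossing times, `NA` where censored), `censored`
#'   (K x N logical), `diverged` (per-realization blow-up flag), and the
#'   spec/config used.
#' @examples
#' spec <- network_spec(chain_adjacency(4, 0.1), nu = 0.14)
#' ens <- simulate_ensemble(spec, sim_config(K = 5, t_max = 200,
#'                                           stop_mode = "first_escape"))
#' @export
simulate_ensemble <- function(spec, config = sim_config()) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "sim_config"))
  res <- .heun_escape_cpp(spec$A, spec$beta, spec$nu, spec$omega,
                          spec$alpha, config$h, config$t_max, config$xi,
                          config$K, config$seed %/% 65536L,
                          config$seed %% 65536L,
                          config$stop_mode == "first_escape",
                          config$noise == "real")
  if (any(res$diverged == 1))
    warning(sum(res$diverged), " realization(s) aborted after |z| > 10")
  structure(list(tau = res$tau, censored = res$censored,
                 diverged = as.logical(res$diverged),
                 spec = spec, config = config),
            class = "escape_ensemble")
}

#' @export
print.escape_ensemble <- function(x, ...) {
  cat("Escape-time ensemble:", nrow(x$tau), "realizations x",
      ncol(x$tau), "nodes (", x$config$stop_mode, ")\n")
  cat("  censored entries:", signif(mean(x$censored), 3), "\n")
  invisible(x)
}

#' Summarise an escape-time ensemble
#'
#' Computes, per realization, recruitment times
#' \eqn{t_n = \tau_n - \min_m \tau_m}; averages them over non-censored
#' realizations into mean recruitment times \eqn{T_n}; scales by the
#' maximum so \eqn{\max(\hat T_n) = 1}; and identifies the first-escaping
#' node of every realization together with the ventral-initiation
#' proportion \eqn{P_V} when a ventral node set is supplied.
#'
#' Realizations in which no node escaped carry no information and are
#' dropped (their fraction is reported).  In `first_escape` ensembles
#' only the first-crossing node is observed, so `T` is unavailable and
#' only initiation statistics are returned.
#'
#' @param ensemble an [simulate_ensemble()] result.
#' @param ventral integer set of node indices counted as ventral
#'   (e.g. `1:8` for the 16-node chain); `NULL` skips `P_V`.
#' @return object of class `ensemble_summary`: `T`, `SE`, `T_hat`,
#'   `first_node`, `P_V`, `censored_fraction`.
#' @export
summarize_ensemble <- function(ensemble, ventral = NULL) {
  stopifnot(inherits(ensemble, "escape_ensemble"))
  tau <- ensemble$tau
  K <- nrow(tau); N <- ncol(tau)
  any_esc <- rowSums(!is.na(tau)) > 0
  if (!any(any_esc)) stop("all realizations fully censored")

  first_node <- rep(NA_integer_, K)
  first_node[any_esc] <- apply(tau[any_esc, , drop = FALSE], 1, which.min)
  pv <- NULL
  if (!is.null(ventral))
    pv <- mean(first_node[any_esc] %in% ventral)

  first_escape <- ensemble$config$stop_mode == "first_escape"
  T_mean <- SE <- T_hat <- NULL
  if (!first_escape) {
    row_min <- rep(NA_real_, K)
    row_min[any_esc] <- apply(tau[any_esc, , drop = FALSE], 1, min,
                              na.rm = TRUE)
    t_rec <- sweep(tau, 1, row_min, "-")
    n_obs <- colSums(!is.na(t_rec))
    if (all(n_obs == 0)) stop("all realizations fully censored")
    T_mean <- colMeans(t_rec, na.rm = TRUE)
    SE <- apply(t_rec, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) <= 1) 0 else sd(v) / sqrt(length(v))
    })
    if (max(T_mean, na.rm = TRUE) <= 0)
      stop("degenerate scaling: all nodes escape simultaneously in every realization")
    T_hat <- T_mean / max(T_mean, na.rm = TRUE)
  }

  structure(list(T = T_mean, SE = SE, T_hat = T_hat,
                 first_node = first_node, P_V = pv,
                 censored_fraction = mean(ensemble$censored),
                 n_informative = sum(any_esc)),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble summary\n")
  if (!is.null(x$T)) {
    cat("  mean recruitment times T_n:\n")
    print(signif(x$T, 4))
  }
  if (!is.null(x$P_V)) cat("  P_V:", signif(x$P_V, 4), "\n")
  cat("  censored fraction:", signif(x$censored_fraction, 3), "\n")
  invisible(x)
}
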