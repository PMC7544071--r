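test_that("chain adjacency reproduces gradients and severing", {
  A <- chain_adjacency(16, 0.1)
  expect_equal(sum(A != 0), 30)
  expect_true(all(A[A != 0] == 0.1))
  expect_equal(A, t(A))

  Ag <- chain_adjacency(16, 0.08, 0.005)
  expect_equal(Ag[1, 2], 0.08)
  expect_equal(Ag[15, 16], 0.08 + 14 * 0.005)
  expect_equal(Ag[16, 15], 0.15)

  As <- chain_adjacency(16, 0.1, severed = c(8, 9))
  expect_equal(As[8, 9], 0)
  expect_equal(As[9, 8], 0)
  expect_equal(sum(As != A), 2)

  expect_error(chain_adjacency(16, 0.01, -0.005), "negative")
})

test_that("excitability gradient stays in the bistable range", {
  nu <- excitability_gradient(16, 0.14, 0.002)
  expect_equal(nu[1], 0.14)
  expect_equal(nu[16], 0.17)
  expect_equal(excitability_gradient(5, 0.3), rep(0.3, 5))
  expect_error(excitability_gradient(16, 0.99, 0.01), "node 2")
})

test_that("network spec validates its invariants", {
  A <- chain_adjacency(4, 0.1)
  expect_s3_class(network_spec(A, 0.2), "network_spec")
  expect_error(network_spec(A, 1.2), "\\(0, 1\\)")
  expect_error(network_spec(A, c(0.2, 0.2)), "per node")
  expect_error(network_spec(-A, 0.2), "nonnegative")
  Ad <- A; diag(Ad) <- 0.1
  expect_error(network_spec(Ad, 0.2), "self-coupling")
})

test_that("noiseless ensembles never leave the background state", {
  spec <- network_spec(chain_adjacency(4, 0.1), 0.2, alpha = 0)
  ens <- simulate_ensemble(spec, sim_config(K = 3, t_max = 5))
  expect_true(all(is.na(ens$tau)))
  expect_true(all(ens$censored))
})

test_that("ensembles are reproducible from the seed", {
  spec <- network_spec(chain_adjacency(4, 0.1), 0.12)
  cfg <- sim_config(K = 8, t_max = 200, seed = 99)
  e1 <- simulate_ensemble(spec, cfg)
  e2 <- simulate_ensemble(spec, cfg)
  expect_identical(e1$tau, e2$tau)
  e3 <- simulate_ensemble(spec, sim_config(K = 8, t_max = 200, seed = 100))
  expect_false(identical(e1$tau, e3$tau))
})

test_that("the simulator's normal stream is standard normal", {
  x <- dominonet:::.sim_rnorm_cpp(200000L, 42, 0, 1L)
  expect_lt(abs(mean(x)), 0.01)
  expect_lt(abs(sd(x) - 1), 0.01)
  expect_lt(abs(mean(x^3)), 0.03)
  expect_lt(abs(mean(x^4) - 3), 0.1)
  expect_gt(ks.test(x[1:50000], pnorm)$p.value, 0.01)
})

test_that("Heun escape times agree with an Euler-Maruyama oracle", {
  # single uncoupled node; oracle at a finer step
  nu <- 0.14; alpha <- 0.05; xi <- 0.5
  spec <- network_spec(matrix(0, 1, 1), nu, alpha = alpha)
  ens <- simulate_ensemble(spec, sim_config(h = 1e-3, t_max = 2000,
                                            xi = xi, K = 400, seed = 5,
                                            stop_mode = "all_escape"))
  tau_heun <- ens$tau[, 1]
  tau_em <- em_escape_single(nu, alpha, h = 1e-4, t_max = 2000, xi = xi,
                             K = 250, seed = 17)
  expect_lt(mean(is.na(tau_heun)), 0.02)
  expect_lt(mean(is.na(tau_em)), 0.02)
  tau_heun <- tau_heun[!is.na(tau_heun)]
  tau_em <- tau_em[!is.na(tau_em)]
  se <- sqrt(var(tau_heun) / length(tau_heun) + var(tau_em) / length(tau_em))
  expect_lt(abs(mean(tau_heun) - mean(tau_em)), 3 * se)
  expect_gt(suppressWarnings(ks.test(tau_heun, tau_em)$p.value), 0.01)
})

test_that("summary implements the recruitment-time definitions", {
  ens <- fake_ensemble(matrix(c(1, 3, 2, 4), nrow = 2))
  s <- summarize_ensemble(ens, ventral = 1)
  expect_equal(s$T, c(0, 1))
  expect_equal(s$T_hat, c(0, 1))
  expect_equal(s$first_node, c(1L, 1L))
  expect_equal(s$P_V, 1)

  # K = 1: zero-width standard errors
  s1 <- summarize_ensemble(fake_ensemble(matrix(c(2, 5), nrow = 1)))
  expect_equal(s1$T, c(0, 3))
  expect_equal(s1$SE, c(0, 0))

  # degenerate scaling: simultaneous escape everywhere
  expect_error(summarize_ensemble(fake_ensemble(matrix(1, 3, 2))),
               "degenerate")
  expect_error(summarize_ensemble(fake_ensemble(matrix(NA_real_, 2, 2))),
               "censored")
})

test_that("relabelling nodes permutes escape-time distributions", {
  # distribution-level check on a short heterogeneous chain
  A <- chain_adjacency(3, 0.1)
  nu <- c(0.10, 0.14, 0.18)
  p <- c(3L, 2L, 1L)      # reversal
  cfg <- sim_config(K = 250, t_max = 400, seed = 21)
  e1 <- simulate_ensemble(network_spec(A, nu), cfg)
  e2 <- simulate_ensemble(network_spec(A[p, p], nu[p]),
                          sim_config(K = 250, t_max = 400, seed = 22))
  for (n in 1:3) {
    a <- e1$tau[, n]; b <- e2$tau[, which(p == n)]
    expect_gt(suppressWarnings(
      ks.test(a[!is.na(a)], b[!is.na(b)])$p.value), 0.01)
  }
})

test_that("homogeneous chains initiate ventrally half the time", {
  spec <- network_spec(chain_adjacency(16, 0.1), 0.14)
  ens <- simulate_ensemble(spec, sim_config(K = 300, t_max = 1500, seed = 3,
                                            stop_mode = "first_escape"))
  s <- summarize_ensemble(ens, ventral = 1:8)
  se <- sqrt(0.25 / s$n_informative)
  expect_lt(abs(s$P_V - 0.5), 3 * se + 1e-12)
})

test_that("edge nodes of a homogeneous chain are recruited late", {
  spec <- network_spec(chain_adjacency(16, 0.1), 0.14)
  ens <- simulate_ensemble(spec, sim_config(K = 150, t_max = 1500, seed = 8))
  s <- summarize_ensemble(ens)
  edge <- mean(s$T[c(1, 2, 15, 16)])
  interior <- mean(s$T[3:14])
  expect_gt(edge, interior)
})
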