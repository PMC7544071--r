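# Shared lazily built fixtures; everything is generated in code so the
# suite carries no data files.

.fixture_cache <- new.env(parent = emptyenv())

with_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small mEC-style event set reused by detection and synthetic tests
mec_events <- function() {
  with_fixture("mec_events", function() make_mec_fixture(seed = 7, n_events = 3))
}

# a manually assembled escape ensemble for summary/comparison tests
fake_ensemble <- function(tau, stop_mode = "all_escape") {
  structure(list(tau = tau, censored = is.na(tau),
                 diverged = rep(FALSE, nrow(tau)),
                 spec = NULL,
                 config = sim_config(K = nrow(tau), stop_mode = stop_mode)),
            class = "escape_ensemble")
}

# Euler-Maruyama reference integrator for a single uncoupled node,
# vectorised across realizations; independent of the package's C++ path
em_escape_single <- function(nu, alpha, h, t_max, xi, K, seed) {
  set.seed(seed)
  zr <- numeric(K); zi <- numeric(K)
  tau <- rep(NA_real_, K)
  alive <- rep(TRUE, K)
  sq_h <- sqrt(h)
  n_steps <- ceiling(t_max / h)
  for (s in seq_len(n_steps)) {
    if (!any(alive)) break
    a2 <- zr^2 + zi^2
    g <- -nu + (2 - a2) * a2
    zr <- zr + h * g * zr + alpha * sq_h * rnorm(K)
    zi <- zi + h * g * zi + alpha * sq_h * rnorm(K)
    crossed <- alive & (zr^2 + zi^2 > xi^2)
    tau[crossed] <- s * h
    alive <- alive & !crossed
  }
  tau
}
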