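# Shared fixtures and oracles for the test suite. Expensive objects (default
# dataset, a moderate SMEMN fit) are built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixtures)) assign(name, maker(), envir = .fixtures)
  get(name, envir = .fixtures)
}

default_dataset <- function() fixture("default_dataset", function()
  simulate_eb_dataset(n_subjects = 300, n_replicates = 4, seed = 101))

# moderate-length SMEMN fit on the default dataset, reused by the spline,
# calibration and acceptance tests (single chain, 4000 sweeps)
smemn_fit <- function() fixture("smemn_fit", function()
  fit_smem(default_dataset(), "normal",
           chain_config(n_chains = 1L, n_iterations = 4000L,
                        burn_in = 1000L, seed = 7)))

# small dataset for fast sampler tests
small_dataset <- function(seed = 5, J = 4, family = "normal")
  simulate_eb_dataset(n_subjects = 100, n_replicates = J,
                      error_family = family, seed = seed)

short_chain <- function(n = 800L, burn = 200L, seed = 1L, ...)
  chain_config(n_chains = 1L, n_iterations = n, burn_in = burn,
               seed = seed, ...)

# Independent Cox-de Boor recursion oracle (textbook definition, scalar and
# recursive on purpose - no code shared with the package implementation).
cox_de_boor <- function(x, tk, i, p) {
  if (p == 0) {
    # right-closed last span so the basis covers the upper boundary
    last <- max(which(tk < tk[length(tk)]))
    if ((tk[i] <= x && x < tk[i + 1]) ||
        (x == tk[length(tk)] && i == last)) 1 else 0
  } else {
    d1 <- tk[i + p] - tk[i]
    d2 <- tk[i + p + 1] - tk[i + 1]
    a <- if (d1 > 0) (x - tk[i]) / d1 * cox_de_boor(x, tk, i, p - 1) else 0
    b <- if (d2 > 0) (tk[i + p + 1] - x) / d2 *
           cox_de_boor(x, tk, i + 1, p - 1) else 0
    a + b
  }
}

oracle_basis <- function(x, knots, degree = 3) {
  tk <- c(rep(knots$boundary[1], degree + 1), knots$interior,
          rep(knots$boundary[2], degree + 1))
  K <- length(tk) - degree - 1
  t(vapply(x, function(xi)
    vapply(seq_len(K), function(i) cox_de_boor(xi, tk, i, degree), 0),
    numeric(K)))
}
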