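# ---------------------------------------------------------------------------
# Shared MCMC machinery: chain configuration, small multivariate samplers,
# draw containers and posterior summaries.
# ---------------------------------------------------------------------------

#' MCMC chain configuration
#'
#' @param n_chains number of independent chains.
#' @param n_iterations total sweeps per chain.
#' @param burn_in sweeps discarded from the front of each chain.
#' @param thin keep every \code{thin}-th post-burn-in draw.
#' @param seed root seed; chain c uses a sub-stream derived from it.
#' @param prop_sd initial random-walk sds for the latent (EE, dES) updates;
#'   adapted during burn-in towards 20-40\% acceptance, then frozen.
#' @param move_probs RJ move mix \code{c(birth, death, move)}; death (and
#'   move) are disabled at zero knots with their mass reassigned to birth.
#' @param k_max cap on the interior knot count.
#' @param store_latents keep thinned per-subject latent draws (memory-heavy).
#' @param verbose emit progress lines with acceptance rates every 1000
#'   sweeps (RJ sampler).
#' @return Object of class \code{chain_config}.
#' @export
chain_config <- function(n_chains = 3L, n_iterations = 12000L,
                         burn_in = 2000L, thin = 1L, seed = 1L,
                         prop_sd = c(60, 30),
                         move_probs = c(birth = 0.35, death = 0.35,
                                        move = 0.30),
                         k_max = 30L, store_latents = FALSE,
                         verbose = FALSE) {
  stopifnot(burn_in < n_iterations, thin >= 1,
            length(move_probs) == 3, abs(sum(move_probs) - 1) < 1e-12)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), prop_sd = prop_sd,
                 move_probs = move_probs, k_max = as.integer(k_max),
                 store_latents = isTRUE(store_latents),
                 verbose = isTRUE(verbose)),
            class = "chain_config")
}

# bivariate normal draws given mean matrix (n x 2) and common covariance
rmvnorm2 <- function(mean, Sigma) {
  n <- nrow(mean)
  mean + matrix(rnorm(2 * n), n, 2) %*% chol(Sigma)
}

rinvwishart <- function(df, S) {
  solve(rWishart(1, df, solve(S))[, , 1])
}

solve2 <- function(M) {
  det_m <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / det_m
}

# Gaussian linear regression coefficient update with independent normal
# priors: y ~ N(D b, sig2 I), b_j ~ N(m0_j, c0_j)
draw_coefficients <- function(D, y, sig2, m0, c0) {
  P <- crossprod(D) / sig2 + diag(1 / c0, length(c0))
  U <- chol(P)
  eta <- crossprod(D, y) / sig2 + m0 / c0
  mu <- backsolve(U, backsolve(U, eta, transpose = TRUE))
  drop(mu + backsolve(U, rnorm(length(c0))))
}

draw_variance <- function(a, b, resid) {
  1 / rgamma(1, a + length(resid) / 2, b + sum(resid^2) / 2)
}

# pool-adjacent-violators projection of a coefficient vector onto the
# non-decreasing cone (used at initialization / refit fallback)
monotone_project <- function(beta) {
  n <- length(beta)
  vals <- as.numeric(beta); wts <- rep(1, n); m <- 0
  for (i in seq_len(n)) {
    m <- m + 1; vals[m] <- beta[i]; wts[m] <- 1
    while (m > 1 && vals[m - 1] > vals[m]) {
      v <- (wts[m - 1] * vals[m - 1] + wts[m] * vals[m]) /
           (wts[m - 1] + wts[m])
      wts[m - 1] <- wts[m - 1] + wts[m]; vals[m - 1] <- v; m <- m - 1
    }
  }
  rep(vals[seq_len(m)], times = wts[seq_len(m)])
}

new_eb_draws <- function(kind, chains, cfg, extra = list()) {
  structure(c(list(kind = kind, chains = chains, config = cfg), extra),
            class = "eb_draws")
}

#' @export
print.eb_draws <- function(x, ...) {
  cat(sprintf("<eb_draws> %s model: %d chain(s) x %d retained draws\n",
              x$kind, length(x$chains), nrow(x$chains[[1]])))
  cat("parameters:", paste(colnames(x$chains[[1]]), collapse = ", "), "\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain PSRF:
#' \eqn{\sqrt{((n-1)/n\,W + (1+1/m)\,B/n)/W}} for m chains of n draws.
#'
#' @param draws an \code{eb_draws} object (needs at least 2 chains).
#' @param parameter parameter (column) name; if missing, all parameters.
#' @return Named vector of PSRF values.
#' @export
gelman_rubin <- function(draws, parameter = NULL) {
  stopifnot(inherits(draws, "eb_draws"))
  if (length(draws$chains) < 2)
    stop("Gelman-Rubin requires at least two chains", call. = FALSE)
  pars <- parameter
  if (is.null(pars)) pars <- colnames(draws$chains[[1]])
  vapply(pars, function(p) {
    M <- vapply(draws$chains, function(ch) ch[, p], draws$chains[[1]][, p])
    n <- nrow(M); m <- ncol(M)
    W <- mean(apply(M, 2, var))
    B <- n * var(colMeans(M))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + (1 + 1 / m) * B / n) / W)
  }, 0)
}

#' Posterior summary of retained draws
#'
#' Pools post-burn-in draws across chains and reports mean, sd and the
#' 2.5/50/97.5 percent quantiles.
#'
#' @param draws an \code{eb_draws} object.
#' @param parameter parameter name(s); default all.
#' @return data.frame with one row per parameter.
#' @export
posterior_summary <- function(draws, parameter = NULL) {
  stopifnot(inherits(draws, "eb_draws"))
  pars <- parameter
  if (is.null(pars)) pars <- colnames(draws$chains[[1]])
  pooled <- do.call(rbind, draws$chains)
  if (nrow(pooled) == 0) stop("no retained draws", call. = FALSE)
  out <- t(vapply(pars, function(p) {
    v <- pooled[, p]
    c(mean = mean(v), sd = sd(v),
      q2.5 = unname(quantile(v, 0.025)), median = median(v),
      q97.5 = unname(quantile(v, 0.975)))
  }, numeric(5)))
  data.frame(parameter = pars, out, row.names = NULL)
}
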