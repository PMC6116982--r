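# ---------------------------------------------------------------------------
# Conditionally conjugate Gibbs samplers for the naive and linear
# measurement error models. Every full conditional is closed form: normal
# updates for regression coefficients and latent pairs, inverse-gamma for
# variances, normal / inverse-Wishart for the latent mean and covariance.
# ---------------------------------------------------------------------------

#' Gibbs sampling for the naive and linear measurement error models
#'
#' Cycles through closed-form full conditionals. For the naive model these
#' are the regression coefficients and error variances of the two device
#' channels. The LMEM adds per-subject latent (EE, dES) pairs (jointly
#' bivariate-normal conditionals), gold-standard error variances, and the
#' latent bivariate-normal mean and covariance.
#'
#' @param spec a \code{\link{naive_spec}} or \code{\link{lmem_spec}}.
#' @param dataset an \code{eb_dataset}.
#' @param chain_cfg a \code{\link{chain_config}}.
#' @return An \code{eb_draws} object.
#' @export
gibbs_fit <- function(spec, dataset, chain_cfg = chain_config()) {
  stopifnot(inherits(spec, "eb_model_spec"))
  if (!spec$kind %in% c("naive", "lmem"))
    stop("gibbs_fit handles the naive and lmem models; use rjmcmc_fit",
         call. = FALSE)
  Z <- covariate_matrix(dataset$covariates)
  if (any(apply(Z, 2, var) == 0))
    stop("degenerate design: a covariate column is constant", call. = FALSE)
  chains <- lapply(seq_len(chain_cfg$n_chains), function(c_id) {
    set.seed(derive_seed(chain_cfg$seed, paste0("chain", c_id)))
    if (spec$kind == "naive") gibbs_chain_naive(spec, dataset, Z, chain_cfg)
    else gibbs_chain_lmem(spec, dataset, Z, chain_cfg)
  })
  new_eb_draws(spec$kind, chains, chain_cfg)
}

#' @rdname gibbs_fit
#' @export
fit_naive <- function(dataset, chain_cfg = chain_config(),
                      hyper = hyperparameters())
  gibbs_fit(naive_spec(hyper), dataset, chain_cfg)

#' @rdname gibbs_fit
#' @export
fit_lmem <- function(dataset, chain_cfg = chain_config(),
                     hyper = hyperparameters())
  gibbs_fit(lmem_spec(hyper), dataset, chain_cfg)

retained_index <- function(cfg) {
  seq(cfg$burn_in + 1, cfg$n_iterations, by = cfg$thin)
}

gibbs_chain_naive <- function(spec, dataset, Z, cfg) {
  hy <- spec$hyper
  n <- nrow(Z); J <- ncol(dataset$y_ee); nJ <- n * J
  Zr <- Z[rep(seq_len(n), J), , drop = FALSE]
  fit_one <- function(w, y) {
    D <- cbind(1, as.vector(w), Zr)
    yv <- as.vector(y)
    m0 <- c(hy$m_beta0, hy$m_beta1, rep(hy$m_gamma, 3))
    c0 <- c(hy$c_beta0, hy$c_beta1, rep(hy$c_gamma, 3))
    b <- qr.coef(qr(D), yv)           # start at OLS
    sig2 <- drop(var(yv - drop(D %*% b)))
    list(D = D, y = yv, m0 = m0, c0 = c0, b = b, sig2 = sig2)
  }
  st <- list(ee = fit_one(dataset$w_ee, dataset$y_ee),
             es = fit_one(dataset$w_es, dataset$y_es))
  keep <- retained_index(cfg)
  par_names <- as.vector(outer(
    c("beta0", "beta1", "gamma1", "gamma2", "gamma3", "sig_eps"),
    c("ee", "es"), paste, sep = "_"))
  out <- matrix(NA_real_, length(keep), length(par_names),
                dimnames = list(NULL, par_names))
  row <- 0L
  for (it in seq_len(cfg$n_iterations)) {
    for (a in c("ee", "es")) {
      s <- st[[a]]
      s$b <- draw_coefficients(s$D, s$y, s$sig2, s$m0, s$c0)
      s$sig2 <- draw_variance(hy$a, hy$b, s$y - drop(s$D %*% s$b))
      st[[a]] <- s
    }
    if (it %in% keep) {
      row <- row + 1L
      out[row, ] <- c(st$ee$b, sqrt(st$ee$sig2), st$es$b, sqrt(st$es$sig2))[
        c(1:5, 6, 7:11, 12)]
    }
  }
  out
}

gibbs_chain_lmem <- function(spec, dataset, Z, cfg) {
  hy <- spec$hyper
  n <- nrow(Z); J <- ncol(dataset$y_ee); nJ <- n * J
  wbar <- cbind(rowMeans(dataset$w_ee), rowMeans(dataset$w_es))
  ybar <- cbind(rowMeans(dataset$y_ee), rowMeans(dataset$y_es))
  Zr <- Z[rep(seq_len(n), J), , drop = FALSE]
  m0 <- c(hy$m_beta0, hy$m_beta1, rep(hy$m_gamma, 3))
  c0 <- c(hy$c_beta0, hy$c_beta1, rep(hy$c_gamma, 3))

  # initial values: latents at gold-standard replicate means
  x <- wbar
  b <- list(); sig_eps2 <- numeric(2); sig_nu2 <- numeric(2)
  ys <- list(as.vector(dataset$y_ee), as.vector(dataset$y_es))
  ws <- list(dataset$w_ee, dataset$w_es)
  for (a in 1:2) {
    D <- cbind(1, rep(x[, a], J), Zr)
    b[[a]] <- qr.coef(qr(D), ys[[a]])
    sig_eps2[a] <- var(ys[[a]] - drop(D %*% b[[a]]))
    sig_nu2[a] <- max(var(as.vector(ws[[a]] - x[, a])), 1)
  }
  mu <- colMeans(x); Sigma <- var(x)

  keep <- retained_index(cfg)
  par_names <- c(as.vector(outer(
    c("beta0", "beta1", "gamma1", "gamma2", "gamma3", "sig_eps"),
    c("ee", "es"), paste, sep = "_")),
    "sig_nu_ee", "sig_nu_es", "mu_ee", "mu_es",
    "Sigma_11", "Sigma_12", "Sigma_22")
  out <- matrix(NA_real_, length(keep), length(par_names),
                dimnames = list(NULL, par_names))
  lat_keep <- if (cfg$store_latents) vector("list", length(keep)) else NULL
  xr <- matrix(NA_real_, length(keep), 4)   # latent ranges per retained draw
  row <- 0L
  for (it in seq_len(cfg$n_iterations)) {
    # regression blocks and variances per attribute
    for (a in 1:2) {
      D <- cbind(1, rep(x[, a], J), Zr)
      b[[a]] <- draw_coefficients(D, ys[[a]], sig_eps2[a], m0, c0)
      sig_eps2[a] <- draw_variance(hy$a, hy$b, ys[[a]] - drop(D %*% b[[a]]))
      sig_nu2[a] <- draw_variance(hy$a, hy$b,
                                  as.vector(ws[[a]] - x[, a]))
    }
    # joint bivariate-normal latent update (common precision across subjects)
    Sinv <- solve2(Sigma)
    P <- Sinv + diag(c(J * (b[[1]][2]^2 / sig_eps2[1] + 1 / sig_nu2[1]),
                       J * (b[[2]][2]^2 / sig_eps2[2] + 1 / sig_nu2[2])))
    V <- solve2(P)
    zg <- cbind(drop(Z %*% b[[1]][3:5]), drop(Z %*% b[[2]][3:5]))
    eta <- cbind(
      J * b[[1]][2] * (ybar[, 1] - b[[1]][1] - zg[, 1]) / sig_eps2[1] +
        J * wbar[, 1] / sig_nu2[1],
      J * b[[2]][2] * (ybar[, 2] - b[[2]][1] - zg[, 2]) / sig_eps2[2] +
        J * wbar[, 2] / sig_nu2[2])
    eta <- eta + matrix(drop(Sinv %*% mu), n, 2, byrow = TRUE)
    x <- rmvnorm2(eta %*% V, V)   # V symmetric
    # latent mean and covariance
    Sinv <- solve2(Sigma)
    Pm <- diag(1 / hy$c_mu) + n * Sinv
    Vm <- solve2(Pm)
    mm <- drop(Vm %*% (hy$m_mu / hy$c_mu + Sinv %*% colSums(x)))
    mu <- drop(mm + chol(Vm) %*% rnorm(2))
    S <- crossprod(sweep(x, 2, mu))
    Sigma <- rinvwishart(hy$d + n, hy$psi + S)

    if (it %in% keep) {
      row <- row + 1L
      out[row, ] <- c(b[[1]], sqrt(sig_eps2[1]), b[[2]], sqrt(sig_eps2[2]),
                      sqrt(sig_nu2[1]), sqrt(sig_nu2[2]), mu,
                      Sigma[1, 1], Sigma[1, 2], Sigma[2, 2])
      xr[row, ] <- c(range(x[, 1]), range(x[, 2]))
      if (cfg$store_latents) lat_keep[[row]] <- x
    }
  }
  attr(out, "latent_range") <- xr
  if (cfg$store_latents) attr(out, "latents") <- lat_keep
  out
}
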