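# ---------------------------------------------------------------------------
# Reversible Jump MCMC for the spline measurement error models (SMEMN and
# SMEM). Per sweep and per attribute: a birth/death/move proposal on the
# interior knots of the monotone cubic B-spline (knot candidates restricted
# to the current latent values, Poisson prior on the knot count), an OLS
# refresh of the spline and covariate coefficients (moves producing
# non-monotone coefficients are rejected), inverse-gamma updates of the
# error variances, a vectorised random-walk Metropolis update of the latent
# (EE, dES) pairs, and - for SMEM - the truncated stick-breaking Gibbs block
# for cluster labels, weights and per-cluster normal parameters.
#
# Spline and covariate coefficients are plug-in OLS quantities given the
# knots and latents (no prior), so RJ moves carry no Jacobian term: the
# acceptance ratio is likelihood x knot-count prior x proposal correction.
# ---------------------------------------------------------------------------

#' Reversible Jump MCMC for the spline measurement error models
#'
#' Fits the SMEMN (bivariate-normal latent prior) or SMEM (truncated
#' Dirichlet process latent prior) model. The number and positions of the
#' interior knots of each monotone device-bias spline are sampled by
#' reversible jump (birth / death / move), with spline and covariate
#' coefficients refit by ordinary least squares and constrained to
#' non-decreasing coefficient vectors so the fitted bias is invertible.
#'
#' With two replicates per subject the Dirichlet-process variant is known to
#' mix poorly; a warning is issued (the bivariate-normal variant is the
#' recommended model at two replicates).
#'
#' @param spec a \code{\link{smemn_spec}} or \code{\link{smem_spec}}.
#' @param dataset an \code{eb_dataset}.
#' @param chain_cfg a \code{\link{chain_config}}.
#' @return An \code{eb_draws} object; \code{$spline} holds per-draw knot
#'   sets, spline coefficients and latent ranges for calibration, and
#'   \code{$boundary_ee}, \code{$boundary_es} the fixed spline domains.
#' @export
rjmcmc_fit <- function(spec, dataset, chain_cfg = chain_config()) {
  stopifnot(inherits(spec, "eb_model_spec"))
  if (!spec$kind %in% c("smemn", "smem"))
    stop("rjmcmc_fit handles the smemn and smem models; use gibbs_fit",
         call. = FALSE)
  if (spec$kind == "smem" && ncol(dataset$w_ee) < 4)
    warning("the Dirichlet-process latent prior is unstable with fewer ",
            "than 4 replicates; consider the smemn model", call. = FALSE)
  Z <- covariate_matrix(dataset$covariates)
  res <- lapply(seq_len(chain_cfg$n_chains), function(c_id) {
    set.seed(derive_seed(chain_cfg$seed, paste0("rjchain", c_id)))
    rj_chain(spec, dataset, Z, chain_cfg)
  })
  new_eb_draws(spec$kind,
               lapply(res, `[[`, "params"), chain_cfg,
               extra = list(spline = lapply(res, `[[`, "spline"),
                            boundary_ee = res[[1]]$boundary_ee,
                            boundary_es = res[[1]]$boundary_es,
                            accept = lapply(res, `[[`, "accept")))
}

#' @rdname rjmcmc_fit
#' @export
fit_smem <- function(dataset, latent_prior = c("normal", "dp"),
                     chain_cfg = chain_config(),
                     hyper = hyperparameters()) {
  latent_prior <- match.arg(latent_prior)
  spec <- if (latent_prior == "dp") smem_spec(hyper) else smemn_spec(hyper)
  rjmcmc_fit(spec, dataset, chain_cfg)
}

# log acceptance ratio pieces for a dimension change k -> k', excluding the
# likelihood term. Exposed internally so tests can assert the antisymmetry
# of matched birth/death proposals.
rj_log_prior_proposal <- function(move, k, lambda, move_probs_fn) {
  # returns an unnamed scalar
  unname(
  if (move == "birth") {
    p_now <- move_probs_fn(k); p_next <- move_probs_fn(k + 1)
    log(lambda) - log(k + 1) + log(p_next["death"]) - log(p_now["birth"])
  } else if (move == "death") {
    p_now <- move_probs_fn(k); p_next <- move_probs_fn(k - 1)
    -log(lambda) + log(k) + log(p_next["birth"]) - log(p_now["death"])
  } else 0)
}

rj_chain <- function(spec, dataset, Z, cfg) {
  hy <- spec$hyper
  dp <- spec$kind == "smem"
  n <- nrow(Z); J <- ncol(dataset$y_ee); nJ <- n * J
  wbar <- cbind(rowMeans(dataset$w_ee), rowMeans(dataset$w_es))
  ybar <- cbind(rowMeans(dataset$y_ee), rowMeans(dataset$y_es))
  ys <- list(as.vector(dataset$y_ee), as.vector(dataset$y_es))
  ws <- list(dataset$w_ee, dataset$w_es)
  # within-replicate sums of squares around subject means: constant in all
  # mean-function updates, needed only for the variance Gibbs steps
  ss_y <- c(sum((dataset$y_ee - ybar[, 1])^2),
            sum((dataset$y_es - ybar[, 2])^2))

  # fixed, generously padded spline domains from the gold-standard means;
  # latent proposals outside are rejected (negligible posterior mass there)
  boundary <- list(latent_boundary(wbar[, 1], 0.25),
                   latent_boundary(wbar[, 2], 0.25))

  x <- wbar
  lambda <- c(hy$lambda_ee, hy$lambda_es)

  move_probs_fn <- function(k) {
    if (k == 0) c(birth = 1, death = 0, move = 0)
    else if (k >= cfg$k_max) c(birth = 0, death = 0.5, move = 0.5)
    else cfg$move_probs
  }

  # per-attribute spline state: knots (interior), beta, gamma, fitted values
  ols_fit <- function(a, interior, xa) {
    ks <- knot_set(interior, boundary[[a]])
    B <- basis_matrix(xa, ks)
    A <- cbind(B, Z)
    cf <- tryCatch(qr.coef(qr(A), ybar[, a]), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) return(NULL)
    K <- ncol(B)
    fit <- drop(A %*% cf)
    list(knots = ks, beta = cf[1:K], gamma = cf[(K + 1):(K + 3)],
         fitted = fit, ssr = J * sum((ybar[, a] - fit)^2))
  }
  sp <- vector("list", 2)
  for (a in 1:2) {
    # start from a single median knot; project to monotone if needed
    f <- ols_fit(a, median(x[, a]), x[, a])
    if (is.null(f)) f <- ols_fit(a, numeric(0), x[, a])
    if (!is_monotone(f$beta)) {
      f$beta <- monotone_project(f$beta)
      f$fitted <- drop(basis_matrix(x[, a], f$knots) %*% f$beta +
                       Z %*% f$gamma)
      f$ssr <- J * sum((ybar[, a] - f$fitted)^2)
    }
    sp[[a]] <- f
  }
  sig_eps2 <- vapply(1:2, function(a)
    max(sum((ys[[a]] - rep(sp[[a]]$fitted, J))^2) / nJ, 1), 0)
  sig_nu2 <- vapply(1:2, function(a)
    max(var(as.vector(ws[[a]] - x[, a])), 1), 0)

  # latent prior state
  if (dp) {
    H <- hy$H
    zeta <- sample.int(min(5, H), n, replace = TRUE)
    v <- c(rbeta(H - 1, 1, hy$alpha), 1)
    pi_h <- stick_break_weights(v)
    mu_h <- matrix(rnorm(2 * H, rep(colMeans(x), each = H),
                         rep(apply(x, 2, sd), each = H)), H, 2)
    Sigma_h <- replicate(H, var(x) + diag(2), simplify = FALSE)
  } else {
    mu <- colMeans(x); Sigma <- var(x)
  }

  prop_sd <- cfg$prop_sd
  acc_lat <- c(0L, 0L); try_lat <- c(0L, 0L)
  acc_rj <- c(0L, 0L); try_rj <- c(0L, 0L)

  keep <- retained_index(cfg)
  par_names <- c("gamma1_ee", "gamma2_ee", "gamma3_ee",
                 "gamma1_es", "gamma2_es", "gamma3_es",
                 "sig_eps_ee", "sig_eps_es", "sig_nu_ee", "sig_nu_es",
                 "k_ee", "k_es",
                 if (dp) "n_clusters" else
                   c("mu_ee", "mu_es", "Sigma_11", "Sigma_12", "Sigma_22"))
  out <- matrix(NA_real_, length(keep), length(par_names),
                dimnames = list(NULL, par_names))
  spline_draws <- vector("list", length(keep))
  row <- 0L

  for (it in seq_len(cfg$n_iterations)) {
    ## (i) reversible jump knot move + (ii) OLS refresh, per attribute
    for (a in 1:2) {
      cur <- sp[[a]]
      k <- cur$knots$k
      mv <- sample(c("birth", "death", "move"), 1,
                   prob = move_probs_fn(k))
      cand_pool <- x[, a][!(x[, a] %in% cur$knots$interior)]
      prop_interior <- NULL
      if (mv == "birth" && length(cand_pool)) {
        prop_interior <- sort(c(cur$knots$interior, sample(cand_pool, 1)))
      } else if (mv == "death" && k > 0) {
        prop_interior <- cur$knots$interior[-sample.int(k, 1)]
      } else if (mv == "move" && k > 0 && length(cand_pool)) {
        pi_ <- cur$knots$interior
        pi_[sample.int(k, 1)] <- sample(cand_pool, 1)
        prop_interior <- sort(pi_)
      }
      try_rj[a] <- try_rj[a] + 1L
      if (!is.null(prop_interior) &&
          all(prop_interior > boundary[[a]][1]) &&
          all(prop_interior < boundary[[a]][2])) {
        prop <- ols_fit(a, prop_interior, x[, a])
        if (!is.null(prop) && is_monotone(prop$beta)) {
          log_lik_ratio <- (cur$ssr - prop$ssr) / (2 * sig_eps2[a])
          log_r <- log_lik_ratio +
            rj_log_prior_proposal(mv, k, lambda[a], move_probs_fn)
          if (log(runif(1)) < log_r) {
            sp[[a]] <- prop
            acc_rj[a] <- acc_rj[a] + 1L
          }
        }
      }
      # OLS refresh at the current knots (latents moved last sweep); keep
      # the previous monotone fit if the refresh violates monotonicity
      ref <- ols_fit(a, sp[[a]]$knots$interior, x[, a])
      if (!is.null(ref) && is_monotone(ref$beta)) sp[[a]] <- ref
    }

    ## (iii) variance updates
    for (a in 1:2) {
      ssr_full <- ss_y[a] + sp[[a]]$ssr
      sig_eps2[a] <- 1 / rgamma(1, hy$a + nJ / 2, hy$b + ssr_full / 2)
      sig_nu2[a] <- draw_variance(hy$a, hy$b, as.vector(ws[[a]] - x[, a]))
    }

    ## (iv) vectorised random-walk MH update of the latent pairs
    xp <- x + cbind(rnorm(n, 0, prop_sd[1]), rnorm(n, 0, prop_sd[2]))
    inb <- xp[, 1] > boundary[[1]][1] & xp[, 1] < boundary[[1]][2] &
           xp[, 2] > boundary[[2]][1] & xp[, 2] < boundary[[2]][2]
    if (any(inb)) {
      idx <- which(inb)
      f1c <- sp[[1]]$fitted[idx]
      f2c <- sp[[2]]$fitted[idx]
      B1p <- basis_matrix(xp[idx, 1], sp[[1]]$knots)
      B2p <- basis_matrix(xp[idx, 2], sp[[2]]$knots)
      f1p <- drop(B1p %*% sp[[1]]$beta) + drop(Z[idx, ] %*% sp[[1]]$gamma)
      f2p <- drop(B2p %*% sp[[2]]$beta) + drop(Z[idx, ] %*% sp[[2]]$gamma)
      dy1 <- ybar[idx, 1]; dy2 <- ybar[idx, 2]
      logr <- J / (2 * sig_eps2[1]) * ((dy1 - f1c)^2 - (dy1 - f1p)^2) +
              J / (2 * sig_eps2[2]) * ((dy2 - f2c)^2 - (dy2 - f2p)^2) +
              J / (2 * sig_nu2[1]) *
                ((wbar[idx, 1] - x[idx, 1])^2 - (wbar[idx, 1] - xp[idx, 1])^2) +
              J / (2 * sig_nu2[2]) *
                ((wbar[idx, 2] - x[idx, 2])^2 - (wbar[idx, 2] - xp[idx, 2])^2)
      # latent prior term
      if (dp) {
        logr <- logr +
          dmvnorm2_log_rows(xp[idx, , drop = FALSE],
                            mu_h[zeta[idx], , drop = FALSE], Sigma_h, zeta[idx]) -
          dmvnorm2_log_rows(x[idx, , drop = FALSE],
                            mu_h[zeta[idx], , drop = FALSE], Sigma_h, zeta[idx])
      } else {
        logr <- logr + dmvnorm2_rows_common(xp[idx, , drop = FALSE], mu, Sigma) -
                       dmvnorm2_rows_common(x[idx, , drop = FALSE], mu, Sigma)
      }
      acc <- log(runif(length(idx))) < logr
      moved <- idx[acc]
      if (length(moved)) {
        x[moved, ] <- xp[moved, ]
        # refresh fitted values for moved subjects
        for (a in 1:2) {
          Bm <- basis_matrix(x[moved, a], sp[[a]]$knots)
          sp[[a]]$fitted[moved] <- drop(Bm %*% sp[[a]]$beta) +
            drop(Z[moved, , drop = FALSE] %*% sp[[a]]$gamma)
        }
        for (a in 1:2)
          sp[[a]]$ssr <- J * sum((ybar[, a] - sp[[a]]$fitted)^2)
      }
      acc_lat <- acc_lat + length(moved); try_lat <- try_lat + n
      # proposal adaptation during burn-in only (frozen afterwards)
      if (it <= cfg$burn_in && it %% 100 == 0) {
        rate <- sum(acc) / length(idx)
        prop_sd <- prop_sd * exp(rate - 0.3)
      }
    }

    ## (v) latent-prior block
    if (dp) {
      # cluster labels: categorical over the truncated stick
      loglik_h <- vapply(seq_len(H), function(h)
        dmvnorm2_rows_common(x, mu_h[h, ], Sigma_h[[h]]), numeric(n))
      lp <- sweep(loglik_h, 2, log(pi_h), "+")
      lp <- lp - apply(lp, 1, max)
      p <- exp(lp); p <- p / rowSums(p)
      cp <- t(apply(p, 1, cumsum))
      u <- runif(n)
      zeta <- pmin(1L + rowSums(cp < u), H)
      nh <- tabulate(zeta, H)
      # stick fractions
      tail_n <- rev(cumsum(rev(nh)))
      v <- c(rbeta(H - 1, 1 + nh[-H], hy$alpha + tail_n[-1]), 1)
      pi_h <- stick_break_weights(v)
      # per-cluster mean and covariance
      for (h in seq_len(H)) {
        members <- which(zeta == h)
        m <- length(members)
        if (m == 0) {
          mu_h[h, ] <- rnorm(2, hy$m_mu, sqrt(hy$c_mu))
          Sigma_h[[h]] <- rinvwishart(hy$d, hy$psi)
        } else {
          xi <- x[members, , drop = FALSE]
          Sinv <- solve2(Sigma_h[[h]])
          Pm <- diag(1 / hy$c_mu) + m * Sinv
          Vm <- solve2(Pm)
          mm <- drop(Vm %*% (hy$m_mu / hy$c_mu + Sinv %*% colSums(xi)))
          mu_h[h, ] <- drop(mm + chol(Vm) %*% rnorm(2))
          S <- crossprod(sweep(xi, 2, mu_h[h, ]))
          Sigma_h[[h]] <- rinvwishart(hy$d + m, hy$psi + S)
        }
      }
    } else {
      Sinv <- solve2(Sigma)
      Pm <- diag(1 / hy$c_mu) + n * Sinv
      Vm <- solve2(Pm)
      mm <- drop(Vm %*% (hy$m_mu / hy$c_mu + Sinv %*% colSums(x)))
      mu <- drop(mm + chol(Vm) %*% rnorm(2))
      S <- crossprod(sweep(x, 2, mu))
      Sigma <- rinvwishart(hy$d + n, hy$psi + S)
    }

    if (cfg$verbose && it %% 1000 == 0)
      message(sprintf(
        "sweep %d: latent acc %.2f, RJ acc (ee %.2f, es %.2f), k = (%d, %d)",
        it, acc_lat[1] / max(try_lat[1], 1), acc_rj[1] / max(try_rj[1], 1),
        acc_rj[2] / max(try_rj[2], 1), sp[[1]]$knots$k, sp[[2]]$knots$k))

    if (it %in% keep) {
      row <- row + 1L
      out[row, ] <- c(sp[[1]]$gamma, sp[[2]]$gamma,
                      sqrt(sig_eps2), sqrt(sig_nu2),
                      sp[[1]]$knots$k, sp[[2]]$knots$k,
                      if (dp) sum(tabulate(zeta, H) > 0) else
                        c(mu, Sigma[1, 1], Sigma[1, 2], Sigma[2, 2]))
      spline_draws[[row]] <- list(
        knots_ee = sp[[1]]$knots$interior, beta_ee = sp[[1]]$beta,
        knots_es = sp[[2]]$knots$interior, beta_es = sp[[2]]$beta,
        gamma_ee = sp[[1]]$gamma, gamma_es = sp[[2]]$gamma,
        xr_ee = range(x[, 1]), xr_es = range(x[, 2]))
    }
  }
  list(params = out, spline = spline_draws,
       boundary_ee = boundary[[1]], boundary_es = boundary[[2]],
       accept = list(latent = acc_lat / pmax(try_lat, 1),
                     rj = acc_rj / pmax(try_rj, 1),
                     prop_sd = prop_sd))
}

# row-wise bivariate normal log density with a common (mu, Sigma)
dmvnorm2_rows_common <- function(x, mu, Sigma) {
  d1 <- x[, 1] - mu[1]; d2 <- x[, 2] - mu[2]
  det_s <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  q <- (d1^2 * Sigma[2, 2] - 2 * d1 * d2 * Sigma[1, 2] + d2^2 * Sigma[1, 1]) /
    det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}

# row-wise log density where each row has its own cluster's (mu, Sigma)
dmvnorm2_log_rows <- function(x, mu_rows, Sigma_list, labels) {
  vapply(seq_len(nrow(x)), function(i)
    dmvnorm2_log(x[i, ], mu_rows[i, ], Sigma_list[[labels[i]]]), 0)
}
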