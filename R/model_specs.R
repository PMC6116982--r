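# ---------------------------------------------------------------------------
# Declarative model specifications: the naive regression, the linear
# measurement error model (LMEM), and the spline measurement error models
# with bivariate-normal (SMEMN) or truncated Dirichlet-process (SMEM) latent
# priors, together with the prior hyperparameters shared by all of them.
# ---------------------------------------------------------------------------

#' Prior hyperparameters
#'
#' Weakly informative, conditionally conjugate priors used by every model:
#' normal priors on intercepts (mean \code{m_beta0}, variance \code{c_beta0}),
#' slopes (mean 1, reflecting an a-priori unbiased device), and covariate
#' coefficients; inverse-gamma(\code{a}, \code{b}) on every error variance;
#' a normal prior on the latent mean vector (centred at 2400 kcal/day EE and
#' 0 dES) and inverse-Wishart(\code{d}, \code{psi}) on the latent covariance;
#' Poisson(\code{lambda}) on spline knot counts; Dirichlet-process
#' concentration \code{alpha} with truncation \code{H}.
#'
#' @param m_beta0,c_beta0 intercept prior mean and variance.
#' @param m_beta1,c_beta1 slope prior mean and variance.
#' @param m_gamma,c_gamma covariate coefficient prior mean and variance.
#' @param a,b inverse-gamma shape and rate for all error variances.
#' @param psi inverse-Wishart scale matrix for latent covariances.
#' @param d inverse-Wishart degrees of freedom.
#' @param m_mu,c_mu latent-mean prior mean vector and variance diagonal.
#' @param lambda_ee,lambda_es Poisson rates for the two knot counts.
#' @param alpha Dirichlet-process concentration.
#' @param H stick-breaking truncation level (default 20; the expected
#'   untruncated tail mass at alpha = 1 is below 1e-6).
#' @return Object of class \code{eb_hyperparameters}.
#' @export
hyperparameters <- function(m_beta0 = 0, c_beta0 = 1e5,
                            m_beta1 = 1, c_beta1 = 1e5,
                            m_gamma = 0, c_gamma = 1e5,
                            a = 0.1, b = 0.1,
                            psi = diag(2), d = 3,
                            m_mu = c(2400, 0), c_mu = c(1e5, 1e5),
                            lambda_ee = 1, lambda_es = 1,
                            alpha = 1, H = 20L) {
  stopifnot(c_beta0 > 0, c_beta1 > 0, c_gamma > 0, a > 0, b > 0,
            d > 1, all(c_mu > 0), alpha > 0, H >= 1)
  structure(list(m_beta0 = m_beta0, c_beta0 = c_beta0,
                 m_beta1 = m_beta1, c_beta1 = c_beta1,
                 m_gamma = m_gamma, c_gamma = c_gamma,
                 a = a, b = b, psi = psi, d = d,
                 m_mu = m_mu, c_mu = c_mu,
                 lambda_ee = lambda_ee, lambda_es = lambda_es,
                 alpha = alpha, H = as.integer(H)),
            class = "eb_hyperparameters")
}

new_model_spec <- function(kind, hyper) {
  stopifnot(inherits(hyper, "eb_hyperparameters"))
  structure(list(kind = kind, hyper = hyper),
            class = c(paste0(kind, "_spec"), "eb_model_spec"))
}

#' Model specifications
#'
#' Constructors for the four model variants. \code{naive_spec} regresses the
#' device reading linearly on the gold standard, ignoring gold-standard
#' error. \code{lmem_spec} treats the gold standard as an unbiased noisy
#' measure of a latent usual value with a bivariate-normal latent prior and
#' a linear device-bias model. \code{smemn_spec} and \code{smem_spec} replace
#' the linear device bias with a free-knot monotone cubic B-spline; they
#' differ only in the latent prior (bivariate normal vs truncated Dirichlet
#' process mixture).
#'
#' @param hyper an \code{\link{eb_hyperparameters}} object.
#' @return An \code{eb_model_spec}.
#' @export
naive_spec <- function(hyper = hyperparameters()) new_model_spec("naive", hyper)

#' @rdname naive_spec
#' @export
lmem_spec <- function(hyper = hyperparameters()) new_model_spec("lmem", hyper)

#' @rdname naive_spec
#' @export
smemn_spec <- function(hyper = hyperparameters()) new_model_spec("smemn", hyper)

#' @rdname naive_spec
#' @export
smem_spec <- function(hyper = hyperparameters()) new_model_spec("smem", hyper)

#' Stick-breaking weights
#'
#' Converts truncated stick-breaking fractions V (with the last fraction 1)
#' into mixture weights \code{pi_h = V_h prod_{l<h} (1 - V_l)}, which sum to
#' one exactly by telescoping.
#'
#' @param v vector of stick fractions in (0, 1] with last element 1.
#' @return Weight vector of the same length.
#' @export
stick_break_weights <- function(v) {
  H <- length(v)
  if (H < 1 || any(v <= 0) || any(v > 1) || v[H] != 1)
    stop("v must lie in (0,1] with final element exactly 1", call. = FALSE)
  if (H == 1) return(1)
  v * cumprod(c(1, 1 - v[-H]))
}

#' Choose the stick-breaking truncation level
#'
#' Smallest H whose expected untruncated tail mass
#' \code{(alpha/(alpha+1))^H} does not exceed \code{eps}.
#'
#' @param alpha Dirichlet-process concentration (> 0).
#' @param eps tail-mass tolerance in (0, 1).
#' @return Integer truncation level.
#' @export
choose_truncation <- function(alpha, eps) {
  stopifnot(alpha > 0, eps > 0, eps < 1)
  max(1L, as.integer(ceiling(log(eps) / log(alpha / (alpha + 1)) - 1e-9)))
}

# ---- log likelihood ------------------------------------------------------

sum_dnorm <- function(x, mean, sd) sum(dnorm(x, mean, sd, log = TRUE))

#' Joint log likelihood of a model state
#'
#' Sums the normal log densities of every observed channel (device EE/dES,
#' and for hierarchical models the gold-standard EE/dES channels and the
#' latent prior) at the parameter and latent values in \code{state}, under
#' the conditional-independence assumptions of the models.
#'
#' State fields by model kind: naive - \code{beta0, beta1} (2-vectors,
#' EE then dES), \code{gamma_ee, gamma_es, sig_eps} (2-vector of sds);
#' lmem adds \code{x} (n x 2 latent matrix), \code{sig_nu} (2-vector),
#' \code{mu} (2-vector), \code{Sigma} (2 x 2); smemn/smem replace the linear
#' device mean with \code{knots_ee, knots_es} (\code{\link{knot_set}}) and
#' \code{beta_ee, beta_es} spline coefficients, smem additionally has
#' \code{zeta} (cluster labels), \code{pi}, \code{mu_h} (H x 2),
#' \code{Sigma_h} (list of 2 x 2).
#'
#' @param spec an \code{eb_model_spec}.
#' @param dataset an \code{eb_dataset} (or compatible list).
#' @param state named list of current parameter/latent values.
#' @return Scalar log likelihood (including the latent prior term for
#'   hierarchical models).
#' @export
log_likelihood <- function(spec, dataset, state) {
  stopifnot(inherits(spec, "eb_model_spec"))
  if (any(unlist(state[grep("^sig", names(state))]) <= 0))
    stop("non-positive standard deviation in state", call. = FALSE)
  Z <- covariate_matrix(dataset$covariates)
  J <- ncol(dataset$y_ee)
  zg_ee <- drop(Z %*% state$gamma_ee)
  zg_es <- drop(Z %*% state$gamma_es)
  kind <- spec$kind

  if (kind == "naive") {
    m_ee <- state$beta0[1] + state$beta1[1] * dataset$w_ee + zg_ee
    m_es <- state$beta0[2] + state$beta1[2] * dataset$w_es + zg_es
    return(sum_dnorm(dataset$y_ee, m_ee, state$sig_eps[1]) +
           sum_dnorm(dataset$y_es, m_es, state$sig_eps[2]))
  }

  x <- state$x
  if (kind == "lmem") {
    f_ee <- state$beta0[1] + state$beta1[1] * x[, 1]
    f_es <- state$beta0[2] + state$beta1[2] * x[, 2]
  } else {
    f_ee <- evaluate_spline(x[, 1], state$knots_ee, state$beta_ee)
    f_es <- evaluate_spline(x[, 2], state$knots_es, state$beta_es)
  }
  ll <- sum_dnorm(dataset$y_ee, rep(f_ee, J) + zg_ee, state$sig_eps[1]) +
        sum_dnorm(dataset$y_es, rep(f_es, J) + zg_es, state$sig_eps[2]) +
        sum_dnorm(dataset$w_ee, rep(x[, 1], J), state$sig_nu[1]) +
        sum_dnorm(dataset$w_es, rep(x[, 2], J), state$sig_nu[2])

  if (kind == "smem") {
    for (i in seq_len(nrow(x))) {
      h <- state$zeta[i]
      ll <- ll + dmvnorm2_log(x[i, ], state$mu_h[h, ], state$Sigma_h[[h]])
    }
  } else {
    ll <- ll + sum(vapply(seq_len(nrow(x)), function(i)
      dmvnorm2_log(x[i, ], state$mu, state$Sigma), 0))
  }
  ll
}

# bivariate normal log density (2-d only; avoids a mvtnorm dependency)
dmvnorm2_log <- function(x, mu, Sigma) {
  d <- x - mu
  det_s <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2] * Sigma[2, 1]
  q <- (d[1]^2 * Sigma[2, 2] - 2 * d[1] * d[2] * Sigma[1, 2] +
        d[2]^2 * Sigma[1, 1]) / det_s
  -log(2 * pi) - 0.5 * log(det_s) - 0.5 * q
}
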