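# ---------------------------------------------------------------------------
# Synthetic energy-balance data generator.
#
# Emulates a validation study in which n subjects carry both gold-standard
# instruments (DLW for EE, DXA-derived dES) and a cheaper biased device, each
# measured over J replicate time periods. Latent usual (EE, EI) pairs come
# from a 5-component bivariate-t mixture; the device is biased through smooth
# monotone functions of the period-specific truth plus linear covariate
# effects; all instruments carry additive errors from a configurable family.
# ---------------------------------------------------------------------------

# Deterministic sub-stream seeds: one root seed, one stream per generator
# component, so components can be regenerated independently.
derive_seed <- function(root, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131L)
  as.integer((as.numeric(root) * 7919 + h) %% 2147483629)
}

#' Simulate error-free covariates
#'
#' Gender is Bernoulli(0.5) (1 = male), age Uniform(20, 40) years and BMI
#' Normal(27, 5) kg/m^2, independent across subjects.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @return data.frame with columns \code{subject_id, gender, age, bmi}.
#' @export
simulate_covariates <- function(n, seed = 1L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  set.seed(seed)
  data.frame(subject_id = seq_len(n),
             gender = rbinom(n, 1, 0.5),
             age    = runif(n, 20, 40),
             bmi    = rnorm(n, 27, 5))
}

# Covariate design matrix in model order (gender, BMI, age), matching the
# coefficient vectors gamma = (gamma_gender, gamma_bmi, gamma_age).
covariate_matrix <- function(covariates) {
  as.matrix(covariates[, c("gender", "bmi", "age")])
}

#' Latent mixture specification
#'
#' A mixture of bivariate t distributions for the latent usual (EE, EI)
#' pairs: distinct location pairs, a common scale matrix, common degrees of
#' freedom, and a fixed draw count per component. The defaults place five
#' components over the physiologic EE range 1900-3100 kcal/day with EI
#' locations chosen so mean dES is near zero, and calibrate the scale
#' cross-term in closed form so the pooled Pearson correlation between EE
#' and EI equals \code{target_cor}.
#'
#' @param locations_ee,locations_ei component location vectors (kcal/day).
#' @param scale_sd_ee,scale_sd_es marginal scale (not sd) parameters of the
#'   common scale matrix.
#' @param df degrees of freedom (> 2).
#' @param n_per_component draws per component.
#' @param target_cor pooled EE-EI Pearson correlation to calibrate the scale
#'   cross-term to; \code{NA} leaves the cross-term at 0.
#' @return Object of class \code{mixture_spec}.
#' @export
mixture_spec <- function(locations_ee = c(1900, 2200, 2500, 2800, 3100),
                         locations_ei = c(2100, 2650, 2300, 2900, 2550),
                         scale_sd_ee = 150, scale_sd_es = 150,
                         df = 5, n_per_component = 60,
                         target_cor = 0.4376) {
  if (length(locations_ee) != length(locations_ei))
    stop("location vectors must have equal length", call. = FALSE)
  if (anyDuplicated(cbind(locations_ee, locations_ei)))
    stop("component locations must be distinct", call. = FALSE)
  if (df <= 2) stop("degrees of freedom must exceed 2", call. = FALSE)
  m <- length(locations_ee)
  cross <- 0
  if (!is.na(target_cor)) {
    # pooled covariance = (df/(df-2)) * Sigma + between-location covariance;
    # solve the off-diagonal of Sigma for the requested pooled correlation
    f <- df / (df - 2)
    dee <- locations_ee - mean(locations_ee)
    dei <- locations_ei - mean(locations_ei)
    B11 <- mean(dee^2); B22 <- mean(dei^2); B12 <- mean(dee * dei)
    C11 <- f * scale_sd_ee^2 + B11
    C22 <- f * scale_sd_es^2 + B22
    cross <- (target_cor * sqrt(C11 * C22) - B12) / f
    if (abs(cross) >= scale_sd_ee * scale_sd_es)
      stop("target correlation unattainable with these locations/scales",
           call. = FALSE)
  }
  scale <- matrix(c(scale_sd_ee^2, cross, cross, scale_sd_es^2), 2, 2)
  if (any(eigen(scale, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("scale matrix must be positive definite", call. = FALSE)
  structure(list(n_components = m,
                 locations_ee = locations_ee, locations_ei = locations_ei,
                 scale = scale, df = df, n_per_component = n_per_component),
            class = "mixture_spec")
}

#' Simulate latent usual (EE, EI, dES) triples
#'
#' Draws \code{n_per_component} pairs from each bivariate-t component and
#' sets usual dES = EI - EE exactly (energy-balance identity).
#'
#' @param spec a \code{\link{mixture_spec}}.
#' @param seed integer seed.
#' @return data.frame with columns \code{x_ee, x_ei, x_es}.
#' @export
simulate_latents <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(seed)
  R <- chol(spec$scale)
  n <- spec$n_per_component
  out <- lapply(seq_len(spec$n_components), function(k) {
    z <- matrix(rnorm(2 * n), n, 2) %*% R
    w <- sqrt(spec$df / rchisq(n, spec$df))
    cbind(spec$locations_ee[k] + z[, 1] * w,
          spec$locations_ei[k] + z[, 2] * w)
  })
  X <- do.call(rbind, out)
  data.frame(x_ee = X[, 1], x_ei = X[, 2], x_es = X[, 2] - X[, 1])
}

#' Device bias function for energy expenditure
#'
#' Smooth monotone bias linking the period-specific true EE to the device's
#' expected reading: \code{2x - 4000 / (1 + exp(-0.002 (x - 2200)))}.
#' Strictly increasing, approximately \code{2x} far below 2200 and
#' \code{2x - 4000} far above.
#'
#' @param x true EE, kcal/day.
#' @return Expected device EE before covariate effects and noise.
#' @export
bias_mee <- function(x) 2 * x - 4000 / (1 + exp(-0.002 * (x - 2200)))

#' Device bias function for change in energy stores
#'
#' \code{1000 / (1 + exp(-0.04 (x - 2000))) + x}: essentially the identity
#' over the physiologic dES range (|x| well below 2000), with a smooth
#' upward shelf far above it. Strictly increasing.
#'
#' @param x true dES, kcal/day.
#' @return Expected device dES before covariate effects and noise.
#' @export
bias_mes <- function(x) 1000 / (1 + exp(-0.04 * (x - 2000))) + x

#' Measurement-error family specification
#'
#' Zero-mean error distributions moment-matched to a target standard
#' deviation: \code{"normal"}; \code{"skewed"}, a skew-normal with shape
#' \code{alpha}; or \code{"bimodal"}, an equal-weight mixture of two normals
#' with component means at \code{+/- separation} component-sds, rescaled so
#' the overall sd equals \code{sd} (separation > 1 gives two genuine modes).
#'
#' @param family one of \code{"normal"}, \code{"skewed"}, \code{"bimodal"}.
#' @param sd target standard deviation, kcal/day.
#' @param alpha skew-normal shape (skewed family).
#' @param separation mode separation in component-sd units (bimodal family).
#' @return Object of class \code{error_spec}.
#' @export
error_spec <- function(family = c("normal", "skewed", "bimodal"), sd,
                       alpha = 4, separation = 1.2) {
  family <- match.arg(family)
  if (!is.numeric(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  structure(list(family = family, sd = sd, alpha = alpha,
                 separation = separation),
            class = "error_spec")
}

#' Draw measurement errors
#'
#' Samples \code{n} errors from the family in \code{spec}. Every family has
#' mean exactly 0 and standard deviation exactly \code{spec$sd} by
#' construction (moment matching).
#'
#' @param spec an \code{\link{error_spec}}.
#' @param n number of draws.
#' @param seed optional integer seed; \code{NULL} uses the current RNG state.
#' @return Numeric vector of length \code{n}.
#' @export
simulate_errors <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "error_spec"))
  if (!is.null(seed)) set.seed(seed)
  switch(spec$family,
    normal = rnorm(n, 0, spec$sd),
    skewed = {
      # SN(0,1,alpha) via the convolution representation, then centre/scale
      d <- spec$alpha / sqrt(1 + spec$alpha^2)
      z <- d * abs(rnorm(n)) + sqrt(1 - d^2) * rnorm(n)
      mu <- d * sqrt(2 / pi)
      (z - mu) / sqrt(1 - mu^2) * spec$sd
    },
    bimodal = {
      # component means +/- a*s0, common sd s0, scaled to overall sd
      a <- spec$separation
      s0 <- spec$sd / sqrt(1 + a^2)
      sgn <- ifelse(runif(n) < 0.5, -1, 1)
      sgn * a * s0 + rnorm(n, 0, s0)
    })
}

# closed-form skewness of the moment-matched skew-normal family
skew_normal_skewness <- function(alpha) {
  d <- alpha / sqrt(1 + alpha^2)
  mu <- d * sqrt(2 / pi)
  (4 - pi) / 2 * mu^3 / (1 - mu^2)^1.5
}

#' Within-person day-to-day variability specification
#'
#' The deviation of a subject's period-j true (EE, dES) from their usual
#' values, drawn jointly bivariate-normal per (subject, period).
#'
#' @param sd_ee,sd_es standard deviations, kcal/day.
#' @param correlation correlation between the EE and dES deviations.
#' @return Object of class \code{within_person_spec}.
#' @export
within_person_spec <- function(sd_ee = 150,
                               sd_es = sqrt(72.86^2 - 50^2),
                               correlation = 0.3) {
  if (sd_ee <= 0 || sd_es <= 0) stop("sds must be positive", call. = FALSE)
  if (abs(correlation) >= 1) stop("|correlation| must be < 1", call. = FALSE)
  structure(list(sd_ee = sd_ee, sd_es = sd_es, correlation = correlation),
            class = "within_person_spec")
}

#' Generator configuration
#'
#' The full stated world of the synthetic study. Defaults: 300 subjects,
#' device covariate effects gamma_ee = (300, 14, -7) and
#' gamma_es = (-200, 8, -5) for (gender, BMI, age); gold-standard instrument
#' error sds 200 (EE) and 50 (dES) which combine with the within-person sds
#' to total gold-standard error sds 250.00 and 72.86; device error sds
#' 395.36 (EE) and 329.77 (dES), calibrated once so the Monte Carlo residual
#' sds of the device channels (see \code{\link{approximate_sigma_y_truth}})
#' are about 405.5 and 334.
#'
#' @param n_subjects number of subjects; the mixture's per-component count is
#'   scaled to match (must be divisible by the number of components).
#' @param n_replicates replicate measurement periods per subject (2 or 4).
#' @param gamma_ee,gamma_es device covariate coefficients (gender, BMI, age).
#' @param mixture a \code{\link{mixture_spec}}.
#' @param within a \code{\link{within_person_spec}}.
#' @param error_family error family for all four instruments.
#' @param sd_u_ee,sd_u_es gold-standard instrument error sds.
#' @param sd_eps_ee,sd_eps_es device instrument error sds.
#' @param seed root seed; independent sub-streams are derived per component.
#' @return Object of class \code{generator_config}.
#' @export
generator_config <- function(n_subjects = 300L, n_replicates = 4L,
                             gamma_ee = c(300, 14, -7),
                             gamma_es = c(-200, 8, -5),
                             mixture = NULL,
                             within = within_person_spec(),
                             error_family = "normal",
                             sd_u_ee = 200, sd_u_es = 50,
                             sd_eps_ee = 395.36, sd_eps_es = 329.77,
                             seed = 1L) {
  if (is.null(mixture)) mixture <- mixture_spec()
  m <- mixture$n_components
  if (n_subjects %% m != 0)
    stop(sprintf("n_subjects must be divisible by %d components", m),
         call. = FALSE)
  mixture$n_per_component <- n_subjects / m
  if (!n_replicates >= 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (length(gamma_ee) != 3 || length(gamma_es) != 3)
    stop("gamma vectors must have length 3 (gender, BMI, age)", call. = FALSE)
  stopifnot(inherits(within, "within_person_spec"))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_replicates = as.integer(n_replicates),
                 gamma_ee = gamma_ee, gamma_es = gamma_es,
                 mixture = mixture, within = within,
                 error_family = match.arg(error_family,
                                          c("normal", "skewed", "bimodal")),
                 sd_u_ee = sd_u_ee, sd_u_es = sd_u_es,
                 sd_eps_ee = sd_eps_ee, sd_eps_es = sd_eps_es,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# draw the within-person deviations: list of two n x J matrices
draw_within <- function(within, n, J) {
  r <- within$correlation
  z1 <- matrix(rnorm(n * J), n, J)
  z2 <- matrix(rnorm(n * J), n, J)
  d_ee <- within$sd_ee * z1
  d_es <- within$sd_es * (r * z1 + sqrt(1 - r^2) * z2)
  list(ee = d_ee, es = d_es)
}

#' Assemble a complete synthetic dataset
#'
#' Generates covariates, latent usual values, within-person deviations and
#' instrument errors, then composes the four measurement channels:
#' gold standard \code{W_ij = X_i + delta_ij + u_ij}, device
#' \code{Y_ij = m(X_i + delta_ij) + gamma' Z_i + eps_ij}. The same
#' within-person deviation enters the gold-standard and device channels of
#' the same period, since both instruments observe the same days.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @return Object of class \code{eb_dataset}: covariates, truth (per-subject
#'   latents), and n x J matrices \code{w_ee, w_es, y_ee, y_es}.
#' @export
assemble_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_subjects; J <- cfg$n_replicates
  covs <- simulate_covariates(n, derive_seed(cfg$seed, "covariates"))
  lat <- simulate_latents(cfg$mixture, derive_seed(cfg$seed, "latents"))
  # mixture emits components in blocks; shuffle so subject order is exchangeable
  set.seed(derive_seed(cfg$seed, "shuffle"))
  lat <- lat[sample.int(n), , drop = FALSE]
  rownames(lat) <- NULL

  set.seed(derive_seed(cfg$seed, "within"))
  d <- draw_within(cfg$within, n, J)

  fam <- cfg$error_family
  u_ee <- matrix(simulate_errors(error_spec(fam, cfg$sd_u_ee), n * J,
                                 derive_seed(cfg$seed, "u_ee")), n, J)
  u_es <- matrix(simulate_errors(error_spec(fam, cfg$sd_u_es), n * J,
                                 derive_seed(cfg$seed, "u_es")), n, J)
  e_ee <- matrix(simulate_errors(error_spec(fam, cfg$sd_eps_ee), n * J,
                                 derive_seed(cfg$seed, "eps_ee")), n, J)
  e_es <- matrix(simulate_errors(error_spec(fam, cfg$sd_eps_es), n * J,
                                 derive_seed(cfg$seed, "eps_es")), n, J)

  Z <- covariate_matrix(covs)
  zg_ee <- drop(Z %*% cfg$gamma_ee)
  zg_es <- drop(Z %*% cfg$gamma_es)

  x_ee_ij <- lat$x_ee + d$ee           # period-specific truths (n x J)
  x_es_ij <- lat$x_es + d$es

  structure(list(
    covariates = covs,
    truth = lat,
    w_ee = x_ee_ij + u_ee,
    w_es = x_es_ij + u_es,
    y_ee = bias_mee(x_ee_ij) + zg_ee + e_ee,
    y_es = bias_mes(x_es_ij) + zg_es + e_es,
    config = cfg),
    class = "eb_dataset")
}

#' Simulate a synthetic energy-balance dataset
#'
#' Convenience front end to \code{\link{assemble_dataset}} with the default
#' generator configuration.
#'
#' @param n_subjects,n_replicates,error_family,seed see
#'   \code{\link{generator_config}}.
#' @param ... further arguments to \code{\link{generator_config}}.
#' @return An \code{eb_dataset}.
#' @export
simulate_eb_dataset <- function(n_subjects = 300L, n_replicates = 4L,
                                error_family = "normal", seed = 1L, ...) {
  assemble_dataset(generator_config(n_subjects = n_subjects,
                                    n_replicates = n_replicates,
                                    error_family = error_family,
                                    seed = seed, ...))
}

#' @export
print.eb_dataset <- function(x, ...) {
  cat(sprintf("<eb_dataset> %d subjects x %d replicates (%s errors)\n",
              nrow(x$covariates), ncol(x$w_ee),
              if (!is.null(x$config)) x$config$error_family else "?"))
  invisible(x)
}

#' Monte Carlo approximation of the device residual sds
#'
#' The device error term in the fitted models absorbs both the instrument
#' error and the within-person deviation propagated through the bias
#' function. This function approximates the resulting "true" residual sds by
#' generating many datasets, removing the mean function evaluated at the
#' usual values, and averaging the residual standard deviations - the
#' starred truth values of the simulation-study tables.
#'
#' @param cfg a \code{\link{generator_config}}.
#' @param n_datasets number of generated datasets (the reference run uses
#'   10000; smaller values give a noisier estimate).
#' @return Named vector \code{c(sd_ee, sd_es)}.
#' @export
approximate_sigma_y_truth <- function(cfg, n_datasets = 10000L) {
  stopifnot(inherits(cfg, "generator_config"))
  sds_ee <- numeric(n_datasets); sds_es <- numeric(n_datasets)
  for (b in seq_len(n_datasets)) {
    cfg_b <- cfg
    cfg_b$seed <- derive_seed(cfg$seed, paste0("sigma_y_truth", b))
    ds <- assemble_dataset(cfg_b)
    Z <- covariate_matrix(ds$covariates)
    mean_ee <- bias_mee(ds$truth$x_ee) + drop(Z %*% cfg$gamma_ee)
    mean_es <- bias_mes(ds$truth$x_es) + drop(Z %*% cfg$gamma_es)
    sds_ee[b] <- sd(ds$y_ee - mean_ee)
    sds_es[b] <- sd(ds$y_es - mean_es)
  }
  c(sd_ee = mean(sds_ee), sd_es = mean(sds_es))
}
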