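# ---------------------------------------------------------------------------
# Monte Carlo simulation study: generate datasets across error families and
# replicate counts, fit the selected models, and summarise parameter
# recovery (Mean Est / Std Err / Bias vs truth) and prediction mean squared
# error of the device mean functions.
# ---------------------------------------------------------------------------

#' Prediction mean squared error of a fitted device mean function
#'
#' Mean over subjects of the squared difference between the posterior-mean
#' fitted device mean and the true generating mean \code{m(X) + gamma' Z},
#' evaluated at each simulated subject (not a fixed grid, so absolute
#' levels depend on the latent distribution). Each model's regression
#' function is evaluated at its own regressor: the hierarchical models
#' (LMEM, SMEMN, SMEM) model the device mean as a function of the latent
#' usual value and are evaluated at the subject's true latent; the naive
#' model regresses on the gold-standard measurement and is evaluated at the
#' subject's gold-standard replicate mean, so the gold-standard noise it
#' wrongly treats as error-free counts against its predictions.
#'
#' @param draws an \code{eb_draws} from any of the four models.
#' @param dataset the simulated \code{eb_dataset} the model was fitted to
#'   (its \code{truth} and \code{config} supply the evaluation points and
#'   the generating mean).
#' @param attribute \code{"ee"} or \code{"es"}.
#' @param max_spline_draws cap on posterior draws used to average the
#'   spline mean function.
#' @return Scalar PMSE (kcal^2/day^2).
#' @export
pmse <- function(draws, dataset, attribute = c("ee", "es"),
                 max_spline_draws = 400L) {
  attribute <- match.arg(attribute)
  stopifnot(inherits(draws, "eb_draws"))
  if (is.null(dataset$truth) || is.null(dataset$config))
    stop("dataset must carry generator truth and config", call. = FALSE)
  cfg <- dataset$config
  Z <- covariate_matrix(dataset$covariates)
  if (attribute == "ee") {
    x <- dataset$truth$x_ee
    true_mean <- bias_mee(x) + drop(Z %*% cfg$gamma_ee)
    w <- rowMeans(dataset$w_ee)
  } else {
    x <- dataset$truth$x_es
    true_mean <- bias_mes(x) + drop(Z %*% cfg$gamma_es)
    w <- rowMeans(dataset$w_es)
  }
  at <- if (draws$kind == "naive") w else x
  fitted_mean <- fitted_device_mean(draws, at, Z, attribute, max_spline_draws)
  mean((fitted_mean - true_mean)^2)
}

# posterior-mean device mean function evaluated at regressor positions x
fitted_device_mean <- function(draws, x, Z, attribute, max_spline_draws) {
  suf <- paste0("_", attribute)
  if (draws$kind %in% c("naive", "lmem")) {
    ps <- posterior_summary(draws)
    g <- function(p) ps$mean[ps$parameter == paste0(p, suf)]
    return(g("beta0") + g("beta1") * x +
             drop(Z %*% c(g("gamma1"), g("gamma2"), g("gamma3"))))
  }
  boundary <- if (attribute == "ee") draws$boundary_ee else draws$boundary_es
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  sdraws <- do.call(c, draws$spline)
  if (length(sdraws) > max_spline_draws)
    sdraws <- sdraws[round(seq(1, length(sdraws),
                               length.out = max_spline_draws))]
  kf <- paste0("knots", suf); bf <- paste0("beta", suf)
  gf <- paste0("gamma", suf)
  acc <- numeric(length(x))
  for (d in sdraws) {
    ks <- knot_set(d[[kf]], boundary)
    acc <- acc + evaluate_spline(xc, ks, d[[bf]]) + drop(Z %*% d[[gf]])
  }
  acc / length(sdraws)
}

#' Simulation-study configuration
#'
#' @param families error families to simulate.
#' @param replicates replicate counts to simulate.
#' @param models models to fit (\code{"naive"}, \code{"lmem"},
#'   \code{"smemn"}, \code{"smem"}).
#' @param n_datasets Monte Carlo datasets per cell (the reference study uses
#'   200; the scaled-down default is 25).
#' @param generator base \code{\link{generator_config}} (its seed and
#'   replicate count are overridden per cell).
#' @param chains \code{\link{chain_config}} used for every fit.
#' @param seed root seed; per-cell seeds are derived from
#'   (root, model, family, replicates, dataset index).
#' @return Object of class \code{study_config}.
#' @export
study_config <- function(families = "normal", replicates = 4L,
                         models = c("naive", "lmem", "smemn"),
                         n_datasets = 25L,
                         generator = generator_config(),
                         chains = chain_config(n_chains = 1L,
                                               n_iterations = 4000L,
                                               burn_in = 1000L),
                         seed = 1L) {
  models <- match.arg(models, c("naive", "lmem", "smemn", "smem"),
                      several.ok = TRUE)
  families <- match.arg(families, c("normal", "skewed", "bimodal"),
                        several.ok = TRUE)
  stopifnot(length(replicates) >= 1, n_datasets >= 2)
  structure(list(families = families, replicates = as.integer(replicates),
                 models = models, n_datasets = as.integer(n_datasets),
                 generator = generator, chains = chains,
                 seed = as.integer(seed)),
            class = "study_config")
}

fit_model <- function(model, dataset, chains, hyper = hyperparameters()) {
  switch(model,
         naive = gibbs_fit(naive_spec(hyper), dataset, chains),
         lmem  = gibbs_fit(lmem_spec(hyper), dataset, chains),
         smemn = rjmcmc_fit(smemn_spec(hyper), dataset, chains),
         smem  = rjmcmc_fit(smem_spec(hyper), dataset, chains),
         stop("unknown model: ", model, call. = FALSE))
}

# parameters reported per model, in simulation-table naming
study_parameters <- function(model) {
  base <- c(sigma_yee = "sig_eps_ee", sigma_yes = "sig_eps_es")
  hier <- c(sigma_wee = "sig_nu_ee", sigma_wes = "sig_nu_es")
  gam <- setNames(
    as.vector(outer(c("gamma1", "gamma2", "gamma3"), c("ee", "es"),
                    paste, sep = "_")),
    as.vector(outer(c("gamma1", "gamma2", "gamma3"), c("ee", "es"),
                    paste, sep = "_")))
  if (model == "naive") c(base, gam) else c(base, hier, gam)
}

study_truth <- function(cfg_gen, sigma_y_truth = c(NA, NA)) {
  c(sigma_yee = unname(sigma_y_truth[1]), sigma_yes = unname(sigma_y_truth[2]),
    sigma_wee = sqrt(cfg_gen$sd_u_ee^2 + cfg_gen$within$sd_ee^2),
    sigma_wes = sqrt(cfg_gen$sd_u_es^2 + cfg_gen$within$sd_es^2),
    setNames(c(cfg_gen$gamma_ee, cfg_gen$gamma_es),
             as.vector(outer(c("gamma1", "gamma2", "gamma3"), c("ee", "es"),
                             paste, sep = "_"))))
}

#' Run the Monte Carlo simulation study
#'
#' For every (model, family, replicate-count) cell, generates
#' \code{n_datasets} datasets with per-cell derived seeds, fits the model,
#' and aggregates posterior means into Mean Est, Std Err (sd of posterior
#' means across datasets) and Bias rows, alongside per-dataset log PMSE of
#' both device mean functions. Individual fit failures are counted and
#' excluded, never silently dropped.
#'
#' @param cfg a \code{\link{study_config}}.
#' @param sigma_y_truth_reps Monte Carlo datasets used to approximate the
#'   device residual-sd truths (the reference run uses 10000; default 200
#'   here for desk-scale runtime); set to 0 to skip.
#' @param verbose print per-cell progress.
#' @return Object of class \code{study_result}: \code{$table} (long-format
#'   parameter summary), \code{$pmse} (per-dataset log PMSE), and
#'   \code{$failures}.
#' @export
run_study <- function(cfg, sigma_y_truth_reps = 200L, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  sy <- c(NA_real_, NA_real_)
  if (sigma_y_truth_reps > 0) {
    gen0 <- cfg$generator
    gen0$seed <- derive_seed(cfg$seed, "sigma_y_truth")
    sy <- approximate_sigma_y_truth(gen0, sigma_y_truth_reps)
  }
  rows <- list(); pmse_rows <- list(); failures <- list()
  for (model in cfg$models) for (fam in cfg$families)
    for (J in cfg$replicates) {
      if (verbose)
        message(sprintf("cell: %s / %s / %d replicates", model, fam, J))
      pars <- study_parameters(model)
      est <- matrix(NA_real_, cfg$n_datasets, length(pars),
                    dimnames = list(NULL, names(pars)))
      lp <- matrix(NA_real_, cfg$n_datasets, 2,
                   dimnames = list(NULL, c("ee", "es")))
      n_fail <- 0L
      for (b in seq_len(cfg$n_datasets)) {
        gen <- cfg$generator
        gen$n_replicates <- J
        gen$error_family <- fam
        gen$seed <- derive_seed(cfg$seed,
                                paste(model, fam, J, b, sep = ":"))
        ds <- assemble_dataset(gen)
        ch <- cfg$chains
        ch$seed <- derive_seed(gen$seed, "fit")
        fit <- tryCatch(fit_model(model, ds, ch), error = function(e) e)
        if (inherits(fit, "error")) {
          n_fail <- n_fail + 1L
          failures[[length(failures) + 1]] <-
            data.frame(model = model, family = fam, replicates = J,
                       dataset = b, message = conditionMessage(fit))
          next
        }
        ps <- posterior_summary(fit)
        est[b, ] <- ps$mean[match(pars, ps$parameter)]
        lp[b, "ee"] <- log(pmse(fit, ds, "ee"))
        lp[b, "es"] <- log(pmse(fit, ds, "es"))
      }
      tr <- study_truth(cfg$generator, sy)
      me <- colMeans(est, na.rm = TRUE)
      se <- apply(est, 2, sd, na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        model = model, family = fam, replicates = J,
        parameter = names(pars), mean_est = unname(me),
        std_err = unname(se), truth = unname(tr[names(pars)]),
        bias = unname(me - tr[names(pars)]),
        n_datasets = cfg$n_datasets - n_fail)
      pmse_rows[[length(pmse_rows) + 1]] <- data.frame(
        model = model, family = fam, replicates = J,
        dataset = seq_len(cfg$n_datasets),
        log_pmse_ee = lp[, "ee"], log_pmse_es = lp[, "es"])
    }
  structure(list(table = do.call(rbind, rows),
                 pmse = do.call(rbind, pmse_rows),
                 failures = if (length(failures))
                   do.call(rbind, failures) else NULL,
                 sigma_y_truth = sy),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(x$table)
  invisible(x)
}
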