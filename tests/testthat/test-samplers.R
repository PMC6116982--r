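test_that("coefficient and variance updates match conjugate closed forms", {
  # intercept-only toy: y ~ N(theta, sig2), theta ~ N(0, c0)
  set.seed(91)
  y <- rnorm(40, 5, 2); sig2 <- 4; c0 <- 10
  post_var <- 1 / (length(y) / sig2 + 1 / c0)
  post_mean <- post_var * sum(y) / sig2
  D <- matrix(1, length(y), 1)
  draws <- replicate(4000, ebmem:::draw_coefficients(D, y, sig2, 0, c0))
  expect_lt(abs(mean(draws) - post_mean), 4 * sqrt(post_var / 4000))
  expect_lt(abs(sd(draws) - sqrt(post_var)), 4 * sqrt(post_var / 4000))
  # variance update: 1/sig2 ~ Gamma(a + n/2, b + SS/2)
  r <- rnorm(60, 0, 3)
  vs <- replicate(4000, ebmem:::draw_variance(0.1, 0.1, r))
  a_post <- 0.1 + 30; b_post <- 0.1 + sum(r^2) / 2
  expect_lt(abs(mean(1 / vs) - a_post / b_post),
            4 * sqrt(a_post / b_post^2 / 4000))
})

test_that("gibbs_fit is deterministic given the seed and validates input", {
  ds <- small_dataset(seed = 92, J = 2)
  cc <- short_chain(n = 300, burn = 100, seed = 9)
  f1 <- fit_lmem(ds, cc); f2 <- fit_lmem(ds, cc)
  expect_identical(f1$chains, f2$chains)
  ds_bad <- ds; ds_bad$covariates$gender <- 1
  expect_error(fit_lmem(ds_bad, cc), "constant")
  expect_error(gibbs_fit(smemn_spec(), ds, cc), "rjmcmc_fit")
})

test_that("zero-noise LMEM pins the latents at the gold-standard means", {
  cfg <- generator_config(n_subjects = 50, n_replicates = 2,
                          within = within_person_spec(1e-6, 1e-6, 0),
                          sd_u_ee = 1e-6, sd_u_es = 1e-6, seed = 93)
  ds <- assemble_dataset(cfg)
  fit <- fit_lmem(ds, short_chain(n = 600, burn = 200, seed = 3,
                                  store_latents = TRUE))
  lat <- attr(fit$chains[[1]], "latents")
  xbar <- Reduce(`+`, lat) / length(lat)
  wbar <- cbind(rowMeans(ds$w_ee), rowMeans(ds$w_es))
  # the inverse-gamma prior keeps sigma_nu near 0.01, so agreement is tight
  expect_lt(max(abs(xbar - wbar)), 0.1)
})

test_that("naive and LMEM recover generator parameters on a dataset", {
  ds <- default_dataset()
  fit <- fit_lmem(ds, short_chain(n = 2000, burn = 500, seed = 15))
  ps <- posterior_summary(fit)
  g <- function(p) ps[ps$parameter == p, ]
  # covariates are error-free: gamma_es recovered nearly without bias
  expect_lt(abs(g("gamma1_es")$mean - (-200)), 4 * g("gamma1_es")$sd)
  expect_lt(abs(g("sig_nu_ee")$mean - 250), 25)
  expect_lt(abs(g("sig_nu_es")$mean - 72.86), 8)
})

test_that("gelman_rubin matches its defining formula and limits", {
  mk <- function(...) {
    chains <- lapply(list(...), function(v) matrix(v, ncol = 1,
                                                   dimnames = list(NULL, "p")))
    ebmem:::new_eb_draws("naive", chains, NULL)
  }
  v <- rnorm(1000)
  # exact copies: B = 0, so PSRF = sqrt((n-1)/n), i.e. 1 up to O(1/n)
  expect_equal(unname(gelman_rubin(mk(v, v), "p")), 1, tolerance = 1e-3)
  far <- gelman_rubin(mk(rnorm(1000), rnorm(1000, 10)), "p")
  expect_gt(far, 5)
  near <- gelman_rubin(mk(rnorm(5000), rnorm(5000)), "p")
  expect_lt(near, 1.05)
  expect_error(gelman_rubin(mk(v), "p"), "two chains")
})

test_that("posterior_summary pools chains and handles constants", {
  mk2 <- ebmem:::new_eb_draws("naive", list(
    matrix(c(1, 2), 2, 1, dimnames = list(NULL, "p")),
    matrix(c(3, 4), 2, 1, dimnames = list(NULL, "p"))), NULL)
  s <- posterior_summary(mk2, "p")
  expect_equal(s$mean, 2.5)
  const <- ebmem:::new_eb_draws("naive", list(
    matrix(7, 10, 1, dimnames = list(NULL, "p"))), NULL)
  sc <- posterior_summary(const, "p")
  expect_equal(sc$mean, 7); expect_equal(sc$sd, 0)
  expect_equal(sc$q2.5, 7); expect_equal(sc$q97.5, 7)
})

test_that("RJ acceptance ratio is antisymmetric for matched birth/death", {
  f <- function(k) {
    if (k == 0) c(birth = 1, death = 0, move = 0)
    else if (k >= 30) c(birth = 0, death = 0.5, move = 0.5)
    else c(birth = 0.35, death = 0.35, move = 0.30)
  }
  for (lambda in c(0.5, 1, 3)) for (k in c(0, 1, 5, 29)) {
    up <- ebmem:::rj_log_prior_proposal("birth", k, lambda, f)
    down <- ebmem:::rj_log_prior_proposal("death", k + 1, lambda, f)
    expect_equal(unname(up + down), 0)
  }
  expect_equal(ebmem:::rj_log_prior_proposal("move", 3, 1, f), 0)
})

test_that("RJ sampler concentrates on few knots for linear truth", {
  set.seed(94)
  n <- 80
  x <- rnorm(n, 2500, 300)
  covs <- data.frame(subject_id = 1:n, gender = rbinom(n, 1, 0.5),
                     age = runif(n, 20, 40), bmi = rnorm(n, 27, 5))
  Z <- as.matrix(covs[, c("gender", "bmi", "age")])
  gee <- c(50, 2, -1)
  mk <- function(v) cbind(v, v) + matrix(rnorm(2 * n, 0, 0.5), n, 2)
  ds <- structure(list(
    covariates = covs, truth = NULL,
    w_ee = mk(x), w_es = mk(x - 2400),
    y_ee = mk(1.5 * x + drop(Z %*% gee)),
    y_es = mk(0.8 * (x - 2400) + drop(Z %*% gee))),
    class = "eb_dataset")
  fit <- fit_smem(ds, "normal", short_chain(n = 800, burn = 300, seed = 5,
                                            prop_sd = c(2, 2)))
  ps <- posterior_summary(fit, c("k_ee", "k_es", "gamma1_ee"))
  # OLS plug-in likelihoods carry no Occam factor, so the knot count is
  # held down by the Poisson prior alone: expect the "four or fewer" regime
  expect_lte(ps$median[1], 4)
  expect_lte(ps$median[2], 4)
  expect_lt(abs(ps$mean[3] - 50), 2)
  # fitted spline within 1% of the generating line over the latent bulk
  grid <- seq(quantile(x, 0.05), quantile(x, 0.95), length.out = 50)
  sm <- Reduce(`+`, lapply(fit$spline[[1]], function(d)
    evaluate_spline(grid, knot_set(d$knots_ee, fit$boundary_ee),
                    d$beta_ee))) / length(fit$spline[[1]])
  rel <- max(abs(sm - 1.5 * grid)) / diff(range(1.5 * grid))
  expect_lt(rel, 0.01)
})

test_that("every retained spline draw is monotone and seeds reproduce", {
  fit <- smemn_fit()
  mono <- vapply(fit$spline[[1]], function(d)
    is_monotone(d$beta_ee) && is_monotone(d$beta_es), TRUE)
  expect_true(all(mono))
  ds <- small_dataset(seed = 95, J = 4)
  cc <- short_chain(n = 250, burn = 100, seed = 77)
  f1 <- fit_smem(ds, "normal", cc)
  f2 <- fit_smem(ds, "normal", cc)
  expect_identical(f1$chains, f2$chains)
})

test_that("knot counts stay parsimonious on default data", {
  ps <- posterior_summary(smemn_fit(), c("k_ee", "k_es"))
  expect_lte(ps$median[1], 4)
  expect_lte(ps$median[2], 4)
})

test_that("the DP variant runs, recovers, and warns at two replicates", {
  ds <- small_dataset(seed = 96, J = 4)
  fit <- fit_smem(ds, "dp", short_chain(n = 700, burn = 300, seed = 6))
  ps <- posterior_summary(fit, c("gamma1_es", "n_clusters"))
  expect_lt(abs(ps$mean[1] - (-200)), 40)
  expect_gte(min(ps$q2.5[2]), 1)
  ds2 <- small_dataset(seed = 97, J = 2)
  expect_warning(fit_smem(ds2, "dp", short_chain(n = 60, burn = 20, seed = 1)),
                 "unstable")
})
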