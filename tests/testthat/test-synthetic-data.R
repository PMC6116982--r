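test_that("covariates follow the stated marginals", {
  cv <- simulate_covariates(300, seed = 11)
  expect_true(all(cv$gender %in% 0:1))
  expect_true(all(cv$age >= 20 & cv$age <= 40))
  expect_gt(mean(cv$gender), 0.38)   # 3.5 sigma binomial bound
  expect_lt(mean(cv$gender), 0.62)
  big <- simulate_covariates(1e5, seed = 12)
  expect_lt(abs(mean(big$bmi) - 27), 3.5 * 5 / sqrt(1e5))
  expect_lt(abs(mean(big$age) - 30), 3.5 * (20 / sqrt(12)) / sqrt(1e5))
  one <- simulate_covariates(1, seed = 13)
  expect_equal(nrow(one), 1)
  expect_true(one$age >= 20 && one$age <= 40)
  expect_error(simulate_covariates(0), ">= 1")
})

test_that("latent mixture hits the target correlation and the identity", {
  lat <- simulate_latents(mixture_spec(n_per_component = 30000), seed = 21)
  expect_lt(abs(cor(lat$x_ee, lat$x_ei) - 0.4376), 0.01)
  expect_identical(lat$x_ei - lat$x_ee - lat$x_es, rep(0, nrow(lat)))
})

test_that("t components approach their scale matrix as df grows", {
  # df -> infinity limit: component sample covariance ~ scale matrix;
  # at finite df the factor is df/(df-2)
  sp_big <- mixture_spec(locations_ee = 0, locations_ei = 0,
                         scale_sd_ee = 100, scale_sd_es = 100,
                         df = 1e6, n_per_component = 60000, target_cor = NA)
  lat <- simulate_latents(sp_big, seed = 22)
  S <- cov(cbind(lat$x_ee, lat$x_ei))
  expect_lt(max(abs(S / 1e4 - diag(2))), 0.05)
  sp5 <- mixture_spec(locations_ee = 0, locations_ei = 0,
                      scale_sd_ee = 100, scale_sd_es = 100,
                      df = 5, n_per_component = 200000, target_cor = NA)
  lat5 <- simulate_latents(sp5, seed = 23)
  expect_lt(abs(var(lat5$x_ee) / (5 / 3 * 1e4) - 1), 0.05)
})

test_that("bias functions match hand evaluations and limits", {
  expect_equal(bias_mee(2200), 2400)
  expect_lt(abs(bias_mee(-1e6) - (-2e6)), 1e-6)
  expect_equal(bias_mes(2000), 2500)
  expect_lt(abs(bias_mes(0) - 0), 1e-30)
  expect_lt(abs(bias_mes(1e6) - (1e6 + 1000)), 1e-6)
  # consistency reconstruction: male, BMI 28.6, age 20.5 at true EE 2199.25
  zg <- sum(c(300, 14, -7) * c(1, 28.6, 20.5))
  expect_lt(abs(bias_mee(2199.25) + zg - 2956), 1.5)
})

test_that("every error family is moment-matched", {
  n <- 1e6
  for (fam in c("normal", "skewed", "bimodal")) {
    sdt <- if (fam == "bimodal") 72.86 else 250
    e <- simulate_errors(error_spec(fam, sdt), n, seed = 31)
    expect_lt(abs(mean(e)), 4 * sdt / sqrt(n))
    expect_lt(abs(sd(e) - sdt), 4 * sdt / sqrt(2 * n))
  }
  # skewness of the skewed family matches the closed skew-normal form
  e <- simulate_errors(error_spec("skewed", 250, alpha = 4), n, seed = 32)
  g1 <- mean((e / sd(e))^3)
  expect_lt(abs(g1 - ebmem:::skew_normal_skewness(4)), 0.02)
  # bimodal family has two genuine modes
  e <- simulate_errors(error_spec("bimodal", 72.86), n, seed = 33)
  d <- density(e)
  dd <- diff(sign(diff(d$y)))
  expect_gte(sum(dd == -2), 2)
  expect_error(error_spec("cauchy", 10))
})

test_that("assembled dataset obeys the measurement equations", {
  # degenerate noise: W equals the usual values, Y the biased means
  cfg0 <- generator_config(
    n_subjects = 50, n_replicates = 2,
    within = within_person_spec(1e-9, 1e-9, 0),
    sd_u_ee = 1e-9, sd_u_es = 1e-9, sd_eps_ee = 1e-9, sd_eps_es = 1e-9,
    seed = 41)
  ds0 <- assemble_dataset(cfg0)
  Z <- as.matrix(ds0$covariates[, c("gender", "bmi", "age")])
  expect_lt(max(abs(ds0$w_ee - ds0$truth$x_ee)), 1e-6)
  expect_lt(max(abs(ds0$y_ee - (bias_mee(ds0$truth$x_ee) +
                                drop(Z %*% c(300, 14, -7))))), 1e-6)
  expect_lt(max(abs(ds0$y_es - (bias_mes(ds0$truth$x_es) +
                                drop(Z %*% c(-200, 8, -5))))), 1e-6)
  # shape contract and determinism
  ds4 <- simulate_eb_dataset(n_subjects = 100, n_replicates = 4, seed = 42)
  expect_equal(dim(ds4$w_es), c(100, 4))
  ds4b <- simulate_eb_dataset(n_subjects = 100, n_replicates = 4, seed = 42)
  expect_identical(ds4, ds4b)
  # energy-balance identity holds exactly for every subject
  expect_identical(ds4$truth$x_ei - ds4$truth$x_ee - ds4$truth$x_es,
                   rep(0, 100))
})

test_that("gold standard is unbiased for the usual values", {
  ds <- simulate_eb_dataset(n_subjects = 2000, n_replicates = 4, seed = 43)
  dev <- rowMeans(ds$w_ee) - ds$truth$x_ee
  expect_lt(abs(mean(dev)), 4 * 250 / sqrt(4 * 2000))
  dev_es <- rowMeans(ds$w_es) - ds$truth$x_es
  expect_lt(abs(mean(dev_es)), 4 * 72.86 / sqrt(4 * 2000))
})

test_that("sigma_y truth approximation matches closed forms", {
  # no within-person propagation: residual sd is the device error sd
  cfg <- generator_config(n_subjects = 100, n_replicates = 2,
                          within = within_person_spec(1e-9, 1e-9, 0),
                          sd_eps_ee = 300, sd_eps_es = 120, seed = 51)
  sy <- approximate_sigma_y_truth(cfg, n_datasets = 50)
  expect_lt(abs(sy["sd_ee"] - 300), 10)
  expect_lt(abs(sy["sd_es"] - 120), 5)
  # m_es is identity on the latent range: variance addition applies
  cfg2 <- generator_config(n_subjects = 100, n_replicates = 2,
                           within = within_person_spec(1e-9, 60, 0),
                           sd_eps_es = 100, seed = 52)
  sy2 <- approximate_sigma_y_truth(cfg2, n_datasets = 50)
  expect_lt(abs(sy2["sd_es"] - sqrt(60^2 + 100^2)), 6)
})

test_that("default configuration reproduces the stated truth rows", {
  cfg <- generator_config(seed = 61)
  expect_equal(sqrt(cfg$sd_u_ee^2 + cfg$within$sd_ee^2), 250)
  expect_equal(sqrt(cfg$sd_u_es^2 + cfg$within$sd_es^2), 72.86)
})
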