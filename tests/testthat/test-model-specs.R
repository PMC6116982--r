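test_that("stick-breaking weights telescope to one", {
  expect_equal(stick_break_weights(1), 1)
  expect_equal(stick_break_weights(c(0.5, 1)), c(0.5, 0.5))
  set.seed(71)
  for (rep in 1:20) {
    H <- sample(2:30, 1)
    v <- c(rbeta(H - 1, 1, 1), 1)
    p <- stick_break_weights(v)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p >= 0))
  }
  expect_error(stick_break_weights(c(0.5, 0.9)), "final element")
})

test_that("truncation level follows the expected tail-mass rule", {
  expect_equal(choose_truncation(1, 0.001), 10L)   # (1/2)^H < 1e-3
  expect_equal(choose_truncation(1, 0.5), 1L)
  eps <- 10^seq(-1, -8)
  H <- vapply(eps, choose_truncation, 0L, alpha = 1)
  expect_true(all(diff(H) >= 0))
  for (i in seq_along(eps)) {
    expect_lt((1 / 2)^H[i], eps[i])
    if (H[i] > 1) expect_gte((1 / 2)^(H[i] - 1), eps[i])
  }
})

test_that("default truncation H = 20 leaves negligible tail at alpha = 1", {
  hy <- hyperparameters()
  expect_gte(hy$H, choose_truncation(hy$alpha, 1e-3))
  expect_lt((hy$alpha / (hy$alpha + 1))^hy$H, 1e-6)
})

make_micro_dataset <- function(y_ee, y_es, w_ee, w_es, z = c(1, 25, 30)) {
  structure(list(
    covariates = data.frame(subject_id = 1, gender = z[1], age = z[3],
                            bmi = z[2]),
    w_ee = matrix(w_ee, 1, 1), w_es = matrix(w_es, 1, 1),
    y_ee = matrix(y_ee, 1, 1), y_es = matrix(y_es, 1, 1)),
    class = "eb_dataset")
}

test_that("log likelihood matches hand-computed normal peaks", {
  # naive model, observations exactly at their regression means, unit sds
  ds <- make_micro_dataset(y_ee = 100 + 2 * 10, y_es = 50 + 3 * 20,
                           w_ee = 10, w_es = 20, z = c(0, 0, 0))
  ds$covariates[, c("gender", "bmi", "age")] <- 0
  st <- list(beta0 = c(100, 50), beta1 = c(2, 3),
             gamma_ee = c(0, 0, 0), gamma_es = c(0, 0, 0),
             sig_eps = c(1, 1))
  expect_equal(log_likelihood(naive_spec(), ds, st), 2 * (-0.5 * log(2 * pi)))
  # lmem with all four channels at their means: four peaks + latent prior
  st2 <- list(beta0 = c(0, 0), beta1 = c(1, 1),
              gamma_ee = c(0, 0, 0), gamma_es = c(0, 0, 0),
              sig_eps = c(1, 1), sig_nu = c(1, 1),
              x = matrix(c(10, 20), 1, 2), mu = c(10, 20), Sigma = diag(2))
  ds2 <- make_micro_dataset(10, 20, 10, 20, z = c(0, 0, 0))
  ds2$covariates[, c("gender", "bmi", "age")] <- 0
  expect_equal(log_likelihood(lmem_spec(), ds2, st2),
               4 * (-0.5 * log(2 * pi)) + (-log(2 * pi)))
  expect_error(log_likelihood(lmem_spec(), ds2,
                              modifyList(st2, list(sig_eps = c(-1, 1)))),
               "non-positive")
})

test_that("duplicating every observation doubles the log likelihood", {
  ds <- small_dataset(seed = 81, J = 2)
  st <- list(beta0 = c(100, -50), beta1 = c(1.2, 0.9),
             gamma_ee = c(10, 1, -1), gamma_es = c(-5, 0.5, 0.2),
             sig_eps = c(300, 200))
  ll1 <- log_likelihood(naive_spec(), ds, st)
  ds2 <- ds
  for (f in c("w_ee", "w_es", "y_ee", "y_es"))
    ds2[[f]] <- cbind(ds[[f]], ds[[f]])
  expect_equal(log_likelihood(naive_spec(), ds2, st), 2 * ll1)
})

test_that("a linear 0-knot spline nests the LMEM device channel", {
  ds <- small_dataset(seed = 82, J = 2)
  n <- nrow(ds$covariates)
  wr <- range(rowMeans(ds$w_ee), rowMeans(ds$w_es))
  b <- c(wr[1] - 3000, wr[2] + 3000)
  ks <- knot_set(numeric(0), b)
  # beta0 + beta1 x as a cubic Bezier: control points equally spaced
  lin_beta <- function(b0, b1) b0 + b1 * (b[1] + (b[2] - b[1]) * (0:3) / 3)
  x <- cbind(rowMeans(ds$w_ee), rowMeans(ds$w_es))
  common <- list(gamma_ee = c(10, 1, -1), gamma_es = c(-5, 0.5, 0.2),
                 sig_eps = c(300, 200), sig_nu = c(250, 70), x = x,
                 mu = colMeans(x), Sigma = cov(x))
  st_lin <- c(common, list(beta0 = c(150, -20), beta1 = c(0.8, 1.1)))
  st_spl <- c(common, list(knots_ee = ks, knots_es = ks,
                           beta_ee = lin_beta(150, 0.8),
                           beta_es = lin_beta(-20, 1.1)))
  expect_equal(log_likelihood(smemn_spec(), ds, st_spl),
               log_likelihood(lmem_spec(), ds, st_lin), tolerance = 1e-10)
})

test_that("every stated hyperparameter is carried with its default", {
  hy <- hyperparameters()
  expect_equal(hy$m_beta0, 0); expect_equal(hy$c_beta0, 1e5)
  expect_equal(hy$m_beta1, 1); expect_equal(hy$c_beta1, 1e5)
  expect_equal(hy$m_gamma, 0); expect_equal(hy$c_gamma, 1e5)
  expect_equal(hy$a, 0.1); expect_equal(hy$b, 0.1)
  expect_equal(hy$psi, diag(2)); expect_equal(hy$d, 3)
  expect_equal(hy$m_mu, c(2400, 0)); expect_equal(hy$c_mu, c(1e5, 1e5))
  expect_equal(hy$lambda_ee, 1); expect_equal(hy$lambda_es, 1)
  expect_equal(hy$alpha, 1)
})
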