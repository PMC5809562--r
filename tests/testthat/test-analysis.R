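test_that("transformed parameters evaluate arithmetic over draws", {
  out <- small_trait_fit(seed = 2, P = 10, n_iter = 400, n_burnin = 150)
  fit <- out$fit
  # self-difference is identically zero
  tr0 <- transform_draws(fit, "zero = D1 - D1")
  expect_true(all(tr0$draws$zero == 0))
  # difference equals elementwise subtraction of the stored draws
  tr <- transform_draws(fit, "dd = D1 - d1")
  flat <- hmpt:::flat_draws(fit$draws)
  expect_equal(tr$draws$dd,
               unname(flat[, "mean_D1"] - flat[, "mean_d1"]))
  expect_equal(tr$summary$p_bayes, mean(tr$draws$dd < 0))
  # individual-level transforms give one series per participant
  tri <- transform_draws(fit, "dd = D1 - d1", level = "individual")
  expect_equal(ncol(tri$draws$dd), 10)
  expect_error(transform_draws(fit, "x = D1 - qqq"), "unknown")
})

test_that("probit-normal moments match quadrature and limits", {
  # degenerate normal: mean pnorm(mu), sd 0
  r <- probit_inverse(0.3, 0)
  expect_equal(r$prob_mean, pnorm(0.3))
  expect_equal(r$prob_sd, 0)
  expect_equal(round(r$prob_mean, 4), 0.6179)
  # large sigma: Bernoulli limit mean 0.5, sd 0.5
  r2 <- probit_inverse(0, 50)
  expect_lt(abs(r2$prob_mean - 0.5), 1e-6)
  expect_lt(abs(r2$prob_sd - 0.5), 0.01)
  # quadrature oracle for an interior case
  oracle_mean <- stats::integrate(function(x)
    stats::pnorm(x) * stats::dnorm(x, 0.3, 0.6), -Inf, Inf)$value
  r3 <- probit_inverse(0.3, 0.6)
  expect_equal(r3$prob_mean, oracle_mean, tolerance = 1e-6)
  expect_equal(round(r3$prob_mean, 4), 0.6015)
})

test_that("probit moment inversion round-trips", {
  for (m in c(0.3, 0.62)) {
    for (s in c(0.05, 0.2)) {
      inv <- probit_moments(m, s)
      fwd <- probit_inverse(inv$mu, inv$sigma)
      expect_equal(fwd$prob_mean, m, tolerance = 1e-6)
      expect_equal(fwd$prob_sd, s, tolerance = 1e-6)
    }
  }
  expect_error(probit_moments(0.5, 0.6), "unattainable")
})

test_that("between-subjects comparisons difference paired draws", {
  out <- small_trait_fit(seed = 6, P = 10, n_iter = 400, n_burnin = 150)
  fit <- out$fit
  self <- between_subjects_compare(fit, fit, "D1")
  expect_equal(self$mean, 0)
  expect_true(all(self$draws == 0))
  out2 <- small_trait_fit(seed = 16, P = 10, n_iter = 400, n_burnin = 150)
  ab <- between_subjects_compare(fit, out2$fit, "D1")
  ba <- between_subjects_compare(out2$fit, fit, "D1")
  expect_equal(ab$draws, -ba$draws)
  expect_equal(ab$p_B, 1 - ba$p_B)
  # custom statistic on constant draws
  mk <- function(v) {
    arr <- array(v, c(1, 50, 1), dimnames = list(NULL, NULL, "mean_D1"))
    list(draws = structure(list(draws = arr), class = "mpt_draws"))
  }
  r <- between_subjects_compare(mk(0.6), mk(0.3), "D1", stat = "x / y")
  expect_equal(r$mean, 2)
  expect_error(between_subjects_compare(fit, out2$fit, "nope"), "not found")
})

test_that("factor group means recover a probit shift between groups", {
  model <- toy_model()
  P <- 120
  grp <- rep(c("g1", "g2"), each = P / 2)
  shift <- ifelse(grp == "g1", -0.25, 0.25)     # probit difference 0.5
  theta <- with_seed(31, {
    z <- cbind(D = 0.2 + shift + rnorm(P, 0, 0.3),
               g = rnorm(P, 0, 0.3))
    pnorm(z)
  })
  dat <- gen_mpt(theta, model, c(t1 = 100), seed = 41)
  fit <- suppressWarnings(fit_trait(
    model, dat, covariates = data.frame(grp = grp),
    predictors = predictor_spec("D ; grp", types = c(grp = "f")),
    settings = mcmc_settings(1500, 500, 2, 2, seed = 9)))
  gm <- group_means_by_factor(fit, "grp")
  d_rows <- gm[gm$parameter == "D", ]
  expect_equal(nrow(d_rows), 2)
  diff_probit <- qnorm(d_rows$mean[d_rows$level == "g2"]) -
    qnorm(d_rows$mean[d_rows$level == "g1"])
  expect_lt(abs(diff_probit - 0.5), 0.15)
  # per-draw sum-to-zero constraint on the probit scale
  draws <- attr(gm, "draws")
  eff <- qnorm(draws[["D:g1"]]) + qnorm(draws[["D:g2"]])
  mu_draws <- 2 * qnorm(hmpt:::flat_draws(fit$draws)[, "mean_D"])
  expect_equal(unname(eff), unname(mu_draws), tolerance = 1e-8)
  expect_error(group_means_by_factor(fit, "nope"), "not fitted")
})

test_that("covariate correlations behave like Pearson correlations", {
  out <- small_trait_fit(seed = 8, P = 20, n_iter = 400, n_burnin = 150)
  fit <- out$fit
  x <- with_seed(5, rnorm(20))
  cc <- covariate_correlations(fit, data.frame(x = x))
  expect_true(all(abs(unlist(cc$r_draws)) <= 1))
  # independent covariate: draws centered near zero
  expect_lt(abs(mean(cc$r_draws[["D1:x"]])), 0.2)
  # affine rescaling leaves r unchanged
  cc2 <- covariate_correlations(fit, data.frame(x = 3 * x + 7))
  expect_equal(cc$r_draws[["D1:x"]], cc2$r_draws[["D1:x"]])
  # a covariate equal to one draw's theta column correlates perfectly there
  flat <- hmpt:::flat_draws(fit$draws, "^theta_D1")
  cov_exact <- data.frame(x = as.numeric(flat[1, paste0("theta_D1[", 1:20, "]")]))
  cc3 <- covariate_correlations(fit, cov_exact)
  expect_equal(cc3$r_draws[["D1:x"]][1], 1, tolerance = 1e-10)
  expect_error(covariate_correlations(fit, data.frame(x = rep(1, 20))),
               "zero variance")
})

test_that("population correlation widens for small samples and is symmetric", {
  # single r draw at 0: density symmetric about zero
  pc <- population_correlation(0, n = 20, grid_size = 801)
  mid <- (length(pc$grid) + 1) / 2
  expect_lt(abs(pc$mean), 0.01)
  expect_equal(pc$density[mid - 100], pc$density[mid + 100], tolerance = 1e-6)
  # small n gives a wider interval than large n
  pc10 <- population_correlation(rep(0.3, 5), n = 10, grid_size = 801)
  pc100 <- population_correlation(rep(0.3, 5), n = 100, grid_size = 801)
  expect_gt(pc10$q97.5 - pc10$q2.5, pc100$q97.5 - pc100$q2.5)
  # huge n concentrates the posterior at the observed r
  pc_big <- population_correlation(0, n = 1e4, grid_size = 2001)
  expect_gt(pc_big$q2.5, -0.03)
  expect_lt(pc_big$q97.5, 0.03)
  # the averaged posterior is wider than the spread of the r draws alone
  r_draws <- with_seed(3, runif(40, 0.25, 0.35))
  pc_mix <- population_correlation(r_draws, n = 30, grid_size = 801)
  expect_gt(pc_mix$q97.5 - pc_mix$q2.5,
            diff(stats::quantile(r_draws, c(0.025, 0.975))))
})
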