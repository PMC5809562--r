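# toy kernels for engine-level checks --------------------------------------

# conjugate beta-binomial: exact Gibbs draw from Beta(a + x, b + n - x)
bb_kernel <- function(a = 2, b = 3, x = 7, n = 20) {
  list(name = "beta_binomial",
       param_names = "rate",
       init = function(chain) list(rate = stats::runif(1)),
       update = function(state, adapt, iter) {
         state$rate <- stats::rbeta(1, a + x, b + n - x)
         state
       },
       extract = function(state) c(rate = state$rate),
       log_post = function(state) 0)
}

# random-walk Metropolis targeting N(m, s^2); with a constant likelihood the
# target is just the prior
rw_normal_kernel <- function(m = 5, s = 2, step = 2.5) {
  list(name = "rw_normal",
       param_names = "x",
       init = function(chain) list(x = stats::rnorm(1, m, s)),
       update = function(state, adapt, iter) {
         prop <- state$x + step * stats::rnorm(1)
         lr <- stats::dnorm(prop, m, s, log = TRUE) -
           stats::dnorm(state$x, m, s, log = TRUE)
         if (log(stats::runif(1)) < lr) state$x <- prop
         state
       },
       extract = function(state) c(x = state$x),
       log_post = function(state) 0)
}

test_that("a conjugate Gibbs kernel recovers the analytic posterior", {
  a <- 2; b <- 3; x <- 7; n <- 20
  st <- mcmc_settings(n_iter = 3000, n_burnin = 500, thin = 1,
                      n_chains = 2, seed = 42)
  d <- run_chains(bb_kernel(a, b, x, n), st)
  flat <- as.vector(d$draws)
  post_mean <- (a + x) / (a + b + n)
  post_var <- (a + x) * (b + n - x) / ((a + b + n)^2 * (a + b + n + 1))
  mc_se <- sqrt(post_var / length(flat))  # draws are iid here
  expect_lt(abs(mean(flat) - post_mean), 3 * mc_se)
})

test_that("identical seeds give bit-identical draws", {
  st <- mcmc_settings(n_iter = 500, n_burnin = 100, thin = 2,
                      n_chains = 2, seed = 9)
  d1 <- run_chains(rw_normal_kernel(), st)
  d2 <- run_chains(rw_normal_kernel(), st)
  expect_identical(d1$draws, d2$draws)
  d3 <- run_chains(rw_normal_kernel(), mcmc_settings(500, 100, 2, 2, seed = 10))
  expect_false(identical(d1$draws, d3$draws))
})

test_that("a constant-likelihood kernel reproduces its prior moments", {
  st <- mcmc_settings(n_iter = 6000, n_burnin = 1000, thin = 2,
                      n_chains = 2, seed = 5)
  d <- run_chains(rw_normal_kernel(m = 5, s = 2), st)
  flat <- as.vector(d$draws)
  ess <- gelman_rubin(d)$ess[1]
  mc_se <- 2 / sqrt(ess)
  expect_lt(abs(mean(flat) - 5), 3 * mc_se)
  expect_lt(abs(stats::sd(flat) - 2), 0.3)
})

test_that("retained length, thinning and extension bookkeeping are exact", {
  st <- mcmc_settings(n_iter = 1000, n_burnin = 200, thin = 5,
                      n_chains = 2, seed = 1)
  k <- rw_normal_kernel()
  d <- run_chains(k, st)
  expect_equal(dim(d$draws), c(2, 160, 1))
  # extend by 0 is the identity
  expect_identical(extend_run(d, k, 0), d)
  # extension adds extra_iter / thin retained iterations per chain
  d2 <- extend_run(d, k, 500)
  expect_equal(dim(d2$draws), c(2, 260, 1))
  expect_identical(d2$draws[, 1:160, ], d$draws[, , ])
  expect_error(extend_run(d, k, 500, thin = 2), "thinning")
})

test_that("an extended run matches a single long run in distribution", {
  # iid Gibbs kernel so the Kolmogorov-Smirnov test applies exactly
  k <- bb_kernel()
  p_ok <- 0L
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    st_half <- mcmc_settings(n_iter = 800, n_burnin = 200, thin = 1,
                             n_chains = 1, seed = 100 + i)
    both <- extend_run(run_chains(k, st_half), k, 600)
    st_full <- mcmc_settings(n_iter = 1400, n_burnin = 200, thin = 1,
                             n_chains = 1, seed = 5000 + i)
    long <- run_chains(k, st_full)
    p <- suppressWarnings(stats::ks.test(as.vector(both$draws),
                                         as.vector(long$draws))$p.value)
    if (p > 0.01) p_ok <- p_ok + 1L
  }
  expect_gte(p_ok / n_rep, 0.9)
})

test_that("split-chain Rhat separates mixed from unmixed chains", {
  # chains drawn iid from the same normal: Rhat close to 1
  arr <- array(with_seed(3, stats::rnorm(4 * 1000)), c(4, 1000, 1),
               dimnames = list(NULL, NULL, "x"))
  d <- structure(list(draws = arr), class = "mpt_draws")
  gr <- gelman_rubin(d)
  expect_lt(gr$rhat[1], 1.05)
  expect_gt(gr$ess[1], 1000)
  # chains at means 0 and 10: gross disagreement
  arr2 <- arr
  arr2[1, , 1] <- arr2[1, , 1] + 10
  gr2 <- gelman_rubin(structure(list(draws = arr2), class = "mpt_draws"))
  expect_gt(gr2$rhat[1], 1.1)
  # constant chains are flagged degenerate with Rhat 1
  arr3 <- array(1, c(2, 100, 1), dimnames = list(NULL, NULL, "x"))
  gr3 <- gelman_rubin(structure(list(draws = arr3), class = "mpt_draws"))
  expect_equal(gr3$rhat[1], 1)
  expect_true(gr3$degenerate[1])
})

test_that("summary table reports moments, quantiles and diagnostics", {
  arr <- array(with_seed(8, stats::rnorm(2 * 4000)), c(2, 4000, 2),
               dimnames = list(NULL, NULL, c("x", "const")))
  arr[, , 2] <- 7
  d <- structure(list(draws = arr), class = "mpt_draws")
  s <- summarize_draws(d)
  expect_equal(s$parameter, c("x", "const"))
  expect_equal(s$sd[2], 0)
  expect_lt(abs(s$mean[1] - s$median[1]), 0.05)
  # 2.5% quantile of a standard normal is about -1.96
  expect_lt(abs(s[1, "q2.5"] + 1.96), 0.1)
})

test_that("draw CSV export and import round-trip", {
  st <- mcmc_settings(n_iter = 300, n_burnin = 100, thin = 2,
                      n_chains = 2, seed = 4)
  d <- run_chains(bb_kernel(), st)
  csv <- tempfile(fileext = ".csv"); meta <- tempfile(fileext = ".json")
  write_draws(d, csv, meta)
  d2 <- read_draws(csv)
  expect_equal(d2$draws[, , 1], d$draws[, , 1], tolerance = 1e-12)
  info <- jsonlite::read_json(meta)
  expect_equal(info$kernel, "beta_binomial")
  expect_equal(unlist(info$parameters), "rate")
  unlink(c(csv, meta))
})

test_that("proposal scales freeze after burn-in", {
  # adaptive kernel records its scale; scale must be constant post burn-in
  scales <- new.env(); scales$trace <- numeric(0)
  k <- list(name = "adaptive_probe", param_names = "x",
            init = function(chain) list(x = 0, sd = 1),
            update = function(state, adapt, iter) {
              prop <- state$x + state$sd * stats::rnorm(1)
              acc <- log(stats::runif(1)) <
                stats::dnorm(prop, log = TRUE) - stats::dnorm(state$x, log = TRUE)
              if (acc) state$x <- prop
              if (adapt) {
                state$sd <- exp(log(state$sd) + rm_step(iter) * (acc - 0.35))
              }
              scales$trace <- c(scales$trace, state$sd)
              state
            },
            extract = function(state) c(x = state$x))
  st <- mcmc_settings(n_iter = 400, n_burnin = 150, thin = 1,
                      n_chains = 1, seed = 2)
  run_chains(k, st)
  post <- scales$trace[151:400]
  expect_equal(length(unique(post)), 1L)
  expect_gt(length(unique(scales$trace[1:150])), 1L)
})

test_that("gaussian target with known covariance is sampled correctly", {
  # 2-parameter Gibbs sampler on a correlated normal
  Sg <- matrix(c(1, 0.6, 0.6, 2), 2)
  k <- list(name = "mvn_gibbs", param_names = c("x1", "x2"),
            init = function(chain) list(v = c(0, 0)),
            update = function(state, adapt, iter) {
              v <- state$v
              v[1] <- stats::rnorm(1, Sg[1, 2] / Sg[2, 2] * v[2],
                                   sqrt(Sg[1, 1] - Sg[1, 2]^2 / Sg[2, 2]))
              v[2] <- stats::rnorm(1, Sg[2, 1] / Sg[1, 1] * v[1],
                                   sqrt(Sg[2, 2] - Sg[2, 1]^2 / Sg[1, 1]))
              state$v <- v
              state
            },
            extract = function(state) c(x1 = state$v[1], x2 = state$v[2]))
  st <- mcmc_settings(n_iter = 6000, n_burnin = 500, thin = 1,
                      n_chains = 2, seed = 77)
  d <- run_chains(k, st)
  flat <- cbind(as.vector(d$draws[, , 1]), as.vector(d$draws[, , 2]))
  emp <- stats::cov(flat)
  expect_lt(max(abs(emp - Sg) / Sg[2, 2]), 0.1)
  expect_gt(min(gelman_rubin(d)$ess), 1000)
})
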