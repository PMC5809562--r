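# Beta-MPT model: independent beta population distributions per parameter
# with gamma hyperpriors on the shapes.

#' Priors for the beta-MPT model
#'
#' Gamma hyperpriors on the beta shape parameters `alpha_s` and `beta_s`
#' (default shape 1, rate 0.1 for both).
#'
#' @param alpha_shape,alpha_rate,beta_shape,beta_rate Positive gamma
#'   hyperparameters.
#' @return Object of class `beta_priors`.
#' @export
beta_priors <- function(alpha_shape = 1, alpha_rate = 0.1,
                        beta_shape = 1, beta_rate = 0.1) {
  stopifnot(alpha_shape > 0, alpha_rate > 0, beta_shape > 0, beta_rate > 0)
  structure(list(alpha_shape = alpha_shape, alpha_rate = alpha_rate,
                 beta_shape = beta_shape, beta_rate = beta_rate),
            class = "beta_priors")
}

#' Mean and variance of a beta distribution
#'
#' @param alpha,beta Positive shape parameters (vectorized).
#' @return List with `mean = alpha/(alpha+beta)` and
#'   `variance = alpha*beta / ((alpha+beta+1)(alpha+beta)^2)`.
#' @export
beta_moments <- function(alpha, beta) {
  stopifnot(all(alpha > 0), all(beta > 0))
  s <- alpha + beta
  list(mean = alpha / s, variance = alpha * beta / ((s + 1) * s^2))
}

#' Beta shape parameters from mean and SD
#'
#' Inverse of [beta_moments()]: `alpha = m(m(1-m)/v - 1)`,
#' `beta = (1-m)(m(1-m)/v - 1)`.  Requires `sd^2 < mean(1-mean)`.
#'
#' @param mean Mean in (0,1) (vectorized).
#' @param sd Positive standard deviation.
#' @return List with `alpha` and `beta`.
#' @export
moments_to_shapes <- function(mean, sd) {
  stopifnot(all(mean > 0), all(mean < 1), all(sd > 0))
  v <- sd^2
  if (any(v >= mean * (1 - mean))) {
    stop("impossible beta distribution: need sd^2 < mean*(1-mean)")
  }
  k <- mean * (1 - mean) / v - 1
  list(alpha = mean * k, beta = (1 - mean) * k)
}

# Metropolis-within-Gibbs kernel for the beta-MPT
beta_kernel <- function(model, data, priors, settings) {
  cm <- compile_mpt(model)
  counts <- data$counts
  P <- nrow(counts); S <- cm$S
  params <- model$params
  ll_rows <- make_ll_rows(cm, counts)
  target <- settings$target_acceptance
  a_sh <- priors$alpha_shape; a_rt <- priors$alpha_rate
  b_sh <- priors$beta_shape; b_rt <- priors$beta_rate

  init <- function(chain) {
    theta <- matrix(stats::rbeta(P * S, 2, 2), P, S,
                    dimnames = list(NULL, params))
    alpha <- stats::rgamma(S, 4, 1) + 1
    beta <- stats::rgamma(S, 4, 1) + 1
    list(theta = theta, lo = stats::qlogis(theta), alpha = alpha, beta = beta,
         ll = ll_rows(theta),
         sd_l = matrix(0.8, P, S), sd_a = rep(0.3, S), sd_b = rep(0.3, S))
  }

  update <- function(state, adapt, iter) {
    theta <- state$theta; lo <- state$lo; ll <- state$ll
    alpha <- state$alpha; beta <- state$beta
    step <- if (adapt) rm_step(iter) else 0
    # individual parameters, logit random walk (beta prior + Jacobian)
    for (s in seq_len(S)) {
      l_new <- lo[, s] + state$sd_l[, s] * stats::rnorm(P)
      th_new_s <- stats::plogis(l_new)
      th_new <- theta; th_new[, s] <- th_new_s
      ll_new <- ll_rows(th_new)
      # Beta(a,b) density plus logit Jacobian theta(1-theta)
      dprior <- alpha[s] * (log(th_new_s) - log(theta[, s])) +
        beta[s] * (log1p(-th_new_s) - log1p(-theta[, s]))
      acc <- log(stats::runif(P)) < (ll_new - ll + dprior)
      if (any(acc)) {
        lo[acc, s] <- l_new[acc]
        theta[acc, s] <- th_new_s[acc]
        ll[acc] <- ll_new[acc]
      }
      if (adapt) {
        state$sd_l[, s] <- exp(log(state$sd_l[, s]) + step * (acc - target))
      }
    }
    # shape parameters, log-scale random walk
    for (s in seq_len(S)) {
      lth <- sum(log(clip01(theta[, s])))
      l1m <- sum(log1p(-clip01(theta[, s])))
      a_new <- alpha[s] * exp(state$sd_a[s] * stats::rnorm(1))
      lr <- P * (lgamma(a_new + beta[s]) - lgamma(a_new) -
                   lgamma(alpha[s] + beta[s]) + lgamma(alpha[s])) +
        (a_new - alpha[s]) * lth +
        stats::dgamma(a_new, a_sh, a_rt, log = TRUE) -
        stats::dgamma(alpha[s], a_sh, a_rt, log = TRUE) +
        log(a_new) - log(alpha[s])
      acc_a <- log(stats::runif(1)) < lr
      if (acc_a) alpha[s] <- a_new
      b_new <- beta[s] * exp(state$sd_b[s] * stats::rnorm(1))
      lr <- P * (lgamma(alpha[s] + b_new) - lgamma(b_new) -
                   lgamma(alpha[s] + beta[s]) + lgamma(beta[s])) +
        (b_new - beta[s]) * l1m +
        stats::dgamma(b_new, b_sh, b_rt, log = TRUE) -
        stats::dgamma(beta[s], b_sh, b_rt, log = TRUE) +
        log(b_new) - log(beta[s])
      acc_b <- log(stats::runif(1)) < lr
      if (acc_b) beta[s] <- b_new
      if (adapt) {
        state$sd_a[s] <- exp(log(state$sd_a[s]) + step * (acc_a - target))
        state$sd_b[s] <- exp(log(state$sd_b[s]) + step * (acc_b - target))
      }
    }
    state$theta <- theta; state$lo <- lo; state$ll <- ll
    state$alpha <- alpha; state$beta <- beta
    state
  }

  theta_names <- as.vector(outer(seq_len(P), params,
                                 function(i, pm) paste0("theta_", pm, "[", i, "]")))
  param_names <- c(paste0("mean_", params), paste0("sd_", params),
                   paste0("alpha_", params), paste0("beta_", params),
                   theta_names)
  extract <- function(state) {
    mom <- beta_moments(state$alpha, state$beta)
    c(mom$mean, sqrt(mom$variance), state$alpha, state$beta,
      as.vector(state$theta))
  }
  log_post <- function(state) sum(state$ll)

  list(name = "beta_mpt", param_names = param_names, init = init,
       update = update, extract = extract, log_post = log_post)
}

#' Fit a beta-MPT model
#'
#' Samples the posterior of the hierarchical MPT model with independent
#' `Beta(alpha_s, beta_s)` population distributions per parameter.
#' Individual parameters are updated by componentwise adaptive Metropolis on
#' the logit scale; the shapes by adaptive random walks on the log scale.
#' Group-level means and SDs are derived from the shapes at every draw.
#'
#' @inheritParams fit_trait
#' @param priors A [beta_priors()] object.
#' @return Object of class `c("beta_fit", "mpt_fit")`.
#' @export
fit_beta <- function(model, data, restrictions = NULL,
                     priors = beta_priors(), settings = mcmc_settings()) {
  if (is.character(model)) model <- read_eqn(model)
  if (!is.null(restrictions)) model <- apply_restrictions(model, restrictions)
  if (is.character(data)) data <- read_freq_csv(data, model)
  if (!inherits(data, "mpt_data")) data <- as_mpt_data(data, model)
  kernel <- beta_kernel(model, data, priors, settings)
  draws <- run_chains(kernel, settings)
  fit <- structure(list(draws = draws, model = model, data = data,
                        priors = priors, settings = settings, type = "beta"),
                   class = c("beta_fit", "mpt_fit"))
  fit$summary <- summarize_draws(draws)
  group <- !grepl("^theta_", fit$summary$parameter)
  rh <- fit$summary$rhat[group]
  fit$converged <- all(is.na(rh) | rh < 1.05)
  if (!fit$converged) {
    warning("convergence not reached: max group-level Rhat = ",
            sprintf("%.3f", max(rh, na.rm = TRUE)),
            "; consider extend_run() or more iterations", call. = FALSE)
  }
  fit
}

#' Prior-implied group mean and SD for the beta-MPT
#'
#' Draws shapes from their gamma hyperpriors and returns the implied group
#' means and SDs on the probability scale.
#'
#' @param priors A [beta_priors()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Data frame with columns `mean` and `sd`.
#' @export
sample_prior_beta <- function(priors = beta_priors(), n = 5000, seed = 1) {
  with_seed(seed, {
    a <- stats::rgamma(n, priors$alpha_shape, priors$alpha_rate)
    b <- stats::rgamma(n, priors$beta_shape, priors$beta_rate)
    mom <- beta_moments(pmax(a, 1e-12), pmax(b, 1e-12))
    data.frame(mean = mom$mean, sd = sqrt(mom$variance))
  })
}
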