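# Post-fit utilities: transformed parameters, probit-normal moment mapping,
# factor-level group means, between-subjects comparisons, and covariate
# correlations with a sampling-error-corrected population posterior.

#' Evaluate transformed parameters over posterior draws
#'
#' Arithmetic expressions over fitted parameter names (e.g.
#' `"deltaDd = D1 - d1"`) are evaluated per retained draw.  At the group
#' level names refer to the probability-scale group means (`pnorm(mu_s)`
#' for the latent-trait model, `alpha/(alpha+beta)` for the beta-MPT); at
#' the individual level to each participant's `theta_ps`, returning one
#' series per participant.
#'
#' @param fit A fitted `mpt_fit`.
#' @param expressions Character vector like `"name = expression"`.
#' @param level `"group"` or `"individual"`.
#' @return List with `draws` (named list of numeric vectors, or matrices
#'   draws x participants for individual level), `summary` (mean, median,
#'   2.5/97.5% quantiles, `p_bayes` = fraction of draws below zero), and
#'   `n_dropped` (draws excluded due to division by zero, reported per
#'   expression).
#' @export
transform_draws <- function(fit, expressions, level = c("group", "individual")) {
  level <- match.arg(level)
  params <- fit$model$params
  flat <- flat_draws(fit$draws)
  parsed <- lapply(expressions, function(e) {
    halves <- strsplit(e, "=", fixed = TRUE)[[1]]
    if (length(halves) != 2L) stop("expression must be 'name = formula': ", e)
    expr <- parse(text = halves[2])[[1]]
    used <- all.vars(expr)
    unknown <- setdiff(used, params)
    if (length(unknown)) stop("expression references unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    list(name = trimws(halves[1]), expr = expr, used = used)
  })
  out_draws <- list(); n_dropped <- integer(0); summaries <- list()
  for (pe in parsed) {
    if (level == "group") {
      env <- as.data.frame(flat[, paste0("mean_", params), drop = FALSE])
      names(env) <- params
      val <- eval(pe$expr, env)
      bad <- !is.finite(val)
      n_dropped[pe$name] <- sum(bad)
      if (any(bad)) {
        warning(sum(bad), " draw(s) dropped (non-finite) for ", pe$name)
        val <- val[!bad]
      }
      out_draws[[pe$name]] <- val
      summaries[[pe$name]] <- data.frame(
        name = pe$name, mean = mean(val), median = stats::median(val),
        q2.5 = stats::quantile(val, 0.025, names = FALSE),
        q97.5 = stats::quantile(val, 0.975, names = FALSE),
        p_bayes = mean(val < 0), stringsAsFactors = FALSE)
    } else {
      P <- nrow(fit$data$counts)
      vals <- sapply(seq_len(P), function(p) {
        env <- as.data.frame(
          flat[, paste0("theta_", pe$used, "[", p, "]"), drop = FALSE])
        names(env) <- pe$used
        eval(pe$expr, env)
      })
      n_dropped[pe$name] <- sum(!is.finite(vals))
      out_draws[[pe$name]] <- vals
      summaries[[pe$name]] <- data.frame(
        name = pe$name, mean = mean(vals, na.rm = TRUE),
        median = stats::median(vals, na.rm = TRUE),
        q2.5 = stats::quantile(vals, 0.025, names = FALSE, na.rm = TRUE),
        q97.5 = stats::quantile(vals, 0.975, names = FALSE, na.rm = TRUE),
        p_bayes = mean(vals < 0, na.rm = TRUE), stringsAsFactors = FALSE)
    }
  }
  list(draws = out_draws, summary = do.call(rbind, summaries),
       n_dropped = n_dropped)
}

#' Probability-scale mean and SD implied by a probit-normal distribution
#'
#' For `X ~ N(mu, sigma^2)`, returns the mean and SD of `pnorm(X)`:
#' `E[pnorm(X)] = pnorm(mu / sqrt(1 + sigma^2))`, and the second moment via
#' adaptive quadrature.
#'
#' @param mu Probit-scale mean (vectorized).
#' @param sigma Probit-scale SD, `>= 0` (vectorized).
#' @return Data frame with columns `prob_mean`, `prob_sd`.
#' @export
probit_inverse <- function(mu, sigma) {
  n <- max(length(mu), length(sigma))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  stopifnot(all(sigma >= 0))
  m1 <- stats::pnorm(mu / sqrt(1 + sigma^2))
  m2 <- vapply(seq_len(n), function(i) {
    if (sigma[i] == 0) return(stats::pnorm(mu[i])^2)
    stats::integrate(function(x) {
      stats::pnorm(x)^2 * stats::dnorm(x, mu[i], sigma[i])
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  data.frame(prob_mean = m1, prob_sd = sqrt(pmax(m2 - m1^2, 0)))
}

#' Invert the probit-normal moment map
#'
#' Finds `(mu, sigma)` on the probit scale whose implied probability-scale
#' mean and SD (see [probit_inverse()]) equal the given values.
#'
#' @param prob_mean Target mean in (0,1).
#' @param prob_sd Target SD (must be attainable: `sd^2 < m(1-m)`).
#' @return List with `mu` and `sigma`.
#' @export
probit_moments <- function(prob_mean, prob_sd) {
  stopifnot(prob_mean > 0, prob_mean < 1, prob_sd >= 0)
  if (prob_sd^2 >= prob_mean * (1 - prob_mean)) {
    stop("unattainable probability-scale moments")
  }
  if (prob_sd == 0) return(list(mu = stats::qnorm(prob_mean), sigma = 0))
  f <- function(lsig) {
    sig <- exp(lsig)
    mu <- stats::qnorm(prob_mean) * sqrt(1 + sig^2)
    probit_inverse(mu, sig)$prob_sd - prob_sd
  }
  r <- stats::uniroot(f, c(-10, 4), tol = 1e-10)
  sigma <- exp(r$root)
  list(mu = stats::qnorm(prob_mean) * sqrt(1 + sigma^2), sigma = sigma)
}

#' Compare a group-level parameter between two independent fits
#'
#' Pairs the retained draws of the probability-scale group means of
#' `parameter` across two fits (truncated to the common length) and
#' evaluates `stat` (an expression in `x` = fit1, `y` = fit2; default the
#' difference).  `p_B` is the fraction of draws with `x < y`.
#'
#' @param fit1,fit2 Fitted `mpt_fit` objects containing `parameter`.
#' @param parameter MPT parameter name.
#' @param stat Expression string in `x` and `y` (default `"x - y"`).
#' @return List with `mean`, `q2.5`, `q97.5`, `p_B`, and the draws.
#' @export
between_subjects_compare <- function(fit1, fit2, parameter, stat = "x - y") {
  nm <- paste0("mean_", parameter)
  f1 <- flat_draws(fit1$draws); f2 <- flat_draws(fit2$draws)
  if (!(nm %in% colnames(f1)) || !(nm %in% colnames(f2))) {
    stop("parameter not found in both fits: ", parameter)
  }
  n <- min(nrow(f1), nrow(f2))
  x <- f1[seq_len(n), nm]; y <- f2[seq_len(n), nm]
  val <- eval(parse(text = stat)[[1]], list(x = x, y = y))
  list(mean = mean(val),
       q2.5 = stats::quantile(val, 0.025, names = FALSE),
       q97.5 = stats::quantile(val, 0.975, names = FALSE),
       p_B = mean(x < y), draws = val)
}

#' Probability-scale group means per factor level
#'
#' For a discrete predictor fitted as a fixed or random effect, returns the
#' draws and summaries of `pnorm(mu_s + eta_sl)` for every level `l` and
#' every MPT parameter the factor was assigned to.  For fixed factors the
#' left-out level's effect is reconstructed from the sum-to-zero
#' constraint.
#'
#' @param fit A `trait_fit` with a factor predictor.
#' @param factor_name Covariate name of the factor.
#' @return Data frame of summaries (parameter, level, mean, sd, q2.5,
#'   q97.5, rhat) with the draws attached as attribute `"draws"`.
#' @export
group_means_by_factor <- function(fit, factor_name) {
  meta <- fit$design$meta
  if (is.null(meta) || !(factor_name %in% meta$col_cov[meta$col_type != "continuous"])) {
    stop("factor not fitted as a discrete predictor: ", factor_name)
  }
  sub <- meta[meta$col_cov == factor_name, ]
  type <- sub$col_type[1]
  f <- factor(fit$covariates[[factor_name]])
  levels_all <- levels(f)
  arr <- fit$draws$draws
  flat <- flat_draws(fit$draws)
  out <- list(); draws_out <- list()
  for (pm in unique(sub$col_param)) {
    mu <- flat[, paste0("mu_", pm)]
    cols <- sub[sub$col_param == pm, ]
    eff <- matrix(0, nrow(flat), length(levels_all),
                  dimnames = list(NULL, levels_all))
    if (type == "fixed") {
      C <- stats::contr.sum(length(levels_all))
      bmat <- flat[, paste0("beta_", cols$col_name), drop = FALSE]
      eff <- bmat %*% t(C)
      colnames(eff) <- levels_all
    } else {
      for (j in seq_len(nrow(cols))) {
        eff[, cols$col_level[j]] <- flat[, paste0("beta_", cols$col_name[j])]
      }
    }
    for (lv in levels_all) {
      dr <- stats::pnorm(mu + eff[, lv])
      draws_out[[paste0(pm, ":", lv)]] <- dr
      # per-chain split for rhat
      n_chain <- dim(arr)[1]; n_iter <- dim(arr)[2]
      dm <- matrix(dr, n_chain, n_iter)
      tmp <- structure(list(draws = array(dm, c(n_chain, n_iter, 1),
                                          dimnames = list(NULL, NULL, "x"))),
                       class = "mpt_draws")
      rh <- tryCatch(gelman_rubin(tmp)$rhat, error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        parameter = pm, level = lv, mean = mean(dr), sd = stats::sd(dr),
        q2.5 = stats::quantile(dr, 0.025, names = FALSE),
        q97.5 = stats::quantile(dr, 0.975, names = FALSE),
        rhat = rh, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "draws") <- draws_out
  res
}

#' Correlations between covariates and individual MPT parameters
#'
#' For every retained draw, the Pearson correlation between each covariate
#' and the individual parameters `theta_p` (probability scale) or their
#' probit transforms (`corProbit = TRUE`).
#'
#' @param fit A fitted `mpt_fit`.
#' @param covariates Data frame of numeric covariates aligned with the
#'   participants.
#' @param corProbit Correlate on the probit scale instead.
#' @return List with `r_draws` (named list of draw vectors, one per
#'   parameter x covariate) and `summary`.
#' @export
covariate_correlations <- function(fit, covariates, corProbit = FALSE) {
  covariates <- as.data.frame(covariates)
  num <- vapply(covariates, is.numeric, logical(1))
  covariates <- covariates[, num, drop = FALSE]
  if (ncol(covariates) == 0L) stop("no numeric covariates")
  P <- nrow(fit$data$counts)
  if (nrow(covariates) != P) stop("covariate rows must match participants")
  params <- fit$model$params
  flat <- flat_draws(fit$draws, "^theta_")
  r_draws <- list(); summaries <- list()
  for (pm in params) {
    th <- flat[, paste0("theta_", pm, "[", seq_len(P), "]"), drop = FALSE]
    if (corProbit) th <- stats::qnorm(clip01(th))
    for (cv in names(covariates)) {
      x <- covariates[[cv]]
      if (stats::sd(x) == 0) stop("covariate has zero variance: ", cv)
      r <- as.vector(stats::cor(t(th), x))
      key <- paste0(pm, ":", cv)
      r_draws[[key]] <- r
      summaries[[key]] <- data.frame(
        parameter = pm, covariate = cv, mean = mean(r),
        q2.5 = stats::quantile(r, 0.025, names = FALSE),
        q97.5 = stats::quantile(r, 0.975, names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  list(r_draws = r_draws, summary = do.call(rbind, summaries))
}

# Gaussian hypergeometric 2F1 by series (converges for |z| < 1; here
# c is large so convergence is fast)
hyp2f1 <- function(a, b, cc, z, max_terms = 1000, tol = 1e-12) {
  term <- 1; total <- 1
  for (j in seq_len(max_terms)) {
    term <- term * (a + j - 1) * (b + j - 1) / ((cc + j - 1) * j) * z
    total <- total + term
    if (abs(term) < tol * abs(total)) break
  }
  total
}

# sampling density of the sample correlation r given rho and n (classic
# small-sample form with the hypergeometric correction factor)
r_density_given_rho <- function(r, rho, n) {
  if (n < 4) stop("need n >= 4")
  lognum <- (n - 1) / 2 * log1p(-rho^2) + (n - 4) / 2 * log1p(-r^2)
  logden <- (n - 3 / 2) * log1p(-rho * r)
  f <- hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * r) / 2)
  exp(lognum - logden) * f
}

#' Sampling-error-corrected posterior of a population correlation
#'
#' Given posterior draws of the sample correlation `r` (e.g. from
#' [covariate_correlations()]), computes for each draw the posterior
#' density of the population correlation `rho` under a uniform prior on
#' `(-1, 1)` using the exact small-sample density of `r` given `rho`, and
#' averages the densities across draws.  The averaged posterior is wider
#' than the spread of the `r` draws alone because it adds the sampling
#' uncertainty from the finite number of participants.
#'
#' @param r_draws Numeric vector of sample-correlation draws in `[-1, 1]`.
#' @param n Number of participants (`>= 4`).
#' @param grid_size Number of grid points on `(-1, 1)`.
#' @return List with `grid`, `density` (averaged, normalized), `mean`,
#'   `q2.5`, `q97.5`.
#' @export
population_correlation <- function(r_draws, n, grid_size = 2001) {
  stopifnot(n >= 4, all(abs(r_draws) <= 1))
  r_draws <- pmin(pmax(r_draws, -1 + 1e-6), 1 - 1e-6)
  grid <- seq(-1 + 1e-6, 1 - 1e-6, length.out = grid_size)
  dens <- rep(0, grid_size)
  for (r in r_draws) {
    d <- vapply(grid, function(rho) r_density_given_rho(r, rho, n), numeric(1))
    area <- sum((d[-1] + d[-grid_size]) / 2) * diff(grid[1:2])
    dens <- dens + d / area
  }
  dens <- dens / length(r_draws)
  area <- sum((dens[-1] + dens[-grid_size]) / 2) * diff(grid[1:2])
  dens <- dens / area
  cdf <- cumsum(c(0, (dens[-1] + dens[-grid_size]) / 2) * diff(grid[1:2]))
  cdf <- cdf / cdf[grid_size]
  qfun <- function(p) grid[which.max(cdf >= p)]
  list(grid = grid, density = dens,
       mean = sum(grid * dens) / sum(dens),
       q2.5 = qfun(0.025), q97.5 = qfun(0.975))
}
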