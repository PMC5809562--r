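# Posterior-predictive simulation, T1/T2 discrepancy statistics with
# posterior-predictive p values, and DIC.

# theta draws as a list of P x S matrices for given draw indices
theta_draws_matrix <- function(fit, indices = NULL) {
  flat <- flat_draws(fit$draws, "^theta_")
  P <- nrow(fit$data$counts)
  params <- fit$model$params
  want <- as.vector(outer(seq_len(P), params,
                          function(i, pm) paste0("theta_", pm, "[", i, "]")))
  flat <- flat[, want, drop = FALSE]
  if (is.null(indices)) indices <- seq_len(nrow(flat))
  lapply(indices, function(m) {
    matrix(flat[m, ], P, length(params), dimnames = list(NULL, params))
  })
}

# observed items per tree, per participant (P x T) and as a check of balance
items_per_tree_observed <- function(data, model) {
  tree_of <- data$tree[colnames(data$counts)]
  sapply(model$trees, function(t) {
    rowSums(data$counts[, tree_of == t, drop = FALSE])
  })
}

#' Draw posterior-predictive frequency tables
#'
#' Simulates `M` replicated data sets from the fitted hierarchical model.
#' With `level = "individual"` each replication uses the individual
#' parameters `theta_ps` of one retained posterior draw; with
#' `level = "group"` fresh participants are drawn from that draw's
#' population distribution (multivariate normal on the probit scale for the
#' latent-trait model, independent betas for the beta-MPT).  Per-tree item
#' counts match the observed ones for every participant.
#'
#' @param fit A fitted `mpt_fit`.
#' @param M Number of predictive tables.
#' @param level `"individual"` or `"group"`.
#' @param seed Integer seed.
#' @return List of `M` count matrices (P x K).
#' @export
posterior_predictive_samples <- function(fit, M = 100,
                                         level = c("individual", "group"),
                                         seed = 1) {
  level <- match.arg(level)
  model <- fit$model
  n_draws <- prod(dim(fit$draws$draws)[1:2])
  indices <- with_seed(seed, {
    if (M <= n_draws) sample.int(n_draws, M)
    else sample.int(n_draws, M, replace = TRUE)
  })
  thetas <- theta_draws_matrix(fit, indices)
  if (level == "group") {
    flat <- flat_draws(fit$draws)
    params <- model$params
    P <- nrow(fit$data$counts)
    thetas <- with_seed(sub_seed(seed, 2), lapply(seq_along(indices), function(j) {
      m <- indices[j]
      if (fit$type == "trait") {
        mu <- flat[m, paste0("mu_", params)]
        sig <- flat[m, paste0("sigma_", params)]
        S <- length(params)
        R <- diag(S)
        if (S > 1) {
          prs <- utils::combn(seq_len(S), 2)
          rho <- flat[m, grep("^rho_", colnames(flat))]
          for (k in seq_len(ncol(prs))) {
            R[prs[1, k], prs[2, k]] <- R[prs[2, k], prs[1, k]] <- rho[k]
          }
        }
        Sg <- diag(sig, S) %*% R %*% diag(sig, S)
        z <- sweep(matrix(stats::rnorm(P * S), P, S) %*%
                     chol(Sg + diag(1e-10, S)), 2L, mu, "+")
        th <- stats::pnorm(z); colnames(th) <- params
        th
      } else {
        al <- flat[m, paste0("alpha_", params)]
        be <- flat[m, paste0("beta_", params)]
        th <- sapply(seq_along(params), function(s)
          stats::rbeta(P, al[s], be[s]))
        colnames(th) <- params
        th
      }
    }))
  }
  n_pt <- items_per_tree_observed(fit$data, model)
  tree_of <- model$categories$tree
  with_seed(sub_seed(seed, 3), lapply(thetas, function(th) {
    probs <- category_probabilities(th, model)
    counts <- matrix(0, nrow(probs), ncol(probs),
                     dimnames = list(NULL, colnames(probs)))
    for (t in model$trees) {
      sel <- which(tree_of == t)
      for (p in seq_len(nrow(probs))) {
        counts[p, sel] <- stats::rmultinom(1, n_pt[p, t], probs[p, sel])
      }
    }
    counts
  }))
}

#' T1 discrepancy: Pearson distance of mean frequencies
#'
#' `sum_k (mean_obs_k - expected_k)^2 / expected_k`, where `mean_obs_k`
#' averages the category frequencies over participants.  Categories with
#' zero expectation are excluded with a warning.
#'
#' @param freqs P x K count matrix (or `mpt_data`).
#' @param expected_mean Length-K vector of expected mean frequencies.
#' @return Scalar statistic.
#' @export
T1_statistic <- function(freqs, expected_mean) {
  if (inherits(freqs, "mpt_data")) freqs <- freqs$counts
  mean_obs <- colMeans(freqs)
  if (any(expected_mean <= 0)) {
    warning("excluding ", sum(expected_mean <= 0),
            " category(ies) with non-positive expected frequency")
    keep <- expected_mean > 0
    mean_obs <- mean_obs[keep]; expected_mean <- expected_mean[keep]
  }
  sum((mean_obs - expected_mean)^2 / expected_mean)
}

#' T2 discrepancy: standardized covariance distance
#'
#' `sum_{k<l} |cov_obs(k,l) - expected_cov(k,l)| / (sd_k sd_l)` with the
#' observed covariance taken across participants.  Only off-diagonal pairs
#' enter the sum.
#'
#' @param freqs P x K count matrix (or `mpt_data`), P >= 2.
#' @param expected_cov K x K expected covariance matrix.
#' @param expected_sd Length-K vector of expected standard deviations.
#' @return Scalar statistic.
#' @export
T2_statistic <- function(freqs, expected_cov, expected_sd) {
  if (inherits(freqs, "mpt_data")) freqs <- freqs$counts
  if (nrow(freqs) < 2L) stop("T2 needs at least two participants")
  if (any(expected_sd <= 0)) stop("expected_sd must be positive")
  co <- stats::cov(freqs)
  K <- ncol(freqs)
  lt <- lower.tri(co)
  denom <- outer(expected_sd, expected_sd)
  sum(abs(co - expected_cov)[lt] / denom[lt])
}

# analytic mean / covariance of the frequencies under one theta draw:
# within-participant multinomial covariance averaged over participants plus
# the between-participant covariance of the expected frequencies
expected_moments <- function(theta, model, n_pt) {
  probs <- category_probabilities(theta, model)
  P <- nrow(probs); K <- ncol(probs)
  tree_of <- model$categories$tree
  n_cat <- n_pt[, tree_of, drop = FALSE]    # P x K items for each category
  m <- probs * n_cat                        # expected frequencies
  cov_within <- matrix(0, K, K)
  same_tree <- outer(tree_of, tree_of, "==")
  for (p in seq_len(P)) {
    mc <- -outer(m[p, ], probs[p, ]) * same_tree
    diag(mc) <- m[p, ] * (1 - probs[p, ])
    cov_within <- cov_within + mc
  }
  cov_within <- cov_within / P
  cov_between <- stats::cov(m) * (P - 1) / P
  list(mean = colMeans(m), cov = cov_within + cov_between,
       expected_freq = m)
}

#' Posterior-predictive p values for the T1 and T2 statistics
#'
#' For each of `M` retained posterior draws, the expected mean frequencies
#' and covariances are computed analytically from that draw's individual
#' parameters; `T_obs` evaluates the observed data and `T_pred` a data set
#' simulated under the draw.  `PPP = mean(T_obs < T_pred)`.  Per-participant
#' PPP values apply the T1 form to each participant's own frequencies.
#'
#' @param fit A fitted `mpt_fit` with individual theta draws.
#' @param M Number of posterior draws to use.
#' @param seed Integer seed.
#' @return Object of class `ppp_result`: `T1_obs`, `T1_pred`, `T2_obs`,
#'   `T2_pred` (length-M vectors), `ppp_T1`, `ppp_T2`, `individual_ppp`.
#' @export
ppp <- function(fit, M = 500, seed = 1) {
  model <- fit$model
  data <- fit$data
  n_draws <- prod(dim(fit$draws$draws)[1:2])
  indices <- with_seed(seed, {
    if (M <= n_draws) sample.int(n_draws, M) else
      sample.int(n_draws, M, replace = TRUE)
  })
  thetas <- theta_draws_matrix(fit, indices)
  n_pt <- items_per_tree_observed(data, model)
  tree_of <- model$categories$tree
  P <- nrow(data$counts)
  T1o <- T1p <- T2o <- T2p <- numeric(length(thetas))
  ind_obs <- ind_pred <- matrix(0, length(thetas), P)
  with_seed(sub_seed(seed, 5), {
    for (j in seq_along(thetas)) {
      th <- thetas[[j]]
      mom <- expected_moments(th, model, n_pt)
      sdv <- sqrt(pmax(diag(mom$cov), 1e-12))
      pred <- matrix(0, P, ncol(data$counts),
                     dimnames = list(NULL, colnames(data$counts)))
      probs <- category_probabilities(th, model)
      for (t in model$trees) {
        sel <- which(tree_of == t)
        for (p in seq_len(P)) {
          pred[p, sel] <- stats::rmultinom(1, n_pt[p, t], probs[p, sel])
        }
      }
      T1o[j] <- T1_statistic(data$counts, mom$mean)
      T1p[j] <- T1_statistic(pred, mom$mean)
      T2o[j] <- T2_statistic(data$counts, mom$cov, sdv)
      T2p[j] <- T2_statistic(pred, mom$cov, sdv)
      ef <- pmax(mom$expected_freq, 1e-12)
      ind_obs[j, ] <- rowSums((data$counts - ef)^2 / ef)
      ind_pred[j, ] <- rowSums((pred - ef)^2 / ef)
    }
  })
  structure(list(T1_obs = T1o, T1_pred = T1p, T2_obs = T2o, T2_pred = T2p,
                 ppp_T1 = mean(T1o < T1p), ppp_T2 = mean(T2o < T2p),
                 individual_ppp = colMeans(ind_obs < ind_pred)),
            class = "ppp_result")
}

#' @export
print.ppp_result <- function(x, ...) {
  cat(sprintf("Posterior-predictive checks (M = %d)\n", length(x$T1_obs)))
  cat(sprintf("  T1 (means):       observed %.2f | predicted %.2f | PPP = %.3f\n",
              mean(x$T1_obs), mean(x$T1_pred), x$ppp_T1))
  cat(sprintf("  T2 (covariances): observed %.2f | predicted %.2f | PPP = %.3f\n",
              mean(x$T2_obs), mean(x$T2_pred), x$ppp_T2))
  invisible(x)
}

#' Deviance information criterion
#'
#' Deviance `D(theta) = -2 log L(theta)` conditional on the individual
#' parameters; `Dbar` averages over retained draws, `pD = Dbar - D(thetabar)`
#' with `thetabar` the posterior mean of the individual parameters, and
#' `DIC = Dbar + pD`.
#'
#' @param fit A fitted `mpt_fit`.
#' @param M Number of draws to average over (default: all retained).
#' @return List with `DIC`, `pD`, `Dbar`.
#' @export
dic <- function(fit, M = NULL) {
  n_draws <- prod(dim(fit$draws$draws)[1:2])
  indices <- if (is.null(M) || M >= n_draws) seq_len(n_draws)
             else round(seq(1, n_draws, length.out = M))
  thetas <- theta_draws_matrix(fit, indices)
  dev <- vapply(thetas, function(th) {
    -2 * log_likelihood(th, fit$data, fit$model)
  }, numeric(1))
  thetabar <- Reduce(`+`, thetas) / length(thetas)
  Dbar <- mean(dev)
  Dhat <- -2 * log_likelihood(thetabar, fit$data, fit$model)
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, pD = pD, Dbar = Dbar)
}
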