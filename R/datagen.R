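# Synthetic-data generators (fixed theta, latent-trait population, beta
# population) and the parameter-recovery simulation harness.

#' Generate response frequencies for a fixed parameter matrix
#'
#' One multinomial draw per participant and tree, with probabilities given
#' by the model's category probabilities at that participant's parameters.
#'
#' @param theta P x S matrix of individual parameters in (0,1), columns
#'   named by model parameter.
#' @param model An `mpt_model`.
#' @param items_per_tree Named vector mapping each tree to its item count.
#' @param seed Integer seed.
#' @return An `mpt_data` frequency table.
#' @export
gen_mpt <- function(theta, model, items_per_tree, seed = 1) {
  items_per_tree <- unlist(items_per_tree)
  if (any(items_per_tree[model$trees] <= 0) ||
      any(is.na(items_per_tree[model$trees]))) {
    stop("items_per_tree must be positive for every tree")
  }
  probs <- category_probabilities(theta, model)
  P <- nrow(probs)
  counts <- matrix(0, P, ncol(probs),
                   dimnames = list(NULL, colnames(probs)))
  tree_of <- model$categories$tree
  with_seed(seed, {
    for (t in model$trees) {
      sel <- which(tree_of == t)
      n_t <- items_per_tree[[t]]
      for (p in seq_len(P)) {
        counts[p, sel] <- stats::rmultinom(1, n_t, probs[p, sel])
      }
    }
  })
  as_mpt_data(counts, model)
}

#' Latent-trait population specification for data generation
#'
#' @param mu_probit Named probit-scale group means (one per model
#'   parameter).
#' @param sigma_probit Probit-scale group SDs (recycled / named).
#' @param correlation Optional S x S correlation matrix (default identity).
#' @param slopes Optional named vector of standardized probit-scale slopes;
#'   a standard-normal covariate is generated and applied to the named
#'   parameters.
#' @return Object of class `trait_pop_spec`.
#' @export
trait_pop_spec <- function(mu_probit, sigma_probit, correlation = NULL,
                           slopes = NULL) {
  if (!is.null(correlation)) {
    if (!isTRUE(all.equal(diag(correlation),
                          rep(1, nrow(correlation)))) ||
        any(eigen(correlation, TRUE, TRUE)$values < -1e-10)) {
      stop("correlation must be PSD with unit diagonal")
    }
  }
  structure(list(mu_probit = mu_probit, sigma_probit = sigma_probit,
                 correlation = correlation, slopes = slopes),
            class = "trait_pop_spec")
}

#' Generate data from a latent-trait MPT population
#'
#' Draws probit values `mu + beta * x + delta_p` with
#' `delta_p ~ MVN(0, diag(sigma) R diag(sigma))`, transforms with `pnorm`,
#' then simulates frequencies via [gen_mpt()].
#'
#' @param P Number of participants.
#' @param items_per_tree Named item counts per tree.
#' @param spec A [trait_pop_spec()].
#' @param model An `mpt_model`.
#' @param seed Integer seed.
#' @return List with `data` (`mpt_data`), `theta` (true P x S matrix),
#'   `covariates` (data frame with the generated predictor, or `NULL`).
#' @export
gen_trait_mpt <- function(P, items_per_tree, spec, model, seed = 1) {
  params <- model$params
  S <- length(params)
  mu <- expand_by_param(spec$mu_probit, params, "mu_probit")
  sig <- expand_by_param(spec$sigma_probit, params, "sigma_probit")
  R <- if (is.null(spec$correlation)) diag(S) else spec$correlation
  Sigma <- diag(sig, S) %*% R %*% diag(sig, S)
  out <- with_seed(seed, {
    ch <- chol(Sigma + diag(1e-12, S))
    delta <- matrix(stats::rnorm(P * S), P, S) %*% ch
    z <- sweep(delta, 2L, mu, "+")
    covariates <- NULL
    if (!is.null(spec$slopes)) {
      x <- stats::rnorm(P)
      xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
      for (pm in names(spec$slopes)) {
        j <- match(pm, params)
        if (is.na(j)) stop("slope on unknown parameter: ", pm)
        z[, j] <- z[, j] + spec$slopes[[pm]] * xs
      }
      covariates <- data.frame(pred = x)
    }
    theta <- stats::pnorm(z)
    colnames(theta) <- params
    list(theta = theta, covariates = covariates)
  })
  data <- gen_mpt(out$theta, model, items_per_tree, seed = sub_seed(seed, 1))
  list(data = data, theta = out$theta, covariates = out$covariates)
}

#' Generate data from a beta-MPT population
#'
#' @param P Number of participants.
#' @param items_per_tree Named item counts per tree.
#' @param mean,sd Group-level mean and SD per parameter (scalar, named, or
#'   length-S); converted to beta shapes via [moments_to_shapes()].
#' @param model An `mpt_model`.
#' @param seed Integer seed.
#' @return List with `data` and `theta`.
#' @export
gen_beta_mpt <- function(P, items_per_tree, mean, sd, model, seed = 1) {
  params <- model$params
  m <- expand_by_param(mean, params, "mean")
  s <- expand_by_param(sd, params, "sd")
  shapes <- moments_to_shapes(m, s)
  theta <- with_seed(seed, {
    th <- sapply(seq_along(params), function(j) {
      stats::rbeta(P, shapes$alpha[j], shapes$beta[j])
    })
    matrix(th, P, length(params), dimnames = list(NULL, params))
  })
  data <- gen_mpt(theta, model, items_per_tree, seed = sub_seed(seed, 1))
  list(data = data, theta = theta)
}

#' Reference recovery-simulation design for the restricted 2HTSM
#'
#' The package's standard benchmark: 50 participants, 16 items for each of
#' the two source trees and 32 new items; probit means `a = 0.3`,
#' `b = -0.1`, `d1 = 0.6`, `D1 = qnorm(0.62)` with probit SDs 0.6, 0.5,
#' 1.0, 0.2; a standard-normal covariate with standardized slopes
#' `-0.3` on `D1` and `0.5` on `d1`.
#'
#' @return List with `model`, `spec` ([trait_pop_spec()]), `P`,
#'   `items_per_tree`.
#' @export
sim_design_2htsm <- function() {
  model <- apply_restrictions(parse_eqn(eqn_2htsm()), restrictions_2htsm())
  spec <- trait_pop_spec(
    mu_probit = c(a = 0.3, b = -0.1, d1 = 0.6, D1 = stats::qnorm(0.62)),
    sigma_probit = c(a = 0.6, b = 0.5, d1 = 1.0, D1 = 0.2),
    slopes = c(D1 = -0.3, d1 = 0.5))
  list(model = model, spec = spec, P = 50,
       items_per_tree = c(E = 16, U = 16, N = 32))
}

#' Parameter-recovery simulation
#'
#' Repeatedly generates latent-trait data, fits the latent-trait model, and
#' aggregates recovery of the probability-scale group means, probit SDs and
#' standardized slopes: mean posterior mean, averaged 95% CI bounds, mean
#' absolute bias, CI coverage of the generating value, and (slopes only)
#' the percentage of replications whose 95% CI excludes zero.  Replications
#' with any group-level `Rhat >= 1.05` are re-fitted with doubled iterations
#' (up to `max_reruns`), then excluded and counted.
#'
#' @param design List with `model`, `spec`, `P`, `items_per_tree` (see
#'   [sim_design_2htsm()]).
#' @param n_replications Number of replications.
#' @param settings [mcmc_settings()] used per replication (its seed is
#'   replaced by a deterministic per-replication sub-seed).
#' @param seed Master seed.
#' @param max_reruns Re-fit attempts per replication before exclusion.
#' @param rhat_threshold Group-level `Rhat` bound of the convergence gate
#'   (set to `Inf` to keep every replication).
#' @return Object of class `sim_report`: list with `table` (the aggregate
#'   data frame), `records` (per-replication posterior summaries) and
#'   `n_excluded`.
#' @export
recovery_simulation <- function(design, n_replications = 100,
                                settings = mcmc_settings(), seed = 1,
                                max_reruns = 3, rhat_threshold = 1.05) {
  model <- design$model
  spec <- design$spec
  params <- model$params
  has_slopes <- !is.null(spec$slopes)
  pred <- if (has_slopes) {
    predictor_spec(paste(paste(names(spec$slopes), collapse = " "), "; pred"))
  } else NULL
  mu <- expand_by_param(spec$mu_probit, params, "mu_probit")
  sig <- expand_by_param(spec$sigma_probit, params, "sigma_probit")
  truth <- c(setNames(stats::pnorm(mu), paste0("mean_", params)),
             setNames(sig, paste0("sigma_", params)),
             if (has_slopes) setNames(spec$slopes,
                                      paste0("beta_", names(spec$slopes),
                                             ":pred")))
  records <- list()
  n_excluded <- 0L
  for (r in seq_len(n_replications)) {
    rseed <- sub_seed(seed, r)
    sim <- gen_trait_mpt(design$P, design$items_per_tree, spec, model,
                         seed = rseed)
    st <- settings
    attempt <- 0L
    repeat {
      st$seed <- sub_seed(rseed, attempt + 1L)
      fit <- suppressWarnings(
        fit_trait(model, sim$data, covariates = sim$covariates,
                  predictors = pred, settings = st))
      grp <- !grepl("^theta_", fit$summary$parameter)
      max_rhat <- suppressWarnings(max(fit$summary$rhat[grp], na.rm = TRUE))
      ok <- is.finite(max_rhat) && max_rhat < rhat_threshold
      if (ok || attempt >= max_reruns) break
      attempt <- attempt + 1L
      st$n_iter <- st$n_iter * 2L
      st$n_burnin <- st$n_burnin * 2L
    }
    if (!ok) {
      n_excluded <- n_excluded + 1L
      next
    }
    sm <- fit$summary
    rownames(sm) <- sm$parameter
    keep <- intersect(names(truth), sm$parameter)
    records[[length(records) + 1L]] <-
      data.frame(replication = r, parameter = keep,
                 true = truth[keep],
                 post_mean = sm[keep, "mean"],
                 lower = sm[keep, "q2.5"],
                 upper = sm[keep, "q97.5"],
                 stringsAsFactors = FALSE)
  }
  if (length(records) == 0L) stop("all replications failed to converge")
  rec <- do.call(rbind, records)
  agg <- do.call(rbind, lapply(split(rec, rec$parameter), function(d) {
    data.frame(parameter = d$parameter[1],
               generating = d$true[1],
               mean_posterior_mean = mean(d$post_mean),
               mean_lower = mean(d$lower),
               mean_upper = mean(d$upper),
               mean_abs_bias = mean(abs(d$post_mean - d$true)),
               coverage_pct = 100 * mean(d$true >= d$lower & d$true <= d$upper),
               zero_excluded_pct = if (grepl("^beta_", d$parameter[1])) {
                 100 * mean(d$lower > 0 | d$upper < 0)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(table = agg[order(agg$parameter), ], records = rec,
                 n_excluded = n_excluded,
                 n_replications = n_replications),
            class = "sim_report")
}

#' @export
print.sim_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replications (%d excluded)\n",
              x$n_replications, x$n_excluded))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
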