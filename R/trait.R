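# Latent-trait MPT model: multivariate-normal random effects on the probit
# scale with a scaled inverse-Wishart prior, plus probit-scale regression on
# continuous covariates and discrete (fixed/random) factors.

#' Priors for the latent-trait MPT model
#'
#' Group means `mu_s` get independent normal priors (default standard
#' normal, which implies a uniform distribution of `pnorm(mu_s)` on the
#' probability scale).  The covariance matrix is `Sigma =
#' diag(xi) Q diag(xi)` with `Q` inverse-Wishart (default: identity scale
#' matrix, `S + 1` degrees of freedom) and scaling factors `xi_s` uniform on
#' `[0, 10]`.  Regression slopes are standardized and get
#' `beta_sk ~ N(0, g_s)` with `g_s ~ Inverse-Gamma(1/2, v^2/2)` (an inverse
#' chi-square(1) prior at the default `v = 1`), forming a multivariate
#' Cauchy prior per parameter.
#'
#' Priors are parameterized by mean and *standard deviation*, not precision;
#' a BUGS-style `dnorm(0, 4)` corresponds to `mu_sd = 0.5`.
#'
#' @param mu_mean,mu_sd Normal prior on each probit group mean; scalars are
#'   recycled, or named vectors per MPT parameter.
#' @param V Inverse-Wishart scale matrix (default identity).
#' @param df Inverse-Wishart degrees of freedom (default `S + 1`).
#' @param xi_bounds Lower/upper bounds of the uniform prior on `xi_s`.
#' @param v_slope Scale `v` of the slope-variance prior
#'   `g ~ Inverse-Gamma(1/2, v^2/2)`.
#' @param fixed_g If `TRUE`, fixes `g_s = 1` (standard-normal slope priors)
#'   instead of sampling it.
#' @return Object of class `trait_priors`.
#' @export
trait_priors <- function(mu_mean = 0, mu_sd = 1, V = NULL, df = NULL,
                         xi_bounds = c(0, 10), v_slope = 1,
                         fixed_g = FALSE) {
  stopifnot(length(xi_bounds) == 2, xi_bounds[1] >= 0,
            xi_bounds[1] < xi_bounds[2], all(mu_sd > 0), v_slope > 0)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd, V = V, df = df,
                 xi_bounds = xi_bounds, v_slope = v_slope,
                 fixed_g = fixed_g),
            class = "trait_priors")
}

# recycle scalar or match named vector against params
expand_by_param <- function(x, params, what) {
  if (length(x) == 1L && is.null(names(x))) {
    return(setNames(rep(x, length(params)), params))
  }
  if (!is.null(names(x))) {
    out <- setNames(rep(x[[1]], length(params)), params)
    unknown <- setdiff(names(x), params)
    if (length(unknown)) stop(what, ": unknown parameter(s) ",
                              paste(unknown, collapse = ", "))
    out[names(x)] <- x
    return(out)
  }
  if (length(x) == length(params)) return(setNames(x, params))
  stop(what, " must be scalar, named, or of length S")
}

#' Predictor specification for the latent-trait model
#'
#' Each assignment names one or more MPT parameters, a semicolon, then one
#' or more covariates, e.g. `"a ; pc"` or `"D1 d1 ; age"`.  Covariate types
#' are `"continuous"` (`"c"`), `"fixed"` (`"f"`, sum-to-zero-coded factor)
#' or `"random"` (`"r"`, indicator-coded factor with a shared variance).
#' Unstated types default to continuous for numeric covariates and fixed
#' factors for character/factor covariates.
#'
#' @param assignments Character vector (or list) of `"params ; covariates"`
#'   strings.
#' @param types Optional named vector mapping covariate names to types.
#' @param v_scale Scale of the slope-variance prior for these predictors.
#' @return Object of class `predictor_spec`.
#' @export
predictor_spec <- function(assignments, types = NULL, v_scale = 1) {
  assignments <- unlist(assignments, use.names = FALSE)
  pairs <- lapply(assignments, function(a) {
    halves <- strsplit(a, ";", fixed = TRUE)[[1]]
    if (length(halves) != 2L) stop("assignment must be 'params ; covariates': ", a)
    list(params = strsplit(trimws(halves[1]), "[[:space:],]+")[[1]],
         covs = strsplit(trimws(halves[2]), "[[:space:],]+")[[1]])
  })
  if (!is.null(types)) {
    types <- vapply(types, function(t) {
      switch(substr(t, 1, 1),
             c = "continuous", f = "fixed", r = "random",
             stop("predictor type must be c(ontinuous), f(ixed) or r(andom)"))
    }, character(1))
  }
  structure(list(pairs = pairs, types = types, v_scale = v_scale),
            class = "predictor_spec")
}

#' Build per-parameter design matrices
#'
#' Continuous covariates are z-standardized (mean 0, variance 1, divisor
#' `P`).  Fixed factors are sum-to-zero coded with `L - 1` columns; random
#' factors are indicator-coded with `L` columns sharing one variance.
#'
#' @param covariates Data frame of covariates (rows = participants).
#' @param spec A [predictor_spec()].
#' @param params Character vector of MPT parameter names.
#' @return List with the stacked design matrix `X`, per-column metadata
#'   (`col_param`, `col_cov`, `col_type`, `col_sd`, `col_level`,
#'   `col_group`), and the variance-group table.
#' @export
build_design <- function(covariates, spec, params) {
  covariates <- as.data.frame(covariates)
  P <- nrow(covariates)
  cols <- list(); meta <- list()
  for (pair in spec$pairs) {
    unknown <- setdiff(pair$params, params)
    if (length(unknown)) stop("predictor assigned to unknown parameter(s): ",
                              paste(unknown, collapse = ", "))
    for (cv in pair$covs) {
      if (!(cv %in% names(covariates))) stop("covariate not found: ", cv)
      x <- covariates[[cv]]
      type <- if (!is.null(spec$types) && cv %in% names(spec$types)) {
        spec$types[[cv]]
      } else if (is.numeric(x)) "continuous" else "fixed"
      for (pm in pair$params) {
        if (type == "continuous") {
          if (!is.numeric(x)) stop("covariate ", cv, " is not numeric")
          sd_pop <- sqrt(mean((x - mean(x))^2))
          if (sd_pop == 0) stop("covariate ", cv, " has zero variance")
          cols[[length(cols) + 1L]] <- (x - mean(x)) / sd_pop
          meta[[length(meta) + 1L]] <- data.frame(
            col_param = pm, col_cov = cv, col_type = "continuous",
            col_sd = sd_pop, col_level = NA_character_,
            col_group = paste0(pm, "|slopes"),
            col_name = paste0(pm, ":", cv), stringsAsFactors = FALSE)
        } else {
          f <- factor(x)
          if (any(table(f) == 0)) stop("factor ", cv, " has an empty level")
          if (nlevels(f) < 2L) stop("factor ", cv, " needs >= 2 levels")
          L <- nlevels(f)
          if (type == "fixed") {
            C <- stats::contr.sum(L)
            Xf <- C[as.integer(f), , drop = FALSE]
            for (j in seq_len(L - 1L)) {
              cols[[length(cols) + 1L]] <- Xf[, j]
              meta[[length(meta) + 1L]] <- data.frame(
                col_param = pm, col_cov = cv, col_type = "fixed",
                col_sd = NA_real_, col_level = levels(f)[j],
                col_group = paste0(pm, "|slopes"),
                col_name = paste0(pm, ":", cv, ":", levels(f)[j]),
                stringsAsFactors = FALSE)
            }
          } else {
            for (j in seq_len(L)) {
              cols[[length(cols) + 1L]] <- as.numeric(f == levels(f)[j])
              meta[[length(meta) + 1L]] <- data.frame(
                col_param = pm, col_cov = cv, col_type = "random",
                col_sd = NA_real_, col_level = levels(f)[j],
                col_group = paste0(pm, "|r:", cv),
                col_name = paste0(pm, ":", cv, ":", levels(f)[j]),
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(cols) == 0L) {
    return(list(X = matrix(0, P, 0), meta = NULL, factors = NULL))
  }
  X <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  if (anyDuplicated(meta$col_name)) stop("duplicate predictor assignment")
  colnames(X) <- meta$col_name
  # factor bookkeeping for getGroupMeans-style summaries
  fmeta <- unique(meta[meta$col_type != "continuous",
                       c("col_cov", "col_type")])
  list(X = X, meta = meta,
       factors = if (nrow(fmeta)) fmeta else NULL)
}

# fast per-participant log-likelihood closure for a compiled model
make_ll_rows <- function(cm, counts) {
  P <- nrow(counts)
  tA <- t(cm$A); tB <- t(cm$B)
  logc_mat <- matrix(cm$logc, P, length(cm$logc), byrow = TRUE)
  M <- cm$M
  function(theta) {
    th <- pmin(pmax(theta, THETA_EPS), 1 - THETA_EPS)
    pb <- exp(log(th) %*% tA + log1p(-th) %*% tB + logc_mat)
    rowSums(counts * log(pmax(pb %*% M, 1e-300)))
  }
}

# crude least-squares projection of the pooled, smoothed category
# proportions onto the model manifold; all participants start near this
# common point (plus chain-specific jitter), which is enough to shorten
# burn-in without per-participant optimization
init_probit_values <- function(model, cm, counts) {
  P <- nrow(counts); S <- cm$S
  pooled <- colSums(counts)
  tree_tot <- tapply(pooled, cm$cat_tree, sum)[cm$cat_tree]
  K_t <- table(cm$cat_tree)[cm$cat_tree]
  phat <- (pooled + 1) / (as.numeric(tree_tot) + as.numeric(K_t))
  obj <- function(z) {
    th <- matrix(stats::pnorm(z), 1, S, dimnames = list(NULL, model$params))
    sum((category_probabilities(th, model)[1, ] - phat)^2)
  }
  fit <- stats::optim(rep(0, S), obj, method = "BFGS",
                      control = list(maxit = 50))
  z_pool <- pmin(pmax(fit$par, -2.5), 2.5)
  matrix(z_pool, P, S, byrow = TRUE, dimnames = list(NULL, model$params))
}

# build the Metropolis-within-Gibbs kernel for the latent-trait model
trait_kernel <- function(model, data, design, priors, settings) {
  cm <- compile_mpt(model)
  attr(model, "compiled") <- cm
  counts <- data$counts
  P <- nrow(counts); S <- cm$S
  params <- model$params
  ll_rows <- make_ll_rows(cm, counts)
  mu_mean <- expand_by_param(priors$mu_mean, params, "mu_mean")
  mu_sd <- expand_by_param(priors$mu_sd, params, "mu_sd")
  V <- if (is.null(priors$V)) diag(S) else priors$V
  df0 <- if (is.null(priors$df)) S + 1 else priors$df
  if (!isTRUE(all.equal(V, t(V))) || any(eigen(V, TRUE)$values <= 0)) {
    stop("V must be symmetric positive definite")
  }
  if (df0 < S) stop("Wishart df must be >= S")
  xi_lo <- priors$xi_bounds[1]; xi_hi <- priors$xi_bounds[2]
  X <- design$X
  meta <- design$meta
  idx_s <- lapply(params, function(pm) {
    if (is.null(meta)) integer(0) else which(meta$col_param == pm)
  })
  groups <- if (is.null(meta)) character(0) else unique(meta$col_group)
  v2 <- priors$v_slope^2
  z0_data <- init_probit_values(model, cm, counts)
  target <- settings$target_acceptance

  sigma_pack <- function(Q, xi) {
    Sg <- diag(xi) %*% Q %*% diag(xi)
    ch <- chol(Sg)
    list(Sigma = Sg, Omega = chol2inv(ch),
         logdet = 2 * sum(log(diag(ch))))
  }

  init <- function(chain) {
    z <- z0_data + matrix(stats::rnorm(P * S, 0, 0.4), P, S)
    beta <- if (is.null(meta)) numeric(0) else rep(0, nrow(meta))
    mu <- colMeans(z)
    Q <- diag(S); xi <- rep(1, S)
    sp <- sigma_pack(Q, xi)
    g <- setNames(rep(1, length(groups)), groups)
    theta <- stats::pnorm(z)
    list(z = z, mu = mu, beta = beta, Q = Q, xi = xi, g = g,
         sp = sp, theta = theta, ll = ll_rows(theta),
         xb = xb_matrix(beta, idx_s, X, P, S),
         sd_z = matrix(0.6, P, S), sd_xi = rep(0.25, S),
         sd_xi2 = rep(0.3, S))
  }

  update <- function(state, adapt, iter) {
    z <- state$z; mu <- state$mu; beta <- state$beta
    xb <- state$xb; sp <- state$sp
    theta <- state$theta; ll <- state$ll
    step <- if (adapt) rm_step(iter) else 0
    mean_mat <- sweep(xb, 2L, mu, "+")
    delta <- z - mean_mat
    dOm <- delta %*% sp$Omega
    # --- componentwise Metropolis on the probit values, one column at a time
    for (s in seq_len(S)) {
      zs_new <- z[, s] + state$sd_z[, s] * stats::rnorm(P)
      th_new <- theta
      th_new[, s] <- stats::pnorm(zs_new)
      ll_new <- ll_rows(th_new)
      d_new <- zs_new - mean_mat[, s]
      d_old <- delta[, s]
      cross <- dOm[, s] - sp$Omega[s, s] * d_old
      dprior <- -0.5 * sp$Omega[s, s] * (d_new^2 - d_old^2) -
        (d_new - d_old) * cross
      acc <- log(stats::runif(P)) < (ll_new - ll + dprior)
      if (any(acc)) {
        z[acc, s] <- zs_new[acc]
        theta[acc, s] <- th_new[acc, s]
        ll[acc] <- ll_new[acc]
        dd <- d_new[acc] - d_old[acc]
        delta[acc, s] <- d_new[acc]
        dOm[acc, ] <- dOm[acc, , drop = FALSE] +
          dd %o% sp$Omega[s, ]
      }
      if (adapt) {
        state$sd_z[, s] <- exp(log(state$sd_z[, s]) + step * (acc - target))
      }
    }
    # --- Gibbs for (mu_s, beta_s) given z and Sigma, one parameter at a time
    for (s in seq_len(S)) {
      om_ss <- sp$Omega[s, s]
      dm <- delta; dm[, s] <- 0
      cond <- -(dm %*% sp$Omega[, s]) / om_ss
      y <- z[, s] - cond           # = mu_s + X_s beta_s + e, e ~ N(0, 1/om_ss)
      js <- idx_s[[s]]
      W <- cbind(rep(1, P), if (length(js)) X[, js, drop = FALSE])
      prior_prec <- c(1 / mu_sd[s]^2,
                      if (length(js)) 1 / state$g[meta$col_group[js]])
      prior_mean <- c(mu_mean[s], rep(0, length(js)))
      A <- om_ss * crossprod(W) + diag(prior_prec, nrow = length(prior_prec))
      bvec <- om_ss * crossprod(W, y) + prior_prec * prior_mean
      ch <- chol(A)
      m_post <- backsolve(ch, forwardsolve(t(ch), bvec))
      drawv <- m_post + backsolve(ch, stats::rnorm(length(m_post)))
      mu[s] <- drawv[1]
      if (length(js)) beta[js] <- drawv[-1]
      xb[, s] <- if (length(js)) X[, js, drop = FALSE] %*% beta[js] else 0
      delta[, s] <- z[, s] - mu[s] - xb[, s]
    }
    dOm <- delta %*% sp$Omega
    # --- Gibbs for Q (inverse Wishart, conjugate given eps = delta / xi)
    eps <- sweep(delta, 2L, state$xi, "/")
    Sn <- V + crossprod(eps)
    Qinv <- stats::rWishart(1, df0 + P, chol2inv(chol(Sn)))[, , 1]
    Q <- chol2inv(chol(Qinv))
    sp <- sigma_pack(Q, state$xi)
    # --- non-centered (interweaved) rescale: hold eps = delta/xi fixed and
    #     move xi_s against the likelihood; crosses the sigma funnel
    xi <- state$xi
    for (s in seq_len(S)) {
      xi_new <- xi[s] * exp(state$sd_xi2[s] * stats::rnorm(1))
      if (xi_new > xi_lo && xi_new < xi_hi && xi_new > 1e-8) {
        d_new <- delta[, s] * (xi_new / xi[s])
        z_new <- z[, s] - delta[, s] + d_new
        th_new <- theta; th_new[, s] <- stats::pnorm(z_new)
        ll_new <- ll_rows(th_new)
        lr <- sum(ll_new - ll) + log(xi_new / xi[s])
        acc2 <- log(stats::runif(1)) < lr
        if (acc2) {
          z[, s] <- z_new; delta[, s] <- d_new
          theta <- th_new; ll <- ll_new
          xi[s] <- xi_new
        }
      } else acc2 <- FALSE
      if (adapt) {
        state$sd_xi2[s] <- exp(log(state$sd_xi2[s]) + step * (acc2 - target))
      }
    }
    # --- centered Metropolis for each scaling factor xi_s (prior side)
    sp <- sigma_pack(Q, xi)
    quad_cur <- sum(delta * (delta %*% sp$Omega))
    for (s in seq_len(S)) {
      xi_new <- xi[s] + state$sd_xi[s] * stats::rnorm(1)
      acc <- FALSE
      if (xi_new > xi_lo && xi_new < xi_hi && xi_new > 1e-8) {
        xi_try <- xi; xi_try[s] <- xi_new
        sp_try <- sigma_pack(Q, xi_try)
        quad_try <- sum(delta * (delta %*% sp_try$Omega))
        lr <- -0.5 * P * (sp_try$logdet - sp$logdet) -
          0.5 * (quad_try - quad_cur)
        if (log(stats::runif(1)) < lr) {
          xi <- xi_try; sp <- sp_try; quad_cur <- quad_try
          acc <- TRUE
        }
      }
      if (adapt) {
        state$sd_xi[s] <- exp(log(state$sd_xi[s]) + step * (acc - target))
      }
    }
    # --- Gibbs for the slope variances g (inverse gamma)
    g <- state$g
    if (length(groups) && !priors$fixed_g) {
      for (gr in groups) {
        js <- which(meta$col_group == gr)
        shape <- 0.5 + length(js) / 2
        rate <- v2 / 2 + sum(beta[js]^2) / 2
        g[gr] <- 1 / stats::rgamma(1, shape, rate)
      }
    }
    state$z <- z; state$mu <- mu; state$beta <- beta
    state$Q <- Q; state$xi <- xi; state$g <- g; state$sp <- sp
    state$theta <- theta; state$ll <- ll; state$xb <- xb
    state
  }

  param_names <- c(paste0("mean_", params),
                   paste0("mu_", params),
                   paste0("sigma_", params))
  if (S > 1) {
    prs <- utils::combn(params, 2)
    param_names <- c(param_names,
                     paste0("rho_", prs[1, ], ".", prs[2, ]))
  }
  if (!is.null(meta)) {
    param_names <- c(param_names, paste0("beta_", meta$col_name))
  }
  theta_names <- as.vector(outer(seq_len(P), params,
                                 function(i, pm) paste0("theta_", pm, "[", i, "]")))
  param_names <- c(param_names, theta_names)

  extract <- function(state) {
    sig <- state$xi * sqrt(diag(state$Q))
    out <- c(stats::pnorm(state$mu), state$mu, sig)
    if (S > 1) {
      cr <- stats::cov2cor(state$sp$Sigma)
      out <- c(out, cr[lower.tri(cr)])  # column-major = combn pair order
    }
    if (length(state$beta)) out <- c(out, state$beta)
    c(out, as.vector(state$theta))
  }

  log_post <- function(state) sum(state$ll)

  list(name = "latent_trait_mpt", param_names = param_names, init = init,
       update = update, extract = extract, log_post = log_post)
}

xb_matrix <- function(beta, idx_s, X, P, S) {
  xb <- matrix(0, P, S)
  if (length(beta)) {
    for (s in seq_len(S)) {
      js <- idx_s[[s]]
      if (length(js)) xb[, s] <- X[, js, drop = FALSE] %*% beta[js]
    }
  }
  xb
}

#' Fit a latent-trait MPT model
#'
#' Samples the posterior of the hierarchical MPT model in which the
#' probit-transformed individual parameters follow a multivariate normal
#' distribution, `qnorm(theta_p) = mu + X beta + delta_p`,
#' `delta_p ~ MVN(0, Sigma)`, using a Metropolis-within-Gibbs sweep:
#' componentwise adaptive Metropolis for the probit values, conjugate Gibbs
#' for `mu`, slopes and factor effects, conjugate inverse-Wishart Gibbs for
#' the correlation backbone `Q`, Metropolis for the scaling factors `xi_s`,
#' and inverse-gamma Gibbs for the slope variances `g_s`.
#'
#' @param model An `mpt_model` (or path to an EQN file).
#' @param data An `mpt_data`, counts matrix/data frame, or CSV path.
#' @param restrictions Optional restrictions (object, text, or file path)
#'   applied to `model` first.
#' @param covariates Optional data frame (or CSV path) of participant
#'   covariates, aligned by row order.
#' @param predictors Optional [predictor_spec()] describing which covariates
#'   predict which MPT parameters.
#' @param priors A [trait_priors()] object.
#' @param settings An [mcmc_settings()] object.
#' @return Object of class `c("trait_fit", "mpt_fit")` with elements
#'   `draws`, `model`, `data`, `design`, `priors`, `settings`, `summary`,
#'   and `converged`.  Unstandardized slopes (`beta_unstd_*`,
#'   standardized slope divided by the covariate's population SD) are
#'   appended to the draws for continuous predictors.  A warning is issued,
#'   never silenced, when any group-level `Rhat >= 1.05`.
#' @export
fit_trait <- function(model, data, restrictions = NULL, covariates = NULL,
                      predictors = NULL, priors = trait_priors(),
                      settings = mcmc_settings()) {
  if (is.character(model)) model <- read_eqn(model)
  if (!is.null(restrictions)) model <- apply_restrictions(model, restrictions)
  if (is.character(data)) data <- read_freq_csv(data, model)
  if (!inherits(data, "mpt_data")) data <- as_mpt_data(data, model)
  if (is.character(covariates)) {
    covariates <- utils::read.csv(covariates, stringsAsFactors = FALSE)
  }
  design <- if (!is.null(predictors)) {
    if (is.null(covariates)) stop("predictors given but no covariates")
    if (nrow(as.data.frame(covariates)) != nrow(data$counts)) {
      stop("covariate rows must align with participants")
    }
    build_design(covariates, predictors, model$params)
  } else {
    list(X = matrix(0, nrow(data$counts), 0), meta = NULL, factors = NULL)
  }
  kernel <- trait_kernel(model, data, design, priors, settings)
  draws <- run_chains(kernel, settings)
  # derived: unstandardized slopes for continuous predictors
  if (!is.null(design$meta)) {
    cont <- which(design$meta$col_type == "continuous")
    if (length(cont)) {
      arr <- draws$draws
      extra <- arr[, , paste0("beta_", design$meta$col_name[cont]),
                   drop = FALSE]
      for (k in seq_along(cont)) {
        extra[, , k] <- extra[, , k] / design$meta$col_sd[cont[k]]
      }
      dimnames(extra)[[3]] <- paste0("beta_unstd_",
                                     design$meta$col_name[cont])
      new <- array(NA_real_, dim = dim(arr) + c(0, 0, length(cont)),
                   dimnames = list(NULL, NULL,
                                   c(dimnames(arr)[[3]],
                                     dimnames(extra)[[3]])))
      new[, , seq_len(dim(arr)[3])] <- arr
      new[, , dim(arr)[3] + seq_along(cont)] <- extra
      draws$draws <- new
    }
  }
  fit <- structure(list(draws = draws, model = model, data = data,
                        design = design, priors = priors,
                        settings = settings, covariates = covariates,
                        type = "trait"),
                   class = c("trait_fit", "mpt_fit"))
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

#' @export
print.mpt_fit <- function(x, ...) {
  cat(sprintf("Hierarchical MPT fit (%s), %d participants, %d parameters\n",
              x$type, nrow(x$data$counts), length(x$model$params)))
  group <- !grepl("^theta_", x$summary$parameter)
  print(x$summary[group, c("parameter", "mean", "sd", "q2.5", "q97.5",
                           "rhat", "ess")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Sample the prior-implied group-level quantities
#'
#' Draws `mu`, `Q` and `xi` from their priors and returns the implied
#' probability-scale group means `pnorm(mu_s)`, probit-scale SDs
#' `sigma_s = xi_s * sqrt(Q_ss)` and (for `S >= 2`) the correlation
#' `rho_12` -- the data behind prior histograms.
#'
#' @param priors A [trait_priors()].
#' @param S Number of MPT parameters.
#' @param n Number of prior draws.
#' @param seed Integer seed.
#' @return Data frame with columns `prob_mean_1..S`, `sigma_1..S`, `rho_12`.
#' @export
sample_prior_predictive <- function(priors, S, n = 5000, seed = 1) {
  V <- if (is.null(priors$V)) diag(S) else priors$V
  df0 <- if (is.null(priors$df)) S + 1 else priors$df
  mu_mean <- expand_by_param(priors$mu_mean, as.character(seq_len(S)), "mu_mean")
  mu_sd <- expand_by_param(priors$mu_sd, as.character(seq_len(S)), "mu_sd")
  with_seed(seed, {
    out <- matrix(NA_real_, n, 2 * S + (S >= 2))
    Vinv <- chol2inv(chol(V))
    for (i in seq_len(n)) {
      mu <- stats::rnorm(S, mu_mean, mu_sd)
      Q <- chol2inv(chol(stats::rWishart(1, df0, Vinv)[, , 1]))
      xi <- stats::runif(S, priors$xi_bounds[1], priors$xi_bounds[2])
      sig <- xi * sqrt(diag(Q))
      row <- c(stats::pnorm(mu), sig)
      if (S >= 2) row <- c(row, stats::cov2cor(Q)[1, 2])
      out[i, ] <- row
    }
    out <- as.data.frame(out)
    names(out) <- c(paste0("prob_mean_", seq_len(S)),
                    paste0("sigma_", seq_len(S)),
                    if (S >= 2) "rho_12")
    out
  })
}
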