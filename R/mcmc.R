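# Model-agnostic MCMC infrastructure: multi-chain driver, convergence
# diagnostics, run extension, draw summaries, and CSV export.

#' MCMC settings
#'
#' @param n_iter Total iterations per chain (default 20000).
#' @param n_burnin Burn-in iterations dropped from the front (default 2000).
#'   Proposal-scale adaptation runs only during burn-in and is frozen
#'   afterwards, so the retained chain is Markov.
#' @param thin Keep every `thin`-th post-burn-in iteration (default 5).
#' @param n_chains Number of independent chains (default 3).
#' @param seed Master integer seed; per-chain sub-seeds are derived
#'   deterministically.
#' @param target_acceptance Robbins-Monro target acceptance rate for scalar
#'   random-walk updates (default 0.35).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 20000, n_burnin = 2000, thin = 5,
                          n_chains = 3, seed = 1, target_acceptance = 0.35) {
  stopifnot(n_burnin < n_iter, thin >= 1, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 target_acceptance = target_acceptance),
            class = "mcmc_settings")
}

# Robbins-Monro log-scale adaptation step for iteration i (vanishing step).
rm_step <- function(i, c0 = 1) c0 / ceiling(i / 50)

#' Run independent MCMC chains
#'
#' A kernel is a list with elements `param_names` (character vector naming
#' every scalar the kernel reports), `init(chain)` returning an initial
#' state, `update(state, adapt, iter)` performing one full sweep (adapting
#' proposal scales only while `adapt` is `TRUE`), `extract(state)` returning
#' the named numeric vector of current values, and optionally
#' `log_post(state)` used to reject non-finite initial states (re-drawn up
#' to 10 times).
#'
#' @param kernel Kernel list as described above.
#' @param settings An [mcmc_settings()] object.
#' @return Object of class `mpt_draws`: list with `draws` (array chain x
#'   retained-iteration x parameter), `settings`, `final_states`,
#'   `kernel_name`, `n_extensions`.
#' @export
run_chains <- function(kernel, settings) {
  stopifnot(inherits(settings, "mcmc_settings"))
  n_keep <- (settings$n_iter - settings$n_burnin) %/% settings$thin
  if (n_keep < 1L) stop("no retained iterations; increase n_iter")
  npar <- length(kernel$param_names)
  draws <- array(NA_real_,
                 dim = c(settings$n_chains, n_keep, npar),
                 dimnames = list(NULL, NULL, kernel$param_names))
  final_states <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    set.seed(sub_seed(settings$seed, ch))
    state <- kernel$init(ch)
    if (!is.null(kernel$log_post)) {
      tries <- 0L
      while (!is.finite(kernel$log_post(state))) {
        tries <- tries + 1L
        if (tries > 10L) stop("non-finite log-posterior after 10 init attempts")
        state <- kernel$init(ch)
      }
    }
    keep_i <- 0L
    for (i in seq_len(settings$n_iter)) {
      state <- kernel$update(state, adapt = i <= settings$n_burnin, iter = i)
      if (i > settings$n_burnin &&
          (i - settings$n_burnin) %% settings$thin == 0L) {
        keep_i <- keep_i + 1L
        draws[ch, keep_i, ] <- kernel$extract(state)
      }
    }
    final_states[[ch]] <- state
  }
  structure(list(draws = draws, settings = settings,
                 final_states = final_states,
                 kernel_name = if (is.null(kernel$name)) "kernel" else kernel$name,
                 n_extensions = 0L),
            class = "mpt_draws")
}

#' Continue sampling from the final states of a previous run
#'
#' Each chain restarts from its stored final state (no new burn-in, no
#' adaptation) and the retained draws are concatenated to the existing ones.
#'
#' @param draws An `mpt_draws` object holding final states.
#' @param kernel The same kernel that produced `draws`.
#' @param extra_iter Additional iterations per chain (0 returns the input
#'   unchanged).
#' @param thin Must equal the original thinning if supplied.
#' @return The extended `mpt_draws`.
#' @export
extend_run <- function(draws, kernel, extra_iter, thin = NULL) {
  stopifnot(inherits(draws, "mpt_draws"))
  if (!is.null(thin) && thin != draws$settings$thin) {
    stop("cannot change thinning when extending a run")
  }
  if (extra_iter == 0L) return(draws)
  s <- draws$settings
  n_new <- extra_iter %/% s$thin
  if (n_new < 1L) stop("extra_iter below one thinning interval")
  npar <- dim(draws$draws)[3]
  add <- array(NA_real_, dim = c(s$n_chains, n_new, npar),
               dimnames = dimnames(draws$draws))
  states <- draws$final_states
  ext <- draws$n_extensions + 1L
  for (ch in seq_len(s$n_chains)) {
    set.seed(sub_seed(s$seed, ch + ext * s$n_chains))
    state <- states[[ch]]
    keep_i <- 0L
    for (i in seq_len(extra_iter)) {
      state <- kernel$update(state, adapt = FALSE, iter = s$n_iter + i)
      if (i %% s$thin == 0L) {
        keep_i <- keep_i + 1L
        add[ch, keep_i, ] <- kernel$extract(state)
      }
    }
    states[[ch]] <- state
  }
  out <- draws
  out$draws <- array(NA_real_,
                     dim = c(s$n_chains, dim(draws$draws)[2] + n_new, npar),
                     dimnames = dimnames(draws$draws))
  out$draws[, seq_len(dim(draws$draws)[2]), ] <- draws$draws
  out$draws[, dim(draws$draws)[2] + seq_len(n_new), ] <- add
  out$final_states <- states
  out$n_extensions <- ext
  out
}

#' Gelman-Rubin convergence diagnostics
#'
#' Split-chain `Rhat` (each chain halved) and effective sample size with the
#' autocorrelation sum truncated at the first negative pair (Geyer's initial
#' positive sequence).  Parameters with zero variance are reported with
#' `Rhat = 1` and flagged as degenerate.
#'
#' @param draws An `mpt_draws` object (>= 2 chains, >= 10 retained
#'   iterations needed for a meaningful `Rhat`).
#' @return Data frame with columns `parameter`, `rhat`, `ess`, `degenerate`.
#' @export
gelman_rubin <- function(draws) {
  arr <- draws$draws
  n_chain <- dim(arr)[1]; n_iter <- dim(arr)[2]; npar <- dim(arr)[3]
  if (n_chain < 2L) stop("need at least 2 chains")
  if (n_iter < 10L) stop("need at least 10 retained iterations")
  half <- n_iter %/% 2L
  out <- data.frame(parameter = dimnames(arr)[[3]],
                    rhat = NA_real_, ess = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(npar)) {
    seqs <- list()
    for (ch in seq_len(n_chain)) {
      x <- arr[ch, , j]
      seqs[[2 * ch - 1]] <- x[seq_len(half)]
      seqs[[2 * ch]] <- x[(n_iter - half + 1):n_iter]
    }
    m <- length(seqs); n <- half
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, stats::var, numeric(1))
    W <- mean(vars)
    if (!is.finite(W) || W <= 0) {
      out$rhat[j] <- 1; out$ess[j] <- NA_real_; out$degenerate[j] <- TRUE
      next
    }
    B <- n * stats::var(means)
    varplus <- (n - 1) / n * W + B / n
    out$rhat[j] <- sqrt(varplus / W)
    # ESS from chain-averaged autocorrelations, initial positive sequence
    max_lag <- min(n - 2L, 1000L)
    rho <- rep(0, max_lag)
    for (sq in seqs) {
      ac <- stats::acf(sq, lag.max = max_lag, plot = FALSE,
                       demean = TRUE)$acf[-1]
      rho <- rho + ac * stats::var(sq) / (m * varplus)
    }
    ssum <- 0
    t <- 1L
    while (t + 1L <= max_lag) {
      pair <- rho[t] + rho[t + 1L]
      if (!is.finite(pair) || pair < 0) break
      ssum <- ssum + pair
      t <- t + 2L
    }
    out$ess[j] <- min(m * n / (1 + 2 * ssum), m * n)
  }
  out
}

#' Summary table of posterior draws
#'
#' @param draws An `mpt_draws` object.
#' @param probs Quantiles to report (default 2.5%, 50%, 97.5%).
#' @return Data frame with mean, SD, median, quantiles, `rhat` and `ess`
#'   per named parameter.
#' @export
summarize_draws <- function(draws, probs = c(0.025, 0.5, 0.975)) {
  arr <- draws$draws
  npar <- dim(arr)[3]
  flat <- matrix(arr, ncol = npar)
  colnames(flat) <- dimnames(arr)[[3]]
  qs <- t(apply(flat, 2L, stats::quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  conv <- tryCatch(gelman_rubin(draws),
                   error = function(e) data.frame(rhat = NA_real_,
                                                  ess = NA_real_))
  out <- data.frame(parameter = colnames(flat),
                    mean = colMeans(flat),
                    sd = apply(flat, 2L, stats::sd),
                    median = apply(flat, 2L, stats::median),
                    stringsAsFactors = FALSE)
  out <- cbind(out, qs, rhat = conv$rhat, ess = conv$ess)
  rownames(out) <- NULL
  out
}

# flatten chains into one (chain*iter) x npar matrix
flat_draws <- function(draws, pattern = NULL) {
  arr <- draws$draws
  flat <- matrix(arr, ncol = dim(arr)[3])
  colnames(flat) <- dimnames(arr)[[3]]
  if (!is.null(pattern)) {
    flat <- flat[, grepl(pattern, colnames(flat)), drop = FALSE]
  }
  flat
}

#' Export draws to CSV with a JSON metadata sidecar
#'
#' @param draws An `mpt_draws` object.
#' @param csv_path Output CSV (columns = named scalar parameters, preceded
#'   by `chain` and `iteration`).
#' @param meta_path Optional JSON sidecar (settings, kernel, parameter
#'   registry).
#' @export
write_draws <- function(draws, csv_path, meta_path = NULL) {
  arr <- draws$draws
  n_chain <- dim(arr)[1]; n_iter <- dim(arr)[2]
  flat <- matrix(arr, ncol = dim(arr)[3])
  colnames(flat) <- dimnames(arr)[[3]]
  df <- data.frame(chain = rep(seq_len(n_chain), times = n_iter),
                   iteration = rep(seq_len(n_iter), each = n_chain))
  df <- cbind(df, as.data.frame(flat, check.names = FALSE))
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(kernel = draws$kernel_name,
                 settings = unclass(draws$settings),
                 n_extensions = draws$n_extensions,
                 parameters = dimnames(arr)[[3]])
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(csv_path)
}

#' Read draws previously written with [write_draws()]
#'
#' The result supports summaries and diagnostics but cannot be extended
#' (chain states are not serialized).
#'
#' @param csv_path CSV produced by [write_draws()].
#' @return An `mpt_draws` object.
#' @export
read_draws <- function(csv_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  chains <- sort(unique(df$chain))
  iters <- sort(unique(df$iteration))
  pars <- setdiff(names(df), c("chain", "iteration"))
  arr <- array(NA_real_, dim = c(length(chains), length(iters), length(pars)),
               dimnames = list(NULL, NULL, pars))
  for (ch in seq_along(chains)) {
    sub <- df[df$chain == chains[ch], ]
    sub <- sub[order(sub$iteration), ]
    arr[ch, , ] <- as.matrix(sub[, pars, drop = FALSE])
  }
  structure(list(draws = arr, settings = NULL, final_states = NULL,
                 kernel_name = "imported", n_extensions = 0L),
            class = "mpt_draws")
}

#' @export
print.mpt_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("MCMC draws: %d chain(s) x %d retained iterations x %d parameters [%s]\n",
              d[1], d[2], d[3], x$kernel_name))
  invisible(x)
}
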