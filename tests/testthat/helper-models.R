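# Shared fixtures: built in code, never stored.

# one-tree toy model: hit with probability D + (1-D)g, miss otherwise
toy_eqn <- function() {
  c("# toy detection model",
    "t1 h D",
    "t1 h (1-D)*g",
    "t1 m (1-D)*(1-g)")
}

toy_model <- function() parse_eqn(toy_eqn())

htsm_model <- function() parse_eqn(eqn_2htsm())

htsm_restricted <- function() {
  apply_restrictions(htsm_model(), restrictions_2htsm())
}

# named theta row for a model, all values equal
theta_at <- function(model, value = 0.5) {
  setNames(rep(value, length(model$params)), model$params)
}

# quick small-data trait fit used by several tests
small_trait_fit <- function(seed = 1, P = 20, items = c(E = 20, U = 20, N = 40),
                            n_iter = 800, n_burnin = 300, n_chains = 2) {
  model <- htsm_restricted()
  sim <- gen_trait_mpt(P, items,
                       trait_pop_spec(mu_probit = c(a = 0.3, b = -0.1,
                                                    d1 = 0.6, D1 = 0.5),
                                      sigma_probit = 0.4),
                       model, seed = seed)
  fit <- suppressWarnings(fit_trait(model, sim$data,
                                    settings = mcmc_settings(n_iter, n_burnin,
                                                             2, n_chains,
                                                             seed = seed)))
  list(fit = fit, sim = sim, model = model)
}
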