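# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG; the caller's RNG state is
# restored afterwards so seeded utilities do not perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic sub-seed for chain/replication k under a master seed.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 104729 * as.double(k)) %% 2147483629)
}

# theta clipping distance from the boundary before taking logs
THETA_EPS <- 1e-9

clip01 <- function(x, eps = THETA_EPS) pmin(pmax(x, eps), 1 - eps)
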