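# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards. All randomness in the package flows through this, so no
# hidden global state leaks between calls.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a per-item 32-bit seed from a base seed and an id, so that
# per-frame randomness is reproducible independently of processing order.
derive_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(id) * 16807 + 12345) %%
               2147483647)
}

vec_norm <- function(v) sqrt(sum(v^2))

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
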