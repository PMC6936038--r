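# shared fixtures: small parameter sets and cached heavy objects

test_params <- function(...) cell_parameters(...)

# params with the suspension energy cached (cheap, ~0.1 s)
test_params_gs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- suspension_energy(cell_parameters())$params
    cache
  }
})

# a mildly deformed, clearly valid shape (seeded, reused across files)
test_shape <- function(amplitude = 0.15, seed = 7) {
  set.seed(seed)
  cvec <- c(stats::rnorm(4, 0, amplitude), stats::rnorm(16, 0, amplitude / 3))
  shape_state(cvec)
}

# session-level cache for expensive ensembles shared between test files
.ens_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ens_cache)) {
    assign(key, force(expr), envir = .ens_cache)
  }
  get(key, envir = .ens_cache)
}
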