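# shared fixture builders (everything generated in code, fixed seeds)

rand_pd <- function(n, seed = NULL, jitter = 1) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + jitter * diag(n)
}

one_factor_model <- function() lsemModel("FX =~ X1 + X2 + X3")

two_factor_model <- function() {
  lsemModel("FX =~ X1 + X2 + X3\nFY =~ Y1 + Y2 + Y3")
}

# small cached datasets; built once per test run
.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- build()
  .fx_cache[[key]]
}

dgm3_pop <- function() cached("dgm3_pop", function() {
  makePopulation(lsemDGM("dgm3", n_factors = 1), group_size = 400, seed = 11)
})

dgm1_pop <- function() cached("dgm1_pop", function() {
  makePopulation(lsemDGM("dgm1", n_factors = 1), group_size = 400, seed = 12)
})

dgm1_pop2f <- function() cached("dgm1_pop2f", function() {
  makePopulation(lsemDGM("dgm1", n_factors = 2), group_size = 400, seed = 13)
})
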