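# Shared fixtures built in code.

# single-cell forcing with sensible open-ocean defaults
mk_forcing <- function(T_c = 15, DOC = 22, POC = 5, DO = 250,
                       Z = 0.5, P = 1, z = 10)
  env_forcing(T_c = T_c, DOC = DOC, POC = POC, DO = DO, Z = Z, P = P, z = z)

# random single-cell forcings for property-style loops
random_forcings <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(T_c = runif(n, -2, 30), DOC = runif(n, 0, 60),
             POC = runif(n, 0, 20), DO = runif(n, 0, 400),
             Z = runif(n, 0, 2), P = runif(n, 0, 3),
             z = runif(n, 0, 250), B = runif(n, 0, 5))
}

# tiny grid for generator/composite tests
mk_grid_small <- function() build_grid(6, 8)

expect_rel_equal <- function(x, y, tol = 1e-10) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
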