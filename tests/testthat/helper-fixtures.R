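# Shared fixtures, built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, force(expr), envir = fixture_env)
  get(name, envir = fixture_env)
}

fix_catalog <- function() memo("catalog", enumerate_dags(3L))

# tiny LIF settings used by unit tests (NOT by acceptance tests)
tiny_circuit <- function(...) circuit_params(n_neurons = 100L, ...)
tiny_settings <- function(duration = 500) sim_settings(duration = duration)

# a single short desk LFP example per named config, shared across tests
fix_lfp <- function(name) memo(paste0("lfp_", name), {
  lif_simulate(named_config(name, fix_catalog()), tiny_circuit(),
               settings = tiny_settings(1000), seed = 99L)
})

# wrap plain matrices into a dataset for diagnostics helpers
as_mini_dataset <- function(ts_list, config, generator = "NN", dt = 1) {
  ex <- lapply(ts_list, function(m)
    structure(list(ts = m, config = config, sampling_interval = dt,
                   meta = list(generator = generator)), class = "ec_example"))
  effconn:::new_dataset(ex, generator, fix_catalog(), list())
}

# small balanced MAR dataset reused by classifier tests (3 per config, short)
fix_mar_mini <- function() memo("mar_mini",
  generate_mar_dataset(fix_catalog(), 3L, mar_params(), N = 400L, seed = 7L))

expect_rel_equal <- function(x, y, tol) expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
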