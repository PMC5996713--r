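test_that("parameter constructors validate their invariants", {
  expect_error(circuit_params(tau_rA = 3, tau_dA = 2))      # rise < decay
  expect_error(circuit_params(v_thr = 10, v_res = 11))      # reset below threshold
  expect_error(inter_circuit_params(j_int_low = 0.2, j_int_high = 0.1))
  expect_error(sim_settings(dt = 0.3, lfp_dt = 1))          # dt must divide lfp_dt
  expect_error(lif_simulate(named_config("empty"), circuit_params(n_neurons = 10),
                            settings = sim_settings(dt = 0.5, lfp_dt = 1)),
               "dt")
})

test_that("build_connectivity: binomial intra counts, edge-gated inter projections", {
  cat3 <- fix_catalog()
  # empty configuration: no inter-circuit synapses at all
  c0 <- build_connectivity(named_config("empty", cat3),
                           circuit_params(n_neurons = 100), seed = 3)
  expect_equal(c0$n_inter, 0)
  expect_length(c0$j_int, 0)
  # intra counts within 4 sd of the Binomial(N(N-1), p) mean
  cc <- build_connectivity(named_config("xy", cat3),
                           circuit_params(n_neurons = 200), seed = 4)
  mean_intra <- 200 * 199 * 0.2
  sd_intra <- sqrt(mean_intra * 0.8)
  for (m in 1:3)
    expect_lt(abs(cc$intra_counts[m] - mean_intra), 4 * sd_intra)
  # univariate X->Y: senders are excitatory cells of X, receivers any cell of Y
  ce <- build_connectivity(named_config("xy", cat3),
                           circuit_params(n_neurons = 50),
                           inter_circuit_params(scale_with_size = FALSE),
                           seed = 5, return_edges = TRUE)
  expect_true(all(ce$inter_sender <= 40))        # n_exc = 40 in circuit X
  expect_true(all(ce$inter_target > 50 & ce$inter_target <= 100))
  expect_length(ce$j_int, 1)
  expect_true(ce$j_int >= 0 && ce$j_int <= 0.18)
  # inter count ~ Binomial(40 * 50, 0.2)
  expect_lt(abs(ce$n_inter - 40 * 50 * 0.2), 4 * sqrt(40 * 50 * 0.2 * 0.8))
})

test_that("ou_rate_series: constant at sigma = 0, OU autocorrelation, rectification", {
  st <- sim_settings(duration = 100)
  r0 <- ou_rate_series(ext_input_params(ou_sigma = 0), st, seed = 1)
  expect_true(all(r0 == 2))
  r <- ou_rate_series(ext_input_params(nu0 = 50, ou_tau = 16, ou_sigma = 1),
                      sim_settings(duration = 4000), seed = 2)
  n <- r - 50  # no rectification bites at this offset
  for (k in c(100, 200, 400)) {  # lags in dt units (5, 10, 20 ms)
    emp <- cor(n[1:(length(n) - k)], n[(k + 1):length(n)])
    expect_lt(abs(emp - exp(-k * 0.05 / 16)), 0.08)
  }
  expect_rel_equal(sd(n), 1, 0.15)
  rneg <- ou_rate_series(ext_input_params(nu0 = 0, ou_sigma = 5), st, seed = 3)
  expect_true(all(rneg >= 0))
})

test_that("zero input gives zero LFP and no dynamics", {
  lfp <- lif_simulate(named_config("empty"), tiny_circuit(),
                      ext = ext_input_params(nu0 = 0, ou_sigma = 0),
                      settings = tiny_settings(200), seed = 1)
  expect_true(all(lfp$values == 0))
})

test_that("subthreshold membrane decay matches the closed-form leak solution", {
  v0 <- 10
  lfp <- lif_simulate(named_config("empty"), tiny_circuit(),
                      settings = tiny_settings(100), seed = 1,
                      v_init = v0, record_v = TRUE,
                      ext_spike_times = numeric(0))  # all input silenced
  t <- 1:100  # ms, LFP tick times
  expected <- v0 * exp(-t / 20)  # neuron 1 is excitatory, tau_m = 20 ms
  expect_equal(unname(lfp$v[1, ]), expected, tolerance = 1e-3)
})

test_that("synaptic cascade peaks at the closed-form two-exponential peak time", {
  circ <- circuit_params(n_neurons = 1, p_conn_intra = 0)
  st <- sim_settings(dt = 0.05, duration = 20, lfp_dt = 0.05)
  lfp <- lif_simulate(named_config("empty"), circ, settings = st, seed = 1,
                      ext_spike_times = 10)
  ticks <- seq_len(ncol(lfp$values)) * 0.05
  peak_t <- ticks[which.max(lfp$values[1, ])]
  # spike lands after the intra latency; I_A then peaks after
  # tau_d tau_r / (tau_d - tau_r) * log(tau_d / tau_r)
  tstar <- 10 + 1 + (2 * 0.4 / (2 - 0.4)) * log(2 / 0.4)
  expect_rel_equal(peak_t, tstar, 1e-3)
  # the sampled amplitude matches the closed form on the same grid
  jump <- 20 * 0.41 / 0.4          # tau_m * J_ext / tau_rA
  cpk <- jump * 0.4 / (2 - 0.4)
  dtv <- peak_t - 11
  expect_rel_equal(max(lfp$values[1, ]), cpk * (exp(-dtv / 2) - exp(-dtv / 0.4)), 1e-6)
})

test_that("LFP is non-negative and runs are seed-deterministic", {
  l1 <- fix_lfp("xy")
  expect_true(all(l1$values >= 0))
  expect_true(all(is.finite(l1$values)))
  l2 <- lif_simulate(named_config("xy", fix_catalog()), tiny_circuit(),
                     settings = tiny_settings(1000), seed = 99L)
  expect_identical(l1$values, l2$values)
  l3 <- lif_simulate(named_config("xy", fix_catalog()), tiny_circuit(),
                     settings = tiny_settings(1000), seed = 100L)
  expect_false(isTRUE(all.equal(l1$values, l3$values)))
})

test_that("generate_nn_dataset is balanced with reproducible labels and metadata", {
  cat3 <- fix_catalog()
  ds <- generate_nn_dataset(cat3, 2L, tiny_circuit(), settings = tiny_settings(200),
                            seed = 17L)
  expect_length(ds$examples, 50)
  expect_equal(as.integer(table(dataset_labels(ds))), rep(2L, 25))
  expect_equal(dim(ds$examples[[1]]$ts), c(3, 200))
  ds2 <- generate_nn_dataset(cat3, 2L, tiny_circuit(), settings = tiny_settings(200),
                             seed = 17L)
  expect_identical(dataset_labels(ds), dataset_labels(ds2))
  expect_identical(lapply(ds$examples, function(e) e$meta$seed),
                   lapply(ds2$examples, function(e) e$meta$seed))
  expect_equal(ds$examples[[33]]$ts, ds2$examples[[33]]$ts)
})
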