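#' Single-circuit LIF parameters
#'
#' Defaults follow the recurrent cortical microcircuit family this model
#' extends: 5000 neurons per circuit, 80% excitatory; membrane time
#' constants 20 ms (excitatory) / 10 ms (inhibitory); threshold 18 mV and
#' reset 11 mV above rest; refractory 2 / 1 ms; AMPA rise/decay 0.4 / 2 ms,
#' GABA rise/decay 0.25 / 5 ms; intra-circuit latency 1 ms; recurrent AMPA
#' efficacies 0.42 / 0.7 and GABA efficacies 1.7 / 2.7 onto excitatory /
#' inhibitory targets. The external AMPA efficacies default to 0.41 / 0.71,
#' chosen so the mean external drive (baseline rate 2 spikes/ms times
#' membrane time constant times efficacy) sits just below the 18 mV
#' threshold: the network then operates in the fluctuation-driven
#' asynchronous-irregular regime, where population rates track input
#' fluctuations fast enough for inter-circuit latencies to be identifiable
#' from LFP cross-correlograms. All synaptic constants and efficacies are
#' configurable assumptions of the model family, not quantities this
#' package claims to have fit.
#'
#' @param n_neurons Neurons per circuit.
#' @param frac_excitatory Fraction of excitatory (pyramidal) neurons.
#' @param p_conn_intra Within-circuit connection probability per directed
#'   pair.
#' @param tau_m_exc,tau_m_inh Membrane time constants, ms.
#' @param v_thr,v_res Spike threshold and reset, mV above rest.
#' @param tau_rp_exc,tau_rp_inh Refractory periods, ms.
#' @param tau_rA,tau_dA,tau_rG,tau_dG Synaptic rise/decay constants, ms.
#' @param tau_L Intra-circuit synaptic latency, ms.
#' @param j_exc,j_inh,j_ext Length-2 efficacy vectors onto (excitatory,
#'   inhibitory) targets for recurrent AMPA, recurrent GABA, and external
#'   AMPA synapses (dimensionless membrane-potential increments).
#' @return List of class `circuit_params`.
#' @export
circuit_params <- function(n_neurons = 5000L, frac_excitatory = 0.8,
                           p_conn_intra = 0.2,
                           tau_m_exc = 20, tau_m_inh = 10,
                           v_thr = 18, v_res = 11,
                           tau_rp_exc = 2, tau_rp_inh = 1,
                           tau_rA = 0.4, tau_dA = 2, tau_rG = 0.25, tau_dG = 5,
                           tau_L = 1,
                           j_exc = c(0.42, 0.7), j_inh = c(1.7, 2.7),
                           j_ext = c(0.41, 0.71)) {
  stopifnot(tau_rA < tau_dA, tau_rG < tau_dG, v_res < v_thr,
            frac_excitatory > 0, frac_excitatory < 1,
            p_conn_intra >= 0, p_conn_intra <= 1,
            all(c(tau_m_exc, tau_m_inh, tau_rp_exc, tau_rp_inh,
                  tau_rA, tau_dA, tau_rG, tau_dG, tau_L) > 0))
  structure(as.list(environment()), class = "circuit_params")
}

#' Inter-circuit connection parameters
#'
#' A directed circuit edge projects from every excitatory neuron of the
#' sender to both neuron classes of the receiver with probability
#' `p_conn_inter`; the shared efficacy of one directed edge is drawn once
#' per example, uniformly in `[j_int_low, j_int_high]`.
#'
#' With `scale_with_size = TRUE`, inter-circuit efficacies are multiplied by
#' `reference_n / n_neurons`, keeping the mean transmitted current at
#' reduced circuit sizes comparable to the reference 5000-neuron circuits
#' (the number of projecting synapses scales linearly with circuit size).
#'
#' @param p_conn_inter Connection probability per directed neuron pair.
#' @param tau_L_int Inter-circuit synaptic latency, ms (default 3).
#' @param j_int_low,j_int_high Bounds of the uniform efficacy draw.
#' @param scale_with_size Scale efficacies for reduced circuits.
#' @param reference_n Circuit size at which efficacies are defined.
#' @return List of class `inter_circuit_params`.
#' @export
inter_circuit_params <- function(p_conn_inter = 0.2, tau_L_int = 3,
                                 j_int_low = 0, j_int_high = 0.18,
                                 scale_with_size = TRUE, reference_n = 5000L) {
  stopifnot(j_int_low >= 0, j_int_low <= j_int_high, tau_L_int > 0)
  structure(as.list(environment()), class = "inter_circuit_params")
}

#' External-input parameters
#'
#' Every neuron receives an independent Poisson spike train whose common
#' time-varying rate is `[nu0 + n(t)]_+`, with `n(t)` an Ornstein-Uhlenbeck
#' noise process (one realization per circuit per example).
#'
#' @param nu0 Baseline signal rate, spikes/ms (default 2).
#' @param ou_tau OU correlation time, ms (default 16).
#' @param ou_sigma OU stationary standard deviation, spikes/ms (default 0.4).
#' @return List of class `ext_input_params`.
#' @export
ext_input_params <- function(nu0 = 2, ou_tau = 16, ou_sigma = 0.4) {
  stopifnot(ou_tau > 0, ou_sigma >= 0)
  structure(as.list(environment()), class = "ext_input_params")
}

#' Simulation settings
#'
#' @param dt Integration step, ms (default 0.05; must divide `lfp_dt` and
#'   resolve the fastest synaptic rise time).
#' @param duration Simulated time, ms.
#' @param lfp_dt LFP sampling interval, ms (1 ms = 1 kHz; `duration /
#'   lfp_dt` timepoints are emitted).
#' @return List of class `sim_settings`.
#' @export
sim_settings <- function(dt = 0.05, duration = 6000, lfp_dt = 1) {
  stopifnot(dt > 0, duration > 0, lfp_dt >= dt)
  if (abs(lfp_dt / dt - round(lfp_dt / dt)) > 1e-9)
    stop("`dt` must divide `lfp_dt`", call. = FALSE)
  structure(list(dt = dt, duration = duration, lfp_dt = lfp_dt),
            class = "sim_settings")
}

#' Rectified Ornstein-Uhlenbeck rate series
#'
#' Exact-discretization OU sample (`n[t+1] = a n[t] + sigma sqrt(1 - a^2) w`,
#' `a = exp(-dt / ou_tau)`, stationary initialization) added to the constant
#' signal rate and rectified at zero.
#'
#' @param ext An [ext_input_params()].
#' @param settings A [sim_settings()].
#' @param seed Optional integer seed.
#' @param n_steps Number of steps (defaults to `duration / dt`).
#' @return Numeric vector of non-negative rates, spikes/ms per `dt` bin.
#' @export
ou_rate_series <- function(ext, settings, seed = NULL,
                           n_steps = round(settings$duration / settings$dt)) {
  if (!is.null(seed)) set.seed(seed)
  a <- exp(-settings$dt / ext$ou_tau)
  n <- numeric(n_steps)
  if (ext$ou_sigma > 0) {
    n[1] <- stats::rnorm(1, 0, ext$ou_sigma)
    innov <- stats::rnorm(n_steps - 1, 0, ext$ou_sigma * sqrt(1 - a^2))
    for (t in seq_len(n_steps - 1)) n[t + 1] <- a * n[t] + innov[t]
  }
  pmax(ext$nu0 + n, 0)
}

# Per-example inter-circuit efficacies, one per present directed edge in
# row-major order, with optional size scaling.
draw_j_int <- function(config, circuit, inter) {
  n_edges <- sum(config$A)
  j <- stats::runif(n_edges, inter$j_int_low, inter$j_int_high)
  if (isTRUE(inter$scale_with_size)) j <- j * inter$reference_n / circuit$n_neurons
  j
}

#' Build the synapse table for one example
#'
#' Independent Bernoulli draws per ordered intra-circuit neuron pair, and,
#' for every directed circuit edge of the configuration, from each
#' excitatory sender neuron to every receiver neuron. Uses the same draw
#' order as [lif_simulate()], so the same seed reproduces the simulator's
#' wiring.
#'
#' @param config A `causal_config`.
#' @param circuit A [circuit_params()].
#' @param inter An [inter_circuit_params()].
#' @param seed Integer seed.
#' @param return_edges Also return the full inter-circuit edge list
#'   (sender/target global neuron indices) -- only sensible for small
#'   circuits.
#' @return List with `intra_counts` (synapses per circuit), `n_inter`,
#'   `n_exc`, `j_int` (per-edge efficacies after scaling), and optionally
#'   `inter_sender` / `inter_target`.
#' @export
build_connectivity <- function(config, circuit = circuit_params(),
                               inter = inter_circuit_params(), seed = 1L,
                               return_edges = FALSE) {
  set.seed(seed)
  j_int <- draw_j_int(config, circuit, inter)
  out <- lif_connectivity_cpp(config$A, circuit$n_neurons, circuit$frac_excitatory,
                              circuit$p_conn_intra, inter$p_conn_inter,
                              j_int, c(circuit$tau_m_exc, circuit$tau_m_inh),
                              circuit$tau_rA, return_edges)
  out$j_int <- j_int
  out
}

#' Simulate the three-circuit LIF network
#'
#' Integrates the membrane and synaptic-current equations for all neurons of
#' three interconnected circuits wired according to `config`, and returns
#' the per-circuit LFP proxy (sum over pyramidal cells of the absolute AMPA
#' and GABA currents) sampled every `lfp_dt`.
#'
#' @param config A `causal_config` (M = 3).
#' @param circuit A [circuit_params()].
#' @param inter An [inter_circuit_params()].
#' @param ext An [ext_input_params()].
#' @param settings A [sim_settings()].
#' @param seed Integer seed; identical inputs and seed give identical
#'   output.
#' @param v_init Initial membrane potential, mV above rest.
#' @param record_v Also record the membrane potential of neuron 1 of each
#'   circuit at every LFP tick.
#' @param record_spikes Also return the spike raster (global neuron index,
#'   time ms).
#' @param ext_spike_times Deterministic test hook: times (ms) at which one
#'   external spike is delivered to every neuron (after the intra-circuit
#'   latency); Poisson input is disabled when this is non-`NULL`.
#' @return An `lfp_timeseries`: list with `values` (3 x timepoints, all
#'   non-negative), `sampling_interval` (ms), `channel_names`, plus `v`
#'   and/or `spikes` when requested, and `j_int`.
#' @export
lif_simulate <- function(config, circuit = circuit_params(),
                         inter = inter_circuit_params(),
                         ext = ext_input_params(),
                         settings = sim_settings(), seed = 1L,
                         v_init = 0, record_v = FALSE, record_spikes = FALSE,
                         ext_spike_times = NULL) {
  if (settings$dt > circuit$tau_rG / 5 + 1e-12)
    stop("`dt` too coarse for the GABA rise time (need dt <= tau_rG / 5)", call. = FALSE)
  set.seed(seed)
  j_int <- draw_j_int(config, circuit, inter)
  n_steps <- round(settings$duration / settings$dt)
  use_poisson <- is.null(ext_spike_times)
  rate <- matrix(0, config$M, n_steps)
  if (use_poisson) {
    for (m in seq_len(config$M))
      rate[m, ] <- ou_rate_series(ext, settings, n_steps = n_steps)
  }
  res <- lif_simulate_cpp(config$A, circuit$n_neurons, circuit$frac_excitatory,
                          circuit$p_conn_intra, inter$p_conn_inter,
                          c(circuit$tau_m_exc, circuit$tau_m_inh),
                          circuit$v_thr, circuit$v_res,
                          c(circuit$tau_rp_exc, circuit$tau_rp_inh),
                          circuit$tau_rA, circuit$tau_dA,
                          circuit$tau_rG, circuit$tau_dG,
                          circuit$tau_L, inter$tau_L_int,
                          circuit$j_exc, circuit$j_inh, circuit$j_ext,
                          j_int, rate,
                          settings$dt, settings$duration, settings$lfp_dt,
                          v_init,
                          if (is.null(ext_spike_times)) numeric(0) else ext_spike_times,
                          use_poisson, record_v, record_spikes)
  out <- structure(list(values = res$lfp, sampling_interval = settings$lfp_dt,
                        channel_names = c("X", "Y", "Z")[seq_len(config$M)],
                        j_int = j_int),
                   class = "lfp_timeseries")
  if (record_v) out$v <- res$v
  if (record_spikes)
    out$spikes <- data.frame(neuron = res$spike_neuron, time = res$spike_time)
  out
}

#' @export
print.lfp_timeseries <- function(x, ...) {
  cat("<lfp_timeseries>", nrow(x$values), "channels x", ncol(x$values),
      "timepoints @", x$sampling_interval, "ms\n")
  invisible(x)
}

#' Generate a balanced LIF-network (NN) dataset
#'
#' `n_per_config` examples per catalog configuration, each with independent
#' connectivity, external inputs and inter-circuit efficacies; per-example
#' seeds derive from the master seed, so any example is reproducible in
#' isolation.
#'
#' @param catalog A `dag_catalog` (M = 3).
#' @param n_per_config Examples per configuration (1000 at paper scale).
#' @param circuit,inter,ext,settings Generator parameters.
#' @param seed Master seed.
#' @param progress Print one line per configuration.
#' @return An `ec_dataset` with `generator = "NN"`; each example's `ts` is
#'   the 3 x timepoints LFP matrix.
#' @export
generate_nn_dataset <- function(catalog, n_per_config,
                                circuit = circuit_params(),
                                inter = inter_circuit_params(),
                                ext = ext_input_params(),
                                settings = sim_settings(), seed = 1L,
                                progress = FALSE) {
  stopifnot(n_per_config >= 1)
  examples <- vector("list", length(catalog) * n_per_config)
  k <- 0L
  for (cf in catalog$configurations) {
    if (progress)
      message("config ", cf$class_index, " (", sum(cf$A), " edges)")
    for (r in seq_len(n_per_config)) {
      k <- k + 1L
      ex_seed <- derive_seed(seed, k)
      lfp <- lif_simulate(cf, circuit, inter, ext, settings, seed = ex_seed)
      examples[[k]] <- structure(
        list(ts = lfp$values, config = cf, sampling_interval = lfp$sampling_interval,
             meta = list(generator = "NN", seed = ex_seed, j_int = lfp$j_int)),
        class = "ec_example")
    }
  }
  new_dataset(examples, "NN", catalog,
              params = list(n_neurons = circuit$n_neurons,
                            duration = settings$duration, dt = settings$dt,
                            lfp_dt = settings$lfp_dt, seed = seed))
}
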