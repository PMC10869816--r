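#' Configuration of the random excitatory/inhibitory population
#'
#' Defaults reproduce the study conditions of the 1000-neuron population:
#' 80\% excitatory, 20\% inhibitory neurons, every ordered pair connected
#' independently with probability 0.2 (so each neuron contacts about 200
#' others, roughly 200,000 synapses in all), unit synaptic weight.
#'
#' @param n number of neurons.
#' @param p_connect connection probability per ordered pair.
#' @param frac_excitatory fraction of excitatory neurons.
#' @param weight synaptic weight magnitude.
#' @param seed RNG seed for wiring and excitatory/inhibitory assignment.
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(n = 1000L, p_connect = 0.2, frac_excitatory = 0.8,
                           weight = 1, seed = 1L) {
  if (p_connect < 0 || p_connect > 1) stop("p_connect must be in [0, 1]")
  if (frac_excitatory < 0 || frac_excitatory > 1)
    stop("frac_excitatory must be in [0, 1]")
  structure(list(n = as.integer(n), p_connect = p_connect,
                 frac_excitatory = frac_excitatory, weight = weight,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Build a random directed network
#'
#' Connects every ordered pair `(i, j)`, `i != j`, independently with
#' probability `p_connect` (no self-connections). The first
#' `ceiling(frac_excitatory * n)` neurons are excitatory (+1 sign), the rest
#' inhibitory (-1); the assignment is then shuffled by the seed so
#' excitatory identity is not index-correlated. The sign of a synapse is
#' determined by its presynaptic neuron.
#'
#' @param cfg a [network_config()].
#' @return An `"hr_network"`: list with `n`, `edges` (data.frame `src`,
#'   `dst`, 1-based), `sign` (per-neuron, +1/-1), `weight`, `cfg`.
#' @examples
#' net <- build_random_network(network_config(n = 50, seed = 7))
#' nrow(net$edges) / (50 * 49)   # close to p_connect
#' @export
build_random_network <- function(cfg = network_config()) {
  n <- cfg$n
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(cfg$seed)
    code
  }
  withr_seed({
    n_exc <- ceiling(cfg$frac_excitatory * n)
    sgn <- sample(c(rep(1, n_exc), rep(-1, n - n_exc)))
    edges <- do.call(rbind, lapply(seq_len(n), function(i) {
      hit <- which(stats::runif(n) < cfg$p_connect)
      hit <- hit[hit != i]
      if (length(hit)) cbind(src = i, dst = hit) else NULL
    }))
  })
  if (is.null(edges)) edges <- cbind(src = integer(0), dst = integer(0))
  structure(list(n = n, edges = as.data.frame(edges), sign = sgn,
                 weight = cfg$weight, cfg = cfg),
            class = "hr_network")
}

#' @export
print.hr_network <- function(x, ...) {
  cat(sprintf("<hr_network: %d neurons (%d excitatory), %d synapses>\n",
              x$n, sum(x$sign > 0), nrow(x$edges)))
  invisible(x)
}

#' Number of directed synapses
#'
#' @param net an `"hr_network"`.
#' @return Integer edge count.
#' @export
synapse_count <- function(net) nrow(net$edges)

#' Simulate the coupled population
#'
#' Every neuron integrates its model (reference or CORDIC) under the common
#' stimulation current plus a synaptic term: each presynaptic spike injects
#' a current step `sign * weight * g` into its targets which then decays
#' exponentially with time constant `tau_syn`. The paper leaves the coupling
#' equation open, so this minimal event-driven exponential-current synapse
#' is a documented modeling choice; the neuron datapath itself remains
#' multiplier-free, the synaptic accumulator is kept in floating point and
#' quantized on injection. Deterministic given the network.
#'
#' @param net an `"hr_network"` from [build_random_network()].
#' @param params an [hr_params()] (its `I` is the common drive).
#' @param T duration in time units.
#' @param model `"reference"` or `"cordic"`.
#' @param g synaptic conductance scale (default 0.002, keeping the
#'   population spiking but non-saturated at I = 0.5).
#' @param tau_syn synaptic decay time constant (default 10 time units).
#' @param threshold,min_separation spike detection, as in [detect_spikes()].
#' @param control a [cordic_control()].
#' @return An `"hr_raster"`: list with `spikes` (per-neuron numeric spike
#'   time vectors), `duration`, `model`, `n`.
#' @export
simulate_network <- function(net, params, T, model = c("reference", "cordic"),
                             g = 0.002, tau_syn = 10,
                             threshold = 1, min_separation = 1,
                             control = cordic_control()) {
  model <- match.arg(model)
  n_steps <- as.integer(floor(T / params$dt))
  dt_shift <- if (model == "cordic") dt_shift_of(params$dt) else 0L
  spikes <- hr_network_sim_cpp(
    net$n, as.integer(net$edges$src) - 1L, as.integer(net$edges$dst) - 1L,
    as.numeric(net$sign), model == "cordic",
    params$I, params$r, params$dt, dt_shift, n_steps,
    g, tau_syn, net$weight, threshold, min_separation,
    params$x0, params$y0, params$z0,
    control$fmt$total_bits, control$fmt$frac_bits,
    control$n_iter, control$start_index, control$state_frac_bits)
  structure(list(spikes = spikes, duration = n_steps * params$dt,
                 model = model, n = net$n),
            class = "hr_raster")
}

#' @export
print.hr_raster <- function(x, ...) {
  counts <- lengths(x$spikes)
  cat(sprintf("<hr_raster: %d neurons, %g time units, %d spikes total (mean %.1f/neuron)>\n",
              x$n, x$duration, sum(counts), mean(counts)))
  invisible(x)
}

#' Random subset of a raster
#'
#' @param raster an `"hr_raster"`.
#' @param k number of neurons to keep (sampled uniformly without
#'   replacement).
#' @param seed RNG seed for the selection.
#' @return An `"hr_raster"` over the selected neurons, with attribute
#'   `neuron_id` giving their original indices.
#' @export
raster_subset <- function(raster, k, seed = 1L) {
  if (k > raster$n) stop("k must not exceed the number of neurons")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- sort(sample.int(raster$n, k))
  out <- structure(list(spikes = raster$spikes[idx], duration = raster$duration,
                        model = raster$model, n = k),
                   class = "hr_raster")
  attr(out, "neuron_id") <- idx
  out
}

#' Raster as a two-column table
#'
#' @param raster an `"hr_raster"`.
#' @return data.frame with columns `neuron_id`, `spike_time`.
#' @export
raster_table <- function(raster) {
  id <- attr(raster, "neuron_id")
  if (is.null(id)) id <- seq_len(raster$n)
  data.frame(neuron_id = rep(id, lengths(raster$spikes)),
             spike_time = unlist(raster$spikes, use.names = FALSE))
}
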