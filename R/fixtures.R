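# Synthetic fixtures with known ground truth, so every module is testable
# without external data.

#' Generate a synthetic PSP-amplitude train observation
#'
#' Produces the normalized PSP-amplitude train of a known Tsodyks synapse
#' driven at a fixed presynaptic rate (the exact release recursion),
#' optionally corrupted with multiplicative Gaussian noise, together with
#' the generating ground truth.
#'
#' @param stp list with `U`, `F`, `D` (the ground truth).
#' @param rate presynaptic rate, spikes/s.
#' @param n_spikes train length (>= 2; a single spike is unfittable).
#' @param noise_sigma SD of multiplicative Gaussian amplitude noise.
#' @param seed integer seed for the noise.
#' @param subtraction logical; whether the amplitudes are
#'   overlap-subtracted (exact recursion) values.
#' @param post_params,synapse_class used for onset-mode (non-subtracted)
#'   amplitudes; defaults to the packaged L2/3 Exc target and the
#'   intracortical excitatory class.
#' @return list of class `bc_psp_observation`: `presyn_rate`,
#'   `normalized_amplitudes`, `subtraction_applied`, `truth`, `seed`.
#' @export
make_psp_train_fixture <- function(stp, rate = 10, n_spikes = 10,
                                   noise_sigma = 0, seed = 1L,
                                   subtraction = TRUE,
                                   post_params = NULL,
                                   synapse_class = NULL) {
  if (n_spikes < 2) stop("n_spikes must be at least 2 (unfittable otherwise)")
  if (stp$U <= 0 || stp$U > 1 || stp$F < 0 || stp$D < 0)
    stop("invalid STP parameters")
  if (is.null(post_params) || is.null(synapse_class)) {
    cfg <- bc_config()
    pops <- build_population_table(cfg)
    if (is.null(post_params)) post_params <- as.list(pops["L2/3 Exc", ])
    if (is.null(synapse_class)) synapse_class <- get_synapse_class(cfg, "exc")
  }
  amps <- simulate_psp_train(stp, post_params, synapse_class, rate,
                             n_spikes, subtraction = subtraction)
  if (noise_sigma > 0) {
    set.seed(seed)
    amps <- amps * (1 + rnorm(n_spikes, 0, noise_sigma))
    amps <- amps / amps[1]
  }
  structure(list(presyn_rate = rate, normalized_amplitudes = amps,
                 subtraction_applied = subtraction, truth = stp,
                 noise_sigma = noise_sigma, seed = seed),
            class = "bc_psp_observation")
}

#' Build a miniature column network for fast end-to-end tests
#'
#' Scales every population down to at most `n_per_pop` neurons while
#' keeping the 13-population topology, and optionally overrides all
#' connection probabilities with a single value `p`.
#'
#' @param n_per_pop cap on neurons per population.
#' @param p optional uniform connection probability (fraction) replacing
#'   the assembled matrix; `NULL` keeps the configured probabilities.
#' @param seed build seed.
#' @param config base configuration.
#' @param ... passed on to [build_network()] (e.g. `stp = TRUE`).
#' @return a `bc_network`.
#' @export
make_toy_network_fixture <- function(n_per_pop = 20, p = NULL, seed = 1L,
                                     config = bc_config(), ...) {
  if (n_per_pop < 1) stop("n_per_pop must be at least 1")
  pops <- config$populations
  scale <- n_per_pop / max(pops$n_exc)
  pops$n_exc <- pmax(1L, as.integer(round(pops$n_exc * scale)))
  pops$n_inh <- pmax(3L, as.integer(round(pops$n_inh * scale)))
  config$populations <- pops
  if (!is.null(p)) {
    config$connectivity$p_exp <- p * 100
    config$connectivity$range_um <- NA_real_
  }
  build_network(config, seed = seed, ...)
}
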