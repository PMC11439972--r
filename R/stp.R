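# Short-term-plasticity calibration: PSP-train simulation, exhaustive
# grid-search fitting of Tsodyks (U, F, D) parameters, and synaptic weight
# scaling so that the STP model's steady state matches the static model.

# unit-PSC membrane response kernel (mV per pA), t in ms
psp_kernel <- function(t, params, tau_syn) {
  tm <- params$tau_m
  k <- tau_syn * tm / (params$c_m * (tm - tau_syn)) *
    (exp(-t / tm) - exp(-t / tau_syn))
  k[t < 0] <- 0
  k
}

#' Simulate a normalized PSP-amplitude train through an STP synapse
#'
#' A presynaptic neuron fires at a fixed rate onto a subthreshold
#' postsynaptic LIF neuron through a Tsodyks synapse; the PSP amplitude of
#' every response is measured and normalized to the first. With
#' `subtraction = TRUE` the overlapping tail of preceding PSPs is
#' subtracted before measuring (membrane linearity then makes the
#' amplitude exactly proportional to the released fraction `u_n x_n`);
#' without subtraction the amplitude is the peak minus the voltage at PSC
#' onset, so residual overlap enters the measurement.
#'
#' @param stp list with `U`, `F`, `D`.
#' @param post_params postsynaptic neuron parameters (`tau_m`, `c_m`, and
#'   `v_rest`, `v_th` for the subthreshold check).
#' @param synapse_class synapse class list (uses `tau_syn`, `psp_mean`).
#' @param presyn_rate presynaptic firing rate, spikes/s.
#' @param n_spikes number of presynaptic spikes (>= 2).
#' @param subtraction logical, see above.
#' @param variant STP relaxation variant, see [stp_spike_update()].
#' @return numeric vector of normalized amplitudes (first element 1).
#' @export
simulate_psp_train <- function(stp, post_params, synapse_class,
                               presyn_rate, n_spikes = 10,
                               subtraction = TRUE,
                               variant = "decay_to_zero") {
  if (presyn_rate <= 0) stop("presyn_rate must be positive")
  if (n_spikes < 2) stop("need at least two presynaptic spikes")
  isi <- 1000 / presyn_rate
  times <- (seq_len(n_spikes) - 1) * isi
  rel <- stp_release_sequence(stp, times, variant)
  w <- abs(psp_to_psc(synapse_class$psp_mean, post_params$c_m,
                      post_params$tau_m, synapse_class$tau_syn))
  # subthreshold check on the full superposed trace
  if (!is.null(post_params$v_th) && !is.null(post_params$v_rest)) {
    tg <- seq(0, times[n_spikes] + 5 * post_params$tau_m, by = 0.1)
    v <- superpose(tg, times, rel * w, post_params, synapse_class$tau_syn)
    if (max(v) + post_params$v_rest >= post_params$v_th)
      stop("postsynaptic neuron crosses threshold; use a smaller weight")
  }
  if (subtraction) return(rel / rel[1])
  amps <- onset_amplitudes(matrix(rel, 1), isi, post_params,
                           synapse_class$tau_syn)[1, ]
  amps / amps[1]
}

superpose <- function(t_grid, times, amps, params, tau_syn) {
  v <- numeric(length(t_grid))
  for (i in seq_along(times))
    v <- v + amps[i] * psp_kernel(t_grid - times[i], params, tau_syn)
  v
}

# Onset-mode PSP amplitudes for released-fraction sequences (rows of
# `rel`, one spike train per row, fixed ISI): peak of the superposed
# response in a post-spike search window minus the voltage at PSC onset.
onset_amplitudes <- function(rel, isi, params, tau_syn,
                             search_ms = min(isi, 25), dt = 0.1) {
  n <- ncol(rel)
  tau_j <- seq(dt, search_ms, by = dt)
  out <- matrix(NA_real_, nrow(rel), n)
  for (k in seq_len(n)) {
    lags_win <- (0:(k - 1)) * isi                 # lag of spikes k, k-1, ... 1
    H <- outer(lags_win, tau_j, function(l, tj) psp_kernel(l + tj, params, tau_syn))
    v_win <- rel[, k:1, drop = FALSE] %*% H       # trace in the window
    v_onset <- if (k == 1) 0 else
      rel[, (k - 1):1, drop = FALSE] %*% psp_kernel((1:(k - 1)) * isi, params, tau_syn)
    out[, k] <- apply(v_win, 1, max) - as.numeric(v_onset)
  }
  out
}

#' Fit Tsodyks STP parameters to an observed PSP-amplitude train
#'
#' Exhaustive grid search over U (0.05 to 1.0 in steps of 0.05) and F, D
#' (0 to 1000 ms in steps of 20 ms), minimizing the RMSE between simulated
#' and observed normalized PSP amplitudes. The simulated amplitudes honor
#' the observation's subtraction flag. Ties are broken deterministically:
#' smallest U, then smallest F, then smallest D.
#'
#' @param observation list with `presyn_rate` (spikes/s),
#'   `normalized_amplitudes` (first element 1) and `subtraction_applied`
#'   (logical); see [make_psp_train_fixture()].
#' @param post_params postsynaptic neuron parameters.
#' @param synapse_class synapse class (for the onset-mode membrane model).
#' @param u_grid,fd_grid optional scan-grid overrides.
#' @param variant STP relaxation variant.
#' @return list of class `bc_stp_fit` with `best` (`U`, `F`, `D`), `rmse`,
#'   and `grid_spec`.
#' @export
fit_stp_parameters <- function(observation, post_params = NULL,
                               synapse_class = NULL,
                               u_grid = seq(0.05, 1, by = 0.05),
                               fd_grid = seq(0, 1000, by = 20),
                               variant = "decay_to_zero") {
  obs <- observation$normalized_amplitudes
  if (is.null(obs) || length(obs) < 2) stop("observation must hold >= 2 amplitudes")
  rate <- observation$presyn_rate
  if (is.null(rate) || rate <= 0) stop("observation must state a positive rate")
  subtraction <- isTRUE(observation$subtraction_applied)
  isi <- 1000 / rate
  n <- length(obs)
  grid <- expand.grid(D = fd_grid, F = fd_grid, U = u_grid)[, c("U", "F", "D")]
  grid <- grid[order(grid$U, grid$F, grid$D), ]
  ef <- ifelse(grid$F > 0, exp(-isi / grid$F), 0)
  ed <- ifelse(grid$D > 0, exp(-isi / grid$D), 0)
  rel <- matrix(NA_real_, nrow(grid), n)
  u <- rep(0, nrow(grid)); x <- rep(1, nrow(grid))
  for (k in seq_len(n)) {
    if (k > 1) {
      u <- if (variant == "decay_to_zero") u * ef else grid$U + (u - grid$U) * ef
      x <- 1 - (1 - x) * ed
    }
    u <- u + grid$U * (1 - u)
    rel[, k] <- u * x
    x <- x * (1 - u)
  }
  sim <- if (subtraction) rel / rel[, 1] else {
    if (is.null(post_params) || is.null(synapse_class))
      stop("onset-mode fitting needs post_params and synapse_class")
    a <- onset_amplitudes(rel, isi, post_params, synapse_class$tau_syn)
    a / a[, 1]
  }
  rmse <- sqrt(rowMeans((sim - matrix(obs, nrow(sim), n, byrow = TRUE))^2))
  best <- which(rmse <= min(rmse) + 1e-12)[1]  # grid sorted by (U, F, D)
  structure(list(
    best = list(U = grid$U[best], F = grid$F[best], D = grid$D[best]),
    rmse = rmse[best],
    grid_spec = list(u_grid = u_grid, fd_grid = fd_grid),
    subtraction = subtraction), class = "bc_stp_fit")
}

#' @export
print.bc_stp_fit <- function(x, ...) {
  cat(sprintf("STP fit: U = %.2f, F = %g ms, D = %g ms (RMSE %.4g, %s mode)\n",
              x$best$U, x$best$F, x$best$D, x$rmse,
              if (x$subtraction) "subtraction" else "onset"))
  invisible(x)
}

#' Calibrate the weight scaling factor of one STP projection
#'
#' Finds the factor by which the static synaptic weight of an STP synapse
#' must be multiplied so that, with the presynaptic neuron firing at fixed
#' inter-spike intervals for 5 s (its resting rate in the static model),
#' the effective transmitted amplitude at the final presynaptic spike
#' deviates from the static target weight by less than 0.1 pA. Updates are
#' proportional (factor times target over observed). A presynaptic rate so
#' low that the window holds a single spike yields factor 1/U (first-spike
#' release).
#'
#' @param stp list with `U`, `F`, `D`; `NULL` means a static projection
#'   (factor 1, no calibration).
#' @param presyn_rate presynaptic resting rate, spikes/s.
#' @param target_psc target (static) PSC amplitude, pA.
#' @param window calibration simulation length, ms.
#' @param tol convergence tolerance on the final amplitude, pA.
#' @param max_iter iteration cap; non-convergence is flagged and the best
#'   iterate returned.
#' @param variant STP relaxation variant.
#' @return list of class `bc_weight_scaling`: `factor`, `converged`,
#'   `final_deviation` (pA), `iterations`.
#' @export
calibrate_weight_scaling <- function(stp, presyn_rate, target_psc,
                                     window = 5000, tol = 0.1,
                                     max_iter = 100,
                                     variant = "decay_to_zero") {
  if (is.null(stp))
    return(structure(list(factor = 1, converged = TRUE, final_deviation = 0,
                          iterations = 0L), class = "bc_weight_scaling"))
  times <- if (presyn_rate <= 0 || 1000 / presyn_rate > window) 0 else
    seq(0, window, by = 1000 / presyn_rate)
  rel_last <- stp_release_sequence(stp, times, variant)[length(times)]
  factor <- 1
  best <- list(factor = factor, dev = Inf)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    observed <- factor * abs(target_psc) * rel_last
    dev <- abs(observed - abs(target_psc))
    if (dev < best$dev) best <- list(factor = factor, dev = dev)
    if (dev < tol) { converged <- TRUE; break }
    factor <- factor * abs(target_psc) / observed
  }
  structure(list(factor = best$factor, converged = converged,
                 final_deviation = best$dev, iterations = it),
            class = "bc_weight_scaling")
}

#' Scale a thalamic STP weight so the first transmitted amplitude is preserved
#'
#' The thalamic input is transient, so its STP weights are not calibrated
#' against a steady state; instead the static weight `w` is divided by the
#' initial release probability so that the first transmitted amplitude of
#' the scaled synapse equals `w` exactly.
#'
#' @param w static weight, pA.
#' @param u_initial initial release probability (equals `U` under the
#'   default variant), in (0, 1].
#' @return scaled weight `w / u_initial`, pA.
#' @export
scale_thalamic_weight <- function(w, u_initial) {
  if (u_initial <= 0 || u_initial > 1) stop("u_initial must be in (0, 1]")
  w / u_initial
}

#' Calibrate weight scaling factors for all STP projections of a network
#'
#' For every recurrent projection that carries STP under the configured
#' parameter table, runs [calibrate_weight_scaling()] with the presynaptic
#' population's resting rate as measured in the static model. Because the
#' factors depend on measured rates, they inherit the seed of the
#' static-model run that produced `rates`.
#'
#' @param config model configuration.
#' @param rates named numeric vector of resting-state mean rates per
#'   population (names like `"L4 Exc"`), e.g. the `mean` column of
#'   [compute_population_rates()].
#' @param min_rate floor (spikes/s) applied to measured rates so silent
#'   populations calibrate on the single-spike limit.
#' @return data.frame of factors matched like the STP parameter table.
#' @export
calibrate_network_weights <- function(config, rates, min_rate = 0.1) {
  pm <- assemble_probability_matrix(config)
  pm <- pm[pm$source_type != "Exc_th" & pm$p > 0, ]
  rows <- list()
  for (i in seq_len(nrow(pm))) {
    pr <- pm[i, ]
    par <- lookup_stp(config$stp_params, pr$source_type, pr$target_type,
                      pr$source_layer, pr$target_layer)
    if (is.null(par)) next
    r <- rates[paste(pr$source_layer, pr$source_type)]
    r <- max(min_rate, if (is.na(r)) min_rate else r)
    cal <- calibrate_weight_scaling(par, r, target_psc = 1)
    rows[[length(rows) + 1]] <- data.frame(
      source_layer = pr$source_layer, source_type = pr$source_type,
      target_layer = pr$target_layer, target_type = pr$target_type,
      rate = r, factor = cal$factor, converged = cal$converged)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("bc_weight_factors", "data.frame")
  out
}
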