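# Single-neuron and single-synapse dynamics in R. These are the reference
# contracts of the fixed-step engine (exact exponential propagators,
# threshold/reset/refractoriness, and the Tsodyks short-term-plasticity
# recursion); the C++ engine applies the same updates network-wide.

#' One fixed-step LIF update
#'
#' Advances a LIF neuron state by one 0.1 ms step with exact exponential
#' propagators of
#' \deqn{dV/dt = -(V - V_{rest})/\tau_m + (I_{exc} + I_{inh})/C_m,}
#' \eqn{dI/dt = -I/\tau_{syn}} (2 ms excitatory, 4 ms inhibitory). PSC
#' amplitude increments delivered at this step add instantaneously to the
#' matching current class after decay. On reaching threshold a spike is
#' emitted, the potential is reset, and a 2.0 ms refractory clamp starts
#' during which V is held at `v_reset` while currents keep evolving.
#'
#' @param state list with `v` (mV), `i_exc`, `i_inh` (pA),
#'   `refr_remaining` (ms).
#' @param params list/row with `tau_m`, `c_m`, `v_rest`, `v_th`, `v_reset`,
#'   `tau_ref`.
#' @param dt step, ms (the simulation resolution).
#' @param input_exc,input_inh PSC amplitude increments (pA) delivered at
#'   this step.
#' @return the updated state, with an added logical `spike`.
#' @export
lif_update <- function(state, params, dt = SIM_RESOLUTION,
                       input_exc = 0, input_inh = 0) {
  tau_e <- 2; tau_i <- 4
  p11e <- exp(-dt / tau_e); p11i <- exp(-dt / tau_i)
  p22 <- exp(-dt / params$tau_m)
  p21e <- tau_e * params$tau_m / (params$c_m * (tau_e - params$tau_m)) * (p11e - p22)
  p21i <- tau_i * params$tau_m / (params$c_m * (tau_i - params$tau_m)) * (p11i - p22)
  spike <- FALSE
  if (state$refr_remaining > 0) {
    v <- params$v_reset
    state$refr_remaining <- max(0, state$refr_remaining - dt)
  } else {
    v <- params$v_rest + (state$v - params$v_rest) * p22 +
      state$i_exc * p21e + state$i_inh * p21i
  }
  state$i_exc <- state$i_exc * p11e + input_exc
  state$i_inh <- state$i_inh * p11i + input_inh
  if (state$refr_remaining == 0 && v >= params$v_th) {
    spike <- TRUE
    v <- params$v_reset
    state$refr_remaining <- params$tau_ref
  }
  state$v <- v
  state$spike <- spike
  state
}

#' Tsodyks short-term-plasticity update at a presynaptic spike
#'
#' Between spikes the release variable `u` relaxes (default variant:
#' exponentially toward 0 with time constant `F`; alternative variant:
#' toward `U`) and the resource variable `x` recovers toward 1 with time
#' constant `D`; `F = 0` or `D = 0` mean instantaneous relaxation. At the
#' spike, first the facilitation bump `u <- u + U(1 - u)` is applied, then
#' the effective amplitude `w_static * u * x` is released, then resources
#' deplete, `x <- x(1 - u)`. With the default variant the first spike of a
#' train transmits exactly `w_static * U`.
#'
#' @param stp state list with `u`, `x` (`u = 0`, `x = 1` before any spike).
#' @param params list with `U`, `F`, `D` (ms).
#' @param dt_since_last_spike time since the previous presynaptic spike,
#'   ms; `Inf` (or negative) for the first spike.
#' @param w_static static synaptic weight, pA.
#' @param variant `"decay_to_zero"` (default) or `"decay_to_U"`.
#' @return list with `amplitude` (pA) and the updated `state`.
#' @export
stp_spike_update <- function(stp, params, dt_since_last_spike, w_static,
                             variant = c("decay_to_zero", "decay_to_U")) {
  variant <- match.arg(variant)
  U <- params$U
  if (U <= 0 || U > 1) stop("U must be in (0, 1]")
  if (is.infinite(dt_since_last_spike) || dt_since_last_spike < 0) {
    u <- if (variant == "decay_to_zero") 0 else U
    x <- 1
  } else {
    ef <- if (params$F > 0) exp(-dt_since_last_spike / params$F) else 0
    ed <- if (params$D > 0) exp(-dt_since_last_spike / params$D) else 0
    u <- if (variant == "decay_to_zero") stp$u * ef else U + (stp$u - U) * ef
    x <- 1 - (1 - stp$x) * ed
  }
  u <- u + U * (1 - u)
  amplitude <- w_static * u * x
  x <- x * (1 - u)
  list(amplitude = amplitude, state = list(u = u, x = x))
}

# Effective released fractions (u_n * x_n) for a presynaptic spike train.
stp_release_sequence <- function(params, spike_times,
                                 variant = "decay_to_zero") {
  st <- list(u = 0, x = 1)
  out <- numeric(length(spike_times))
  last <- -Inf
  for (i in seq_along(spike_times)) {
    r <- stp_spike_update(st, params, spike_times[i] - last, 1, variant)
    out[i] <- r$amplitude
    st <- r$state
    last <- spike_times[i]
  }
  out
}

# Subthreshold membrane trace of one neuron receiving exponential PSC
# amplitude increments `amps` (pA) at `times` (ms), by exact propagators.
# Returns voltage deflection from rest on the step grid.
lif_trace <- function(params, times, amps, tau_syn, duration,
                      dt = SIM_RESOLUTION) {
  n <- ceiling(duration / dt)
  p11 <- exp(-dt / tau_syn)
  p22 <- exp(-dt / params$tau_m)
  p21 <- tau_syn * params$tau_m /
    (params$c_m * (tau_syn - params$tau_m)) * (p11 - p22)
  inc <- numeric(n + 1)
  k <- pmin(n + 1, floor(times / dt) + 1)
  for (i in seq_along(k)) inc[k[i]] <- inc[k[i]] + amps[i]
  v <- numeric(n + 1)
  cur <- inc[1]
  for (s in seq_len(n)) {
    v[s + 1] <- v[s] * p22 + cur * p21
    cur <- cur * p11 + inc[s + 1]
  }
  v
}
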