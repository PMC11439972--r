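# External inputs: background Poisson drive, cell-type-specific
# stimulation, and the transient thalamic (VPM) input population.

#' Generate explicit background Poisson spike trains
#'
#' One independent homogeneous Poisson source per neuron at its cell
#' type's background rate, delivered one-to-one with a fixed 0.5 mV EPSP
#' and 0.1 ms delay. The network engine draws an equivalent drive
#' internally during simulation; this explicit generator exists for
#' inspection and statistical testing of the contract.
#'
#' @param rates named vector of rates per cell type, spikes/s.
#' @param types character vector giving each neuron's cell type.
#' @param duration ms.
#' @param seed integer seed.
#' @return list of numeric spike-time vectors (ms), one per neuron.
#' @export
generate_background_input <- function(rates, types, duration, seed = 1L) {
  if (anyNA(rates[unique(types)]))
    stop("missing background rate for cell type(s): ",
         paste(setdiff(unique(types), names(rates)), collapse = ", "))
  set.seed(seed)
  lapply(types, function(ct) {
    r <- rates[[ct]] / 1000 # spikes per ms
    if (r <= 0) return(numeric())
    n_exp <- duration * r
    t <- cumsum(rexp(ceiling(n_exp + 6 * sqrt(n_exp) + 10), r))
    while (length(t) && t[length(t)] < duration)
      t <- c(t, t[length(t)] + cumsum(rexp(100, r)))
    t[t < duration]
  })
}

#' Define a cell-type-specific stimulation protocol
#'
#' An additional homogeneous Poisson input with a fixed EPSP amplitude is
#' applied to one population with an on/off schedule (default 1 s on, 1 s
#' off) repeated `repeats` times per rate level. The default nine levels
#' per cell type are 0 plus eight equally spaced levels up to the
#' cell-type maximum (1000 spikes/s for Exc and PV, 200 spikes/s for SOM
#' and VIP).
#'
#' @param target_population population label such as `"L2/3 SOM"`.
#' @param levels stimulation rates, spikes/s; must include 0.
#' @param on_duration,off_duration window lengths, ms.
#' @param repeats on-windows per level.
#' @param epsp stimulus EPSP amplitude, mV.
#' @return list of class `bc_protocol`.
#' @export
stimulus_protocol <- function(target_population,
                              levels = NULL,
                              on_duration = 1000, off_duration = 1000,
                              repeats = 20, epsp = 0.5) {
  type <- strsplit(target_population, " ")[[1]][2]
  if (is.null(levels)) {
    r_max <- if (type %in% c("Exc", "PV")) 1000 else 200
    levels <- seq(0, r_max, length.out = 9)
  }
  if (!any(levels == 0)) stop("levels must include 0")
  if (max(levels) > 1000) stop("levels must not exceed 1000 spikes/s")
  structure(list(target_population = target_population, levels = levels,
                 on_duration = on_duration, off_duration = off_duration,
                 repeats = repeats, epsp = epsp), class = "bc_protocol")
}

#' Build the gated stimulation input for a network run
#'
#' Expands a protocol into the engine's piecewise-constant rate schedule:
#' after `warmup` ms, each level (in the given order) runs `repeats`
#' on/off cycles; the stimulus is silent during off-windows and at the
#' zero level.
#'
#' @param protocol a [stimulus_protocol()].
#' @param network the [build_network()] result to stimulate.
#' @param warmup leading stimulus-free period, ms.
#' @return list with `engine` (engine input), `schedule` (data.frame of
#'   on-windows: `level`, `rep`, `t_on`, `t_off`) and `total_duration`.
#' @export
generate_stimulation_input <- function(protocol, network, warmup = 10000) {
  pop <- protocol$target_population
  if (!pop %in% rownames(network$populations))
    stop("no such population in the network: ", pop)
  i <- match(pop, rownames(network$populations))
  idx <- network$offset[[pop]] + seq_len(network$populations$n[i])
  tp <- network$populations[i, ]
  w <- psp_to_psc(protocol$epsp, tp$c_m, tp$tau_m, 2)
  breaks <- 0; rates <- 0; t <- warmup
  sched <- list()
  for (lv in protocol$levels) {
    for (r in seq_len(protocol$repeats)) {
      breaks <- c(breaks, t, t + protocol$on_duration)
      rates <- c(rates, lv, 0)
      sched[[length(sched) + 1]] <-
        data.frame(level = lv, rep = r, t_on = t, t_off = t + protocol$on_duration)
      t <- t + protocol$on_duration + protocol$off_duration
    }
  }
  list(engine = list(idx = as.integer(idx - 1L), w = rep(w, length(idx)),
                     breaks = as.integer(round(breaks / SIM_RESOLUTION)),
                     rates = rates / 1000),
       schedule = do.call(rbind, sched), total_duration = t)
}

# log-normal rate time course, t in ms, result in spikes/s
thalamic_rate <- function(t, pars) {
  r <- numeric(length(t))
  ok <- t > pars$t0
  dt <- t[ok] - pars$t0
  r[ok] <- pars$A * exp(-(log(dt) - pars$mu)^2 / (2 * pars$sigma^2)) / dt
  r
}

#' Fit a log-normal function to thalamic firing-rate samples
#'
#' Least-squares fit of
#' \deqn{r(t) = A \exp(-(\ln(t - t_0) - \mu)^2 / (2\sigma^2)) / (t - t_0)}
#' (zero for `t <= t0`) to `(t, rate)` samples, as used for the
#' touch-evoked VPM firing-rate time course.
#'
#' @param t sample times, ms.
#' @param rate sampled rates, spikes/s (>= 0).
#' @param start optional list of starting values (`A`, `t0`, `mu`,
#'   `sigma`).
#' @return list with the fitted parameters and `rss` (residual sum of
#'   squares).
#' @export
fit_thalamic_time_course <- function(t, rate, start = NULL) {
  if (length(t) < 4 || length(rate) != length(t))
    stop("need at least 4 (t, rate) samples")
  if (any(rate < 0)) stop("rates must be non-negative")
  if (all(rate == 0))
    return(list(A = 0, t0 = min(t), mu = 0, sigma = 1, rss = 0))
  if (is.null(start)) {
    tp <- t[which.max(rate)]
    start <- list(A = max(rate) * tp, t0 = max(0, min(t[rate > 0]) - 1),
                  mu = log(max(tp, 0.5)), sigma = 0.6)
  }
  obj <- function(p) {
    pars <- list(A = exp(p[1]), t0 = p[2], mu = p[3], sigma = exp(p[4]))
    if (pars$t0 >= min(t[rate > 0])) return(1e12)
    sum((thalamic_rate(t, pars) - rate)^2)
  }
  p0 <- c(log(start$A), start$t0, start$mu, log(start$sigma))
  fit <- nlminb(p0, obj, control = list(iter.max = 2000, eval.max = 4000,
                                        rel.tol = 1e-14, x.tol = 1e-12))
  # polish from the first optimum (the surface is mildly ill-conditioned)
  fit <- nlminb(fit$par, obj, control = list(iter.max = 2000,
                                             rel.tol = 1e-14, x.tol = 1e-12))
  p <- fit$par
  list(A = exp(p[1]), t0 = p[2], mu = p[3], sigma = exp(p[4]),
       rss = fit$objective)
}

#' Thalamic input specification
#'
#' Sizes the thalamic (VPM barreloid) population from the cortical neuron
#' count and assembles the stimulation schedule: the rate profile is
#' replayed at every stimulus onset as independent inhomogeneous Poisson
#' trains in all thalamic neurons.
#'
#' @param config model configuration.
#' @param repeats number of stimuli.
#' @param inter_stimulus_interval ms between stimulus onsets.
#' @param first_onset time of the first onset, ms.
#' @param time_factor horizontal stretch of the rate profile
#'   (`f'(t) = f(t / time_factor)`), applied to Exc targets' drive in the
#'   response-time scans; the profile itself is shared.
#' @return list of class `bc_thalamic_spec` (includes `n_th`).
#' @export
thalamic_input_spec <- function(config = bc_config(), repeats = 10,
                                inter_stimulus_interval = 1000,
                                first_onset = 10000, time_factor = 1) {
  pops <- build_population_table(config)
  n_th <- config$thalamic_doubling * round(sum(pops$n) / config$s1_vpm_ratio)
  pars <- as.list(stats::setNames(config$thalamic_profile$value,
                                  config$thalamic_profile$param))
  structure(list(n_th = n_th, profile = pars, repeats = repeats,
                 inter_stimulus_interval = inter_stimulus_interval,
                 first_onset = first_onset, time_factor = time_factor),
            class = "bc_thalamic_spec")
}

#' Generate thalamic spike trains (inhomogeneous Poisson by thinning)
#'
#' Each thalamic neuron draws an independent inhomogeneous Poisson
#' realization of the shared rate profile at every stimulus repeat
#' (thinning against the profile maximum on the 0.1 ms grid).
#'
#' @param spec a [thalamic_input_spec()].
#' @param seed integer seed.
#' @return list of numeric spike-time vectors (ms), one per thalamic
#'   neuron, with the onset times as attribute `onsets`.
#' @export
generate_thalamic_spikes <- function(spec, seed = 1L) {
  set.seed(seed)
  tf <- spec$time_factor
  prof <- function(t) thalamic_rate(t / tf, spec$profile) # spikes/s
  onsets <- spec$first_onset +
    (seq_len(spec$repeats) - 1) * spec$inter_stimulus_interval
  span <- min(spec$inter_stimulus_interval, 400 * tf) # profile support, ms
  tg <- seq(0, span, by = SIM_RESOLUTION)
  rmax <- max(prof(tg))
  trains <- vector("list", spec$n_th)
  for (i in seq_len(spec$n_th)) {
    tt <- numeric()
    if (rmax > 0) {
      for (on in onsets) {
        n_cand <- stats::rpois(1, rmax / 1000 * span)
        cand <- sort(runif(n_cand, 0, span))
        keep <- runif(n_cand) < prof(cand) / rmax
        tt <- c(tt, on + cand[keep])
      }
    }
    trains[[i]] <- tt
  }
  attr(trains, "onsets") <- onsets
  trains
}

#' Build thalamic projections onto the cortical network
#'
#' Thalamic neurons target Exc and PV cells in all layers; SOM cells only
#' in L4 at the configured attenuation (50%) of probability and weight;
#' VIP cells are never targeted. EPSPs are log-normal (0.49 +/- 0.13 mV;
#' half for SOM), delays log-normal (1.72 +/- 0.73 ms). With `stp = TRUE`
#' the fitted thalamic STP parameters are attached and weights are
#' initial-release scaled (`w / u`).
#'
#' @param spec a [thalamic_input_spec()].
#' @param network the target [build_network()].
#' @param seed integer seed for connectivity and weight draws.
#' @param weight_factor,delay_factor scaling factors for the thalamic
#'   synaptic weights onto Exc cells and for all thalamic delays
#'   (response-time scans).
#' @return list with `engine` (replay input for [simulate_network()]),
#'   `onsets`, and the projection bookkeeping table.
#' @export
attach_thalamic_input <- function(spec, network, seed = 1L,
                                  weight_factor = 1, delay_factor = 1) {
  config <- network$config
  pm <- network$projection_matrix
  th <- pm[pm$source_type == "Exc_th", ]
  if (any(th$target_type == "VIP"))
    stop("thalamic input must not target VIP cells")
  trains <- generate_thalamic_spikes(spec, seed = seed)
  set.seed(seed + 1L)
  pops <- network$populations
  pre_l <- list(); post_l <- list(); w_l <- list(); d_l <- list(); id_l <- list()
  stp_sets <- list(); stp_key <- character()
  rows <- list()
  for (i in seq_len(nrow(th))) {
    pr <- th[i, ]
    tkey <- paste(pr$target_layer, pr$target_type)
    nt <- pops[tkey, "n"]
    conn <- sample_connections(pr$p, spec$n_th, nt)
    if (!nrow(conn)) next
    cls <- get_synapse_class(config,
                             if (pr$target_type == "SOM") "th_som" else "th")
    par <- draw_synaptic_parameters(cls, pops[tkey, ], nrow(conn))
    w <- par$w
    if (pr$target_type == "Exc") w <- w * weight_factor
    d <- pmax(1, round(par$d * delay_factor / SIM_RESOLUTION))
    sid <- -1L
    if (network$stp) {
      stp_par <- lookup_stp(config$stp_params, "Exc_th", pr$target_type)
      if (!is.null(stp_par)) {
        w <- scale_thalamic_weight(w, stp_par$U)
        k <- paste(stp_par$U, stp_par$F, stp_par$D)
        j <- match(k, stp_key)
        if (is.na(j)) {
          stp_sets[[length(stp_sets) + 1]] <- stp_par
          stp_key <- c(stp_key, k)
          j <- length(stp_sets)
        }
        sid <- as.integer(j - 1L)
      }
    }
    k <- length(pre_l) + 1L
    pre_l[[k]] <- conn$pre
    post_l[[k]] <- network$offset[[tkey]] + conn$post
    w_l[[k]] <- w
    d_l[[k]] <- as.integer(d)
    id_l[[k]] <- rep(sid, nrow(conn))
    rows[[k]] <- data.frame(target = tkey, p = pr$p, n_syn = nrow(conn))
  }
  pre <- unlist(pre_l)
  ord <- order(pre)
  steps <- lapply(trains, function(tt) as.integer(round(tt / SIM_RESOLUTION)))
  engine <- list(
    spike_ptr = c(0L, cumsum(lengths(steps))),
    spike_steps = unlist(steps),
    src_ptr = c(0L, cumsum(tabulate(pre[ord], nbins = spec$n_th))),
    tgt = as.integer(unlist(post_l)[ord] - 1L),
    w = unlist(w_l)[ord],
    delay_steps = unlist(d_l)[ord],
    stp_id = unlist(id_l)[ord],
    stp_U = vapply(stp_sets, `[[`, 0, "U"),
    stp_F = vapply(stp_sets, `[[`, 0, "F"),
    stp_D = vapply(stp_sets, `[[`, 0, "D"))
  if (!length(engine$spike_steps)) engine$spike_steps <- integer()
  list(engine = engine, onsets = attr(trains, "onsets"),
       projections = do.call(rbind, rows))
}
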