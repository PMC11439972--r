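# Network construction: instantiate populations, synapses, background
# drive and (optionally) short-term plasticity from a configuration.

# Resolve STP parameters for a projection, or NULL if it is static.
# Layer-specific rows take precedence over layer-generic (NA) rows.
lookup_stp <- function(stp_tab, source_type, target_type,
                       source_layer = NA, target_layer = NA) {
  m <- stp_tab[stp_tab$source_type == source_type &
               stp_tab$target_type == target_type, , drop = FALSE]
  if (!nrow(m)) return(NULL)
  spec <- m[!is.na(m$source_layer) & m$source_layer == source_layer &
            !is.na(m$target_layer) & m$target_layer == target_layer, ,
            drop = FALSE]
  generic <- m[is.na(m$source_layer), , drop = FALSE]
  r <- if (nrow(spec)) spec[1, ] else if (nrow(generic)) generic[1, ] else NULL
  if (is.null(r)) return(NULL)
  list(U = r$U, F = r$F, D = r$D)
}

#' Build a column network ready for simulation
#'
#' Instantiates the 13 cortical populations, samples all intracortical
#' synapses (pairwise Bernoulli, log-normal weights and delays), attaches
#' the cell-type-specific background drive, and optionally equips
#' projections with Tsodyks short-term plasticity (STP).
#'
#' @param config model configuration, see [bc_config()].
#' @param seed integer seed for connectivity realization and initial
#'   membrane potentials.
#' @param stp logical; build the STP variant (Base-STP) instead of the
#'   static-synapse variant (Base).
#' @param weight_factors optional data.frame (`source_type`, `target_type`,
#'   `source_layer`, `target_layer`, `factor`) of STP weight scaling
#'   factors as produced by [calibrate_network_weights()]; matched like the
#'   STP parameter table. Unmatched STP projections keep factor 1.
#' @param stp_exclude optional data.frame (`source_type`, `target_type`)
#'   of projections whose STP is excluded (kept static), for ablation runs.
#' @param p_overrides optional data.frame (`source_layer`, `source_type`,
#'   `target_layer`, `target_type`, `factor`) multiplying selected
#'   connection probabilities (e.g. 50% SOM->PV).
#' @param w_scale optional data.frame (`source_type`, `target_layer`,
#'   `target_type`, `factor`) multiplying synaptic weights of matching
#'   recurrent projections (used by the thalamic-response scans).
#' @param remove one of "none", "intralaminar", "interlaminar": drop the
#'   matching recurrent connections (ablation variants).
#' @param size_factor integer scaling of all population sizes; probabilities
#'   are re-integrated for a footprint scaled by the same factor in area
#'   (the "double-sized" variant uses 2).
#' @return an object of class `bc_network`.
#' @export
build_network <- function(config = bc_config(), seed = 1L, stp = FALSE,
                          weight_factors = NULL, stp_exclude = NULL,
                          p_overrides = NULL, w_scale = NULL,
                          remove = c("none", "intralaminar", "interlaminar"),
                          size_factor = 1L) {
  remove <- match.arg(remove)
  set.seed(seed)
  pops <- build_population_table(config)
  if (size_factor != 1L) {
    pops$n <- as.integer(round(pops$n * size_factor))
    config$surface_x <- config$surface_x * sqrt(size_factor)
    config$surface_y <- config$surface_y * sqrt(size_factor)
  }
  n_total <- sum(pops$n)
  offset <- c(0L, cumsum(pops$n))[seq_len(nrow(pops))]
  names(offset) <- rownames(pops)
  pm <- assemble_probability_matrix(config)

  # per-neuron parameter vectors
  idx <- rep(seq_len(nrow(pops)), pops$n)
  neurons <- list(
    tau_m = pops$tau_m[idx], c_m = pops$c_m[idx],
    v_rest = pops$v_rest[idx], v_th = pops$v_th[idx],
    v_reset = pops$v_reset[idx],
    ref_steps = as.integer(round(pops$tau_ref[idx] / SIM_RESOLUTION)))
  neurons$v0 <- if (identical(config$v_init, "uniform"))
    runif(n_total, neurons$v_rest, neurons$v_th) else neurons$v_rest

  cortical <- pm[pm$source_type != "Exc_th", ]
  if (!is.null(p_overrides)) {
    for (i in seq_len(nrow(p_overrides))) {
      o <- p_overrides[i, ]
      hit <- cortical$source_layer == o$source_layer &
        cortical$source_type == o$source_type &
        cortical$target_layer == o$target_layer &
        cortical$target_type == o$target_type
      cortical$p[hit] <- cortical$p[hit] * o$factor
    }
  }
  if (remove == "intralaminar")
    cortical$p[cortical$source_layer == cortical$target_layer] <- 0
  if (remove == "interlaminar")
    cortical$p[cortical$source_layer != cortical$target_layer] <- 0

  # synapse lists per projection
  stp_sets <- list()
  stp_key <- character()
  get_stp_id <- function(par) {
    if (is.null(par)) return(-1L)
    k <- paste(par$U, par$F, par$D)
    i <- match(k, stp_key)
    if (is.na(i)) {
      stp_sets[[length(stp_sets) + 1]] <<- par
      stp_key <<- c(stp_key, k)
      i <- length(stp_sets)
    }
    as.integer(i - 1L)
  }
  pre_l <- list(); post_l <- list(); w_l <- list(); d_l <- list(); id_l <- list()
  proj_rows <- list()
  for (i in seq_len(nrow(cortical))) {
    pr <- cortical[i, ]
    if (pr$p <= 0) next
    skey <- paste(pr$source_layer, pr$source_type)
    tkey <- paste(pr$target_layer, pr$target_type)
    ns <- pops[skey, "n"]; nt <- pops[tkey, "n"]
    conn <- sample_connections(pr$p, ns, nt,
                               same_population = identical(skey, tkey))
    if (!nrow(conn)) next
    cls <- get_synapse_class(config, if (pr$source_type == "Exc") "exc" else "inh")
    tp <- pops[tkey, ]
    par <- draw_synaptic_parameters(cls, tp, nrow(conn))
    w <- par$w
    if (!is.null(w_scale)) {
      for (j in seq_len(nrow(w_scale))) {
        o <- w_scale[j, ]
        if (pr$source_type == o$source_type &&
            pr$target_layer == o$target_layer &&
            pr$target_type == o$target_type)
          w <- w * o$factor
      }
    }
    stp_par <- NULL
    if (stp) {
      excluded <- !is.null(stp_exclude) &&
        any(stp_exclude$source_type == pr$source_type &
            stp_exclude$target_type == pr$target_type)
      if (!excluded)
        stp_par <- lookup_stp(config$stp_params, pr$source_type,
                              pr$target_type, pr$source_layer, pr$target_layer)
      if (!is.null(stp_par) && !is.null(weight_factors)) {
        wf <- weight_factors
        hit <- wf$source_type == pr$source_type &
          wf$target_type == pr$target_type &
          (is.na(wf$source_layer) | wf$source_layer == pr$source_layer) &
          (is.na(wf$target_layer) | wf$target_layer == pr$target_layer)
        if (any(hit)) w <- w * wf$factor[which(hit)[1]]
      }
    }
    sid <- get_stp_id(stp_par)
    k <- length(pre_l) + 1L
    pre_l[[k]] <- offset[[skey]] + conn$pre
    post_l[[k]] <- offset[[tkey]] + conn$post
    w_l[[k]] <- w
    d_l[[k]] <- as.integer(round(par$d / SIM_RESOLUTION))
    id_l[[k]] <- rep(sid, nrow(conn))
    proj_rows[[k]] <- data.frame(pr[, c("source_layer", "source_type",
                                        "target_layer", "target_type", "p")],
                                 n_syn = nrow(conn), stp = !is.null(stp_par))
  }
  pre <- as.integer(unlist(pre_l)); post <- as.integer(unlist(post_l))
  ord <- order(pre)
  syn <- list(
    src_ptr = c(0L, cumsum(tabulate(pre, nbins = n_total))),
    tgt = as.integer(post[ord] - 1L),
    w = as.numeric(unlist(w_l))[ord],
    delay_steps = as.integer(unlist(d_l))[ord],
    stp_id = as.integer(unlist(id_l))[ord],
    stp_U = vapply(stp_sets, `[[`, 0, "U"),
    stp_F = vapply(stp_sets, `[[`, 0, "F"),
    stp_D = vapply(stp_sets, `[[`, 0, "D"))

  # background drive: one independent Poisson source per neuron
  br <- config$background_rates
  rate_col <- if (stp) "r_bg_stp" else "r_bg_static"
  bg_rate_type <- stats::setNames(br[[rate_col]], br$type)
  if (anyNA(bg_rate_type[CELL_TYPES])) stop("missing background rate for a cell type")
  bg_cls <- get_synapse_class(config, "bg")
  background <- list(
    rate = as.numeric(bg_rate_type[pops$type[idx]]) / 1000, # spikes per ms
    w = psp_to_psc(bg_cls$psp_mean, neurons$c_m, neurons$tau_m, bg_cls$tau_syn),
    delay_steps = as.integer(round(bg_cls$delay_mean / SIM_RESOLUTION)))

  structure(list(
    config = config, seed = seed, stp = stp, populations = pops,
    offset = offset, n_total = n_total, neurons = neurons, synapses = syn,
    background = background, projection_matrix = pm,
    projections = do.call(rbind, proj_rows),
    pop_of_neuron = factor(rownames(pops)[idx], levels = rownames(pops)),
    stp_variant = config$stp_variant), class = "bc_network")
}

#' @export
print.bc_network <- function(x, ...) {
  cat("barrelsim network (", if (x$stp) "STP" else "static",
      " synapses)\n", sep = "")
  cat(" ", x$n_total, "neurons in", nrow(x$populations), "populations;",
      length(x$synapses$tgt), "synapses in", nrow(x$projections),
      "realized projections\n")
  cat("  built with seed", x$seed, "\n")
  invisible(x)
}

#' @export
summary.bc_network <- function(object, ...) {
  print(object)
  cat("\nPopulations:\n")
  print.data.frame(object$populations[, c("layer", "type", "n", "tau_m",
                                          "c_m", "v_rest", "v_th")])
  invisible(object)
}

empty_replay <- function() {
  list(spike_ptr = integer(), spike_steps = integer(), src_ptr = 0L,
       tgt = integer(), delay_steps = integer(), stp_id = integer(),
       w = numeric(), stp_U = numeric(), stp_F = numeric(), stp_D = numeric())
}

empty_stimulus <- function() {
  list(idx = integer(), w = numeric(), breaks = integer(), rates = numeric())
}

#' Simulate a built network
#'
#' Runs the fixed-step (0.1 ms) engine: exact-propagator LIF updates,
#' event-driven synaptic delivery with per-synapse delays and optional
#' Tsodyks short-term plasticity, per-neuron Poisson background input and,
#' if supplied, a gated stimulation input and replayed thalamic sources.
#' Given identical network, inputs and `seed` the spike output is bitwise
#' reproducible.
#'
#' @param network a [build_network()] result.
#' @param duration simulated time, ms.
#' @param seed integer seed for the input randomness of this run.
#' @param stimulus optional stimulation input from
#'   [generate_stimulation_input()].
#' @param thalamic optional thalamic input from [attach_thalamic_input()].
#' @param record_v optional integer vector of neuron indices (1-based)
#'   whose membrane potential is recorded every step.
#' @return an object of class `bc_spikes`: data.frame with `id` (neuron)
#'   and `t` (spike time, ms), with the population labels, recording
#'   window and any voltage traces as attributes.
#' @export
simulate_network <- function(network, duration, seed = 1L, stimulus = NULL,
                             thalamic = NULL, record_v = NULL) {
  if (duration <= 0) stop("duration must be positive")
  n_steps <- as.integer(round(duration / SIM_RESOLUTION))
  stim <- if (is.null(stimulus)) empty_stimulus() else stimulus$engine
  replay <- if (is.null(thalamic)) empty_replay() else thalamic$engine
  res <- .bc_engine(network$neurons, network$synapses, network$background,
                    stim, replay, n_steps, SIM_RESOLUTION, as.double(seed),
                    if (is.null(record_v)) integer() else as.integer(record_v - 1L),
                    if (identical(network$stp_variant, "decay_to_U")) 1L else 0L)
  out <- data.frame(id = res$id, t = res$step * SIM_RESOLUTION)
  attr(out, "pop") <- network$pop_of_neuron
  attr(out, "window") <- c(0, duration)
  attr(out, "n_total") <- network$n_total
  if (!is.null(record_v)) attr(out, "v") <- res$v
  class(out) <- c("bc_spikes", "data.frame")
  out
}

#' @export
print.bc_spikes <- function(x, ...) {
  w <- attr(x, "window")
  cat("Spike trains:", nrow(x), "spikes from", attr(x, "n_total"),
      "neurons over", diff(w), "ms\n")
  invisible(x)
}

#' @export
summary.bc_spikes <- function(object, ...) {
  print(object)
  print(compute_population_rates(object))
  invisible(object)
}

#' Raster plot of a spike-train set
#'
#' @param x a `bc_spikes` object.
#' @param max_points subsample cap on plotted spikes.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bc_spikes <- function(x, max_points = 2e5, ...) {
  k <- if (nrow(x) > max_points) sort(sample.int(nrow(x), max_points)) else
    seq_len(nrow(x))
  graphics::plot(x$t[k], x$id[k], pch = ".", xlab = "time (ms)",
                 ylab = "neuron", ...)
  invisible(x)
}
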