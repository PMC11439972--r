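# Protocol orchestration: resting state, cell-type-specific stimulation,
# and thalamic stimulation with the published model variants expressed as
# configuration changes (STP exclusions, background-rate offsets,
# connection-probability overrides, connection removals, double size,
# thalamic scan factors).

#' Run configuration for the simulation protocols
#'
#' Bundles the model variant and the reproducibility/ablation settings
#' shared by all protocols. Instance `i` of a run derives its seeds
#' deterministically from `seed_base`.
#'
#' @param variant `"Base"` (static synapses) or `"Base-STP"`.
#' @param n_instances number of simulation instances.
#' @param seed_base base seed.
#' @param warmup initial transient excluded from analysis, ms.
#' @param r_bg_offsets named vector of additive background-rate changes
#'   per cell type, spikes/s (e.g. `c(SOM = -200)`).
#' @param stp_exclude data.frame (`source_type`, `target_type`) of
#'   projections whose STP is excluded (Base-STP ablations).
#' @param p_overrides data.frame of connection-probability multipliers,
#'   see [build_network()].
#' @param w_scale data.frame of recurrent weight multipliers (thalamic
#'   response scans), see [build_network()].
#' @param remove `"none"`, `"intralaminar"` or `"interlaminar"` connection
#'   removal.
#' @param size_factor population-size scaling (2 = double-sized variant).
#' @param weight_factors STP weight-scaling factors, see
#'   [build_network()]; required for meaningful Base-STP runs.
#' @param config base model configuration.
#' @return list of class `bc_run_config`.
#' @export
run_config <- function(variant = c("Base", "Base-STP"), n_instances = 20,
                       seed_base = 1L, warmup = 10000,
                       r_bg_offsets = NULL, stp_exclude = NULL,
                       p_overrides = NULL, w_scale = NULL,
                       remove = "none", size_factor = 1L,
                       weight_factors = NULL, config = bc_config()) {
  variant <- match.arg(variant)
  if (!is.null(r_bg_offsets)) {
    br <- config$background_rates
    col <- if (variant == "Base-STP") "r_bg_stp" else "r_bg_static"
    i <- match(names(r_bg_offsets), br$type)
    if (anyNA(i)) stop("unknown cell type in r_bg_offsets")
    br[[col]][i] <- br[[col]][i] + r_bg_offsets
    config$background_rates <- br
  }
  structure(list(variant = variant, stp = variant == "Base-STP",
                 n_instances = n_instances, seed_base = seed_base,
                 warmup = warmup, stp_exclude = stp_exclude,
                 p_overrides = p_overrides, w_scale = w_scale,
                 remove = remove, size_factor = size_factor,
                 weight_factors = weight_factors, config = config),
            class = "bc_run_config")
}

build_from_run_config <- function(rc, instance) {
  build_network(rc$config, seed = rc$seed_base + instance, stp = rc$stp,
                weight_factors = rc$weight_factors,
                stp_exclude = rc$stp_exclude, p_overrides = rc$p_overrides,
                w_scale = rc$w_scale, remove = rc$remove,
                size_factor = rc$size_factor)
}

#' Simulate the resting state and its activity statistics
#'
#' Background input only. Each instance simulates `duration` ms; rates,
#' pairwise spike-count correlations and CV ISI are computed on the
#' post-warmup window and averaged across instances.
#'
#' @param rc a [run_config()].
#' @param duration simulated time per instance, ms.
#' @return list of class `bc_resting_state`: `rates` (population table
#'   averaged over instances), `ai` (per-layer mean correlation and CV
#'   ISI with the configured criteria bounds), `per_instance` details.
#' @export
run_resting_state <- function(rc = run_config(), duration = 15000) {
  if (duration <= rc$warmup)
    stop("duration must exceed the warmup period")
  win <- c(rc$warmup, duration)
  rates_acc <- NULL
  ai_rows <- list()
  inst_rates <- list()
  for (i in seq_len(rc$n_instances)) {
    net <- build_from_run_config(rc, i)
    sp <- simulate_network(net, duration, seed = rc$seed_base + 1000L + i)
    r <- compute_population_rates(sp, win)
    inst_rates[[i]] <- stats::setNames(r$mean, r$population)
    rates_acc <- if (is.null(rates_acc)) r[, -1] else rates_acc + r[, -1]
    ai_rows[[i]] <- do.call(rbind, lapply(LAYERS, function(l) {
      data.frame(instance = i, layer = l,
                 correlation = compute_pairwise_correlation(
                   sp, l, win, seed = rc$seed_base + i)$mean_correlation,
                 cv_isi = compute_cv_isi(
                   sp, l, win, seed = rc$seed_base + 7000L + i)$mean_cv)
    }))
  }
  rates <- cbind(population = rownames(rates_acc), rates_acc / rc$n_instances)
  ai_all <- do.call(rbind, ai_rows)
  ai <- do.call(rbind, lapply(LAYERS, function(l) {
    a <- ai_all[ai_all$layer == l, ]
    data.frame(layer = l, correlation = mean(a$correlation, na.rm = TRUE),
               cv_isi = mean(a$cv_isi, na.rm = TRUE))
  }))
  crit <- stats::setNames(rc$config$ai_criteria$value,
                          rc$config$ai_criteria$criterion)
  ai$corr_in_awake_range <- ai$correlation >= crit["corr_awake_min"] &
    ai$correlation <= crit["corr_awake_max"]
  ai$cv_between_states <- ai$cv_isi >= crit["cv_isi_anesth_up"] &
    ai$cv_isi <= crit["cv_isi_awake_max"]
  structure(list(rates = rates, ai = ai, per_instance = inst_rates,
                 ai_per_instance = ai_all, variant = rc$variant),
            class = "bc_resting_state")
}

#' @export
print.bc_resting_state <- function(x, ...) {
  cat("Resting state (", x$variant, "), mean rates (spikes/s):\n", sep = "")
  print.data.frame(x$rates[, c("population", "mean", "sd", "median")],
                   row.names = FALSE, digits = 3)
  cat("\nAI statistics:\n")
  print.data.frame(x$ai, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the cell-type-specific stimulation protocol
#'
#' Applies the gated Poisson stimulus to one population and evaluates the
#' normalized responses of all same-layer populations: per instance,
#' rates over the last `eval_ms` of every on-window are averaged over
#' repeats, normalized to the zero level, and tested against 1
#' ([normalize_responses_and_test()]).
#'
#' @param rc a [run_config()].
#' @param protocol a [stimulus_protocol()].
#' @param eval_ms evaluated tail of each on-window, ms.
#' @return list of class `bc_stimulation`: `responses` (per observed
#'   population, a `bc_response` table), `protocol`, `variant`.
#' @export
run_cell_type_stimulation <- function(rc = run_config(), protocol,
                                      eval_ms = 500) {
  layer <- strsplit(protocol$target_population, " ")[[1]][1]
  obs_pops <- NULL
  inst_rates <- list() # instance -> population x level matrix
  for (i in seq_len(rc$n_instances)) {
    net <- build_from_run_config(rc, i)
    if (is.null(obs_pops))
      obs_pops <- rownames(net$populations)[net$populations$layer == layer]
    stim <- generate_stimulation_input(protocol, net, warmup = rc$warmup)
    sp <- simulate_network(net, stim$total_duration,
                           seed = rc$seed_base + 1000L + i, stimulus = stim)
    pop <- attr(sp, "pop")
    n_of <- stats::setNames(net$populations$n, rownames(net$populations))
    sched <- stim$schedule
    m <- matrix(NA_real_, length(obs_pops), length(protocol$levels),
                dimnames = list(obs_pops, protocol$levels))
    for (p in obs_pops) {
      sel <- sp$id %in% which(pop == p)
      tt <- sp$t[sel]
      for (j in seq_along(protocol$levels)) {
        wnd <- sched[sched$level == protocol$levels[j], ]
        cnt <- sum(vapply(seq_len(nrow(wnd)), function(k) {
          sum(tt >= wnd$t_off[k] - eval_ms & tt < wnd$t_off[k])
        }, numeric(1)))
        m[p, j] <- cnt / (nrow(wnd) * eval_ms / 1000) / n_of[[p]]
      }
    }
    inst_rates[[i]] <- m
  }
  responses <- lapply(obs_pops, function(p) {
    rr <- matrix(t(vapply(inst_rates, function(m) m[p, ],
                          numeric(length(protocol$levels)))),
                 ncol = length(protocol$levels))
    # populations too silent to normalize (baseline 0 in almost all
    # instances) are reported as NULL rather than aborting the run
    tryCatch(normalize_responses_and_test(rr, protocol$levels),
             error = function(e) NULL)
  })
  names(responses) <- obs_pops
  responses <- Filter(Negate(is.null), responses)
  structure(list(responses = responses, protocol = protocol,
                 variant = rc$variant, per_instance = inst_rates),
            class = "bc_stimulation")
}

#' @export
print.bc_stimulation <- function(x, ...) {
  cat("Stimulation of ", x$protocol$target_population, " (", x$variant,
      "); response at the top level:\n", sep = "")
  top <- do.call(rbind, lapply(names(x$responses), function(p) {
    r <- x$responses[[p]]
    r <- r[nrow(r), ]
    data.frame(population = p, level = r$level, r_norm = r$r_norm,
               pct_change = r$pct_change, p_value = r$p_value)
  }))
  print.data.frame(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the thalamic stimulation protocol
#'
#' Attaches the transient thalamic input (repeated every second) and
#' computes per-population PSTHs with peak extraction, plus peak RMSEs
#' against the configured reference table. Scan factors stretch the input
#' time course (`time_factor`), scale thalamic weights onto Exc cells
#' (`weight_factor`) and all thalamic delays (`delay_factor`); recurrent
#' weight scaling onto L2/3 targets is passed through `rc$w_scale`.
#'
#' @param rc a [run_config()].
#' @param repeats stimuli per instance.
#' @param duration simulated time per instance, ms.
#' @param time_factor,weight_factor,delay_factor thalamic scan factors.
#' @return list of class `bc_thalamic_run`: `peaks` (population peak
#'   table averaged over instances), `rmse`, `psth` (averaged PSTHs).
#' @export
run_thalamic_protocol <- function(rc = run_config(), repeats = 10,
                                  duration = 20000, time_factor = 1,
                                  weight_factor = 1, delay_factor = 1) {
  spec <- thalamic_input_spec(rc$config, repeats = repeats,
                              first_onset = rc$warmup,
                              time_factor = time_factor)
  peaks_acc <- NULL; psth_acc <- NULL
  for (i in seq_len(rc$n_instances)) {
    net <- build_from_run_config(rc, i)
    th <- attach_thalamic_input(spec, net, seed = rc$seed_base + 3000L + i,
                                weight_factor = weight_factor,
                                delay_factor = delay_factor)
    sp <- simulate_network(net, duration, seed = rc$seed_base + 1000L + i,
                           thalamic = th)
    pk <- compute_psth_and_peaks(sp, th$onsets)
    if (is.null(peaks_acc)) {
      peaks_acc <- pk[, c("a_peak", "t_peak")]
      psth_acc <- lapply(attr(pk, "psth"), `[[`, "rate")
      psth_t <- attr(pk, "psth")[[1]]$t
      pops <- pk$population
    } else {
      peaks_acc <- peaks_acc + pk[, c("a_peak", "t_peak")]
      psth_acc <- Map(`+`, psth_acc, lapply(attr(pk, "psth"), `[[`, "rate"))
    }
  }
  peaks <- data.frame(population = pops, peaks_acc / rc$n_instances)
  rmse <- compute_peak_rmse(peaks, rc$config$reference_peaks)
  psth <- lapply(psth_acc, function(r) data.frame(t = psth_t,
                                                  rate = r / rc$n_instances))
  structure(list(peaks = peaks, rmse = rmse, psth = psth,
                 variant = rc$variant,
                 factors = c(time = time_factor, weight = weight_factor,
                             delay = delay_factor)),
            class = "bc_thalamic_run")
}

#' @export
print.bc_thalamic_run <- function(x, ...) {
  cat("Thalamic stimulation (", x$variant, "), peak responses:\n", sep = "")
  print.data.frame(x$peaks, row.names = FALSE, digits = 3)
  cat(sprintf("\npeak RMSE: amplitude %.2f spikes/s, time %.2f ms\n",
              x$rmse$rmse_amplitude, x$rmse$rmse_time))
  invisible(x)
}

#' Grid scan of thalamic-response parameters
#'
#' Evaluates [run_thalamic_protocol()] on a factor grid and returns the
#' RMSE bookkeeping table with the best-fit (smallest-RMSE) point, for
#' the amplitude scan (recurrent weight factors onto L2/3 Exc, SOM and
#' VIP targets) or the timing scan (thalamic weight/time/delay factors).
#'
#' @param rc a [run_config()].
#' @param grid data.frame of scan points; columns `exc_factor`,
#'   `som_factor`, `vip_factor` and/or `weight_factor`, `time_factor`,
#'   `delay_factor`.
#' @param objective `"amplitude"` or `"time"` RMSE.
#' @param ... passed to [run_thalamic_protocol()].
#' @return list: `scan` (grid with RMSE columns), `best` (row index of
#'   the argmin).
#' @export
run_thalamic_scan <- function(rc = run_config(), grid,
                              objective = c("amplitude", "time"), ...) {
  objective <- match.arg(objective)
  if (!nrow(grid)) stop("empty scan grid")
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, , drop = FALSE]
    rci <- rc
    ws <- NULL
    map <- c(exc_factor = "Exc", som_factor = "SOM", vip_factor = "VIP")
    for (col in names(map)) {
      if (col %in% names(g))
        ws <- rbind(ws, data.frame(source_type = "Exc", target_layer = "L2/3",
                                   target_type = map[[col]],
                                   factor = g[[col]]))
    }
    if (!is.null(ws)) rci$w_scale <- rbind(rc$w_scale, ws)
    run <- run_thalamic_protocol(
      rci,
      time_factor = if ("time_factor" %in% names(g)) g$time_factor else 1,
      weight_factor = if ("weight_factor" %in% names(g)) g$weight_factor else 1,
      delay_factor = if ("delay_factor" %in% names(g)) g$delay_factor else 1,
      ...)
    cbind(g, rmse_amplitude = run$rmse$rmse_amplitude,
          rmse_time = run$rmse$rmse_time)
  })
  scan <- do.call(rbind, res)
  key <- if (objective == "amplitude") scan$rmse_amplitude else scan$rmse_time
  list(scan = scan, best = which.min(key))
}
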