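# Background-input calibration: two-stage grid scan of the cell-type-
# specific background rates against in vivo reference firing rates.

target_rate_vector <- function(config) {
  rr <- config$reference_rates
  tgt <- rr[rr$target == 1, ]
  stats::setNames(tgt$mean, paste(tgt$layer, tgt$type))
}

#' Evaluate mean population rates of the column model for given background rates
#'
#' Builds the network with `r_bg` and measures mean population firing
#' rates in the evaluation window, averaged across simulation instances
#' (each instance uses its own derived seed for connectivity and inputs).
#' This is the model-evaluation function consumed by
#' [optimize_background_rates()].
#'
#' @param r_bg named vector `c(Exc=, PV=, SOM=, VIP=)`, spikes/s.
#' @param config model configuration.
#' @param stp logical, build the STP variant.
#' @param n_instances simulation instances to average.
#' @param duration simulated time per instance, ms.
#' @param eval_window analysis window, ms.
#' @param seed_base base seed; instance i uses `seed_base + i`.
#' @param weight_factors optional STP weight factors (see
#'   [build_network()]).
#' @return named vector of mean rates per population (spikes/s).
#' @export
evaluate_model_rates <- function(r_bg, config = bc_config(), stp = FALSE,
                                 n_instances = 10, duration = 15000,
                                 eval_window = c(10000, 15000),
                                 seed_base = 1L, weight_factors = NULL) {
  br <- config$background_rates
  col <- if (stp) "r_bg_stp" else "r_bg_static"
  br[[col]] <- as.numeric(r_bg[br$type])
  config$background_rates <- br
  acc <- NULL
  for (i in seq_len(n_instances)) {
    net <- build_network(config, seed = seed_base + i, stp = stp,
                         weight_factors = weight_factors)
    sp <- simulate_network(net, duration, seed = seed_base + 1000L + i)
    r <- compute_population_rates(sp, eval_window)
    acc <- if (is.null(acc)) r$mean else acc + r$mean
    names(acc) <- r$population
  }
  acc / n_instances
}

#' Two-stage grid optimization of the background rates
#'
#' Scans cell-type-specific background rates on a coarse grid (default
#' step 500 spikes/s), then on a fine grid (default step 100 spikes/s)
#' centered on the coarse optimum, minimizing the RMSPE
#' ([compute_rmspe()]) of the mean rates of the seven L2/3 and L4 target
#' populations. The full scan record is returned so second/third-best
#' settings can be inspected.
#'
#' @param evaluate function mapping a named rate vector
#'   `c(Exc=, PV=, SOM=, VIP=)` to named mean population rates; use
#'   [evaluate_model_rates()] (possibly wrapped with fixed instance
#'   counts) for the real model, or a stub for testing.
#' @param targets named vector of target rates (default: the packaged
#'   reference means for L2/3 and L4).
#' @param bounds named list per cell type of `c(min, max)` scan bounds,
#'   spikes/s.
#' @param coarse_step,fine_step grid steps, spikes/s.
#' @param fine_span half-width of the fine grid around the coarse
#'   optimum, spikes/s.
#' @return list of class `bc_bg_optimum`: `best` (named rates), `rmspe`,
#'   `scan` (data.frame of all evaluated settings with stage labels).
#' @export
optimize_background_rates <- function(evaluate,
                                      targets = target_rate_vector(bc_config()),
                                      bounds = list(Exc = c(3000, 7000),
                                                    PV = c(0, 8000),
                                                    SOM = c(0, 4000),
                                                    VIP = c(0, 6000)),
                                      coarse_step = 500, fine_step = 100,
                                      fine_span = 400) {
  if (!all(CELL_TYPES %in% names(bounds))) stop("bounds must cover all cell types")
  grid_axes <- function(b, step) lapply(b, function(x) {
    if (x[2] < x[1]) stop("empty scan bounds")
    seq(x[1], x[2], by = step)
  })
  run_stage <- function(axes, stage) {
    g <- expand.grid(axes[CELL_TYPES], KEEP.OUT.ATTRS = FALSE)
    names(g) <- CELL_TYPES
    res <- lapply(seq_len(nrow(g)), function(i) {
      r_bg <- unlist(g[i, ])
      rates <- evaluate(r_bg)
      e <- compute_rmspe(rates[names(targets)], targets)
      cbind(g[i, ], rmspe = e$value, stage = stage,
            as.data.frame(as.list(rates[names(targets)]), check.names = FALSE))
    })
    do.call(rbind, res)
  }
  coarse <- run_stage(grid_axes(bounds, coarse_step), "coarse")
  b0 <- coarse[which.min(coarse$rmspe), CELL_TYPES]
  fine_bounds <- lapply(CELL_TYPES, function(ct) {
    c(max(bounds[[ct]][1], b0[[ct]] - fine_span),
      min(bounds[[ct]][2], b0[[ct]] + fine_span))
  })
  names(fine_bounds) <- CELL_TYPES
  fine <- run_stage(grid_axes(fine_bounds, fine_step), "fine")
  scan <- rbind(coarse, fine)
  best <- scan[which.min(scan$rmspe), ]
  structure(list(best = unlist(best[CELL_TYPES]), rmspe = best$rmspe,
                 scan = scan), class = "bc_bg_optimum")
}

#' @export
print.bc_bg_optimum <- function(x, ...) {
  cat("Background-rate optimum (RMSPE", format(x$rmspe, digits = 4), "):\n")
  print(x$best)
  cat(nrow(x$scan), "settings evaluated\n")
  invisible(x)
}
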