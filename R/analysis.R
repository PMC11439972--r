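# Activity statistics: population rates, pairwise spike-count
# correlations, CV ISI, PSTHs with peak extraction, peak RMSE against
# reference tables, and normalized stimulus-response curves with t-tests.

spikes_pop <- function(spikes) {
  p <- attr(spikes, "pop")
  if (is.null(p)) stop("spike set carries no population labels")
  p
}

#' Population firing-rate statistics
#'
#' Per-neuron rates are spike counts over the analysis window divided by
#' its length; the returned table gives mean, SD, median and quartiles
#' across the neurons of each population.
#'
#' @param spikes a `bc_spikes` object.
#' @param window length-2 numeric, analysis window in ms (default: the
#'   full recording).
#' @return data.frame keyed by population with columns `n`, `mean`, `sd`,
#'   `median`, `q25`, `q75` (spikes/s).
#' @export
compute_population_rates <- function(spikes, window = attr(spikes, "window")) {
  if (diff(window) <= 0) stop("empty analysis window")
  rec <- attr(spikes, "window")
  if (window[1] < rec[1] || window[2] > rec[2])
    stop("window outside the recording")
  pop <- spikes_pop(spikes)
  keep <- spikes$t >= window[1] & spikes$t < window[2]
  counts <- tabulate(spikes$id[keep], nbins = length(pop))
  rate <- counts / (diff(window) / 1000)
  out <- do.call(rbind, lapply(levels(pop), function(pn) {
    r <- rate[pop == pn]
    data.frame(population = pn, n = length(r), mean = mean(r), sd = sd(r),
               median = median(r), q25 = unname(quantile(r, 0.25)),
               q75 = unname(quantile(r, 0.75)))
  }))
  rownames(out) <- out$population
  out
}

# binned spike counts for a set of neuron ids
bin_counts <- function(spikes, ids, window, bin) {
  edges <- seq(window[1], window[2], by = bin)
  n_bins <- length(edges) - 1
  m <- matrix(0L, length(ids), n_bins)
  keep <- spikes$id %in% ids & spikes$t >= window[1] & spikes$t < edges[n_bins + 1]
  if (any(keep)) {
    ri <- match(spikes$id[keep], ids)
    ci <- pmin(n_bins, floor((spikes$t[keep] - window[1]) / bin) + 1)
    for (k in seq_along(ri)) m[ri[k], ci[k]] <- m[ri[k], ci[k]] + 1L
  }
  m
}

#' Mean pairwise spike-count correlation in a layer
#'
#' Neurons of the layer (all cell types pooled) that fired at least once
#' in the window are eligible; `n_sample` of them are drawn at random and
#' the Pearson correlation of their binned spike counts (10 ms bins) is
#' averaged over all distinct pairs.
#'
#' @param spikes a `bc_spikes` object.
#' @param layer layer label (`"L2/3"`, ...); `NULL` pools all neurons.
#' @param window analysis window, ms.
#' @param n_sample neurons to sample (all eligible ones, flagged, if
#'   fewer).
#' @param bin bin width, ms.
#' @param seed sampling seed.
#' @return list: `mean_correlation`, `n_used`, `all_sampled` flag.
#' @export
compute_pairwise_correlation <- function(spikes, layer = NULL,
                                         window = attr(spikes, "window"),
                                         n_sample = 200, bin = 10,
                                         seed = 1L) {
  pop <- spikes_pop(spikes)
  in_layer <- if (is.null(layer)) rep(TRUE, length(pop)) else
    startsWith(as.character(pop), layer)
  keep <- spikes$t >= window[1] & spikes$t < window[2]
  active <- intersect(which(in_layer),
                      unique(spikes$id[keep]))
  if (length(active) < 2)
    return(list(mean_correlation = NA_real_, n_used = length(active),
                all_sampled = TRUE))
  set.seed(seed)
  ids <- if (length(active) > n_sample) sort(sample(active, n_sample)) else active
  m <- bin_counts(spikes, ids, window, bin)
  cc <- suppressWarnings(cor(t(m)))
  v <- cc[upper.tri(cc)]
  list(mean_correlation = mean(v, na.rm = TRUE), n_used = length(ids),
       all_sampled = length(active) <= n_sample)
}

#' Mean coefficient of variation of inter-spike intervals in a layer
#'
#' Neurons firing below `min_rate` in the window are excluded before
#' sampling; per neuron CV = SD(ISI)/mean(ISI), averaged over the sample.
#'
#' @inheritParams compute_pairwise_correlation
#' @param min_rate eligibility threshold, spikes/s.
#' @return list: `mean_cv`, `n_used`, `all_sampled`.
#' @export
compute_cv_isi <- function(spikes, layer = NULL,
                           window = attr(spikes, "window"),
                           n_sample = 200, min_rate = 1, seed = 1L) {
  pop <- spikes_pop(spikes)
  in_layer <- if (is.null(layer)) rep(TRUE, length(pop)) else
    startsWith(as.character(pop), layer)
  keep <- spikes$t >= window[1] & spikes$t < window[2]
  counts <- tabulate(spikes$id[keep], nbins = length(pop))
  need <- ceiling(min_rate * diff(window) / 1000)
  eligible <- which(in_layer & counts >= pmax(2, need))
  if (!length(eligible))
    return(list(mean_cv = NA_real_, n_used = 0L, all_sampled = TRUE))
  set.seed(seed)
  ids <- if (length(eligible) > n_sample) sort(sample(eligible, n_sample)) else eligible
  sp <- spikes[keep & spikes$id %in% ids, ]
  cvs <- vapply(ids, function(i) {
    isi <- diff(sort(sp$t[sp$id == i]))
    if (length(isi) < 2) return(NA_real_)
    sd(isi) / mean(isi)
  }, numeric(1))
  list(mean_cv = mean(cvs, na.rm = TRUE), n_used = length(ids),
       all_sampled = length(eligible) <= n_sample)
}

#' Population PSTH and response peak
#'
#' Peristimulus time histogram in 0.5 ms bins, averaged over stimulus
#' repeats and normalized per neuron: rate in a bin equals the spike count
#' divided by (bin width x number of neurons x number of repeats), in
#' spikes/s. The response peak is the largest bin between 0 and
#' `search_window` ms after onset; ties break to the earliest bin.
#'
#' @param spikes a `bc_spikes` object.
#' @param onsets stimulus onset times, ms.
#' @param bin bin width, ms.
#' @param window PSTH extent after onset, ms.
#' @param search_window peak search extent after onset, ms.
#' @return data.frame of class `bc_psth`: per population, nested `psth`
#'   columns plus `a_peak` (spikes/s) and `t_peak` (ms, bin center).
#' @export
compute_psth_and_peaks <- function(spikes, onsets, bin = 0.5, window = 50,
                                   search_window = 50) {
  if (!length(onsets)) stop("need at least one stimulus onset")
  pop <- spikes_pop(spikes)
  n_bins <- ceiling(window / bin)
  centers <- (seq_len(n_bins) - 0.5) * bin
  out <- list()
  for (pn in levels(pop)) {
    ids <- which(pop == pn)
    counts <- numeric(n_bins)
    sel <- spikes$id %in% ids
    tt <- spikes$t[sel]
    for (on in onsets) {
      rel <- tt[tt >= on & tt < on + window] - on
      if (length(rel))
        counts <- counts + tabulate(floor(rel / bin) + 1, nbins = n_bins)
    }
    rate <- counts / (bin / 1000 * length(ids) * length(onsets))
    srch <- centers <= search_window
    pk <- which.max(rate[srch]) # which.max takes the earliest maximum
    out[[pn]] <- data.frame(population = pn, a_peak = rate[srch][pk],
                            t_peak = centers[srch][pk])
    attr(out[[pn]], "psth") <- data.frame(t = centers, rate = rate)
  }
  res <- do.call(rbind, out)
  attr(res, "psth") <- lapply(out, attr, "psth")
  attr(res, "bin") <- bin
  class(res) <- c("bc_psth", "data.frame")
  res
}

#' RMSE of PSTH peaks against a reference table
#'
#' Root-mean-square error of peak amplitudes and peak times over
#' populations. The amplitude comparison uses zero as the reference for
#' VIP; the time comparison omits VIP (no observable VIP response in the
#' reference data).
#'
#' @param simulated a [compute_psth_and_peaks()] result.
#' @param reference data.frame with `layer`, `type`, `a_peak`, `t_peak`.
#' @return list: `rmse_amplitude` (spikes/s), `rmse_time` (ms).
#' @export
compute_peak_rmse <- function(simulated, reference) {
  ref_pop <- paste(reference$layer, reference$type)
  i <- match(simulated$population, ref_pop)
  if (anyNA(i)) stop("reference table missing population(s): ",
                     paste(simulated$population[is.na(i)], collapse = ", "))
  ref <- reference[i, ]
  is_vip <- ref$type == "VIP"
  a_ref <- ifelse(is_vip, 0, ref$a_peak)
  rmse_a <- sqrt(mean((simulated$a_peak - a_ref)^2))
  tsel <- !is_vip
  rmse_t <- sqrt(mean((simulated$t_peak[tsel] - ref$t_peak[tsel])^2))
  list(rmse_amplitude = rmse_a, rmse_time = rmse_t)
}

#' Normalize stimulus-response rates and test deviation from baseline
#'
#' Per simulation instance, population rates at every stimulation level
#' are normalized by that instance's zero-level rate; per level, the
#' normalized values are tested for deviation from 1 with a two-tailed
#' one-sample t-test. Instances with a zero baseline rate are flagged and
#' excluded. Zero-variance samples return p = 1 with a flag.
#'
#' @param rates matrix of rates (instances x levels) for one population,
#'   with the zero level identified by `levels`.
#' @param levels stimulation levels (spikes/s) labelling the columns;
#'   must contain 0.
#' @return data.frame of class `bc_response`: per level `r_norm` (mean),
#'   `sem`, `p_value`, `pct_change`, `n`, `degenerate` flag.
#' @export
normalize_responses_and_test <- function(rates, levels) {
  z <- which(levels == 0)
  if (length(z) != 1) stop("levels must contain exactly one 0")
  base <- rates[, z]
  ok <- base > 0
  if (sum(ok) < 2) stop("fewer than two instances with nonzero baseline")
  norm <- rates[ok, , drop = FALSE] / base[ok]
  out <- lapply(seq_along(levels), function(j) {
    v <- norm[, j]
    degen <- sd(v) == 0
    p <- if (j == z) NA_real_ else if (degen) 1 else t.test(v, mu = 1)$p.value
    data.frame(level = levels[j], r_norm = mean(v),
               sem = sd(v) / sqrt(length(v)), p_value = p,
               pct_change = (mean(v) - 1) * 100, n = length(v),
               degenerate = degen)
  })
  res <- do.call(rbind, out)
  attr(res, "excluded_instances") <- which(!ok)
  class(res) <- c("bc_response", "data.frame")
  res
}

#' Root-mean-square percentage error of population rates
#'
#' Per population the error is (simulated - target)/target; the returned
#' value is the root mean square of these fractions (the background-input
#' optimization objective).
#'
#' @param simulated_means,targets equal-length rate vectors, spikes/s;
#'   targets must be positive.
#' @return list: `value`, `per_population_errors`.
#' @export
compute_rmspe <- function(simulated_means, targets) {
  if (length(simulated_means) != length(targets))
    stop("length mismatch between simulated means and targets")
  if (any(targets <= 0)) stop("targets must be positive (percentage error)")
  err <- (simulated_means - targets) / targets
  list(value = sqrt(mean(err^2)), per_population_errors = err)
}
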