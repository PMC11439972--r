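# toy bc_spikes constructor for analysis tests
mk_spikes <- function(id, t, n_neurons, pops = NULL, window = c(0, 1000)) {
  x <- data.frame(id = id, t = t)
  attr(x, "pop") <- if (is.null(pops))
    factor(rep("P1", n_neurons)) else pops
  attr(x, "window") <- window
  attr(x, "n_total") <- n_neurons
  class(x) <- c("bc_spikes", "data.frame")
  x
}

test_that("population rates count spikes per neuron over the window", {
  s0 <- mk_spikes(integer(), numeric(), 5)
  expect_true(all(compute_population_rates(s0)$mean == 0))
  s1 <- mk_spikes(rep(1L, 10), seq(100, 4900, length.out = 10), 1,
                  window = c(0, 5000))
  expect_equal(compute_population_rates(s1)$mean, 2)
  # Poisson surrogate at 20 spikes/s
  set.seed(3)
  n <- 100; dur <- 10000
  tr <- lapply(1:n, function(i) cumsum(rexp(400, 0.02)))
  tr <- lapply(tr, function(x) x[x < dur])
  s2 <- mk_spikes(rep(seq_len(n), lengths(tr)), unlist(tr), n,
                  window = c(0, dur))
  r <- compute_population_rates(s2)
  se <- sqrt(20 / (dur / 1000) / n)
  expect_lt(abs(r$mean - 20), 3 * se)
  expect_error(compute_population_rates(s1, c(500, 500)), "empty")
})

test_that("pairwise correlation detects identity, independence and exclusion", {
  dur <- 20000
  set.seed(8)
  base <- cumsum(rexp(300, 0.01)); base <- base[base < dur]
  # two identical trains -> correlation 1
  s <- mk_spikes(c(rep(1L, length(base)), rep(2L, length(base))),
                 c(base, base), 2, window = c(0, dur))
  expect_equal(compute_pairwise_correlation(s, window = c(0, dur))$mean_correlation, 1)
  # independent Poisson trains -> mean within 3 SE of 0
  n <- 60
  tr <- lapply(1:n, function(i) { x <- cumsum(rexp(300, 0.01)); x[x < dur] })
  si <- mk_spikes(rep(seq_len(n), lengths(tr)), unlist(tr), n, window = c(0, dur))
  cc <- compute_pairwise_correlation(si, window = c(0, dur), seed = 2)
  n_pairs <- choose(n, 2)
  expect_lt(abs(cc$mean_correlation), 3 / sqrt(dur / 10) / sqrt(n_pairs) * 10)
  expect_lt(abs(cc$mean_correlation), 0.01)
  # silent neurons are excluded before sampling
  s3 <- mk_spikes(rep(1:2, each = length(base)), rep(base, 2), 3,
                  window = c(0, dur))
  cc3 <- compute_pairwise_correlation(s3, window = c(0, dur))
  expect_equal(cc3$n_used, 2)
})

test_that("CV ISI is 0 for regular, about 1 for Poisson, excludes low rates", {
  dur <- 30000
  reg <- seq(10, dur - 10, by = 100)
  s <- mk_spikes(rep(1L, length(reg)), reg, 1, window = c(0, dur))
  expect_equal(compute_cv_isi(s, window = c(0, dur))$mean_cv, 0)
  set.seed(12)
  n <- 50
  tr <- lapply(1:n, function(i) { x <- cumsum(rexp(800, 0.02)); x[x < dur] })
  sp <- mk_spikes(rep(seq_len(n), lengths(tr)), unlist(tr), n, window = c(0, dur))
  cv <- compute_cv_isi(sp, window = c(0, dur))
  m <- mean(lengths(tr))
  se <- sqrt(0.5 / m / n) # CV estimator SD approx sqrt(1/2m) per neuron
  expect_lt(abs(cv$mean_cv - 1), max(3 * se, 0.05))
  # a 0.5 spikes/s neuron is excluded
  slow <- seq(0, dur - 1, by = 2000)
  s5 <- mk_spikes(c(rep(1L, length(reg)), rep(2L, length(slow))),
                  c(reg, slow), 2, window = c(0, dur))
  expect_equal(compute_cv_isi(s5, window = c(0, dur), min_rate = 1)$n_used, 1)
})

test_that("PSTH normalization is repeat-invariant and conserves spike counts", {
  pops <- factor(rep("P1", 10))
  onsets1 <- c(1000)
  onsets2 <- c(1000, 2000)
  # one spike 10 ms after every onset from every neuron
  mk <- function(onsets) {
    t <- as.vector(outer(onsets + 10.2, rep(0, 10), "+"))
    mk_spikes(rep(1:10, each = length(onsets)), t, 10, pops,
              window = c(0, 4000))
  }
  p1 <- compute_psth_and_peaks(mk(onsets1), onsets1)
  p2 <- compute_psth_and_peaks(mk(onsets2), onsets2)
  expect_equal(p1$a_peak, p2$a_peak) # doubling repeats leaves the PSTH unchanged
  expect_equal(p1$t_peak, p2$t_peak)
  expect_equal(p1$t_peak, 10.25)     # bin center on the 0.5 ms grid
  # conservation: integral x bin x neurons x repeats = spike count in window
  ps <- attr(p2, "psth")$P1
  total <- sum(ps$rate) * 0.5 / 1000 * 10 * 2
  expect_equal(total, 20)            # 10 neurons x 2 onsets, all within 50 ms
  # silent population: flat zero, peak 0
  s0 <- mk_spikes(integer(), numeric(), 10, pops, window = c(0, 4000))
  p0 <- compute_psth_and_peaks(s0, onsets1)
  expect_equal(p0$a_peak, 0)
})

test_that("peak RMSE applies the VIP rules", {
  ref <- data.frame(layer = c("L4", "L4", "L4", "L2/3"),
                    type = c("Exc", "PV", "SOM", "VIP"),
                    a_peak = c(30, 80, 15, 0), t_peak = c(10, 8, 14, NA))
  sim <- data.frame(population = c("L4 Exc", "L4 PV", "L4 SOM", "L2/3 VIP"),
                    a_peak = c(30, 80, 15, 0), t_peak = c(10, 8, 14, 3))
  r0 <- compute_peak_rmse(sim, ref)
  expect_equal(r0$rmse_amplitude, 0)
  expect_equal(r0$rmse_time, 0)  # VIP time excluded despite the mismatch
  sim2 <- sim; sim2$a_peak[1] <- 40
  expect_equal(compute_peak_rmse(sim2, ref)$rmse_amplitude, 5)
  # VIP amplitude compared against zero
  sim3 <- sim; sim3$a_peak[4] <- 12
  expect_equal(compute_peak_rmse(sim3, ref)$rmse_amplitude, sqrt(144 / 4))
  expect_error(compute_peak_rmse(
    data.frame(population = "L6 Exc", a_peak = 1, t_peak = 1), ref), "missing")
})

test_that("response normalization and t-test match the textbook forms", {
  lv <- c(0, 100, 200)
  # all instances identical to baseline: r_norm 1, degenerate p = 1
  m <- matrix(5, nrow = 6, ncol = 3)
  r <- normalize_responses_and_test(m, lv)
  expect_equal(r$r_norm, c(1, 1, 1))
  expect_true(all(r$degenerate[-1]))
  expect_equal(r$p_value[-1], c(1, 1))
  # constructed normalized values 1.1 +/- 0.05: t equals (mean-1)/SE
  set.seed(21)
  v <- 1.1 + 0.05 * scale(rnorm(20))[, 1]
  m2 <- cbind(rep(1, 20), v)
  r2 <- normalize_responses_and_test(m2, c(0, 50))
  tt <- (mean(v) - 1) / (sd(v) / sqrt(20))
  expect_equal(r2$p_value[2], 2 * stats::pt(-abs(tt), df = 19))
  expect_equal(r2$pct_change[2], (mean(v) - 1) * 100)
  # zero-baseline instances are flagged and excluded
  m3 <- rbind(m2, c(0, 2))
  r3 <- normalize_responses_and_test(m3, c(0, 50))
  expect_equal(attr(r3, "excluded_instances"), 21L)
  expect_equal(r3$n[1], 20)
})
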