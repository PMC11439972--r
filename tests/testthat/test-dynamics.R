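test_that("LIF update has the resting fixed point and exact exponential decay", {
  pops <- bc_test_pops()
  p <- as.list(pops["L5 Exc", ])
  st <- list(v = p$v_rest, i_exc = 0, i_inh = 0, refr_remaining = 0)
  for (k in 1:50) st <- lif_update(st, p)
  expect_equal(st$v, p$v_rest)
  st <- list(v = p$v_rest + 10, i_exc = 0, i_inh = 0, refr_remaining = 0)
  for (k in 1:200) st <- lif_update(st, p)
  expect_lt(abs((st$v - p$v_rest) - 10 * exp(-20 / p$tau_m)), 1e-9)
})

test_that("no spike is possible within the 2 ms refractory period", {
  pops <- bc_test_pops()
  p <- as.list(pops["L2/3 PV", ])
  st <- list(v = p$v_th + 1, i_exc = 0, i_inh = 0, refr_remaining = 0)
  st <- lif_update(st, p)
  expect_true(st$spike)
  # hammer with huge input: no spike for the next 2.0 ms
  for (k in 1:20) {
    st <- lif_update(st, p, input_exc = 1e5)
    expect_false(st$spike)
  }
  # afterwards the accumulated drive fires the neuron quickly
  fired <- FALSE
  for (k in 1:20) {
    st <- lif_update(st, p, input_exc = 1e5)
    fired <- fired || st$spike
  }
  expect_true(fired)
})

test_that("halving dt leaves subthreshold trajectories unchanged (exact propagators)", {
  pops <- bc_test_pops()
  p <- as.list(pops["L4 SOM", ])
  v1 <- barrelsim:::lif_trace(p, 0.4, 120, 2, 30, dt = 0.1)
  v2 <- barrelsim:::lif_trace(p, 0.4, 120, 2, 30, dt = 0.05)
  expect_equal(v1[1 + 10 * (5:29)], v2[1 + 20 * (5:29)], tolerance = 1e-12)
})

test_that("STP update matches the first-spike rule and state bounds", {
  par <- list(U = 0.3, F = 150, D = 250)
  r <- stp_spike_update(list(u = 0, x = 1), par, Inf, w_static = 10)
  expect_equal(r$amplitude, 10 * 0.3) # first spike transmits w * U
  # depression only (D large, F = 0): x non-increasing over a long train
  par2 <- list(U = 0.5, F = 0, D = 1e9)
  st <- list(u = 0, x = 1)
  xs <- numeric(30)
  last <- -Inf; t <- 0
  for (k in 1:30) {
    r <- stp_spike_update(st, par2, t - last, 1)
    st <- r$state; xs[k] <- st$x; last <- t; t <- t + 50
  }
  expect_true(all(diff(xs) <= 1e-12))
  # bounds hold for arbitrary random trains
  set.seed(5)
  for (rep in 1:20) {
    par3 <- list(U = runif(1, 0.05, 1), F = runif(1, 0, 800), D = runif(1, 0, 800))
    st <- list(u = 0, x = 1); last <- -Inf
    for (t in cumsum(rexp(200, 0.02))) {
      r <- stp_spike_update(st, par3, t - last, 1)
      st <- r$state; last <- t
      expect_true(st$u >= 0 && st$u <= 1 && st$x >= 0 && st$x <= 1)
    }
  }
})

test_that("periodic-train amplitudes converge to the recursion fixed point", {
  par <- list(U = 0.4, F = 120, D = 380)
  T_isi <- 40
  rel <- barrelsim:::stp_release_sequence(par, (0:999) * T_isi)
  # closed-form fixed point of the two-variable recursion
  ef <- exp(-T_isi / par$F); ed <- exp(-T_isi / par$D)
  u_star <- par$U / (1 - (1 - par$U) * ef)
  x_star <- (1 - ed) / (1 - (1 - u_star) * ed)
  expect_lt(abs(rel[1000] - u_star * x_star), 1e-10)
})

test_that("network simulation is deterministic and respects the static limit", {
  net <- make_toy_network_fixture(n_per_pop = 15, seed = 3)
  s1 <- simulate_network(net, 1500, seed = 9)
  s2 <- simulate_network(net, 1500, seed = 9)
  expect_identical(s1$id, s2$id)
  expect_identical(s1$t, s2$t)
  s3 <- simulate_network(net, 1500, seed = 10)
  expect_false(identical(s1$t, s3$t))
  # STP network with all-static parameter table reduces exactly to static
  cfg <- bc_test_config()
  cfg$stp_params <- cfg$stp_params[0, ]
  net_s <- make_toy_network_fixture(n_per_pop = 15, seed = 3, config = cfg)
  net_p <- make_toy_network_fixture(n_per_pop = 15, seed = 3, config = cfg,
                                    stp = TRUE)
  a <- simulate_network(net_s, 1500, seed = 9)
  b <- simulate_network(net_p, 1500, seed = 9)
  expect_identical(a$id, b$id)
  expect_identical(a$t, b$t)
})

test_that("a driven neuron's engine firing rate matches an independent scalar simulation", {
  # one isolated neuron receiving 0.5 mV EPSPs at 3000 spikes/s
  cfg <- bc_test_config()
  br <- cfg$background_rates
  br$r_bg_static <- c(3000, 0, 0, 0)[match(br$type, c("Exc", "PV", "SOM", "VIP"))]
  cfg$background_rates <- br
  net <- make_toy_network_fixture(n_per_pop = 4, p = 0, seed = 2, config = cfg)
  dur <- 20000
  sp <- simulate_network(net, dur, seed = 4)
  pop <- attr(sp, "pop")
  exc_ids <- which(pop == "L2/3 Exc")
  rate_engine <- sum(sp$id %in% exc_ids) / length(exc_ids) / (dur / 1000)
  # independent reference: R-coded scalar LIF with explicit Poisson input
  p <- as.list(bc_test_pops()["L2/3 Exc", ])
  w <- psp_to_psc(0.5, p$c_m, p$tau_m, 2)
  set.seed(99)
  n_rep <- 6; n_steps <- dur / 0.1
  counts <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    spikes_in <- cumsum(rexp(dur * 3 * 1.2 + 200, 3))  # rate 3 per ms
    inc <- tabulate(floor(spikes_in[spikes_in < dur] / 0.1) + 2, nbins = n_steps)
    st <- list(v = p$v_rest, i_exc = 0, i_inh = 0, refr_remaining = 0)
    nsp <- 0
    for (k in seq_len(n_steps)) {
      st <- lif_update(st, p, input_exc = inc[k] * w)
      nsp <- nsp + st$spike
    }
    counts[r] <- nsp
  }
  ref <- counts / (dur / 1000)
  se <- sqrt(stats::var(ref) / n_rep + stats::var(ref) / length(exc_ids))
  expect_lt(abs(rate_engine - mean(ref)), 3 * max(se, 0.2))
})

test_that("a single presynaptic spike produces the configured PSP in the engine", {
  # two-population chain built by hand: neuron 1 (source) driven over
  # threshold once; neuron 2 receives a static weight from psp_to_psc(0.5)
  pops <- bc_test_pops()
  p <- as.list(pops["L2/3 Exc", ])
  w <- psp_to_psc(0.5, p$c_m, p$tau_m, 2)
  net <- list(
    neurons = list(tau_m = rep(p$tau_m, 2), c_m = rep(p$c_m, 2),
                   v_rest = rep(p$v_rest, 2), v_th = c(p$v_th, 1e6),
                   v_reset = rep(p$v_rest, 2), ref_steps = rep(20L, 2),
                   v0 = c(p$v_th + 1, p$v_rest)),
    synapses = list(src_ptr = c(0L, 1L, 1L), tgt = 1L, w = w,
                    delay_steps = 10L, stp_id = -1L, stp_U = numeric(),
                    stp_F = numeric(), stp_D = numeric()),
    background = list(rate = c(0, 0), w = c(0, 0), delay_steps = 1L),
    pop_of_neuron = factor(c("src", "tgt")), n_total = 2L,
    stp_variant = "decay_to_zero")
  class(net) <- "bc_network"
  # neuron 1 starts above threshold, so it fires exactly once at t = 0
  sp <- simulate_network(net, 100, seed = 1, record_v = 2)
  v2 <- attr(sp, "v")[, 1]
  expect_equal(sum(sp$id == 1), 1)  # source spiked exactly once
  expect_lt(abs(max(v2 - p$v_rest) - 0.5), 1e-3)
})
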