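test_that("spatial integration matches a Monte-Carlo kernel-average oracle", {
  cfg <- bc_test_config()
  expect_equal(derive_model_probability(0, 100, cfg), 0)
  expect_equal(derive_model_probability(0.2, NA, cfg), 0.2)
  # rectangle equal to the model footprint: consistency, P = P_exp
  p_same <- derive_model_probability(0.2, c(cfg$surface_x, cfg$surface_y), cfg)
  expect_lt(abs(p_same - 0.2) / 0.2, 1e-6)
  # disc-range case against Monte-Carlo integration of the decay kernel
  set.seed(7)
  n <- 1e6
  lam <- cfg$decay_length
  # pairs in the model rectangle
  d_rect <- sqrt((runif(n, 0, cfg$surface_x) - runif(n, 0, cfg$surface_x))^2 +
                 (runif(n, 0, cfg$surface_y) - runif(n, 0, cfg$surface_y))^2)
  # pairs in a disc of radius 100 um (rejection sampling)
  rdisc <- function(n) {
    x <- matrix(runif(4 * n, -1, 1), ncol = 2)
    x <- x[rowSums(x^2) <= 1, , drop = FALSE][seq_len(n), ] * 100
  }
  d_disc <- sqrt(rowSums((rdisc(n) - rdisc(n))^2))
  p_mc <- 0.15 * mean(exp(-d_rect / lam)) / mean(exp(-d_disc / lam))
  p_pkg <- derive_model_probability(0.15, 100, cfg)
  expect_lt(abs(p_pkg - p_mc) / p_mc, 0.01)
  expect_error(derive_model_probability(1.2, 100, cfg), "0, 1")
})

test_that("subtype pooling is a cell-number-weighted average", {
  p <- matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2)
  n_pre <- c(10, 30); n_post <- c(5, 5)
  expect_equal(pool_subtype_probabilities(p, n_pre, n_post),
               sum(outer(n_pre, n_post) * p) / sum(outer(n_pre, n_post)))
  expect_equal(pool_subtype_probabilities(matrix(0.2), 7, 3), 0.2)
})

test_that("assembled matrix is complete with the documented fill-in rules", {
  pm <- assemble_probability_matrix(bc_test_config())
  cortical <- pm[pm$source_type != "Exc_th", ]
  intra <- cortical$source_layer == cortical$target_layer
  expect_equal(nrow(cortical), 169)
  expect_equal(sum(intra), 43)
  expect_equal(sum(!intra), 126)
  g <- function(sl, st, tl, tt)
    cortical[cortical$source_layer == sl & cortical$source_type == st &
             cortical$target_layer == tl & cortical$target_type == tt, ]
  # text-anchored entries
  expect_equal(g("L4", "SOM", "L4", "PV")$p_exp, 36.30)
  expect_equal(g("L2/3", "SOM", "L2/3", "PV")$p_exp, 11.81)
  expect_equal(g("L4", "SOM", "L4", "Exc")$p_exp, 19.8)
  # Exc<->PV reciprocity where Exc->PV was missing
  expect_equal(g("L4", "Exc", "L4", "PV")$p_exp, g("L4", "PV", "L4", "Exc")$p_exp)
  expect_equal(g("L5", "Exc", "L5", "PV")$p_exp, g("L5", "PV", "L5", "Exc")$p_exp)
  # L5 SOM-related entries are L2/3-L4 averages
  expect_equal(g("L5", "SOM", "L5", "Exc")$p_exp,
               mean(c(g("L2/3", "SOM", "L2/3", "Exc")$p_exp,
                      g("L4", "SOM", "L4", "Exc")$p_exp)))
  # L6 non-Exc->Exc intra-layer entries copied from L5
  expect_equal(g("L6", "SOM", "L6", "PV")$p_exp, g("L5", "SOM", "L5", "PV")$p_exp)
  expect_equal(g("L6", "Exc", "L6", "PV")$p_exp, g("L5", "Exc", "L5", "PV")$p_exp)
  # all probabilities are valid fractions
  expect_true(all(pm$p >= 0 & pm$p <= 1))
})

test_that("halving the L4 SOM->PV probability gives the reduced-connectivity value", {
  pm <- assemble_probability_matrix(bc_test_config())
  p0 <- pm$p[pm$source_layer == "L4" & pm$source_type == "SOM" &
             pm$target_layer == "L4" & pm$target_type == "PV"] * 100
  expect_equal(p0, 36.30)
  expect_equal(round(p0 / 2, 1), 18.2, tolerance = 0.051)
})

test_that("thalamic rows follow the layer rules", {
  cfg <- bc_test_config()
  pm <- assemble_probability_matrix(cfg)
  th <- pm[pm$source_type == "Exc_th", ]
  expect_false(any(th$target_type == "VIP"))
  expect_equal(th$p[th$target_layer == "L2/3" & th$target_type == "Exc"],
               th$p[th$target_layer == "L4" & th$target_type == "Exc"] *
                 cfg$ratio_l23_l4)
  expect_equal(th$p[th$target_layer == "L4" & th$target_type == "SOM"],
               th$p[th$target_layer == "L4" & th$target_type == "Exc"] *
                 cfg$som_attenuation)
  expect_true(all(th$target_layer[th$target_type == "SOM"] == "L4"))
})

test_that("Bernoulli sampling respects probability, autapses and multapse exclusion", {
  expect_equal(nrow(sample_connections(0, 50, 50, seed = 1)), 0)
  full <- sample_connections(1, 3, 3, same_population = TRUE, seed = 1)
  expect_equal(nrow(full), 9)
  expect_equal(sum(full$pre == full$post), 3) # autapses present
  expect_false(any(duplicated(full[, c("pre", "post")])))
  # empirical density over 200 seeds within 3 SE of the binomial expectation
  counts <- vapply(1:200, function(s)
    nrow(sample_connections(0.1, 100, 100, seed = s)), numeric(1))
  se <- sqrt(10000 * 0.1 * 0.9) / sqrt(200)
  expect_lt(abs(mean(counts) - 1000), 3 * se)
})

test_that("weight and delay draws match the class definitions", {
  cfg <- bc_test_config()
  pops <- bc_test_pops()
  tgt <- as.list(pops["L2/3 Exc", ])
  # background class: fixed 0.5 mV equivalent, fixed 0.1 ms delay
  bg <- draw_synaptic_parameters("bg", tgt, 10, config = cfg)
  expect_equal(length(unique(bg$w)), 1)
  expect_equal(bg$w[1], psp_to_psc(0.5, tgt$c_m, tgt$tau_m, 2))
  expect_true(all(bg$d == 0.1))
  # inhibitory draws are all negative
  inh <- draw_synaptic_parameters("inh", tgt, 1000, config = cfg)
  expect_true(all(inh$w < 0))
  # moment matching: 1e5 draws of the excitatory class reproduce 0.5 +/- 0.5 mV
  set.seed(11)
  n <- 1e5
  exc <- draw_synaptic_parameters("exc", tgt, n, config = cfg)
  unit <- psp_to_psc(1, tgt$c_m, tgt$tau_m, 2)
  psp <- exc$w / unit
  expect_lt(abs(mean(psp) - 0.5) / 0.5, 0.02)
  expect_lt(abs(sd(psp) - 0.5) / 0.5, 0.02)
  # delays on the grid, floored at one step
  expect_true(all(exc$d >= 0.1))
  expect_equal(exc$d, round(exc$d / 0.1) * 0.1)
})
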