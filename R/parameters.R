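#' barrelsim: a layered barrel-cortex microcircuit simulator
#'
#' Tools to build, calibrate, simulate and analyse a spiking model of a
#' mouse barrel-cortex column with excitatory (Exc) neurons and PV, SOM and
#' VIP interneurons across layers 2/3 to 6. See the package vignette for
#' the underlying model and its assumptions.
#'
#' @useDynLib barrelsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rlnorm runif rnorm optim t.test cor sd quantile
#'   median nlminb rexp
#' @importFrom utils read.delim
#' @keywords internal
"_PACKAGE"

LAYERS <- c("L2/3", "L4", "L5", "L6")
CELL_TYPES <- c("Exc", "PV", "SOM", "VIP")
SIM_RESOLUTION <- 0.1 # ms, fixed-step integration grid
TAU_REF <- 2.0        # ms, absolute refractory period, all populations

extdata <- function(file) {
  path <- system.file("extdata", file, package = "barrelsim")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

read_table <- function(file) {
  read.delim(extdata(file), comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Adjust an in vitro membrane time constant to in vivo conditions
#'
#' Applies a fractional reduction in membrane resistance (and hence, at
#' fixed capacitance, in the membrane time constant) that approximates the
#' transition from a silent in vitro preparation to the awake state.
#'
#' @param tau_m_invitro membrane time constant measured in vitro, ms.
#' @param reduction_fraction fractional decrease in membrane resistance,
#'   in `[0, 1)` (e.g. 0.509 for excitatory, 0.049 for inhibitory cells).
#' @return adjusted membrane time constant in ms (full precision; reported
#'   table values round to one decimal).
#' @export
adjust_membrane_time_constant <- function(tau_m_invitro, reduction_fraction) {
  if (any(tau_m_invitro <= 0)) stop("tau_m_invitro must be positive")
  if (any(reduction_fraction < 0) || any(reduction_fraction >= 1))
    stop("reduction_fraction must be in [0, 1)")
  tau_m_invitro * (1 - reduction_fraction)
}

#' Convert a target PSP amplitude into the PSC amplitude producing it
#'
#' For a LIF neuron with membrane time constant `tau_m` and capacitance
#' `C_m` receiving an exponentially decaying postsynaptic current with
#' decay constant `tau_syn`, returns the PSC amplitude (pA) whose membrane
#' response peaks at exactly `psp` (mV):
#' \deqn{PSC = C_m (a-1) PSP / (\tau_{syn} (a^{1/(1-a)} - a^{a/(1-a)}))}
#' with \eqn{a = \tau_{syn}/\tau_m}. At \eqn{a = 1} the analytic limit
#' \eqn{C_m e \cdot PSP / \tau_{syn}} is used (the general expression is
#' 0/0 there).
#'
#' @param psp target PSP peak amplitude, mV (sign is preserved).
#' @param c_m membrane capacitance, pF.
#' @param tau_m membrane time constant, ms.
#' @param tau_syn PSC decay time constant, ms.
#' @return PSC amplitude in pA.
#' @export
psp_to_psc <- function(psp, c_m, tau_m, tau_syn) {
  if (any(c_m <= 0) || any(tau_m <= 0) || any(tau_syn <= 0))
    stop("c_m, tau_m and tau_syn must be positive")
  n <- max(length(psp), length(c_m), length(tau_m), length(tau_syn))
  psp <- rep_len(psp, n); c_m <- rep_len(c_m, n)
  tau_m <- rep_len(tau_m, n); tau_syn <- rep_len(tau_syn, n)
  a <- tau_syn / tau_m
  lim <- abs(a - 1) < 1e-12   # analytic limit at the removable singularity
  out <- numeric(n)
  out[lim] <- c_m[lim] * exp(1) * psp[lim] / tau_syn[lim]
  i <- !lim
  out[i] <- c_m[i] * (a[i] - 1) * psp[i] /
    (tau_syn[i] * (a[i]^(1 / (1 - a[i])) - a[i]^(a[i] / (1 - a[i]))))
  out
}

#' Distribute an inhibitory cell count over PV, SOM and VIP types
#'
#' Apportions `n_inh` according to the relative quantities `fractions`
#' using largest-remainder rounding, so the three integer counts always sum
#' to `n_inh` exactly.
#'
#' @param n_inh total inhibitory neuron count in the layer.
#' @param fractions numeric length-3 vector of relative quantities
#'   (f_PV, f_SOM, f_VIP); any non-negative scale.
#' @return named integer vector `c(PV=, SOM=, VIP=)`.
#' @export
allocate_interneuron_counts <- function(n_inh, fractions) {
  if (n_inh < 0) stop("n_inh must be non-negative")
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0))
    stop("fractions must be three non-negative numbers")
  if (sum(fractions) == 0) stop("at least one fraction must be positive")
  quota <- n_inh * fractions / sum(fractions)
  base <- floor(quota)
  rem <- quota - base
  short <- n_inh - sum(base)
  if (short > 0) {
    # ties broken by type order (PV, SOM, VIP) for determinism
    extra <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), c("PV", "SOM", "VIP"))
}

#' Merge per-layer VIP counts into the single L2/3 VIP population
#'
#' VIP cells are mostly found in L2/3 and connectivity data for deeper
#' layers are lacking, so the model pools all VIP cells into one L2/3
#' population.
#'
#' @param per_layer_vip_counts non-negative VIP counts per layer.
#' @return total VIP count assigned to L2/3.
#' @export
merge_vip_population <- function(per_layer_vip_counts) {
  if (any(per_layer_vip_counts < 0)) stop("counts must be non-negative")
  sum(per_layer_vip_counts)
}

param_group <- function(layer, type) {
  if (type == "VIP") return("VIP")
  grp <- if (layer %in% c("L2/3", "L4")) "L23L4" else "L5L6"
  paste0(grp, "_", type)
}

#' Assemble the population table of the column model
#'
#' Builds the 13 populations (Exc/PV/SOM per layer plus the merged L2/3
#' VIP population) with their neuron counts and LIF parameters. Interneuron
#' counts follow the apportionment rule; the VIP portions of every layer
#' are pooled into L2/3. L2/3 membrane parameters are reused for L4 and L5
#' parameters for L6.
#'
#' @param config model configuration, see [bc_config()].
#' @return data.frame with one row per population: `layer`, `type`, `n`,
#'   and the LIF parameters `tau_m`, `c_m`, `v_rest`, `v_th`, `v_reset`,
#'   `tau_ref`.
#' @export
build_population_table <- function(config = bc_config()) {
  pops <- config$populations
  fr <- config$fractions
  np <- config$neuron_params
  if (!identical(pops$layer, LAYERS)) stop("population table must list the four layers")
  vip_parts <- integer(length(LAYERS))
  rows <- list()
  for (i in seq_along(LAYERS)) {
    layer <- LAYERS[i]
    f <- fr[fr$layer == layer, c("f_pv", "f_som", "f_vip")]
    if (nrow(f) != 1) stop("missing interneuron fractions for ", layer)
    counts <- allocate_interneuron_counts(pops$n_inh[i], as.numeric(f))
    vip_parts[i] <- counts[["VIP"]]
    rows[[layer]] <- data.frame(
      layer = layer,
      type = c("Exc", "PV", "SOM"),
      n = c(pops$n_exc[i], counts[["PV"]], counts[["SOM"]]))
  }
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(layer = "L2/3", type = "VIP",
                               n = merge_vip_population(vip_parts)))
  prm <- lapply(seq_len(nrow(tab)), function(i) {
    g <- param_group(tab$layer[i], tab$type[i])
    r <- np[np$group == g, ]
    if (nrow(r) != 1) stop("missing neuron parameters for group ", g)
    red <- if (tab$type[i] == "Exc") config$rm_reduction_exc else config$rm_reduction_inh
    tau_m <- if (isTRUE(config$use_printed_tau_m)) r$tau_m_printed else
      adjust_membrane_time_constant(r$tau_m_invitro, red)
    data.frame(tau_m = tau_m, c_m = r$c_m, v_rest = r$v_rest, v_th = r$v_th)
  })
  tab <- cbind(tab, do.call(rbind, prm))
  tab$v_reset <- tab$v_rest   # no separate reset value; no adaptation
  tab$tau_ref <- TAU_REF
  ord <- order(match(tab$layer, LAYERS), match(tab$type, CELL_TYPES))
  tab <- tab[ord, ]
  rownames(tab) <- paste(tab$layer, tab$type)
  class(tab) <- c("bc_populations", "data.frame")
  tab
}

#' @export
print.bc_populations <- function(x, ...) {
  cat("Column populations:", nrow(x), "populations,", sum(x$n), "neurons\n")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Model configuration
#'
#' Loads the packaged parameter tables and returns the configuration list
#' consumed by the model-building functions. Every component can be
#' overridden via `...` (e.g. `bc_config(rm_reduction_exc = 0.4)`).
#'
#' @param ... named overrides for any configuration element.
#' @return a list of class `bc_config` with elements: `populations`,
#'   `fractions`, `neuron_params`, `synapse_classes`, `connectivity`,
#'   `thalamic_connectivity`, `stp_params`, `reference_rates`,
#'   `thalamic_profile`, `ai_criteria`, `reference_peaks`, geometry and the
#'   scalar modeling constants documented in the vignette.
#' @export
bc_config <- function(...) {
  cfg <- list(
    populations = read_table("populations.tsv"),
    fractions = read_table("interneuron_fractions.tsv"),
    neuron_params = read_table("neuron_params.tsv"),
    synapse_classes = read_table("synapse_classes.tsv"),
    connectivity = read_table("connectivity_synthetic.tsv"),
    thalamic_connectivity = read_table("thalamic_connectivity_synthetic.tsv"),
    stp_params = read_table("stp_params_synthetic.tsv"),
    reference_rates = read_table("reference_rates.tsv"),
    thalamic_profile = read_table("thalamic_profile_synthetic.tsv"),
    ai_criteria = read_table("ai_criteria_synthetic.tsv"),
    reference_peaks = read_table("reference_peaks_synthetic.tsv"),
    background_rates = read_table("background_rates_base.tsv"),
    # membrane-resistance reductions from silent to awake state
    rm_reduction_exc = 0.509,
    rm_reduction_inh = 0.049,
    use_printed_tau_m = TRUE,
    # geometry of the column footprint and lateral decay of connectivity
    surface_x = 200, surface_y = 300,      # um
    decay_length = 160,                    # um, exponential decay constant
    # thalamic input sizing
    s1_vpm_ratio = 56, thalamic_doubling = 2,
    ratio_l23_l4 = 0.2,                    # TC synapse-number ratio L2/3:L4
    som_attenuation = 0.5,                 # thalamic P and weight factor for SOM
    # dynamics
    v_init = "uniform",                    # or "rest"
    stp_variant = "decay_to_zero"          # or "decay_to_U"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(names(cfg), "background_rates"))
    if (length(bad)) stop("unknown configuration element(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "bc_config"
  cfg
}

#' @export
print.bc_config <- function(x, ...) {
  cat("barrelsim model configuration\n")
  cat("  footprint:", x$surface_x, "x", x$surface_y, "um;",
      "decay length", x$decay_length, "um\n")
  cat("  R_m reduction: exc", x$rm_reduction_exc, "/ inh", x$rm_reduction_inh, "\n")
  cat("  background rates (spikes/s):\n")
  print.data.frame(x$background_rates, row.names = FALSE)
  invisible(x)
}

# Synapse-class lookup -----------------------------------------------------

get_synapse_class <- function(config, class) {
  r <- config$synapse_classes[config$synapse_classes$class == class, ]
  if (nrow(r) != 1) stop("unknown synapse class: ", class)
  as.list(r)
}
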