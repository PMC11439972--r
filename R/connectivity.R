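# Connectivity: spatial integration of experimental connection
# probabilities, assembly of the full projection matrix, Bernoulli
# connection sampling and log-normal weight/delay draws.

# Mean of the exponential decay kernel exp(-d / lambda) over displacements
# of two points placed uniformly in a rectangle a x b. Uses the product
# triangular density of coordinate differences on a deterministic
# quadrature grid.
mean_kernel_rect <- function(a, b, lambda, n = 200) {
  dx <- (seq_len(n) - 0.5) / n * a
  dy <- (seq_len(n) - 0.5) / n * b
  fx <- 2 * (a - dx) / a^2 * (a / n)   # density x bin width
  fy <- 2 * (b - dy) / b^2 * (b / n)
  d <- sqrt(outer(dx^2, dy^2, "+"))
  sum(outer(fx, fy) * exp(-d / lambda))
}

# Same for two points uniform in a disc of radius R (known distance
# density for the unit disc, scaled).
mean_kernel_disc <- function(R, lambda, n = 2000) {
  d <- (seq_len(n) - 0.5) / n * 2 * R
  t <- d / (2 * R)
  dens <- (2 * d / R^2) * (2 / pi) * (acos(t) - t * sqrt(pmax(0, 1 - t^2)))
  sum(dens * exp(-d / lambda)) * (2 * R / n)
}

#' Derive a model connection probability from an experimental one
#'
#' Experimental pairwise connection probabilities are measured over a
#' limited lateral sampling range. Assuming connection probability decays
#' exponentially with lateral distance (decay constant
#' `geometry$decay_length`), this function rescales `p_exp` so that the
#' decay kernel averaged over the experimental sampling domain equals
#' `p_exp`, and returns the kernel average over the model footprint.
#'
#' @param p_exp experimental connection probability, fraction in `[0, 1]`.
#' @param experimental_range lateral sampling domain: a single value is the
#'   radius (um) of a disc; a length-2 vector gives the sides of a
#'   rectangle; `NA` means the value already refers to the model footprint
#'   (returned unchanged).
#' @param geometry list with `surface_x`, `surface_y`, `decay_length` (um);
#'   a full [bc_config()] works.
#' @return model connection probability, fraction in `[0, 1]`.
#' @export
derive_model_probability <- function(p_exp, experimental_range, geometry) {
  if (p_exp < 0 || p_exp > 1) stop("p_exp must be in [0, 1]")
  if (length(experimental_range) == 1 && is.na(experimental_range))
    return(p_exp)
  if (any(experimental_range <= 0)) stop("experimental range must be positive")
  lam <- geometry$decay_length
  k_model <- mean_kernel_rect(geometry$surface_x, geometry$surface_y, lam)
  k_exp <- if (length(experimental_range) == 2)
    mean_kernel_rect(experimental_range[1], experimental_range[2], lam)
  else mean_kernel_disc(experimental_range, lam)
  min(1, max(0, p_exp * k_model / k_exp))
}

#' Combine morphological-subtype connection probabilities into a cell-type value
#'
#' Morphology-based connectivity estimates distinguish finer subtypes than
#' the model's four cell types. The subtype probabilities are combined by
#' weighted averaging with the subtype cell counts: for a projection, the
#' weight of a (pre-subtype, post-subtype) entry is the product of the two
#' subtype counts (the number of cell pairs it describes).
#'
#' @param p matrix or vector of subtype connection probabilities.
#' @param n_pre,n_post subtype cell counts for the pre- and postsynaptic
#'   sides (recycled against the rows/columns of `p`).
#' @return the pooled cell-type connection probability.
#' @export
pool_subtype_probabilities <- function(p, n_pre, n_post) {
  p <- as.matrix(p)
  w <- outer(n_pre, n_post)
  if (!all(dim(w) == dim(p))) stop("counts do not match probability matrix")
  sum(w * p) / sum(w)
}

#' Assemble the full projection probability matrix
#'
#' Completes the packaged experimental/estimated entries with the model's
#' fill-in rules and returns one row per projection:
#' * intra-layer `Exc -> PV` missing in a layer: set equal to `PV -> Exc`
#'   (reciprocity of Exc-PV pairs);
#' * L5 `Exc -> SOM`, `SOM -> Exc`, `SOM -> SOM` missing: averages of the
#'   L2/3 and L4 entries;
#' * L6 intra-layer entries other than `Exc -> Exc`: copied from L5;
#' * entries with a recorded experimental sampling range are re-integrated
#'   over the model footprint via [derive_model_probability()];
#' * thalamic rows: Exc and PV in all layers, with L2/3 = L4 x the
#'   configured L2/3-to-L4 synapse ratio; SOM targeted only in L4 at the
#'   configured attenuation (default 50%) of the L4 Exc value; VIP never
#'   targeted.
#'
#' @param config model configuration, see [bc_config()].
#' @return data.frame of class `bc_projection_matrix` with columns
#'   `source_layer`, `source_type`, `target_layer`, `target_type`,
#'   `p_exp` (percent), `p` (fraction), `provenance`.
#' @export
assemble_probability_matrix <- function(config = bc_config()) {
  tab <- config$connectivity
  key <- function(sl, st, tl, tt) paste(sl, st, tl, tt, sep = "|")
  tab$k <- key(tab$source_layer, tab$source_type, tab$target_layer, tab$target_type)
  if (anyDuplicated(tab$k)) stop("duplicated connectivity entries")
  get <- function(sl, st, tl, tt) {
    i <- match(key(sl, st, tl, tt), tab$k)
    if (is.na(i)) NULL else tab[i, ]
  }
  add <- function(sl, st, tl, tt, p_exp, prov) {
    tab <<- rbind(tab, data.frame(
      source_layer = sl, source_type = st, target_layer = tl,
      target_type = tt, p_exp = p_exp, range_um = NA_real_,
      provenance = prov, k = key(sl, st, tl, tt)))
  }
  # (1) Exc<->PV reciprocity where Exc->PV is missing
  for (l in LAYERS) {
    if (is.null(get(l, "Exc", l, "PV"))) {
      pe <- get(l, "PV", l, "Exc")
      if (!is.null(pe))   # L6 is instead completed from L5 below
        add(l, "Exc", l, "PV", pe$p_exp, "assumption:reciprocity")
    }
  }
  # (2) L5 SOM-related entries as L2/3-L4 averages
  for (pr in list(c("Exc", "SOM"), c("SOM", "Exc"), c("SOM", "SOM"))) {
    if (is.null(get("L5", pr[1], "L5", pr[2]))) {
      v <- c(get("L2/3", pr[1], "L2/3", pr[2])$p_exp,
             get("L4", pr[1], "L4", pr[2])$p_exp)
      if (length(v) != 2) stop("missing L2/3 or L4 entry for L5 average")
      add("L5", pr[1], "L5", pr[2], mean(v), "assumption:L2/3-L4-average")
    }
  }
  # (3) L6 intra-layer non-Exc->Exc entries copied from L5
  for (st in c("Exc", "PV", "SOM")) for (tt in c("Exc", "PV", "SOM")) {
    if (st == "Exc" && tt == "Exc") next
    if (is.null(get("L6", st, "L6", tt))) {
      src <- get("L5", st, "L5", tt)
      if (is.null(src)) stop("missing L5 counterpart for L6 ", st, "->", tt)
      add("L6", st, "L6", tt, src$p_exp, "assumption:copied-from-L5")
    }
  }
  # completeness: all ordered population pairs must now be present
  pops <- expand.grid(layer = LAYERS, type = c("Exc", "PV", "SOM"),
                      stringsAsFactors = FALSE)
  pops <- rbind(pops, data.frame(layer = "L2/3", type = "VIP"))
  all_k <- as.vector(outer(paste(pops$layer, pops$type, sep = "|"),
                           paste(pops$layer, pops$type, sep = "|"),
                           function(a, b) paste(a, b, sep = "|")))
  missing <- setdiff(all_k, tab$k)
  if (length(missing))
    stop("projection matrix incomplete after assembly: ",
         paste(utils::head(missing, 5), collapse = "; "))
  # spatial integration where an experimental range is recorded
  tab$p <- vapply(seq_len(nrow(tab)), function(i) {
    derive_model_probability(tab$p_exp[i] / 100, tab$range_um[i], config)
  }, numeric(1))
  # thalamic rows
  th <- config$thalamic_connectivity
  l4 <- function(tt) th$p[th$layer == "L4" & th$type == tt]
  th_rows <- rbind(
    th[, c("layer", "type", "p")],
    data.frame(layer = "L2/3", type = c("Exc", "PV"),
               p = c(l4("Exc"), l4("PV")) * config$ratio_l23_l4),
    data.frame(layer = "L4", type = "SOM",
               p = l4("Exc") * config$som_attenuation))
  tab <- rbind(tab[, c("source_layer", "source_type", "target_layer",
                       "target_type", "p_exp", "p", "provenance")],
               data.frame(source_layer = "TH", source_type = "Exc_th",
                          target_layer = th_rows$layer,
                          target_type = th_rows$type,
                          p_exp = th_rows$p, p = th_rows$p / 100,
                          provenance = "thalamic"))
  rownames(tab) <- NULL
  class(tab) <- c("bc_projection_matrix", "data.frame")
  tab
}

#' @export
print.bc_projection_matrix <- function(x, ...) {
  intra <- x$source_layer == x$target_layer
  th <- x$source_type == "Exc_th"
  cat("Projection matrix:", sum(intra & !th), "intra-layer,",
      sum(!intra & !th), "inter-layer,", sum(th), "thalamic projections\n")
  invisible(x)
}

#' Write the assembled probability matrix as a delimited table
#'
#' Exports the projection matrix in a wide source-by-target layout
#' (percent) for inspection, alongside the long-format provenance table.
#'
#' @param matrix result of [assemble_probability_matrix()].
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
export_probability_matrix <- function(matrix, path) {
  m <- matrix[matrix$source_type != "Exc_th", ]
  src <- paste(m$source_layer, m$source_type)
  tgt <- paste(m$target_layer, m$target_type)
  u <- unique(c(src, tgt))
  wide <- matrix(0, length(u), length(u), dimnames = list(u, u))
  wide[cbind(src, tgt)] <- round(m$p * 100, 2)
  utils::write.table(wide, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Sample pairwise Bernoulli connections for one projection
#'
#' Every ordered (pre, post) pair is connected independently with
#' probability `p`; at most one synapse per ordered pair (no multapses);
#' self-connections (autapses) are permitted when the projection is within
#' one population.
#'
#' @param p connection probability, fraction.
#' @param n_src,n_tgt source and target population sizes.
#' @param same_population logical; if `TRUE` pre and post index the same
#'   cells and autapses are allowed (they are not excluded either way,
#'   matching the pairwise Bernoulli contract).
#' @param seed optional integer seed (applied via [set.seed()]); if `NULL`
#'   the current RNG stream is used.
#' @return data.frame with integer columns `pre`, `post` (1-based).
#' @export
sample_connections <- function(p, n_src, n_tgt, same_population = FALSE,
                               seed = NULL) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (p == 0 || n_src == 0 || n_tgt == 0)
    return(data.frame(pre = integer(), post = integer()))
  hit <- which(runif(n_src * n_tgt) < p)
  data.frame(pre = as.integer((hit - 1) %% n_src + 1),
             post = as.integer((hit - 1) %/% n_src + 1))
}

# moment-matched log-normal parameters from linear-space mean m > 0, sd s
lnorm_params <- function(m, s) {
  if (m <= 0) stop("log-normal mean must be positive")
  sig2 <- log(1 + (s / m)^2)
  list(mu = log(m) - sig2 / 2, sigma = sqrt(sig2))
}

#' Draw synaptic weights and delays for one synapse class
#'
#' PSP magnitudes are log-normal with the class's linear-space mean and SD
#' (moment matched), the class sign is applied, and the PSP is converted to
#' a PSC amplitude (pA) with the target neuron's membrane parameters via
#' [psp_to_psc()]. Delays are log-normal with the class's mean and SD,
#' rounded to the simulation grid with a minimum of one step. Classes with
#' zero SD (the background input) return fixed values.
#'
#' @param synapse_class a row of the synapse-class table as a list (see
#'   `bc_config()$synapse_classes`), or a class name plus `config`.
#' @param target_params list/row with the target's `c_m` and `tau_m`.
#' @param n number of draws.
#' @param config configuration used to resolve a class given by name.
#' @return list with numeric vectors `w` (pA, signed) and `d` (ms).
#' @export
draw_synaptic_parameters <- function(synapse_class, target_params, n = 1,
                                     config = NULL) {
  if (is.character(synapse_class)) {
    if (is.null(config)) config <- bc_config()
    synapse_class <- get_synapse_class(config, synapse_class)
  }
  sc <- synapse_class
  if (sc$delay_mean <= 0) stop("delay mean must be positive")
  psp <- if (sc$psp_sd == 0) rep(sc$psp_mean, n) else {
    lp <- lnorm_params(abs(sc$psp_mean), sc$psp_sd)
    rlnorm(n, lp$mu, lp$sigma)
  }
  w <- sc$sign * psp_to_psc(abs(psp), target_params$c_m, target_params$tau_m,
                            sc$tau_syn)
  d <- if (sc$delay_sd == 0) rep(sc$delay_mean, n) else {
    lp <- lnorm_params(sc$delay_mean, sc$delay_sd)
    rlnorm(n, lp$mu, lp$sigma)
  }
  d <- pmax(1, round(d / SIM_RESOLUTION)) * SIM_RESOLUTION
  list(w = w, d = d)
}
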