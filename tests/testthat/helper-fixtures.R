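# Shared test fixtures: configuration, populations and a cheap toy network.
bc_test_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- bc_config()
    cfg
  }
})

bc_test_pops <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- build_population_table(bc_test_config())
    p
  }
})

# exact Tsodyks release recursion, written independently of the package
# implementation (array recursion instead of stateful updates)
oracle_release <- function(U, F, D, times) {
  n <- length(times)
  u <- numeric(n); x <- numeric(n); rel <- numeric(n)
  u_prev <- 0; x_prev <- 1; t_prev <- -Inf
  for (k in seq_len(n)) {
    dt <- times[k] - t_prev
    ef <- if (F > 0 && is.finite(dt)) exp(-dt / F) else 0
    ed <- if (D > 0 && is.finite(dt)) exp(-dt / D) else 0
    uk <- u_prev * ef
    xk <- 1 - (1 - x_prev) * ed
    uk <- uk + U * (1 - uk)
    rel[k] <- uk * xk
    x_prev <- xk * (1 - uk)
    u_prev <- uk
    t_prev <- times[k]
  }
  rel
}
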