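# Independent oracles and fixture builders, deliberately naive:
# direct unshifted summation, no sharing with the package internals.

RT_298 <- 1.987204e-3 * 298.15

bw_direct <- function(b, rt = RT_298) -rt * log(mean(exp(-b / rt)))

de_direct <- function(b, rt = RT_298) {
  full <- bw_direct(b, rt)
  100 * (bw_direct(b[-which.min(b)], rt) - full) / full
}

# random positive-barrier ensemble on a typical chemical range
rand_ensemble <- function(n, lo = 1, hi = 50) {
  barrier_ensemble(runif(n, lo, hi))
}

# hand-built trace with a prescribed change series (values are irrelevant
# to converged_after beyond the changes they induce)
trace_from_values <- function(values, metric = "relative",
                              floor = 1e-8, start_n = 1L) {
  ns <- seq.int(start_n, start_n + length(values) - 1L)
  diffs <- abs(diff(values))
  prev <- values[-length(values)]
  ch <- if (metric == "relative") 100 * diffs / pmax(abs(prev), floor) else diffs
  structure(list(statistic = "boltzmann_average",
                 points = data.frame(n = ns, value = values),
                 changes = data.frame(n = ns[-1L], change = ch),
                 metric = metric, converged_after = NA_integer_),
            class = "convergence_trace")
}
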