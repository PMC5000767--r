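#' Windowed convergence rule for running barrier statistics
#'
#' A running statistic (Boltzmann-weighted average or disproportionate
#' effect, tracked as conformations accrue in sampling order) is declared
#' converged at prefix length \eqn{n^*} when the changes produced by the
#' next \code{window} additions all stay strictly below \code{threshold}.
#' Requiring a full window of subsequent stability prevents declaring
#' convergence to an incorrect value on a momentarily quiet series.
#'
#' @param threshold Maximum allowed change, in percent for the
#'   \code{"relative"} metric or in the statistic's own units for
#'   \code{"absolute"}.  Non-negative; default 5.  A threshold of 0 gives a
#'   rule that can never fire (changes must be strictly below it), useful
#'   for forcing exhaustive evaluation.
#' @param window Number of consecutive sub-threshold changes required
#'   (>= 1); default 5.
#' @param metric \code{"relative"} (percent change versus the previous
#'   value, the default) or \code{"absolute"} (plain difference).
#' @param denominator_floor Lower bound on the denominator of the relative
#'   change, in the statistic's units, protecting against division by a
#'   near-zero previous value (relevant for the disproportionate effect,
#'   which can approach 0).  Default \code{1e-8}.
#' @param semantics Which prefix length is reported: \code{"window_start"}
#'   (default) reports the length \eqn{n^*} whose estimate the subsequent
#'   window confirms; \code{"window_end"} reports \eqn{n^* +}
#'   \code{window}, the length at which confirmation completes.
#'
#' @return An object of class \code{convergence_rule}.
#' @examples
#' convergence_rule()                      # 5% over 5 consecutive additions
#' convergence_rule(threshold = 2, window = 10)
#' @export
convergence_rule <- function(threshold = 5, window = 5,
                             metric = c("relative", "absolute"),
                             denominator_floor = 1e-8,
                             semantics = c("window_start", "window_end")) {
  metric <- match.arg(metric)
  semantics <- match.arg(semantics)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0) {
    stop("invalid convergence rule: threshold must be finite and >= 0",
         call. = FALSE)
  }
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
      window < 1 || window != floor(window)) {
    stop("invalid convergence rule: window must be an integer >= 1",
         call. = FALSE)
  }
  if (!is.numeric(denominator_floor) || length(denominator_floor) != 1L ||
      !is.finite(denominator_floor) || denominator_floor <= 0) {
    stop("invalid convergence rule: denominator_floor must be > 0",
         call. = FALSE)
  }
  structure(
    list(threshold = as.numeric(threshold), window = as.integer(window),
         metric = metric, denominator_floor = as.numeric(denominator_floor),
         semantics = semantics),
    class = "convergence_rule"
  )
}

#' @export
print.convergence_rule <- function(x, ...) {
  unit <- if (x$metric == "relative") "%" else " (absolute)"
  cat(sprintf("Convergence rule: change < %g%s over %d consecutive additions (%s)\n",
              x$threshold, unit, x$window, x$semantics))
  invisible(x)
}

#' Running (prefix) statistic over conformations in sampling order
#'
#' For each prefix of the ensemble's records, computes the chosen statistic
#' over the first \eqn{n} conformations, together with the step-to-step
#' change used by the convergence rule.  The Boltzmann-average trace starts
#' at \eqn{n = 1}; the disproportionate-effect trace starts at \eqn{n = 2},
#' the first prefix on which it is defined.
#'
#' @param ensemble A \code{\link{barrier_ensemble}}.
#' @param statistic \code{"boltzmann_average"} or
#'   \code{"disproportionate_effect"}.
#' @param thermal A \code{\link{thermal_context}}.
#' @param rule A \code{\link{convergence_rule}} supplying the change metric
#'   and denominator floor (its threshold/window are not consulted here).
#' @return An object of class \code{convergence_trace}: a list with
#'   \code{statistic}, \code{points} (data frame \code{n}, \code{value}),
#'   \code{changes} (data frame \code{n}, \code{change}; one fewer row than
#'   \code{points}), \code{metric} and \code{converged_after}
#'   (\code{NA} until \code{\link{converged_after}} is applied).
#' @examples
#' e <- barrier_ensemble(c(10, 20, 12, 11))
#' running_statistic(e, "boltzmann_average")
#' @export
running_statistic <- function(ensemble,
                              statistic = c("boltzmann_average",
                                            "disproportionate_effect"),
                              thermal = thermal_context(),
                              rule = convergence_rule()) {
  stopifnot(inherits(ensemble, "barrier_ensemble"))
  validate_barrier_ensemble(ensemble)
  statistic <- match.arg(statistic)
  thermal <- as_thermal_context(thermal)
  stopifnot(inherits(rule, "convergence_rule"))
  b <- ensemble$barrier
  n_total <- length(b)
  n_min <- if (statistic == "boltzmann_average") 1L else 2L
  if (n_total < n_min) {
    stop(sprintf("too few records: %s requires at least %d conformation(s)",
                 statistic, n_min), call. = FALSE)
  }
  ns <- seq.int(n_min, n_total)
  f <- if (statistic == "boltzmann_average") {
    function(k) boltzmann_average_raw(b[seq_len(k)], thermal$rt)
  } else {
    function(k) disproportionate_effect_raw(b[seq_len(k)], thermal$rt)
  }
  values <- vapply(ns, f, numeric(1))
  changes <- if (length(values) > 1L) {
    prev <- values[-length(values)]
    diffs <- abs(diff(values))
    if (rule$metric == "relative") {
      100 * diffs / pmax(abs(prev), rule$denominator_floor)
    } else {
      diffs
    }
  } else {
    numeric(0)
  }
  structure(
    list(statistic = statistic,
         points = data.frame(n = ns, value = values),
         changes = data.frame(n = ns[-1L], change = changes),
         metric = rule$metric,
         converged_after = NA_integer_),
    class = "convergence_trace"
  )
}

#' @export
print.convergence_trace <- function(x, ...) {
  cat(sprintf("Convergence trace of %s (%s changes): %d point(s)\n",
              x$statistic, x$metric, nrow(x$points)))
  if (is.na(x$converged_after)) {
    cat("converged_after: not evaluated or not converged\n")
  } else {
    cat(sprintf("converged_after: %d conformations\n", x$converged_after))
  }
  df <- merge(x$points, x$changes, by = "n", all.x = TRUE)
  print.data.frame(df, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Apply the windowed convergence rule to a trace
#'
#' Finds the smallest prefix length \eqn{n^*} such that the \code{window}
#' consecutive changes recorded at steps \eqn{n^*+1, \ldots, n^*+window}
#' all fall strictly below the rule's threshold.  Under
#' \code{"window_end"} semantics the reported count is \eqn{n^* + window}
#' instead.  A trace too short to host a full window after any candidate
#' returns \code{NA} -- never a guess.
#'
#' @param trace A \code{convergence_trace} from
#'   \code{\link{running_statistic}}.
#' @param rule A \code{\link{convergence_rule}}.
#' @return The converged-after conformation count (integer), or
#'   \code{NA_integer_} if the trace never satisfies the rule.
#' @examples
#' e <- barrier_ensemble(rep(15, 8))
#' tr <- running_statistic(e, "boltzmann_average")
#' converged_after(tr)   # 1: constant from the first point on
#' @export
converged_after <- function(trace, rule = convergence_rule()) {
  stopifnot(inherits(trace, "convergence_trace"),
            inherits(rule, "convergence_rule"))
  ch <- trace$changes$change
  ns <- trace$points$n
  w <- rule$window
  n_candidates <- length(ch) - w + 1L   # candidate window start positions
  if (n_candidates >= 1L) {
    below <- ch < rule$threshold
    for (i in seq_len(n_candidates)) {
      if (all(below[i:(i + w - 1L)])) {
        # window i..i+w-1 covers the changes made at steps ns[i+1]..ns[i+w];
        # the estimate confirmed is the one at ns[i]
        n_star <- ns[i]
        if (rule$semantics == "window_end") n_star <- ns[i + w]
        return(as.integer(n_star))
      }
    }
  }
  NA_integer_
}

#' Combined convergence of both criteria
#'
#' Evaluates the windowed rule on the Boltzmann-average trace and on the
#' disproportionate-effect trace of the same ensemble and returns the
#' larger of the two converged-after counts -- the smallest sample size at
#' which both criteria are satisfied.  Returns \code{NA} if either
#' criterion never converges within the ensemble.
#'
#' @param ensemble A \code{\link{barrier_ensemble}} with >= 2 records.
#' @param rule A \code{\link{convergence_rule}}.
#' @param thermal A \code{\link{thermal_context}}.
#' @return Integer count, or \code{NA_integer_}.
#' @examples
#' e <- barrier_ensemble(rep(12, 8))
#' combined_converged_after(e)   # 2: the DE trace only starts at n = 2
#' @export
combined_converged_after <- function(ensemble, rule = convergence_rule(),
                                     thermal = thermal_context()) {
  stopifnot(inherits(ensemble, "barrier_ensemble"))
  if (nrow(ensemble) < 2L) stop("DE undefined for n < 2", call. = FALSE)
  ca_bwa <- converged_after(
    running_statistic(ensemble, "boltzmann_average", thermal, rule), rule)
  ca_de <- converged_after(
    running_statistic(ensemble, "disproportionate_effect", thermal, rule), rule)
  if (is.na(ca_bwa) || is.na(ca_de)) return(NA_integer_)
  max(ca_bwa, ca_de)
}

#' Sensitivity of the convergence count to MD sampling order
#'
#' The converged-after count depends on the order in which conformations
#' happen to be drawn from the trajectory.  This applies
#' \code{\link{combined_converged_after}} to seeded random permutations of
#' the ensemble's records and returns the resulting multiset of counts.
#'
#' @param ensemble A \code{\link{barrier_ensemble}} with >= 2 records.
#' @param rule A \code{\link{convergence_rule}}.
#' @param thermal A \code{\link{thermal_context}}.
#' @param n_permutations Number of random permutations (>= 1).
#' @param seed Integer seed; the full stream of permutations is a pure
#'   function of it (the caller's RNG state is left untouched).
#' @return Integer vector of length \code{n_permutations};
#'   \code{NA} entries mark permutations under which the rule never fires.
#' @export
ordering_sensitivity <- function(ensemble, rule = convergence_rule(),
                                 thermal = thermal_context(),
                                 n_permutations = 100, seed = 1) {
  stopifnot(inherits(ensemble, "barrier_ensemble"))
  if (!is.numeric(n_permutations) || length(n_permutations) != 1L ||
      !is.finite(n_permutations) || n_permutations < 1 ||
      n_permutations != floor(n_permutations)) {
    stop("n_permutations must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != floor(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  n <- nrow(ensemble)
  with_local_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(j) {
      idx <- sample.int(n)
      perm <- ensemble[idx, , drop = FALSE]
      attr(perm, "system_label") <- attr(ensemble, "system_label")
      attr(perm, "qm_region") <- attr(ensemble, "qm_region")
      class(perm) <- class(ensemble)
      combined_converged_after(perm, rule, thermal)
    }, integer(1))
  })
}

# Run code under a temporary RNG seed, restoring the caller's state.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
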