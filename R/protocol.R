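#' Computational cost model for hierarchical screening
#'
#' Pre-screening evaluates every conformation with a cheap small QM region,
#' then only a subset with the expensive big QM region.  Costs are measured
#' in big-QM-evaluation equivalents: one small-QM evaluation costs
#' \code{relative_cost} of one big-QM evaluation.
#'
#' @param relative_cost Cost of one small-QM evaluation relative to one
#'   big-QM evaluation, in \eqn{(0, 1]}.  Default 0.1.
#' @param baseline_big_evaluations Number of big-QM evaluations the
#'   protocol is compared against (the no-screening baseline).  Default
#'   \code{NULL}: use the ensemble size at the point of use.
#' @return An object of class \code{cost_model}.
#' @examples
#' cost_model()                    # small QM at 10% of big-QM cost
#' cost_model(0.25, baseline_big_evaluations = 18)
#' @export
cost_model <- function(relative_cost = 0.1, baseline_big_evaluations = NULL) {
  if (!is.numeric(relative_cost) || length(relative_cost) != 1L ||
      !is.finite(relative_cost) || relative_cost < 0 || relative_cost > 1) {
    stop("invalid cost model: relative_cost must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(baseline_big_evaluations)) {
    if (!is.numeric(baseline_big_evaluations) ||
        length(baseline_big_evaluations) != 1L ||
        !is.finite(baseline_big_evaluations) ||
        baseline_big_evaluations <= 0) {
      stop("invalid cost model: baseline must be > 0", call. = FALSE)
    }
    baseline_big_evaluations <- as.numeric(baseline_big_evaluations)
  }
  structure(list(relative_cost = as.numeric(relative_cost),
                 baseline_big_evaluations = baseline_big_evaluations),
            class = "cost_model")
}

#' Percent computational cost saved by pre-screening
#'
#' \deqn{100 \times \frac{baseline - (n_{small} \cdot c + n_{big})}
#' {baseline}}{100 (baseline - (n_small c + n_big)) / baseline}
#' where \eqn{c} is the small:big relative cost.  May be negative: a
#' protocol that pre-screens everything and still evaluates most big-QM
#' barriers costs more than the no-screening baseline.
#'
#' @param cost A \code{\link{cost_model}}; its
#'   \code{baseline_big_evaluations} must be set (or supply
#'   \code{baseline}).
#' @param n_small_prescreened Number of small-QM evaluations performed
#'   (>= 0).
#' @param n_big_evaluated Number of big-QM evaluations performed (>= 0).
#' @param baseline Overrides the cost model's baseline.
#' @return Savings in percent of the baseline cost.
#' @examples
#' cost_savings(cost_model(0.1), 20, 8, baseline = 20)   # 50
#' @export
cost_savings <- function(cost, n_small_prescreened, n_big_evaluated,
                         baseline = cost$baseline_big_evaluations) {
  stopifnot(inherits(cost, "cost_model"))
  if (is.null(baseline) || !is.numeric(baseline) || length(baseline) != 1L ||
      !is.finite(baseline) || baseline <= 0) {
    stop("invalid cost model: baseline must be > 0", call. = FALSE)
  }
  if (n_small_prescreened < 0 || n_big_evaluated < 0) {
    stop("evaluation counts must be >= 0", call. = FALSE)
  }
  total <- n_small_prescreened * cost$relative_cost + n_big_evaluated
  100 * (baseline - total) / baseline
}

#' Rank conformations by their small-QM barrier
#'
#' Orders conformation ids ascending by the cheap small-QM barrier (lowest
#' first), the order in which the screening protocol spends expensive
#' big-QM evaluations.  Ties keep sampling order (stable sort), so the
#' ranking is deterministic.
#'
#' @param paired A \code{\link{paired_ensemble}}.
#' @return Character vector of conformation ids, lowest small-QM barrier
#'   first.
#' @examples
#' p <- paired_ensemble(barrier_small = c(20, 18, 19),
#'                      barrier_big = c(16, 15, 17),
#'                      conformation_id = c("a", "b", "c"))
#' rank_by_small(p)   # "b" "c" "a"
#' @export
rank_by_small <- function(paired) {
  stopifnot(inherits(paired, "paired_ensemble"))
  validate_paired_ensemble(paired)
  paired$conformation_id[order(paired$barrier_small)]  # stable radix/shell
}

#' Correlation of small-QM and big-QM barriers
#'
#' Rank (Spearman) correlation between the per-conformation barriers of
#' the two QM-region sizes, with average-rank treatment of ties; the
#' screening protocol is profitable when this is positive.  Linear
#' (Pearson) correlation is available as an option.
#'
#' @param paired A \code{\link{paired_ensemble}} with >= 3 pairs.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return Correlation coefficient in \eqn{[-1, 1]}.
#' @examples
#' p <- paired_ensemble(barrier_small = c(18, 20, 22),
#'                      barrier_big = c(14, 15, 19))
#' barrier_correlation(p)   # 1: perfectly monotone
#' @export
barrier_correlation <- function(paired, method = c("spearman", "pearson")) {
  stopifnot(inherits(paired, "paired_ensemble"))
  method <- match.arg(method)
  if (nrow(paired) < 3L) {
    stop("correlation requires at least 3 pairs", call. = FALSE)
  }
  if (stats::sd(paired$barrier_small) == 0 ||
      stats::sd(paired$barrier_big) == 0) {
    stop("undefined correlation: zero variance on one side", call. = FALSE)
  }
  stats::cor(paired$barrier_small, paired$barrier_big, method = method)
}

#' Run the ranked small-QM to big-QM screening protocol
#'
#' Consumes big-QM barriers in \code{\link{rank_by_small}} order (lowest
#' small-QM barrier first).  After each big-QM evaluation the
#' Boltzmann-average and disproportionate-effect convergence criteria are
#' re-evaluated over the big-QM barriers evaluated so far, and evaluation
#' stops at the first count at which
#' \code{\link{combined_converged_after}} succeeds on that sequence.  If
#' the rule never fires, all conformations are evaluated and
#' \code{converged = FALSE}; the final averages then equal the full-set
#' values.
#'
#' Convergence inside the protocol is judged on the ranked evaluation
#' order -- the only sequence that exists as evaluations accrue -- which by
#' design differs from MD sampling order.
#'
#' @param paired A \code{\link{paired_ensemble}}.
#' @param rule A \code{\link{convergence_rule}}.
#' @param thermal A \code{\link{thermal_context}}.
#' @param cost A \code{\link{cost_model}}; a \code{NULL} baseline defaults
#'   to the ensemble size.
#' @return An object of class \code{protocol_result}: list with
#'   \code{evaluation_order} (all ids, ranked), \code{n_big_evaluated},
#'   \code{converged}, \code{converged_after} (the count the rule
#'   confirmed, \code{NA} if exhausted), \code{final_boltzmann_average},
#'   \code{final_disproportionate_effect}, \code{total_cost} (big-QM
#'   evaluation equivalents), \code{savings} (percent), \code{n_pairs}.
#' @examples
#' p <- paired_ensemble(barrier_small = rep(20, 8), barrier_big = rep(15, 8))
#' run_protocol(p)$n_big_evaluated   # 7: first count hosting a full window
#' @export
run_protocol <- function(paired, rule = convergence_rule(),
                         thermal = thermal_context(), cost = cost_model()) {
  stopifnot(inherits(paired, "paired_ensemble"),
            inherits(rule, "convergence_rule"),
            inherits(cost, "cost_model"))
  validate_paired_ensemble(paired)
  thermal <- as_thermal_context(thermal)
  n <- nrow(paired)
  ord_ids <- rank_by_small(paired)
  ord_idx <- match(ord_ids, paired$conformation_id)
  big <- paired$barrier_big[ord_idx]

  n_big <- n
  converged <- FALSE
  conv_count <- NA_integer_
  for (m in 2:max(2L, n)) {
    if (m > n) break
    sub <- barrier_ensemble(big[seq_len(m)],
                            conformation_id = ord_ids[seq_len(m)],
                            sample_time = paired$sample_time[ord_idx[seq_len(m)]],
                            system_label = attr(paired, "system_label"),
                            qm_region = "big")
    cc <- combined_converged_after(sub, rule, thermal)
    if (!is.na(cc)) {
      n_big <- m
      converged <- TRUE
      conv_count <- cc
      break
    }
  }

  evaluated <- barrier_ensemble(big[seq_len(n_big)],
                                conformation_id = ord_ids[seq_len(n_big)],
                                system_label = attr(paired, "system_label"),
                                qm_region = "big")
  baseline <- if (is.null(cost$baseline_big_evaluations)) n else
    cost$baseline_big_evaluations
  total_cost <- n * cost$relative_cost + n_big
  structure(
    list(evaluation_order = ord_ids,
         n_big_evaluated = as.integer(n_big),
         converged = converged,
         converged_after = conv_count,
         final_boltzmann_average = boltzmann_average(evaluated, thermal),
         final_disproportionate_effect =
           if (n_big >= 2L) disproportionate_effect(evaluated, thermal)
           else NA_real_,
         total_cost = total_cost,
         savings = 100 * (baseline - total_cost) / baseline,
         n_pairs = as.integer(n),
         baseline = baseline),
    class = "protocol_result"
  )
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("Screening protocol over %d conformation pairs\n", x$n_pairs))
  cat(sprintf("  big-QM evaluations: %d (%s)\n", x$n_big_evaluated,
              if (x$converged) sprintf("converged, rule fired at n = %d",
                                       x$converged_after)
              else "not converged; all evaluated"))
  cat(sprintf("  Boltzmann-weighted average: %.4g kcal/mol\n",
              x$final_boltzmann_average))
  cat(sprintf("  disproportionate effect: %.4g %%\n",
              x$final_disproportionate_effect))
  cat(sprintf("  total cost: %.3g big-QM equivalents; savings %.3g%% of baseline %g\n",
              x$total_cost, x$savings, x$baseline))
  invisible(x)
}
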