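#' Boltzmann-weighted (exponential) average barrier
#'
#' Computes \deqn{\Delta E = -RT \,\ln\Big[\frac{1}{n}\sum_{i=1}^{n}
#' \exp(-\Delta E_i / RT)\Big]}{dE = -RT ln[(1/n) sum exp(-dE_i/RT)]}
#' over the barriers of an ensemble.  Low-barrier conformations dominate
#' this average, which is why it is preferred over the arithmetic mean for
#' rate-determining barriers from multiple conformations.
#'
#' Evaluation shifts all barriers by the ensemble minimum before
#' exponentiation (log-sum-exp), so barriers of several hundred kcal/mol do
#' not underflow.  The result always lies between the minimum barrier and
#' the arithmetic mean (Jensen's inequality), approaching the minimum as
#' \eqn{T \to 0} and the mean as \eqn{T \to \infty}.
#'
#' @param ensemble A \code{\link{barrier_ensemble}}.
#' @param thermal A \code{\link{thermal_context}} (or a bare temperature in
#'   kelvin).  Default 298.15 K.
#' @return The average barrier in kcal/mol.
#' @examples
#' e <- barrier_ensemble(c(10, 20))
#' boltzmann_average(e)          # ~10.41, pulled toward the low barrier
#' arithmetic_average(e)         # 15
#' @seealso \code{\link{arithmetic_average}},
#'   \code{\link{disproportionate_effect}}
#' @export
boltzmann_average <- function(ensemble, thermal = thermal_context()) {
  stopifnot(inherits(ensemble, "barrier_ensemble"))
  validate_barrier_ensemble(ensemble)
  thermal <- as_thermal_context(thermal)
  boltzmann_average_raw(ensemble$barrier, thermal$rt)
}

# log-sum-exp on a bare numeric vector; callers guarantee validity
boltzmann_average_raw <- function(b, rt) {
  m <- min(b)
  m - rt * log(mean(exp(-(b - m) / rt)))
}

#' Arithmetic average barrier
#'
#' The direct mean \eqn{(1/n)\sum_i \Delta E_i} of the ensemble's barriers,
#' provided for comparison with \code{\link{boltzmann_average}}.  It is
#' always greater than or equal to the Boltzmann-weighted average, with
#' equality only when all barriers coincide.
#'
#' @inheritParams boltzmann_average
#' @return The mean barrier in kcal/mol.
#' @export
arithmetic_average <- function(ensemble) {
  stopifnot(inherits(ensemble, "barrier_ensemble"))
  validate_barrier_ensemble(ensemble)
  mean(ensemble$barrier)
}

#' Disproportionate effect of the lowest-barrier conformation
#'
#' With few sampled conformations, a single anomalously low barrier can
#' dominate the Boltzmann-weighted average.  The disproportionate effect
#' quantifies this as
#' \deqn{DE = \frac{\Delta E^{a-l} - \Delta E^{a}}{\Delta E^{a}} \times
#' 100\%}{DE = 100 (dE[a-l] - dE[a]) / dE[a]}
#' where \eqn{\Delta E^{a}} is the Boltzmann-weighted average over all
#' conformations and \eqn{\Delta E^{a-l}} the same average with the single
#' lowest-barrier conformation excluded (ties: the earliest such
#' conformation in sampling order is dropped).  A large \eqn{DE} flags
#' under-sampling; it is non-negative by construction.
#'
#' @inheritParams boltzmann_average
#' @return The disproportionate effect in percent.
#' @examples
#' disproportionate_effect(barrier_ensemble(c(10, 20)))   # ~92%
#' disproportionate_effect(barrier_ensemble(c(10, 10, 20)))  # damped
#' @export
disproportionate_effect <- function(ensemble, thermal = thermal_context()) {
  stopifnot(inherits(ensemble, "barrier_ensemble"))
  validate_barrier_ensemble(ensemble)
  if (nrow(ensemble) < 2L) stop("DE undefined for n < 2", call. = FALSE)
  thermal <- as_thermal_context(thermal)
  disproportionate_effect_raw(ensemble$barrier, thermal$rt)
}

disproportionate_effect_raw <- function(b, rt) {
  full <- boltzmann_average_raw(b, rt)
  drop <- boltzmann_average_raw(b[-which.min(b)], rt)
  100 * (drop - full) / full
}
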