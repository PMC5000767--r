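#' Thermal context for Boltzmann weighting
#'
#' Bundles the absolute temperature and the gas constant that enter the
#' Boltzmann-weighted average through the thermal energy \eqn{RT}.
#'
#' @param temperature Absolute temperature in kelvin; strictly positive and
#'   finite.  Default 298.15 K (standard laboratory conditions).
#' @param gas_constant Gas constant in kcal/(mol K).  Default
#'   \code{1.987204e-3}.
#'
#' @return An object of class \code{thermal_context}: a list with elements
#'   \code{temperature}, \code{gas_constant} and \code{rt} (their product,
#'   kcal/mol).
#' @examples
#' thermal_context()           # 298.15 K
#' thermal_context(310)        # physiological
#' @export
thermal_context <- function(temperature = 298.15, gas_constant = 1.987204e-3) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0 ||
      !is.numeric(gas_constant) || length(gas_constant) != 1L ||
      !is.finite(gas_constant) || gas_constant <= 0) {
    stop("invalid thermal context: temperature and gas constant must be ",
         "finite and strictly positive", call. = FALSE)
  }
  structure(
    list(temperature = as.numeric(temperature),
         gas_constant = as.numeric(gas_constant),
         rt = as.numeric(temperature) * as.numeric(gas_constant)),
    class = "thermal_context"
  )
}

as_thermal_context <- function(x) {
  if (inherits(x, "thermal_context")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(thermal_context(x))
  stop("invalid thermal context", call. = FALSE)
}

#' @export
print.thermal_context <- function(x, ...) {
  cat(sprintf("Thermal context: T = %g K, R = %g kcal/(mol K), RT = %.6g kcal/mol\n",
              x$temperature, x$gas_constant, x$rt))
  invisible(x)
}
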