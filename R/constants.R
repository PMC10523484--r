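# Boltzmann constant in kcal/mol/K (CODATA value commonly used by MD engines)
KB_KCAL <- 0.0019872041

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.  Defaults to 310 K, the
#'   simulation temperature used throughout the package; 298 K ("room
#'   temperature") is the other value commonly quoted for barrier heights.
#' @return kT in kcal/mol (about 0.616 at 310 K, 0.592 at 298 K).
#' @examples
#' kT_kcal()      # 310 K
#' kT_kcal(298)   # room temperature
#' @export
kT_kcal <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  KB_KCAL * temperature
}

#' The alchemical coupling-parameter schedule used for the FEP windows
#'
#' Eleven lambda values concentrated near the endpoints; the ten intervals
#' between them are the FEP windows.  lambda = 0 is the alanine (wild-type)
#' endpoint, lambda = 1 the threonine (mutant) endpoint.
#'
#' @return Numeric vector of 11 lambda values from 0 to 1.
#' @export
default_lambda_schedule <- function() {
  c(0, 0.03125, 0.0625, 0.125, 0.25, 0.5, 0.75, 0.875, 0.9375, 0.96875, 1)
}

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(mean(exp(x)))
logmeanexp <- function(x) logsumexp(x) - log(length(x))
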