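#' Convert phosphorus concentrations between mass and molar units
#'
#' Phosphate-phosphorus concentrations are reported either as mass of P per
#' litre (micrograms per litre, the convention of lake monitoring programmes)
#' or as molar concentration (micromoles per litre, the convention of culture
#' media recipes). Conversion uses the standard atomic weight of phosphorus,
#' 30.973762 g/mol.
#'
#' @param x numeric vector of concentrations.
#' @return numeric vector in the other unit.
#' @examples
#' phosphorus_ug_to_umol(60)    # ~1.94 umol/L
#' phosphorus_umol_to_ug(47.47) # ~1470 ug/L
#' @export
phosphorus_ug_to_umol <- function(x) x / .p_molar_mass

#' @rdname phosphorus_ug_to_umol
#' @export
phosphorus_umol_to_ug <- function(x) x * .p_molar_mass

.p_molar_mass <- 30.973762

#' Boltzmann constant in electron-volts per Kelvin
#'
#' Used to rescale temperature as 1/kT for Arrhenius regressions.
#' @export
boltzmann_ev <- 8.62e-5

# Decimal year of a Date: year + fraction elapsed within the calendar year.
# Shared by the lake-record simulator and the seasonal regression so that a
# noiseless simulated sinusoid is recovered exactly.
decimal_year <- function(date) {
  date <- as.Date(date)
  yr <- as.integer(format(date, "%Y"))
  start <- as.Date(paste0(yr, "-01-01"))
  end <- as.Date(paste0(yr + 1L, "-01-01"))
  yr + as.numeric(date - start) / as.numeric(end - start)
}

# internal: stop unless condition holds
stopf <- function(cond, fmt, ...) {
  if (!cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
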