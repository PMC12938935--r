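#' Physical constants and unit helpers
#'
#' The package stores chromophore positions in Angstrom and the emission
#' wavelength `lambda0` in nm (default 280 nm, the near-UV absorption band of
#' tryptophan).  Rates and energies live in a declared unit system: either
#' "gamma" (dimensionless multiples of the single-site radiative rate, the
#' convention used throughout the test fixtures) or "cm-1" (spectroscopic
#' wavenumbers, needed to convert collective decay rates into lifetimes in
#' seconds).
#'
#' @name units
NULL

#' Speed of light in cm/s
#' @export
SPEED_OF_LIGHT_CM_S <- 2.99792458e10

#' Radiative wavenumber k0 = 2*pi/lambda0 in 1/Angstrom
#'
#' @param lambda0_nm wavelength in nm.
#' @return k0 in 1/Angstrom, so that `alpha = k0 * r` is dimensionless when
#'   `r` is a separation in Angstrom.
#' @export
k0_per_angstrom <- function(lambda0_nm = 280) {
  2 * pi / (lambda0_nm * 10)
}

#' Carrier transition energy in cm^-1
#'
#' The on-site excitation energy hbar*omega0 expressed as a wavenumber,
#' 1/lambda0.  At 280 nm this is about 35714 cm^-1.  In the rotating frame
#' used by the propagators this enters only as a global phase and is dropped.
#'
#' @param lambda0_nm wavelength in nm.
#' @return energy in cm^-1.
#' @export
omega0_cm1 <- function(lambda0_nm = 280) {
  1e7 / lambda0_nm
}

#' Convert a rate in cm^-1 to an angular rate in 1/s
#'
#' Spectroscopic convention: rate[1/s] = 2*pi*c * rate[cm^-1].
#'
#' @param rate_cm1 rate in cm^-1.
#' @return rate in 1/s.
#' @export
rate_cm1_to_per_s <- function(rate_cm1) {
  2 * pi * SPEED_OF_LIGHT_CM_S * rate_cm1
}

#' Radiative lifetime (s) from a decay rate in cm^-1
#'
#' tau = 1/(2*pi*c*Gamma) with c in cm/s.  A zero rate gives +Inf (a
#' perfectly dark mode).
#'
#' @param gamma_cm1 decay rate in cm^-1.
#' @return lifetime in seconds.
#' @export
lifetime_s_from_rate_cm1 <- function(gamma_cm1) {
  ifelse(gamma_cm1 > 0, 1 / (2 * pi * SPEED_OF_LIGHT_CM_S * gamma_cm1), Inf)
}
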