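#' Physical constants used throughout the package
#'
#' A single record of the CODATA constants and gyromagnetic ratios needed by
#' the contact-shift and relaxation expressions. All values are SI.
#'
#' @return A named list with elements:
#'   \describe{
#'     \item{mu0}{vacuum permeability, T^2 m^3 J^-1}
#'     \item{muB}{Bohr magneton, J T^-1}
#'     \item{kB}{Boltzmann constant, J K^-1}
#'     \item{hbar}{reduced Planck constant, J s}
#'     \item{h}{Planck constant, J s}
#'     \item{c_cm}{speed of light, cm s^-1 (converts cm^-1 to Joules)}
#'     \item{gamma}{named vector of gyromagnetic ratios in rad s^-1 T^-1 for
#'       \code{"1H"}, \code{"15N"}, \code{"13C"}}
#'   }
#' @examples
#' physical_constants()$gamma[["1H"]]
#' @export
physical_constants <- function() {
  list(
    mu0   = 4 * pi * 1e-7,
    muB   = 9.2740100783e-24,
    kB    = 1.380649e-23,
    hbar  = 1.054571817e-34,
    h     = 6.62607015e-34,
    c_cm  = 2.99792458e10,
    gamma = c("1H" = 2.6752218744e8,
              "15N" = -2.7126e7,
              "13C" = 6.728284e7)
  )
}

# Energy of 1 cm^-1 in Joules
.wavenumber_to_joule <- function(E_cm) {
  pc <- physical_constants()
  E_cm * pc$h * pc$c_cm
}

#' Gyromagnetic ratio lookup
#'
#' @param nucleus one of \code{"1H"}, \code{"15N"}, \code{"13C"}
#' @return gyromagnetic ratio in rad s^-1 T^-1
#' @export
gyromagnetic_ratio <- function(nucleus = c("1H", "15N", "13C")) {
  nucleus <- match.arg(nucleus)
  physical_constants()$gamma[[nucleus]]
}
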