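#' Unit conversions and physical constants
#'
#' Internal working units are Angstrom (length), picosecond (time) and
#' kcal/mol (energy). Densities are reported in particles/nm^3 at the user
#' interface. These helpers centralise every conversion so that no module
#' carries its own factors.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
angstrom_to_nm <- function(x) x / 10

#' @rdname units
#' @export
nm_to_angstrom <- function(x) x * 10

#' @rdname units
#' @export
per_A3_to_per_nm3 <- function(x) x * 1000

#' @rdname units
#' @export
per_nm3_to_per_A3 <- function(x) x / 1000

#' @rdname units
#' @export
kcal_to_kj <- function(x) x * 4.184

#' @rdname units
#' @export
kj_to_kcal <- function(x) x / 4.184

#' Convert Kirkwood-Buff integrals from A^3/particle to cm^3/mol
#'
#' @param g_A3 integral value(s) in cubic Angstrom per particle.
#' @return value(s) in cm^3/mol.
#' @export
A3_to_cm3mol <- function(g_A3) g_A3 * 1e-24 * 6.02214076e23

#' Convert a diffusion coefficient from A^2/ps to 1e-5 cm^2/s
#'
#' The conventional reporting unit for water self-diffusion. 1 A^2/ps =
#' 1e-16 cm^2 / 1e-12 s = 1e-4 cm^2/s = 1e1 in units of 1e-5 cm^2/s.
#'
#' @param d diffusion coefficient(s) in A^2/ps.
#' @return value(s) in 1e-5 cm^2/s.
#' @export
A2ps_to_1e5cm2s <- function(d) d * 10

#' Ratio of the minimum-energy distance to the zero-crossing distance of a
#' 12-6 Lennard-Jones potential: Rmin = 2^(1/6) * sigma.
#' @export
RMIN_OVER_SIGMA <- 2^(1/6)

#' Coulomb energy prefactor e^2/(4 pi eps0) in kcal/mol * Angstrom
#'
#' For two elementary charges separated by r Angstrom the Coulomb energy is
#' `COULOMB_KCAL_A / r` kcal/mol.
#' @export
COULOMB_KCAL_A <- 332.06371
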