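#' Unit conventions and converters
#'
#' All interfaces use kJ/mol for energies, nm for distances, ps for time,
#' amu for masses and degrees for angles; angles are converted to radians
#' internally.  In this unit system 1 kJ/mol equals 1 amu nm^2 ps^-2, so
#' accelerations are forces divided by masses with no extra factor.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
deg2rad <- function(x) x * pi / 180

#' @rdname units
#' @export
rad2deg <- function(x) x * 180 / pi

#' @rdname units
#' @export
angstrom2nm <- function(x) x / 10

#' @rdname units
#' @export
nm2angstrom <- function(x) x * 10

#' @rdname units
#' @export
kjmol2ev <- function(x) x / 96.48533212

#' @rdname units
#' @export
ev2kjmol <- function(x) x * 96.48533212

#' @rdname units
#' @export
ev2nm <- function(x) 1239.84198 / x

#' @rdname units
#' @export
nm2ev <- function(x) 1239.84198 / x

# Boltzmann constant, kJ mol^-1 K^-1
.kB <- 0.008314462618
# Coulomb prefactor, kJ mol^-1 nm e^-2
.f_coulomb <- 138.935458
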