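#' Physical constants used throughout the package
#'
#' Energies are kcal/mol, lengths Angstrom, temperatures Kelvin everywhere
#' in this package; unit conversion happens only at I/O boundaries.
#'
#' @format `kB_kcal` is the Boltzmann constant in kcal/mol/K;
#'   `coulomb_kcal` is the Coulomb prefactor in kcal*A/mol/e^2.
#' @name constants
NULL

#' @rdname constants
#' @export
kB_kcal <- 1.9872e-3

#' @rdname constants
#' @export
coulomb_kcal <- 332.0637

# inverse temperature 1/(kB*T), mol/kcal
beta_from_T <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("temperature must be a single positive number (K)", call. = FALSE)
  1 / (kB_kcal * T)
}
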