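## Physical constants (CODATA 2018) and the unit conversions used
## package-wide.  Working units: nm, ns, K, kJ/mol; force kJ mol^-1 nm^-1;
## conductance pS.  Everything that crosses a unit boundary goes through
## this table so round-trip tests can pin the conversions down.

#' Physical constants used throughout the package
#'
#' A named list of CODATA values in SI units, plus the gas constant in the
#' package's energy units (kJ/mol/K).
#'
#' @format Named list with elements `kB` (J/K), `e` (C), `N_A` (1/mol),
#'   `eps0` (F/m), `R_kJ` (kJ/mol/K).
#' @export
phys_const <- list(
  kB   = 1.380649e-23,      # Boltzmann constant, J/K
  e    = 1.602176634e-19,   # elementary charge, C
  N_A  = 6.02214076e23,     # Avogadro number, 1/mol
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  R_kJ = 8.31446261815324e-3 # molar gas constant, kJ/mol/K
)

#' Unit conversions
#'
#' Helpers converting between the package's working units (nm, ns, kJ/mol)
#' and the SI / electrophysiology units in which parameters are usually
#' quoted.
#'
#' @param x numeric value(s) to convert.
#' @return Converted numeric value(s).
#' @name units
NULL

#' @rdname units
#' @details `emV_to_kJmol`: energy of one elementary charge across `x` mV,
#'   as molar energy (1 e.mV = 0.0964853... kJ/mol).
#' @export
emV_to_kJmol <- function(x) x * phys_const$e * phys_const$N_A * 1e-6

#' @rdname units
#' @details `m2s_to_nm2ns`: diffusion coefficient from m^2/s to nm^2/ns.
#' @export
m2s_to_nm2ns <- function(x) x * 1e9

#' @rdname units
#' @details `per_ns_to_per_s`: rate from ns^-1 to s^-1.
#' @export
per_ns_to_per_s <- function(x) x * 1e9

#' @rdname units
#' @details `S_to_pS`: conductance from siemens to picosiemens.
#' @export
S_to_pS <- function(x) x * 1e12

## thermal energy kB*T in kJ/mol
kBT_kJmol <- function(T) phys_const$R_kJ * T
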