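#' Physical constants and unit conversions
#'
#' All user-facing quantities in the package use a single set of units:
#' lengths in Angstrom (Å), times in femtoseconds (fs) for trajectories and
#' picoseconds (ps) for correlation functions and lineshapes, frequencies in
#' wavenumbers (cm^-1), and charges in elementary charge units (e).
#' Conversions live here and nowhere else.
#'
#' * `coulomb_eVA`: Coulomb constant, 14.3996 eV Å / e^2. The electric field
#'   of a point charge q (in e) at distance r (in Å) is `coulomb_eVA * q / r^2`
#'   in V/Å.
#' * `c_cm_per_ps`: speed of light, 0.0299792458 cm/ps; converts wavenumbers
#'   to angular frequency via `omega = 2*pi*c*nu`.
#'
#' @format A named list with elements `coulomb_eVA` and `c_cm_per_ps`.
#' @export
vib_constants <- list(
  coulomb_eVA = 14.3996,
  c_cm_per_ps = 0.0299792458
)

#' Convert a wavenumber to angular frequency
#'
#' @param nu_cm1 frequency in cm^-1 (vectorized).
#' @return angular frequency in rad/ps.
#' @export
cm1_to_radps <- function(nu_cm1) {
  2 * pi * vib_constants$c_cm_per_ps * nu_cm1
}

#' Convert an angular frequency to a wavenumber
#'
#' @param omega_radps angular frequency in rad/ps (vectorized).
#' @return frequency in cm^-1.
#' @export
radps_to_cm1 <- function(omega_radps) {
  omega_radps / (2 * pi * vib_constants$c_cm_per_ps)
}

#' Femtoseconds to picoseconds
#' @param t_fs time in fs.
#' @return time in ps.
#' @export
fs_to_ps <- function(t_fs) t_fs / 1000

#' Picoseconds to femtoseconds
#' @param t_ps time in ps.
#' @return time in fs.
#' @export
ps_to_fs <- function(t_ps) t_ps * 1000

# internal: abort with a classed condition so callers can test error classes
vib_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "vibsolv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: full-precision number formatting for text files whose round trip
# must be bit-exact ("%.17g" is the shortest format guaranteed to round-trip
# an IEEE double)
fmt_full <- function(x) sprintf("%.17g", x)

# internal: derive a reproducible sub-seed for an independent random stream.
# Keeps results < 2^31 so set.seed() accepts them.
derive_seed <- function(seed, stream) {
  seed <- as.double(seed)
  as.integer((abs(seed) * 48271 + stream * 7919 + 12345) %% 2147483647)
}
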