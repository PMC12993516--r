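#' Isotope constants
#'
#' Bundles the reference constants needed for delta-13C arithmetic. The only
#' member is the 13C/12C isotope ratio of the international VPDB (Vienna
#' PeeDee Belemnite) standard, against which all delta values are expressed.
#'
#' @param r_vpdb Dimensionless 13C/12C ratio of the VPDB standard. The
#'   standard literature value 0.0111802 is the default.
#' @return An object of class `isotope_constants`.
#' @examples
#' isotope_constants()
#' @export
isotope_constants <- function(r_vpdb = 0.0111802) {
  if (!is.numeric(r_vpdb) || length(r_vpdb) != 1L || !is.finite(r_vpdb) ||
      r_vpdb <= 0) {
    stop(errorCondition("r_vpdb must be a single positive number",
                        class = c("rsil_invalid_constants", "rsil_error")))
  }
  structure(list(r_vpdb = r_vpdb), class = "isotope_constants")
}

#' @export
print.isotope_constants <- function(x, ...) {
  cat("Isotope constants: R(VPDB) =", format(x$r_vpdb, digits = 8), "\n")
  invisible(x)
}

#' Convert delta-13C to isotope-amount fraction
#'
#' A delta value in permil vs VPDB corresponds to a sample isotope ratio
#' R' = (delta/1000 + 1) * R_VPDB; the isotope-amount fraction (the fraction
#' of carbon atoms that are 13C) is x = R'/(1 + R'). The mapping is strictly
#' increasing in delta and exactly invertible by [atom_fraction_to_delta()].
#'
#' @param delta_permil Numeric vector of delta-13C values in permil (parts
#'   per thousand) vs VPDB. Values below -1000 permil imply a negative
#'   isotope ratio and are rejected.
#' @param constants An [isotope_constants()] object.
#' @return Numeric vector of 13C atom fractions in `[0, 1)`.
#' @seealso [atom_fraction_to_delta()], [atom_percent()]
#' @examples
#' delta_to_atom_fraction(0)        # VPDB itself: ~0.011057
#' delta_to_atom_fraction(-1000)    # no 13C at all: 0
#' @export
delta_to_atom_fraction <- function(delta_permil, constants = isotope_constants()) {
  stopifnot(inherits(constants, "isotope_constants"))
  if (!is.numeric(delta_permil)) {
    stop(errorCondition("delta_permil must be numeric",
                        class = c("rsil_invalid_measurement", "rsil_error")))
  }
  bad <- !is.na(delta_permil) & delta_permil < -1000
  if (any(bad)) {
    stop(errorCondition(
      sprintf("delta-13C below -1000 permil implies a negative isotope ratio (got %s)",
              paste(format(delta_permil[bad]), collapse = ", ")),
      class = c("rsil_invalid_measurement", "rsil_error")))
  }
  r_sample <- (delta_permil / 1000 + 1) * constants$r_vpdb
  r_sample / (1 + r_sample)
}

#' Convert isotope-amount fraction to delta-13C
#'
#' Exact inverse of [delta_to_atom_fraction()]: recovers the sample ratio
#' R' = x/(1 - x) and expresses it as delta = 1000 * (R'/R_VPDB - 1) permil.
#'
#' @param x13c Numeric vector of 13C atom fractions, each in `[0, 1)`.
#' @inheritParams delta_to_atom_fraction
#' @return Numeric vector of delta-13C values in permil vs VPDB.
#' @examples
#' atom_fraction_to_delta(0.10)   # a 10 atom% pool is ~ +8938 permil
#' @export
atom_fraction_to_delta <- function(x13c, constants = isotope_constants()) {
  stopifnot(inherits(constants, "isotope_constants"))
  if (!is.numeric(x13c)) {
    stop(errorCondition("x13c must be numeric",
                        class = c("rsil_domain_error", "rsil_error")))
  }
  bad <- !is.na(x13c) & (x13c < 0 | x13c >= 1)
  if (any(bad)) {
    stop(errorCondition("atom fraction must lie in [0, 1)",
                        class = c("rsil_domain_error", "rsil_error")))
  }
  r_sample <- x13c / (1 - x13c)
  1000 * (r_sample / constants$r_vpdb - 1)
}

#' Atom percent from atom fraction
#'
#' Atom percent is simply the atom fraction times 100; it is the unit the
#' mixing-model mass balance is written in.
#'
#' @inheritParams atom_fraction_to_delta
#' @return Numeric vector, 13C atom percent.
#' @export
atom_percent <- function(x13c) {
  100 * x13c
}

#' Delta-13C straight to atom percent
#'
#' Convenience chain of [delta_to_atom_fraction()] and [atom_percent()],
#' the conversion applied to every instrument reading before inversion.
#'
#' @inheritParams delta_to_atom_fraction
#' @return Numeric vector, 13C atom percent.
#' @export
delta_to_atom_percent <- function(delta_permil, constants = isotope_constants()) {
  atom_percent(delta_to_atom_fraction(delta_permil, constants))
}
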