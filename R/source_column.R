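#' Ion mass in kg (singly charged positive ion)
#' @param ion `"D+"`, `"H+"`, `"T+"`, or a nuclide symbol.
#' @return Mass in kg (atomic mass minus one electron).
#' @keywords internal
ion_mass_kg <- function(ion = "D+") {
  sym <- switch(ion, "D+" = "H-2", "H+" = "H-1", "T+" = "H-3", ion)
  k <- nuclear_constants()$physical
  (nuclide_mass_u(sym) - k$electron_mass_u) * k$amu_kg
}

#' Space-charge-matched extraction gap (Child-Langmuir)
#'
#' For a planar extraction gap, the Child-Langmuir law gives the
#' space-charge-limited current density
#' `J = (4/9) eps0 sqrt(2q/m) V^(3/2) / d^2`. Solving for the electrode
#' distance at which the gap just transports the plasma-supplied current
#' density `J`:
#' \deqn{d = \sqrt{\frac{4\epsilon_0}{9J}\sqrt{\frac{2q}{m}}\,V^{3/2}}}
#' so `d` grows as `V^(3/4)` at fixed `J`. A multiplicative `calibration`
#' factor (default 1) is exposed for plasma-meniscus corrections that are
#' not modeled here.
#'
#' @param J_mA_cm2 Extracted current density in mA/cm^2 (default 5, the
#'   design value of the compact-generator prototype).
#' @param V_volts Extraction voltage in volts; vectorised.
#' @param ion Ion species, default `"D+"`.
#' @param calibration Multiplicative factor on the gap (default 1).
#' @return Matched gap in metres.
#' @export
#' @examples
#' matched_gap(5, 1e5)   # ~0.156 m
matched_gap <- function(J_mA_cm2 = 5, V_volts, ion = "D+", calibration = 1) {
  if (any(J_mA_cm2 <= 0)) stop("current density must be positive")
  if (any(V_volts <= 0)) stop("extraction voltage must be positive")
  k <- nuclear_constants()$physical
  j_si <- J_mA_cm2 * 10  # mA/cm^2 -> A/m^2
  m <- ion_mass_kg(ion)
  calibration * sqrt(4 * k$epsilon0_F_per_m / (9 * j_si) *
                       sqrt(2 * k$elementary_charge_C / m) * V_volts^1.5)
}

#' Child-Langmuir current density for a given gap
#'
#' The forward law `J = (4/9) eps0 sqrt(2q/m) V^(3/2) / d^2`, returned in
#' mA/cm^2; inverse of [matched_gap()].
#'
#' @param V_volts Extraction voltage, volts.
#' @param gap_m Electrode distance, metres.
#' @inheritParams matched_gap
#' @return Current density in mA/cm^2.
#' @export
child_langmuir_J <- function(V_volts, gap_m, ion = "D+") {
  stopifnot(all(V_volts > 0), all(gap_m > 0))
  k <- nuclear_constants()$physical
  m <- ion_mass_kg(ion)
  j_si <- 4 / 9 * k$epsilon0_F_per_m *
    sqrt(2 * k$elementary_charge_C / m) * V_volts^1.5 / gap_m^2
  j_si / 10  # A/m^2 -> mA/cm^2
}

#' Gap perveance
#'
#' Secondary output of the extraction design: `P = I/V^(3/2)` per unit
#' area, i.e. `J/V^(3/2)` in A m^-2 V^-3/2.
#'
#' @inheritParams child_langmuir_J
#' @return Perveance per unit area.
#' @export
gap_perveance <- function(V_volts, gap_m, ion = "D+") {
  child_langmuir_J(V_volts, gap_m, ion) * 10 / V_volts^1.5
}

# Which side of the matched gap maps to which beam shape is a documented
# convention, not derived physics: a gap smaller than matched means the
# space-charge-limited J exceeds the plasma supply (concave meniscus) ->
# "convergent"; larger than matched -> "divergent".
.beam_class_convention <- c(smaller = "convergent", larger = "divergent")

#' Classify an extraction gap as parallel, convergent or divergent
#'
#' Compares an actual electrode distance with the space-charge-matched gap
#' for the given current density and voltage. Within `rel_tol` of the
#' matched value the beam is `"parallel"`; the mapping of the two
#' off-matched sides follows a documented convention (gap smaller than
#' matched: `"convergent"`; larger: `"divergent"`).
#'
#' @param actual_gap_m Actual electrode distance, metres.
#' @inheritParams matched_gap
#' @param V_volts Extraction voltage, volts.
#' @param rel_tol Relative half-width of the `"parallel"` band (default 0.05).
#' @return A list: `classification`, `actual_gap_m`, `matched_gap_m`,
#'   `relative_mismatch`.
#' @export
#' @examples
#' classify_beam(0.156, 5, 1e5)
classify_beam <- function(actual_gap_m, J_mA_cm2 = 5, V_volts, ion = "D+",
                          rel_tol = 0.05) {
  stopifnot(actual_gap_m > 0, rel_tol >= 0)
  d0 <- matched_gap(J_mA_cm2, V_volts, ion)
  mis <- (actual_gap_m - d0) / d0
  cls <- if (abs(mis) <= rel_tol) "parallel"
         else if (mis < 0) .beam_class_convention[["smaller"]]
         else .beam_class_convention[["larger"]]
  list(classification = cls, actual_gap_m = actual_gap_m,
       matched_gap_m = d0, relative_mismatch = mis)
}

#' Matched gap versus extraction voltage
#'
#' Tabulates [matched_gap()] over a voltage range, reproducing the shape of
#' the gap-voltage design curve of a compact generator extraction column.
#'
#' @param V_min,V_max Voltage range, volts.
#' @param n Number of points.
#' @inheritParams matched_gap
#' @return Data frame with columns `V_volts`, `gap_m`.
#' @export
gap_curve <- function(V_min, V_max, n = 100, J_mA_cm2 = 5, ion = "D+") {
  stopifnot(V_min > 0, V_max >= V_min, n >= 2)
  v <- seq(V_min, V_max, length.out = n)
  data.frame(V_volts = v, gap_m = matched_gap(J_mA_cm2, v, ion))
}
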