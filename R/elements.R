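# Natural isotope table for the elements occurring in unmodified peptides.
# Masses in Da; abundances are atom fractions (CIAAW/NIST representative
# values). Average atomic masses used throughout the package are the
# abundance-weighted means of this table, so average and isotopic
# calculations are mutually consistent.
.isotope_table <- list(
  H = list(mass = c(1.0078250319, 2.0141017779),
           abundance = c(0.999885, 0.000115)),
  C = list(mass = c(12.0000000000, 13.0033548378),
           abundance = c(0.9893, 0.0107)),
  N = list(mass = c(14.0030740052, 15.0001088984),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.9949146221, 16.9991315, 17.9991604),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001))
)

#' Supported chemical elements
#'
#' Element symbols for which the packaged natural-isotope table has entries.
#'
#' @return Character vector of element symbols.
#' @export
element_symbols <- function() names(.isotope_table)

#' Atomic masses from the packaged isotope table
#'
#' `atomic_average_masses()` returns abundance-weighted mean masses;
#' `atomic_monoisotopic_masses()` returns the mass of each element's most
#' abundant isotope.
#'
#' @return Named numeric vector (Da per atom).
#' @export
atomic_average_masses <- function() {
  vapply(.isotope_table, function(e) sum(e$mass * e$abundance), numeric(1))
}

#' @rdname atomic_average_masses
#' @export
atomic_monoisotopic_masses <- function() {
  vapply(.isotope_table, function(e) e$mass[which.max(e$abundance)],
         numeric(1))
}

# Mass of the charge carrier added per charge in positive-mode ESI.
# "physical": the proton mass. "paper": exactly 1.000 Da per charge, the
# convention under which the packaged reference oligomer table's printed
# masses are exact integers times m/z minus z (see reproduce_table1()).
.proton_mass <- 1.00727646688

.charge_carrier_mass <- function(convention = c("physical", "paper")) {
  convention <- match.arg(convention)
  if (convention == "physical") .proton_mass else 1.0
}
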