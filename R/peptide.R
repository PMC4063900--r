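# Residue (amino-acid minus water) elemental compositions, 20 canonical
# one-letter codes. A linear peptide is the residue sum plus one water.
.residue_compositions <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

.water <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

#' Human amyloid-beta 1-40 sequence
#'
#' The canonical human sequence (APP residues 672-711), the default peptide
#' throughout the package. Its single tyrosine (Tyr10) is the site of
#' oxidative di-tyrosine cross-linking.
#'
#' @return One-letter amino-acid string of length 40.
#' @export
#' @examples
#' nchar(abeta40_sequence())
abeta40_sequence <- function() "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV"

#' Read a peptide sequence from a string or single-record FASTA file
#'
#' @param x Either a plain one-letter amino-acid string, or the path to a
#'   FASTA file containing exactly one record.
#' @return Validated upper-case sequence string.
#' @export
read_sequence <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (file.exists(x) && !grepl("^[ARNDCQEGHILKMFPSTWYV]+$", toupper(x))) {
    recs <- seqinr::read.fasta(x, seqtype = "AA", as.string = TRUE)
    if (length(recs) != 1L)
      stop("FASTA file '", x, "' must contain exactly one record, found ",
           length(recs))
    x <- as.character(recs[[1]])
  }
  validate_sequence(x)
}

validate_sequence <- function(seq) {
  seq <- toupper(gsub("[[:space:]]", "", seq))
  if (nchar(seq) == 0L) stop("peptide sequence is empty")
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), names(.residue_compositions))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  seq
}

#' Elemental composition of a linear peptide
#'
#' Sums residue compositions over the sequence and adds one water for the
#' free termini of an unmodified linear chain.
#'
#' @param seq Peptide as one-letter string or single-record FASTA path.
#' @return Named integer vector of atom counts over C, H, N, O, S.
#' @export
#' @examples
#' composition_from_sequence("G")   # glycine: C2 H5 N O2
#' average_mass(composition_from_sequence(abeta40_sequence()))
composition_from_sequence <- function(seq) {
  seq <- read_sequence(seq)
  chars <- strsplit(seq, "")[[1]]
  comp <- Reduce(`+`, .residue_compositions[chars]) + .water
  validate_composition(comp)
}

validate_composition <- function(comp) {
  if (is.null(names(comp)) || any(!nzchar(names(comp))))
    stop("composition must be a named count vector")
  if (any(comp < 0)) stop("negative atom count in composition")
  if (all(comp == 0)) stop("composition is empty (all counts zero)")
  if (any(comp != round(comp))) stop("atom counts must be integers")
  storage.mode(comp) <- "integer"
  comp
}

#' Composition of a cross-linked oligomer
#'
#' An oligomer of `n` chains joined by `k` tyrosine-tyrosine covalent bonds
#' has `n` times the monomer composition minus two hydrogens per bond: each
#' di-tyrosine bond forms by radical coupling with loss of 2 H (nominal
#' -2 Da). At most `n - 1` bonds can connect `n` chains.
#'
#' @param monomer Monomer elemental composition (named counts).
#' @param n Oligomer order (1 = monomer, 2 = dimer, ...).
#' @param k Number of Tyr-Tyr bonds, `0 <= k <= n - 1`.
#' @return Named integer atom-count vector.
#' @export
#' @examples
#' mono <- composition_from_sequence(abeta40_sequence())
#' average_mass(oligomer_composition(mono, n = 2, k = 0)) -
#'   average_mass(oligomer_composition(mono, n = 2, k = 1))  # ~2.016 Da
oligomer_composition <- function(monomer, n, k = 0) {
  monomer <- validate_composition(monomer)
  stopifnot(length(n) == 1L, n >= 1, n == round(n),
            length(k) == 1L, k >= 0, k == round(k))
  if (k > n - 1)
    stop("k = ", k, " cross-links exceed the maximum n - 1 = ", n - 1,
         " joining ", n, " chains")
  comp <- monomer * as.integer(n)
  if (k > 0) {
    if (comp[["H"]] < 2 * k) stop("monomer has too few hydrogens for ", k,
                                  " cross-links")
    comp[["H"]] <- comp[["H"]] - 2L * as.integer(k)
  }
  validate_composition(comp)
}

#' Average and monoisotopic mass of a composition
#'
#' @param comp Named atom-count vector over supported elements.
#' @return Mass in Da.
#' @export
average_mass <- function(comp) {
  comp <- validate_composition(comp)
  .composition_mass(comp, atomic_average_masses())
}

#' @rdname average_mass
#' @export
monoisotopic_mass <- function(comp) {
  comp <- validate_composition(comp)
  .composition_mass(comp, atomic_monoisotopic_masses())
}

.composition_mass <- function(comp, masses) {
  unknown <- setdiff(names(comp)[comp > 0], names(masses))
  if (length(unknown))
    stop("element(s) missing from the isotope table: ",
         paste(unknown, collapse = ", "))
  sum(comp[comp > 0] * masses[names(comp)[comp > 0]])
}

#' Convert between neutral mass and m/z
#'
#' Positive-mode ESI: an ion of charge `z` carries `z` charge-carrier
#' adducts, so `M = z * mz - z * m_carrier` and conversely. Under the
#' `"physical"` convention the carrier is a proton (1.00728 Da); under the
#' `"paper"` convention it is exactly 1.000 Da per charge, which is the
#' arithmetic that reproduces the packaged reference oligomer table.
#'
#' @param mz m/z in Th.
#' @param mass Neutral mass in Da.
#' @param z Positive integer charge.
#' @param convention `"physical"` (default) or `"paper"`.
#' @return Mass in Da (`mass_from_mz`) or m/z in Th (`mz_from_mass`).
#' @export
#' @examples
#' mass_from_mz(2165.82, 4, convention = "paper")  # 8659.28
mass_from_mz <- function(mz, z, convention = c("physical", "paper")) {
  stopifnot(all(mz > 0))
  z <- .check_charge(z)
  z * mz - z * .charge_carrier_mass(match.arg(convention))
}

#' @rdname mass_from_mz
#' @export
mz_from_mass <- function(mass, z, convention = c("physical", "paper")) {
  stopifnot(all(mass > 0))
  z <- .check_charge(z)
  mass / z + .charge_carrier_mass(match.arg(convention))
}

.check_charge <- function(z) {
  if (any(z < 1) || any(z != round(z)))
    stop("charge z must be a positive integer (got ",
         paste(z, collapse = ", "), ")")
  as.integer(z)
}

#' Tabulate cross-linked oligomer species
#'
#' Builds a species table (one row per combination of oligomer order,
#' cross-link count and charge) with average and monoisotopic masses and
#' m/z, optionally written as CSV.
#'
#' @param seq Peptide sequence (string or FASTA path).
#' @param n Vector of oligomer orders.
#' @param z Vector of charges.
#' @param convention Mass convention for the m/z column.
#' @param file Optional CSV path to write the table to.
#' @return `data.frame` with columns `n`, `k`, `z`, `average_mass_Da`,
#'   `monoisotopic_mass_Da`, `mz_Th`, `convention`.
#' @export
species_table <- function(seq = abeta40_sequence(), n = 1:3,
                          z = 1:10, convention = c("physical", "paper"),
                          file = NULL) {
  convention <- match.arg(convention)
  mono <- composition_from_sequence(seq)
  grid <- do.call(rbind, lapply(n, function(ni)
    expand.grid(n = ni, k = 0:(ni - 1), z = z)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    comp <- oligomer_composition(mono, grid$n[i], grid$k[i])
    avg <- average_mass(comp)
    data.frame(n = grid$n[i], k = grid$k[i], z = grid$z[i],
               average_mass_Da = avg,
               monoisotopic_mass_Da = monoisotopic_mass(comp),
               mz_Th = mz_from_mass(avg, grid$z[i], convention),
               convention = convention)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$n, out$k, out$z), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
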