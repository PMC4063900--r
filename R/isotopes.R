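#' Isotopic distribution of an elemental composition
#'
#' Computes the neutral-mass isotopologue distribution by convolving the
#' natural per-element isotope distributions. Isotopologues are aggregated
#' into nucleon-number bins (one bin per extra neutron); each bin carries
#' the abundance-weighted mean mass of its isotopologues, so adjacent bins
#' are spaced by approximately one neutron mass gap (~1.0033 Da for
#' carbon-dominated peptides). Per-element powers use binary-exponentiation
#' convolution, so large compositions stay fast.
#'
#' @param comp Named atom-count vector (see
#'   [composition_from_sequence()]).
#' @param prune_below Drop bins with relative abundance below this fraction
#'   of the total, then renormalise to sum 1. Default `1e-6`.
#' @return An `isotope_pattern`: data frame with columns `mass` (Da,
#'   strictly increasing) and `abundance` (fractions summing to 1).
#' @export
#' @examples
#' p <- isotopic_distribution(composition_from_sequence("GG"))
#' sum(p$abundance)
isotopic_distribution <- function(comp, prune_below = 1e-6) {
  comp <- validate_composition(comp)
  stopifnot(prune_below >= 0, prune_below < 1)
  unknown <- setdiff(names(comp)[comp > 0], names(.isotope_table))
  if (length(unknown))
    stop("element(s) missing from the isotope table: ",
         paste(unknown, collapse = ", "))

  dist <- NULL  # list(p = abundances by extra-neutron bin, m = mean masses)
  for (el in names(comp)[comp > 0]) {
    iso <- .isotope_table[[el]]
    offs <- round(iso$mass - iso$mass[1])
    single <- list(p = numeric(max(offs) + 1), m = numeric(max(offs) + 1))
    single$p[offs + 1] <- iso$abundance
    single$m[offs + 1] <- iso$mass
    el_dist <- .dist_power(single, comp[[el]])
    dist <- if (is.null(dist)) el_dist else .dist_convolve(dist, el_dist)
  }

  keep <- dist$p >= prune_below * sum(dist$p) & dist$p > 0
  p <- dist$p[keep] / sum(dist$p[keep])
  structure(data.frame(mass = dist$m[keep], abundance = p),
            class = c("isotope_pattern", "data.frame"))
}

# Convolution of two extra-neutron-binned distributions; abundances
# multiply pairwise, masses add with abundance-weighted averaging per bin.
.dist_convolve <- function(a, b, tail_prune = 1e-15) {
  na <- length(a$p); nb <- length(b$p)
  p <- numeric(na + nb - 1)
  pm <- numeric(na + nb - 1)
  for (i in seq_len(na)) {
    if (a$p[i] == 0) next
    idx <- i:(i + nb - 1)
    contrib <- a$p[i] * b$p
    p[idx] <- p[idx] + contrib
    pm[idx] <- pm[idx] + contrib * (a$m[i] + b$m)
  }
  m <- ifelse(p > 0, pm / pmax(p, .Machine$double.xmin), 0)
  keep <- seq_len(max(which(p > tail_prune * max(p)), 1L))
  list(p = p[keep], m = m[keep])
}

.dist_power <- function(d, n) {
  result <- NULL
  base <- d
  while (n > 0) {
    if (n %% 2 == 1)
      result <- if (is.null(result)) base else .dist_convolve(result, base)
    n <- n %/% 2
    if (n > 0) base <- .dist_convolve(base, base)
  }
  result
}

#' Project an isotope pattern onto the m/z axis at a given charge
#'
#' Maps each neutral isotopologue mass through [mz_from_mass()]; adjacent
#' peaks are then spaced by about 1.0033/z Th, the spacing from which the
#' charge state is read off an isotopic envelope.
#'
#' @param pattern An `isotope_pattern`.
#' @param z Positive integer charge.
#' @param convention Mass convention (see [mz_from_mass()]).
#' @return Data frame with columns `mz` (Th) and `abundance`.
#' @export
envelope_mz_peaks <- function(pattern, z,
                              convention = c("physical", "paper")) {
  stopifnot(inherits(pattern, "isotope_pattern"))
  data.frame(mz = mz_from_mass(pattern$mass, z, match.arg(convention)),
             abundance = pattern$abundance)
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("Isotopic distribution:", nrow(x), "isotopologue bins,",
      sprintf("monoisotopic %.4f Da, mean %.4f Da\n",
              x$mass[1], sum(x$mass * x$abundance)))
  print.data.frame(utils::head(as.data.frame(x), 8), ...)
  if (nrow(x) > 8) cat("...", nrow(x) - 8, "more bins\n")
  invisible(x)
}
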