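# Independent brute-force isotopic-distribution oracle: convolves the
# per-element single-atom distributions one atom at a time (naive
# polynomial multiplication), with no pruning and no binary
# exponentiation, i.e. a different code path from the package's
# implementation. Distributions are indexed by extra-neutron count.
oracle_isotope_table <- list(
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

oracle_isotopic_distribution <- function(comp) {
  p <- 1; pm <- 0  # abundance and abundance*mass by extra-neutron bin
  for (el in names(comp)) {
    if (comp[[el]] == 0) next
    iso <- oracle_isotope_table[[el]]
    offs <- round(iso$mass - iso$mass[1])
    ap <- numeric(max(offs) + 1); am <- numeric(max(offs) + 1)
    ap[offs + 1] <- iso$abundance
    am[offs + 1] <- iso$abundance * iso$mass
    for (atom in seq_len(comp[[el]])) {
      np <- numeric(length(p) + length(ap) - 1)
      nm <- numeric(length(np))
      for (i in seq_along(p)) {
        idx <- i:(i + length(ap) - 1)
        np[idx] <- np[idx] + p[i] * ap
        nm[idx] <- nm[idx] + pm[i] * ap + p[i] * am
      }
      p <- np; pm <- nm
    }
  }
  keep <- p > 0
  data.frame(mass = pm[keep] / p[keep], abundance = p[keep])
}

# Align an oracle distribution with a package pattern on nominal bins and
# return the total-variation distance between the (renormalised)
# abundances over the union of bins.
tv_distance <- function(pattern, oracle) {
  key <- function(m) round(m - min(oracle$mass))
  all_bins <- sort(unique(c(key(pattern$mass), key(oracle$mass))))
  a <- numeric(length(all_bins)); b <- numeric(length(all_bins))
  a[match(key(pattern$mass), all_bins)] <- pattern$abundance
  b[match(key(oracle$mass), all_bins)] <- oracle$abundance / sum(oracle$abundance)
  sum(abs(a / sum(a) - b)) / 2
}

abeta_monomer <- composition_from_sequence(abeta40_sequence())
abeta_avg <- average_mass(abeta_monomer)
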