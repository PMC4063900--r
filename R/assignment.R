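# Nominal spacing between adjacent isotopologues of a singly charged
# peptide ion (one extra neutron), Th.
.isotope_spacing <- 1.0033

.assignment_error <- function(class, message, data = list()) {
  stop(structure(class = c(class, "dityrims_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), data = data)))
}

#' Pick isotopologue centroids in an m/z window
#'
#' Optionally gates the spectrum to a drift-time interval (summing the
#' gated drift columns first, mirroring the extraction of envelopes at the
#' arrival time of one conformer), then finds local maxima in the m/z
#' profile above a relative threshold and refines each apex by three-point
#' parabolic interpolation.
#'
#' @param spectrum A `spectrum2d`.
#' @param window `c(lo, hi)` m/z window, Th.
#' @param drift_gate Optional `c(lo, hi)` drift gate, ms.
#' @param rel_threshold Keep maxima above this fraction of the window
#'   maximum (default 0.05).
#' @return A `centroid_list`: data frame with `mz` and `intensity`,
#'   with the window and gate as attributes. An empty window yields an
#'   empty list, not an error. Peaks closer than one grid step merge into
#'   a single centroid (the resolution limit of the grid).
#' @export
pick_centroids <- function(spectrum, window, drift_gate = NULL,
                           rel_threshold = 0.05) {
  stopifnot(inherits(spectrum, "spectrum2d"), length(window) == 2,
            window[1] < window[2], rel_threshold >= 0, rel_threshold < 1)
  cols <- if (is.null(drift_gate)) seq_along(spectrum$drift)
          else which(spectrum$drift >= drift_gate[1] &
                     spectrum$drift <= drift_gate[2])
  rows <- which(spectrum$mz >= window[1] & spectrum$mz <= window[2])
  empty <- structure(data.frame(mz = numeric(0), intensity = numeric(0)),
                     window = window, drift_gate = drift_gate,
                     class = c("centroid_list", "data.frame"))
  if (!length(rows) || !length(cols)) return(empty)
  prof <- rowSums(spectrum$intensity[rows, cols, drop = FALSE])
  if (max(prof) <= 0) return(empty)
  thr <- rel_threshold * max(prof)
  n <- length(prof)
  if (n < 3) return(empty)
  apex <- which(prof[2:(n - 1)] > thr &
                prof[2:(n - 1)] >= prof[1:(n - 2)] &
                prof[2:(n - 1)] > prof[3:n]) + 1L
  if (!length(apex)) return(empty)
  mzs <- spectrum$mz[rows]
  step <- mean(diff(mzs))
  cent <- t(vapply(apex, function(i) {
    y0 <- prof[i - 1]; y1 <- prof[i]; y2 <- prof[i + 1]
    denom <- y0 - 2 * y1 + y2
    delta <- if (denom < 0) 0.5 * (y0 - y2) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    c(mz = mzs[i] + delta * step, intensity = y1 - 0.25 * (y0 - y2) * delta)
  }, numeric(2)))
  out <- data.frame(mz = cent[, 1], intensity = cent[, 2])
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, window = window, drift_gate = drift_gate,
            class = c("centroid_list", "data.frame"))
}

#' Infer the charge state from isotopic peak spacing
#'
#' The median spacing between adjacent centroids is compared with the
#' theoretical isotopologue spacing 1.0033/z for each candidate charge;
#' the best match is accepted if it deviates by less than `max_deviation`
#' (relative). The median is robust to a single missed or merged peak.
#' Ties break toward the smaller charge.
#'
#' @param centroids A `centroid_list` with at least 3 centroids.
#' @param z_max Largest charge considered (default 12).
#' @param max_deviation Maximum accepted relative deviation of the median
#'   spacing from 1.0033/z (default 0.2).
#' @return Integer charge. Fewer than 3 centroids signal an error of class
#'   `"dityrims_insufficient_envelope"`; no acceptable charge signals
#'   `"dityrims_unassignable"`.
#' @export
infer_charge <- function(centroids, z_max = 12, max_deviation = 0.2) {
  stopifnot(inherits(centroids, "centroid_list"), z_max >= 1)
  if (nrow(centroids) < 3)
    .assignment_error("dityrims_insufficient_envelope",
                      sprintf("need >= 3 centroids to read the envelope spacing, got %d",
                              nrow(centroids)),
                      list(n_centroids = nrow(centroids)))
  spacing <- stats::median(diff(centroids$mz))
  zs <- seq_len(z_max)
  dev <- abs(spacing - .isotope_spacing / zs)
  z <- zs[which.min(dev)]  # which.min takes the first, i.e. smallest z, on ties
  rel <- dev[z] / (.isotope_spacing / z)
  if (rel >= max_deviation)
    .assignment_error("dityrims_unassignable",
                      sprintf("median spacing %.4f Th matches no charge <= %d within %.0f%%",
                              spacing, z_max, 100 * max_deviation),
                      list(spacing = spacing, best_z = z, deviation = rel))
  as.integer(z)
}

#' Intensity-weighted average m/z of an envelope
#'
#' @param centroids A non-empty `centroid_list`.
#' @return Average m/z, Th.
#' @export
average_mz <- function(centroids) {
  stopifnot(inherits(centroids, "centroid_list"))
  if (nrow(centroids) == 0) stop("cannot average an empty centroid list")
  sum(centroids$mz * centroids$intensity) / sum(centroids$intensity)
}

#' Assign oligomer order and cross-link count from a measured mass
#'
#' Searches all (n, k) with `1 <= n <= n_max`, `0 <= k <= n - 1` for the
#' candidate mass `n * monomer_mass - 2 * k * 1.008` closest to the
#' measurement. Ties break toward fewer cross-links.
#'
#' @param mass Measured neutral mass, Da.
#' @param monomer_mass Monomer mass on the same scale (average by
#'   default throughout the package), Da.
#' @param n_max Largest oligomer order considered.
#' @param tolerance Maximum accepted residual, Da.
#' @return List with `n`, `k`, `residual` (Da, signed measured minus
#'   theoretical). A residual above `tolerance` signals an error of class
#'   `"dityrims_unassigned"` carrying the best candidate.
#' @export
#' @examples
#' mono <- average_mass(composition_from_sequence(abeta40_sequence()))
#' assign_species(8657.73, mono)  # cross-linked dimer: n = 2, k = 1
assign_species <- function(mass, monomer_mass, n_max = 4, tolerance = 1.0) {
  stopifnot(mass > 0, monomer_mass > 0, n_max >= 1, tolerance > 0)
  cand <- do.call(rbind, lapply(seq_len(n_max), function(n)
    data.frame(n = n, k = 0:(n - 1))))
  cand$theoretical <- cand$n * monomer_mass - 2 * cand$k * 1.008
  cand$residual <- mass - cand$theoretical
  cand <- cand[order(abs(cand$residual), cand$k), , drop = FALSE]
  best <- cand[1, ]
  if (abs(best$residual) > tolerance)
    .assignment_error("dityrims_unassigned",
                      sprintf("no (n, k) within %.2f Da of %.2f Da; best is n=%d k=%d at %+.2f Da",
                              tolerance, mass, best$n, best$k, best$residual),
                      list(n = best$n, k = best$k,
                           residual = best$residual))
  list(n = best$n, k = best$k, residual = best$residual)
}

#' Full envelope assignment for one analyst-specified window
#'
#' Convenience wrapper chaining [pick_centroids()], [infer_charge()],
#' [average_mz()], [mass_from_mz()] and [assign_species()].
#'
#' @inheritParams pick_centroids
#' @inheritParams infer_charge
#' @inheritParams assign_species
#' @param convention Mass convention used to convert average m/z to mass.
#' @return A one-row data frame: `z`, `avg_mz`, `mass`, `n`, `k`,
#'   `residual`.
#' @export
assign_envelope <- function(spectrum, window, monomer_mass,
                            drift_gate = NULL, rel_threshold = 0.05,
                            z_max = 12, n_max = 4, tolerance = 1.0,
                            convention = c("physical", "paper")) {
  convention <- match.arg(convention)
  cent <- pick_centroids(spectrum, window, drift_gate, rel_threshold)
  z <- infer_charge(cent, z_max)
  mz <- average_mz(cent)
  mass <- mass_from_mz(mz, z, convention)
  sp <- assign_species(mass, monomer_mass, n_max, tolerance)
  data.frame(z = z, avg_mz = mz, mass = mass, n = sp$n, k = sp$k,
             residual = sp$residual)
}
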