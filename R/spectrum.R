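#' Describe one oligomer species for the spectrum simulator
#'
#' A scenario couples an oligomer species (order `n`, cross-link count `k`,
#' charge `z`) to its gas-phase arrival-time behaviour: one or more
#' Gaussian drift-time components (compact and/or extended conformers) with
#' individual amplitudes.
#'
#' @param n,k,z Oligomer order, Tyr-Tyr bond count and charge.
#' @param drift_centers Component centers, ms.
#' @param drift_widths Component standard deviations, ms (recycled).
#' @param amplitudes Relative component amplitudes (recycled); scaled so
#'   that the species' integrated intensity is
#'   `total_intensity * sum(amplitudes)`.
#' @param total_intensity Overall intensity scale for the species.
#' @param monomer Monomer elemental composition; defaults to human
#'   amyloid-beta 1-40.
#' @param label Optional species label (default e.g. `"DIM4+k1"`).
#' @return A `species_scenario` object.
#' @export
#' @examples
#' species_scenario(2, 1, 8, drift_centers = 7.17, drift_widths = 0.2)
species_scenario <- function(n, k, z, drift_centers, drift_widths = 0.3,
                             amplitudes = 1, total_intensity = 1,
                             monomer = composition_from_sequence(abeta40_sequence()),
                             label = NULL) {
  comp <- oligomer_composition(monomer, n, k)
  z <- .check_charge(z)
  m <- length(drift_centers)
  stopifnot(m >= 1, all(drift_centers > 0))
  drift_widths <- rep_len(drift_widths, m)
  amplitudes <- rep_len(amplitudes, m)
  stopifnot(all(drift_widths > 0), all(amplitudes >= 0),
            total_intensity >= 0)
  if (is.null(label)) {
    stem <- c("MON", "DIM", "TRI", "TET", "PEN", "HEX")
    stem <- if (n <= length(stem)) stem[n] else paste0("OLI", n)
    label <- sprintf("%s%d+%s", stem, z, if (k > 0) paste0("k", k) else "")
  }
  structure(list(n = n, k = k, z = z, composition = comp,
                 components = data.frame(center = drift_centers,
                                         width = drift_widths,
                                         amplitude = amplitudes),
                 total_intensity = total_intensity, label = label),
            class = "species_scenario")
}

#' Render a synthetic 2D (m/z x drift time) spectrum
#'
#' Each scenario contributes the outer product of its isotopic envelope
#' (Gaussian peaks of width `mz_sigma` at each isotopologue m/z) and its
#' Gaussian drift-time components. Peaks are unit-area Gaussian densities,
#' so the integrated spectrum intensity (noise off) equals the sum over
#' scenarios of `total_intensity * sum(amplitudes)`. Additive Gaussian
#' noise, truncated at zero, is scaled to `noise_sd` times the noiseless
#' maximum. Output is reproducible: identical inputs and seed give an
#' identical matrix.
#'
#' @param scenarios List of [species_scenario()] objects (possibly empty).
#' @param mz_range,drift_range Axis ranges, c(lo, hi).
#' @param mz_step,drift_step Grid steps; defaults 0.02 Th and 0.05 ms
#'   resolve isotopic spacings down to charge 10+ and the 6-17 ms drift
#'   window of the amyloid-beta oligomers.
#' @param mz_sigma Peak width (sd) in m/z, Th.
#' @param noise_sd Noise sd as a fraction of the noiseless maximum.
#' @param seed Integer seed for the noise.
#' @param convention Mass convention for peak positions.
#' @param prune_below Isotopologue pruning threshold (see
#'   [isotopic_distribution()]).
#' @return A `spectrum2d` object: `mz`, `drift` axes and an
#'   `intensity` matrix of dimension `length(mz) x length(drift)`.
#' @export
render_spectrum <- function(scenarios, mz_range, drift_range,
                            mz_step = 0.02, drift_step = 0.05,
                            mz_sigma = 0.02, noise_sd = 0, seed = 1L,
                            convention = c("physical", "paper"),
                            prune_below = 1e-4) {
  convention <- match.arg(convention)
  stopifnot(mz_sigma > 0, noise_sd >= 0,
            length(mz_range) == 2, length(drift_range) == 2,
            mz_range[1] < mz_range[2], drift_range[1] < drift_range[2])
  mz <- seq(mz_range[1], mz_range[2], by = mz_step)
  drift <- seq(drift_range[1], drift_range[2], by = drift_step)
  intensity <- matrix(0, nrow = length(mz), ncol = length(drift))

  for (sc in scenarios) {
    stopifnot(inherits(sc, "species_scenario"))
    peaks <- envelope_mz_peaks(
      isotopic_distribution(sc$composition, prune_below), sc$z, convention)
    if (any(peaks$mz < mz_range[1]) || any(peaks$mz > mz_range[2]) ||
        any(sc$components$center < drift_range[1]) ||
        any(sc$components$center > drift_range[2]))
      stop("grid does not cover species '", sc$label,
           "' (envelope ", sprintf("%.3f-%.3f Th", min(peaks$mz),
                                   max(peaks$mz)),
           ", drift centers ", paste(sprintf("%.2f", sc$components$center),
                                     collapse = ", "), " ms)")
    mz_profile <- rowSums(vapply(seq_len(nrow(peaks)), function(i)
      peaks$abundance[i] * stats::dnorm(mz, peaks$mz[i], mz_sigma),
      numeric(length(mz))))
    drift_profile <- rowSums(vapply(seq_len(nrow(sc$components)),
      function(j) sc$components$amplitude[j] *
        stats::dnorm(drift, sc$components$center[j], sc$components$width[j]),
      numeric(length(drift))))
    intensity <- intensity +
      sc$total_intensity * outer(mz_profile, drift_profile)
  }

  if (noise_sd > 0 && max(intensity) > 0) {
    noise <- with_seed(seed, stats::rnorm(length(intensity), sd =
                                            noise_sd * max(intensity)))
    intensity <- pmax(intensity + noise, 0)
  }

  new_spectrum2d(mz, drift, intensity,
                 meta = list(seed = seed, convention = convention,
                             scenario = paste(vapply(scenarios, `[[`,
                                                     "", "label"),
                                              collapse = "+")))
}

new_spectrum2d <- function(mz, drift, intensity, meta = list()) {
  stopifnot(all(diff(mz) > 0), all(diff(drift) > 0),
            nrow(intensity) == length(mz), ncol(intensity) == length(drift))
  if (any(intensity < 0)) stop("spectrum intensities must be non-negative")
  structure(list(mz = mz, drift = drift, intensity = intensity,
                 meta = meta), class = "spectrum2d")
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Integrated intensity of a spectrum
#'
#' Sum of the intensity matrix times the grid cell area; for a noiseless
#' rendered spectrum whose grid covers every peak this equals the total
#' scheduled intensity of the scenarios.
#'
#' @param x A `spectrum2d`.
#' @return Scalar integrated intensity.
#' @export
integrated_intensity <- function(x) {
  stopifnot(inherits(x, "spectrum2d"))
  sum(x$intensity) * mean(diff(x$mz)) * mean(diff(x$drift))
}

#' Extract a drift-time profile from a 2D spectrum
#'
#' Sums intensity over an m/z window, giving the arrival-time distribution
#' of the species in that window.
#'
#' @param x A `spectrum2d`.
#' @param mz_window `c(lo, hi)` in Th; default the full axis.
#' @param condition Label attached to the profile (e.g. `"before"`).
#' @return A `drift_profile`: data frame with `time` (ms) and `intensity`.
#' @export
drift_profile <- function(x, mz_window = range(x$mz),
                          condition = "profile") {
  stopifnot(inherits(x, "spectrum2d"))
  rows <- x$mz >= mz_window[1] & x$mz <= mz_window[2]
  structure(data.frame(time = x$drift,
                       intensity = colSums(x$intensity[rows, , drop = FALSE])),
            condition = condition,
            class = c("drift_profile", "data.frame"))
}

#' Write / read the package's 2D-spectrum TSV format
#'
#' Plain UTF-8 TSV: `#key=value` comment lines carrying metadata (seed,
#' scenario, ...), a `mz<TAB>drift_ms<TAB>intensity` header, then one row
#' per grid cell. The round trip is lossless to double precision.
#'
#' @param x A `spectrum2d`.
#' @param path File path.
#' @return `read_spectrum` returns the `spectrum2d`; `write_spectrum`
#'   returns `path` invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum2d"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (key in names(x$meta))
    writeLines(sprintf("#%s=%s", key, x$meta[[key]]), con)
  writeLines("mz\tdrift_ms\tintensity", con)
  grid <- expand.grid(i = seq_along(x$mz), j = seq_along(x$drift))
  writeLines(sprintf("%.10g\t%.10g\t%.12g", x$mz[grid$i], x$drift[grid$j],
                     x$intensity[cbind(grid$i, grid$j)]), con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- sub("=.*$", "", kv)
      meta[[key]] <- sub("^[^=]*=", "", kv)
    }
  }
  body <- lines[!is_meta]
  if (length(body) <= 1L)
    stop("spectrum file '", path, "' contains no data rows")
  fields <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("malformed spectrum row at line ",
         which(!is_meta)[bad[1] + 1L], " of '", path, "'")
  vals <- matrix(as.numeric(unlist(fields)), ncol = 3, byrow = TRUE)
  if (anyNA(vals))
    stop("non-numeric value in spectrum file '", path, "' at line ",
         which(!is_meta)[which(is.na(rowSums(vals)))[1] + 1L])
  neg <- which(vals[, 3] < 0)
  if (length(neg))
    stop("negative intensity in spectrum file '", path, "' at line ",
         which(!is_meta)[neg[1] + 1L])
  mz <- sort(unique(vals[, 1]))
  drift <- sort(unique(vals[, 2]))
  if (nrow(vals) != length(mz) * length(drift))
    stop("spectrum file '", path, "' is not a complete m/z x drift grid")
  intensity <- matrix(0, length(mz), length(drift))
  intensity[cbind(match(vals[, 1], mz), match(vals[, 2], drift))] <- vals[, 3]
  if (!is.null(meta$seed)) meta$seed <- as.integer(meta$seed)
  new_spectrum2d(mz, drift, intensity, meta)
}

#' @export
print.spectrum2d <- function(x, ...) {
  cat(sprintf("2D IMS-MS spectrum: %d x %d grid, m/z %.2f-%.2f Th, drift %.2f-%.2f ms\n",
              length(x$mz), length(x$drift), min(x$mz), max(x$mz),
              min(x$drift), max(x$drift)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  cat(sprintf("  max intensity %.4g, integrated %.4g\n",
              max(x$intensity), integrated_intensity(x)))
  invisible(x)
}

#' @export
plot.spectrum2d <- function(x, ...) {
  graphics::image(x$drift, x$mz, t(x$intensity),
                  xlab = "drift time (ms)", ylab = "m/z (Th)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  ...)
  invisible(x)
}
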