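test_that("isotopic distribution matches the brute-force convolution oracle", {
  for (comp in list(c(C = 2L),
                    composition_from_sequence("GG"),
                    composition_from_sequence("CMW"),
                    abeta_monomer)) {
    pat <- isotopic_distribution(comp, prune_below = 0)
    expect_s3_class(pat, "isotope_pattern")
    expect_equal(sum(pat$abundance), 1, tolerance = 1e-9)
    expect_lt(tv_distance(pat, oracle_isotopic_distribution(comp)), 1e-9)
  }
})

test_that("two-carbon distribution follows the closed-form binomial", {
  r <- 0.0107  # 13C natural abundance
  pat <- isotopic_distribution(c(C = 2L), prune_below = 0)
  binom <- dbinom(0:2, 2, r)
  expect_equal(pat$abundance, binom, tolerance = 1e-12)
  expect_equal(pat$abundance[2] / pat$abundance[1],
               2 * r / (1 - r), tolerance = 1e-12)
})

test_that("abundances renormalise to one after pruning and bins are neutron-spaced", {
  pat <- isotopic_distribution(abeta_monomer, prune_below = 1e-3)
  expect_equal(sum(pat$abundance), 1, tolerance = 1e-9)
  expect_true(all(diff(pat$mass) > 0))
  expect_true(all(abs(diff(pat$mass) - 1.0033) < 0.01))
})

test_that("envelope spacing times charge stays within 0.5% of one neutron gap", {
  set.seed(42)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    seq_i <- paste(sample(aa, sample(15:120, 1), replace = TRUE),
                   collapse = "")
    comp <- composition_from_sequence(seq_i)
    pat <- isotopic_distribution(comp, prune_below = 1e-4)
    for (z in c(1, 4, 8, 12)) {
      env <- envelope_mz_peaks(pat, z)
      expect_true(all(abs(diff(env$mz) * z / 1.0033 - 1) < 0.005),
                  label = sprintf("composition %d, z=%d", i, z))
    }
  }
})

test_that("monomer and dimer envelopes at the same m/z differ by their spacing", {
  # a 4+ monomer and an 8+ dimer overlap near m/z 1083 but their
  # envelope spacings (~0.251 vs ~0.125 Th) identify them
  mon <- envelope_mz_peaks(isotopic_distribution(abeta_monomer), 4)
  dim <- envelope_mz_peaks(
    isotopic_distribution(oligomer_composition(abeta_monomer, 2, 0)), 8)
  expect_equal(median(diff(mon$mz)), 1.0033 / 4, tolerance = 2e-3)
  expect_equal(median(diff(dim$mz)), 1.0033 / 8, tolerance = 2e-3)
  expect_lt(abs(weighted.mean(mon$mz, mon$abundance) -
                  weighted.mean(dim$mz, dim$abundance)), 1.5)
})

test_that("rendered spectra are deterministic under a fixed seed", {
  sc <- species_scenario(1, 0, 4, drift_centers = 6.3, drift_widths = 0.2)
  render <- function(seed) render_spectrum(list(sc), c(1080, 1086),
                                           c(5, 8), noise_sd = 0.02,
                                           seed = seed)
  expect_identical(render(7)$intensity, render(7)$intensity)
  expect_false(identical(render(7)$intensity, render(8)$intensity))
  expect_true(all(render(7)$intensity >= 0))
})

test_that("noiseless rendering conserves scheduled intensity and recovers drift moments", {
  sc <- species_scenario(2, 1, 8, drift_centers = 7.17,
                         drift_widths = 0.25, amplitudes = 2,
                         total_intensity = 50)
  sp <- render_spectrum(list(sc), c(1078, 1090), c(5, 10), noise_sd = 0)
  expect_equal(integrated_intensity(sp), 100, tolerance = 1e-3)

  prof <- drift_profile(sp)
  mu <- weighted.mean(prof$time, prof$intensity)
  sd_fit <- sqrt(weighted.mean((prof$time - mu)^2, prof$intensity))
  expect_equal(mu, 7.17, tolerance = 1e-6)
  expect_equal(sd_fit, 0.25, tolerance = 1e-3)

  empty <- render_spectrum(list(), c(1000, 1001), c(5, 6), noise_sd = 0)
  expect_true(all(empty$intensity == 0))
})

test_that("rendering rejects grids that do not cover a species", {
  sc <- species_scenario(2, 0, 4, drift_centers = 10.4)
  expect_error(render_spectrum(list(sc), c(1000, 1010), c(5, 12)),
               "DIM4")
  expect_error(render_spectrum(list(sc), c(2160, 2175), c(5, 8)),
               "drift")
})

test_that("spectrum TSV round-trips losslessly and rejects malformed files", {
  sc <- species_scenario(1, 0, 3, drift_centers = 6.0, drift_widths = 0.3)
  sp <- render_spectrum(list(sc), c(1442, 1449), c(5, 7),
                        noise_sd = 0.01, seed = 11)
  f <- tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$mz, sp$mz, tolerance = 1e-12)
  expect_equal(back$drift, sp$drift, tolerance = 1e-12)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-12)
  expect_equal(back$meta$seed, 11L)

  writeLines(c("#seed=1", "mz\tdrift_ms\tintensity",
               "1000\t5\t-3"), f)
  expect_error(read_spectrum(f), "negative intensity.*line 3")
  writeLines(c("#seed=1", "mz\tdrift_ms\tintensity"), f)
  expect_error(read_spectrum(f), "no data rows")
})
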