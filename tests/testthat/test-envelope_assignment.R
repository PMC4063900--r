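render_species <- function(n, k, z, drift = 7, width = 0.25, ...,
                           noise_sd = 0, seed = 1) {
  sc <- species_scenario(n, k, z, drift_centers = drift,
                         drift_widths = width, total_intensity = 100)
  peaks <- envelope_mz_peaks(isotopic_distribution(sc$composition), z)
  render_spectrum(list(sc),
                  mz_range = range(peaks$mz) + c(-1, 1),
                  drift_range = c(drift - 2, drift + 2),
                  noise_sd = noise_sd, seed = seed, ...)
}

test_that("centroids land on the true peak positions of a rendered envelope", {
  sp <- render_species(1, 0, 4)
  cent <- pick_centroids(sp, range(sp$mz))
  truth <- envelope_mz_peaks(isotopic_distribution(abeta_monomer), 4)
  truth <- truth[truth$abundance > 0.05 * max(truth$abundance), ]
  for (mz in truth$mz)
    expect_lt(min(abs(cent$mz - mz)), 0.005)
})

test_that("flat or empty windows yield an empty centroid list, not an error", {
  sp <- render_species(1, 0, 4)
  expect_equal(nrow(pick_centroids(sp, c(min(sp$mz), min(sp$mz) + 0.3))), 0)
  out_of_band <- pick_centroids(sp, c(min(sp$mz), min(sp$mz) + 1e-6))
  expect_s3_class(out_of_band, "centroid_list")
  expect_equal(nrow(out_of_band), 0)
})

test_that("charge inference recovers the true charge over the full species grid", {
  for (n in 1:3)
    for (z in 2:10) {
      sp <- render_species(n, 0, z)
      cent <- pick_centroids(sp, range(sp$mz))
      expect_identical(infer_charge(cent), as.integer(z),
                       label = sprintf("n=%d z=%d", n, z))
    }
})

test_that("charge inference is invariant to uniform intensity rescaling", {
  sp <- render_species(2, 0, 6)
  cent <- pick_centroids(sp, range(sp$mz))
  scaled <- cent
  scaled$intensity <- scaled$intensity * 1e4
  expect_identical(infer_charge(cent), infer_charge(scaled))
})

test_that("drift gating disambiguates co-migrating monomer 4+ and dimer 8+", {
  mon <- species_scenario(1, 0, 4, drift_centers = 6.28,
                          drift_widths = 0.2, total_intensity = 60)
  dim <- species_scenario(2, 0, 8, drift_centers = 7.4,
                          drift_widths = 0.2, total_intensity = 60)
  sp <- render_spectrum(list(mon, dim), c(1080, 1087), c(5, 9))
  z_fast <- infer_charge(pick_centroids(sp, c(1082, 1085),
                                        drift_gate = c(6.0, 6.6)))
  z_slow <- infer_charge(pick_centroids(sp, c(1082, 1085),
                                        drift_gate = c(7.1, 7.7)))
  expect_identical(z_fast, 4L)
  expect_identical(z_slow, 8L)
})

test_that("charge inference signals insufficient or unreadable envelopes", {
  sp <- render_species(1, 0, 4)
  cent <- pick_centroids(sp, range(sp$mz))
  expect_error(infer_charge(cent[1:2, ]),
               class = "dityrims_insufficient_envelope")
  fake <- cent
  fake$mz <- seq(1000, by = 3.7, length.out = nrow(fake))  # no valid z
  expect_error(infer_charge(fake), class = "dityrims_unassignable")
})

test_that("average m/z is the intensity-weighted centroid mean", {
  sp <- render_species(2, 0, 4)
  cent <- pick_centroids(sp, range(sp$mz))
  expect_equal(average_mz(cent[3, , drop = FALSE]), cent$mz[3])
  sym <- cent[1:3, ]
  sym$intensity <- c(1, 5, 1)
  sym$mz <- c(10, 11, 12)
  expect_equal(average_mz(sym), 11)
  # simulator round trip: weighted envelope center matches theory
  th <- mz_from_mass(average_mass(oligomer_composition(abeta_monomer, 2, 0)), 4)
  expect_lt(abs(average_mz(cent) - th), 0.03)
  expect_error(average_mz(cent[0, ]), "empty")
})

test_that("species assignment recovers order and bond count from the mass alone", {
  res <- assign_species(8657.73, 4329.84, n_max = 4, tolerance = 1.0)
  expect_identical(res[c("n", "k")], list(n = 2L, k = 1L))
  res <- assign_species(12985.28, 4329.84, n_max = 4, tolerance = 1.0)
  expect_identical(res[c("n", "k")], list(n = 3L, k = 2L))
  res <- assign_species(4329.84, 4329.84)
  expect_identical(res[c("n", "k")], list(n = 1L, k = 0L))
  expect_equal(res$residual, 0)

  # exact on simulated oligomer masses for every (n <= 4, k <= n-1)
  for (n in 1:4)
    for (k in 0:(n - 1)) {
      m <- average_mass(oligomer_composition(abeta_monomer, n, k))
      res <- assign_species(m, abeta_avg, n_max = 4, tolerance = 1.0)
      expect_identical(res[c("n", "k")], list(n = n, k = k))
      expect_lt(abs(res$residual), 0.1)
    }

  err <- tryCatch(assign_species(4000, 4329.84, tolerance = 0.5),
                  dityrims_unassigned = function(e) e)
  expect_s3_class(err, "dityrims_unassigned")
  expect_identical(err$data$n, 1L)
})

test_that("assign_envelope chains picking, charge, mass and species", {
  sp <- render_species(2, 1, 8, drift = 7.17)
  res <- assign_envelope(sp, range(sp$mz), abeta_avg)
  expect_identical(res$z, 8L)
  expect_identical(c(res$n, res$k), c(2L, 1L))
  expect_lt(abs(res$mass -
                  average_mass(oligomer_composition(abeta_monomer, 2, 1))),
            0.25)
})
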