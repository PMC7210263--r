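# Independent constants for cross-checking (CODATA-derived, written here
# from first principles rather than imported from the package):
# 1 Eh = 627.509474 kcal/mol; 1 cm^-1 of photon energy = 0.0028591459 kcal/mol
IND_HARTREE <- 627.509474
IND_WAVENUMBER <- 0.0028591459

test_that("pinned unit constants match an independent table", {
  expect_equal(HARTREE_TO_KCAL, IND_HARTREE, tolerance = 1e-6)
  expect_equal(WAVENUMBER_TO_KCAL, IND_WAVENUMBER, tolerance = 1e-4)
})

test_that("zero-point energy sums positive modes only", {
  expect_equal(zpe_from_frequencies(numeric(0)), 0.0)
  expect_equal(zpe_from_frequencies(c(1000, 2000)), 0.5 * 3000 * 0.0028591)
  expect_equal(zpe_from_frequencies(c(-500, 1000)), 0.5 * 1000 * 0.0028591)
  expect_equal(zpe_from_frequencies(c(0, 100)), 0.5 * 100 * 0.0028591)
  # independent arithmetic with the stand-alone constant
  set.seed(9)
  f <- runif(20, -500, 3500)
  expect_equal(zpe_from_frequencies(f),
               sum(f[f > 0]) / 2 * 0.0028591, tolerance = 1e-12)
})

test_that("the e0 consistency identity holds to 1e-9", {
  se <- species_energetics(-100.1, c(500, 1500), level = "A")
  expect_lt(abs(se$e0 - (se$e_elec * HARTREE_TO_KCAL + se$zpe)), 1e-9)
  expect_gte(se$zpe, 0)
})

test_that("activation energy reproduces the hand-computed example", {
  # r: E = -100.100 Eh, ZPE = 31.3757 kcal/mol; ts: E = -100.000, ZPE = 28.2379
  r <- structure(list(e_elec = -100.100, zpe = 31.3757,
                      e0 = -100.100 * 627.5095 + 31.3757, level = "A"),
                 class = "species_energetics")
  ts <- structure(list(e_elec = -100.000, zpe = 28.2379,
                       e0 = -100.000 * 627.5095 + 28.2379, level = "A"),
                  class = "species_energetics")
  expect_equal(activation_energy(r, ts), 59.613, tolerance = 1e-4)
  expect_equal(activation_energy(r, r), 0.0)
})

test_that("mixing levels of theory is refused", {
  a <- species_energetics(-1, 100, level = "B97-D3/def2-mSVP")
  b <- species_energetics(-1, 100, level = "wB97X-D3/def2-TZVP")
  expect_error(activation_energy(a, b), class = "rxnforge_consistency")
  expect_error(reaction_enthalpy(a, list(b)), class = "rxnforge_consistency")
})

test_that("negative activation energies warn but are retained", {
  r <- species_energetics(-100.0, c(1000), level = "A")
  ts <- species_energetics(-100.01, c(1000), level = "A")
  expect_warning(ea <- activation_energy(r, ts), "negative")
  expect_lt(ea, 0)
})

test_that("enthalpy is additive, antisymmetric and path-consistent", {
  r <- species_energetics(-100.0, c(800, 1600), level = "A")
  p1 <- species_energetics(-60.0, c(900), level = "A")
  p2 <- species_energetics(-39.9839321, c(700), level = "A")
  expect_error(reaction_enthalpy(r, list()), class = "rxnforge_invalid_input")
  expect_equal(reaction_enthalpy(r, r), 0.0)
  # antisymmetry is exact
  set.seed(13)
  for (k in 1:25) {
    a <- species_energetics(runif(1, -120, -40), runif(5, 100, 3500), level = "A")
    b <- species_energetics(runif(1, -120, -40), runif(5, 100, 3500), level = "A")
    expect_identical(reaction_enthalpy(a, list(b)),
                     -reaction_enthalpy(b, list(a)))
    # path consistency: Ea(fwd) - Ea(rev) == dH through any shared TS
    ts <- species_energetics(max(a$e_elec, b$e_elec) + 0.05,
                             runif(4, 100, 3000), level = "A")
    ea_f <- suppressWarnings(activation_energy(a, ts))
    ea_r <- suppressWarnings(activation_energy(b, ts))
    expect_lt(abs((ea_f - ea_r) - reaction_enthalpy(a, list(b))), 1e-9)
  }
})
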