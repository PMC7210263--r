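test_that("imaginary-frequency check counts and thresholds correctly", {
  expect_equal(check_ts_imaginary(c(-612.3, 95.0, 210.0)),
               list(one_imaginary = TRUE, imag_magnitude_ok = TRUE))
  # below 100 cm^-1 in magnitude: typically a conformational mode
  expect_equal(check_ts_imaginary(c(-80.0, 150.0)),
               list(one_imaginary = TRUE, imag_magnitude_ok = FALSE))
  expect_equal(check_ts_imaginary(c(-500.0, -300.0, 900.0)),
               list(one_imaginary = FALSE, imag_magnitude_ok = FALSE))
  # exactly 100 passes ("less than 100" is the removal rule)
  expect_true(check_ts_imaginary(c(-100.0, 50))$imag_magnitude_ok)
  expect_error(check_ts_imaginary(numeric(0)), class = "rxnforge_invalid_input")
})

test_that("energy-drift boundary semantics are strict on 'more than'", {
  h <- 1 / HARTREE_TO_KCAL
  expect_true(check_energy_drift(-100 + 2.9 * h, -100))
  expect_false(check_energy_drift(-100 + 3.1 * h, -100))
  expect_true(check_energy_drift(-100 + 3.0 * h, -100))
  expect_true(check_energy_drift(-100 - 2.9 * h, -100))
})

make_ts_record <- function(elements, geometry, freqs, modes) {
  structure(list(elements = elements, geometry = geometry,
                 energy = -1, frequencies = freqs,
                 modes = lapply(modes, function(m) m / sqrt(sum(m^2))),
                 converged = TRUE, charge = 0L, multiplicity = 1L),
            class = "optfreq_result")
}

test_that("mode match isolates bond-stretch character of the imaginary mode", {
  # collinear A-H...B hydrogen transfer: only H moves, along the axis
  els <- c("O", "H", "O")
  geom <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(2.2, 0, 0))
  rg <- mol_graph(els, rbind(c(1, 2)))
  pg <- mol_graph(els, rbind(c(2, 3)))
  u <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))
  ts <- make_ts_record(els, geom, c(-800), list(u))
  mm <- check_mode_match(ts, rg, pg)
  expect_true(mm$ok)
  expect_true(all(mm$scores$score[mm$scores$role == "changing"] > 0))

  # spectator-localized mode: displacement only on an unchanged bond
  els2 <- c("O", "H", "O", "H")
  geom2 <- rbind(geom, c(-0.5, 0.8, 0))
  rg2 <- mol_graph(els2, rbind(c(1, 2), c(1, 4)))
  pg2 <- mol_graph(els2, rbind(c(2, 3), c(1, 4)))
  u2 <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(-0.5, 0.8, 0))
  ts2 <- make_ts_record(els2, geom2, c(-800), list(u2))
  expect_false(check_mode_match(ts2, rg2, pg2)$ok)

  # exact tie rejects: changing pair (1,2) and unchanged pair (3,4) are
  # geometric translates with identical mode displacements, so their scores
  # are bitwise equal and the strict comparison fails
  els3 <- c("O", "H", "O", "H")
  geom3 <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(0, 2, 0), c(1.1, 2, 0))
  rg3 <- mol_graph(els3, rbind(c(1, 2), c(3, 4)))
  pg3 <- mol_graph(els3, rbind(c(3, 4)))
  u3 <- rbind(c(-1, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0))
  s3 <- check_mode_match(make_ts_record(els3, geom3, c(-800), list(u3)),
                         rg3, pg3)
  expect_identical(s3$scores$score[s3$scores$role == "changing"],
                   s3$scores$score[s3$scores$role == "unchanged"])
  expect_false(s3$ok)

  expect_error(check_mode_match(ts, rg, rg), class = "rxnforge_no_reaction")
})

test_that("mode-match scores are invariant under rigid motion and sign flip", {
  suite <- make_verification_suite(seed = 5, n_per_class = 3,
                                   classes = "clean")
  for (q in seq_len(nrow(suite))) {
    ts <- suite$ts[[q]]
    base <- check_mode_match(ts, suite$rg[[q]], suite$pg[[q]])
    set.seed(q)
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
                c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
    R <- Rx %*% Rz
    shift <- matrix(runif(3, -5, 5), nrow(ts$geometry), 3, byrow = TRUE)
    ts2 <- ts
    ts2$geometry <- ts$geometry %*% t(R) + shift
    ts2$modes <- lapply(ts$modes, function(m) -(m %*% t(R)))
    rot <- check_mode_match(ts2, suite$rg[[q]], suite$pg[[q]])
    expect_lt(max(abs(base$scores$score - rot$scores$score)), 1e-10)
    expect_equal(base$ok, rot$ok)
  }
})

test_that("minimum check treats empty mode lists as minima", {
  expect_true(check_minimum(c(100, 200, 300)))
  expect_false(check_minimum(c(-5, 200)))
  expect_true(check_minimum(numeric(0)))
  expect_false(check_minimum(c(-0.5, 10)))
  expect_true(check_minimum(c(-0.5, 10), zero_threshold = -1))
})

test_that("verification reports are the conjunction of their checks", {
  suite <- make_verification_suite(seed = 23, n_per_class = 4)
  for (q in seq_len(nrow(suite))) {
    rep <- verify_reaction(suite$r[[q]], suite$ts[[q]], suite$p[[q]],
                           suite$rg[[q]], suite$pg[[q]], suite$string[[q]])
    expect_equal(rep$passed,
                 rep$one_imaginary && rep$imag_magnitude_ok &&
                   rep$energy_drift_ok && rep$mode_match_ok &&
                   rep$endpoints_are_minima)
    expect_equal(rep$passed, suite$should_pass[q],
                 label = paste(suite$defect[q], q))
  }
})

test_that("each defect class fails exactly its own check", {
  suite <- make_verification_suite(seed = 31, n_per_class = 3)
  expected_fail <- list(
    two_imag = "one_imaginary",
    small_imag = "imag_magnitude_ok",
    drift = "energy_drift_ok",
    spectator_mode = "mode_match_ok"
  )
  for (q in seq_len(nrow(suite))) {
    rep <- verify_reaction(suite$r[[q]], suite$ts[[q]], suite$p[[q]],
                           suite$rg[[q]], suite$pg[[q]], suite$string[[q]])
    cls <- suite$defect[q]
    if (cls == "clean") next
    expect_false(rep[[expected_fail[[cls]]]], label = cls)
    # untouched checks still pass, except magnitude which is defined FALSE
    # whenever the one-imaginary count fails
    others <- setdiff(c("energy_drift_ok", "endpoints_are_minima"),
                      expected_fail[[cls]])
    for (ck in others) expect_true(rep[[ck]], label = paste(cls, ck))
  }
})

test_that("raising the magnitude cutoff never turns a fail into a pass", {
  suite <- make_verification_suite(seed = 41, n_per_class = 3)
  for (q in seq_len(nrow(suite))) {
    lo <- verify_reaction(suite$r[[q]], suite$ts[[q]], suite$p[[q]],
                          suite$rg[[q]], suite$pg[[q]], suite$string[[q]],
                          imag_magnitude_min = 100)
    hi <- verify_reaction(suite$r[[q]], suite$ts[[q]], suite$p[[q]],
                          suite$rg[[q]], suite$pg[[q]], suite$string[[q]],
                          imag_magnitude_min = 500)
    expect_true(!(!lo$passed && hi$passed))
  }
})

test_that("tidy() lays a report out one row per check", {
  suite <- make_verification_suite(seed = 2, n_per_class = 1,
                                   classes = "clean")
  rep <- verify_reaction(suite$r[[1]], suite$ts[[1]], suite$p[[1]],
                         suite$rg[[1]], suite$pg[[1]], suite$string[[1]])
  td <- tidy(rep)
  expect_equal(nrow(td), 5)
  expect_true(all(td$passed))
})
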