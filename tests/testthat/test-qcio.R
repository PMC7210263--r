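test_that("XYZ round-trips to printed precision and validates counts", {
  one <- read_xyz("1\n\nH 0 0 0")
  expect_equal(one$elements, "H")
  expect_equal(one$geometry, matrix(0, 1, 3))
  set.seed(5)
  geom <- matrix(rnorm(15), 5, 3)
  els <- c("C", "H", "H", "H", "H")
  rt <- read_xyz(write_xyz(els, geom))
  expect_equal(rt$elements, els)
  expect_lt(max(abs(rt$geometry - geom)), 1e-6)
  expect_error(read_xyz("3\n\nH 0 0 0\nH 1 0 0"), class = "rxnforge_parse")
})

test_that("opt+freq logs round-trip every field at printed precision", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    els <- sample(c("C", "H", "O", "N"), n, replace = TRUE)
    geom <- matrix(rnorm(3 * n, sd = 2), n, 3)
    nm <- sample(1:5, 1)
    freqs <- round(c(-runif(1, 100, 900), runif(nm - 1, 10, 3800)), 4)[1:nm]
    modes <- lapply(seq_len(nm), function(k) matrix(rnorm(3 * n), n, 3))
    txt <- make_mock_optfreq_log(-100.5, els, geom, freqs, modes,
                                 converged = rep %% 2 == 0)
    r <- parse_optfreq_log(txt)
    expect_equal(r$energy, -100.5)
    expect_equal(r$elements, els)
    expect_lt(max(abs(r$geometry - geom)), 1e-7)
    expect_equal(r$frequencies, freqs)
    expect_equal(r$converged, rep %% 2 == 0)
    for (k in seq_len(nm)) {
      expect_equal(sqrt(sum(r$modes[[k]]^2)), 1, tolerance = 1e-8)
      unit <- modes[[k]] / sqrt(sum(modes[[k]]^2))
      expect_lt(max(abs(r$modes[[k]] - unit)), 1e-6)
    }
  }
})

test_that("imaginary frequencies stay negative end to end", {
  txt <- make_mock_optfreq_log(-1.0, c("O", "H"), matrix(0:5, 2, 3),
                               c(-500, 1200),
                               list(matrix(1, 2, 3), matrix(2, 2, 3)))
  r <- parse_optfreq_log(txt)
  expect_equal(r$frequencies, c(-500, 1200))
  expect_length(r$modes, 2)
})

test_that("incomplete logs error instead of defaulting", {
  full <- make_mock_optfreq_log(-1.0, c("O", "H"), matrix(0:5, 2, 3),
                                c(100), list(matrix(1, 2, 3)))
  lines <- strsplit(full, "\n")[[1]]
  truncated <- paste(lines[seq_len(grep("^frequencies$", lines) - 2)],
                     collapse = "\n")
  expect_error(parse_optfreq_log(truncated), class = "rxnforge_incomplete_log")
  expect_error(parse_optfreq_log("not a log"), class = "rxnforge_parse")
  expect_error(
    make_mock_optfreq_log(-1, c("O", "H"), matrix(0:5, 2, 3),
                          c(1, 2), list(matrix(1, 2, 3))),
    class = "rxnforge_spec")
})

test_that("string paths locate the highest-energy node, first on ties", {
  g <- matrix(rnorm(9), 3, 3)
  sp <- parse_string_output(make_mock_string_output(
    c(0.0, 0.030, 0.010), c("O", "H", "H"), g, g))
  expect_equal(sp$ts_node_index, 2)
  sp2 <- parse_string_output(make_mock_string_output(
    c(0.0, 0.030, 0.030), c("O", "H", "H"), g, g))
  expect_equal(sp2$ts_node_index, 2)
  expect_error(make_mock_string_output(0.1, c("H"), matrix(0, 1, 3),
                                       matrix(0, 1, 3)),
               class = "rxnforge_spec")
})

test_that("engine inputs are deterministic and validated", {
  cfg <- engine_config("B97-D3", "def2-mSVP")
  g <- matrix(seq_len(15) / 7, 5, 3)
  els <- c("C", "H", "H", "H", "H")
  expect_identical(write_engine_input(els, g, cfg),
                   write_engine_input(els, g, cfg))
  expect_equal(length(grep("^[A-Z]", strsplit(write_engine_input(els, g, cfg),
                                              "\n")[[1]])), 5)
  expect_error(engine_config("B97-D3", ""), class = "rxnforge_config")
})

test_that("seeded batches of mock logs are distinct and reproducible", {
  gen <- function() {
    vapply(1:50, function(i) {
      set.seed(i)
      n <- 3L
      make_mock_optfreq_log(-50 - runif(1), c("O", "H", "H"),
                            matrix(rnorm(9), 3, 3), runif(3, 100, 3000),
                            lapply(1:3, function(k) matrix(rnorm(9), 3, 3)))
    }, character(1))
  }
  b1 <- gen(); b2 <- gen()
  expect_identical(b1, b2)
  expect_equal(length(unique(b1)), 50)
  for (txt in b1[1:5]) expect_s3_class(parse_optfreq_log(txt), "optfreq_result")
})
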