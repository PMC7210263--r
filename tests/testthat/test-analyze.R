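# small hand-mapped reactions used across the analysis tests
rsmi_water <- "[O:1]([H:2])[H:3]"
psmi_water <- "[O:1][H:2].[H:3]"            # O-H homolysis
rsmi_ch4 <- "[C:1]([H:2])([H:3])([H:4])[H:5]"
psmi_ch4 <- "[C:1]([H:4])[H:5].[H:2][H:3]"  # CH2 + H2
rsmi_ethane <- "[C:1]([C:2]([H:6])([H:7])[H:8])([H:3])([H:4])[H:5]"
psmi_ethene <- "[C:1](=[C:2]([H:7])[H:8])([H:4])[H:5].[H:3][H:6]"

test_that("bond-change counts use connectivity only", {
  expect_equal(count_bond_changes(rsmi_water, rsmi_water), 0)
  expect_equal(count_bond_changes(rsmi_water, psmi_water), 1)
  expect_equal(count_bond_changes(rsmi_ch4, psmi_ch4), 3)
  # the ethane -> ethene C-C order change does not count here
  expect_equal(count_bond_changes(rsmi_ethane, psmi_ethene), 3)
})

test_that("bond-change types include pure order changes", {
  expect_equal(bond_change_types(rsmi_ch4, psmi_ch4),
               sort(c("C-H", "C-H", "H-H")))
  expect_equal(bond_change_types(rsmi_ethane, psmi_ethene),
               sort(c("C-H", "C-H", "H-H", "C-C")))
  expect_equal(bond_change_types(rsmi_water, rsmi_water), character(0))
  # type multiset is never smaller than the connectivity count
  for (pair in list(c(rsmi_water, psmi_water), c(rsmi_ch4, psmi_ch4),
                    c(rsmi_ethane, psmi_ethene))) {
    expect_gte(length(bond_change_types(pair[1], pair[2])),
               count_bond_changes(pair[1], pair[2]))
  }
})

test_that("the reactive center collects atoms incident to any change", {
  expect_equal(reactive_center(rsmi_water, psmi_water), c(1, 3))
  expect_equal(reactive_center(rsmi_ch4, psmi_ch4), c(1, 2, 3))
  # order change pulls both carbons in
  expect_true(all(c(1, 2) %in% reactive_center(rsmi_ethane, psmi_ethene)))
  expect_error(reactive_center(rsmi_water, rsmi_water),
               class = "rxnforge_no_reaction")
})

test_that("templates are label-invariant and spectator-invariant", {
  t_water <- extract_template(rsmi_water, psmi_water)
  # same reaction, relabeled hydrogens
  t_water2 <- extract_template("[O:1]([H:3])[H:2]", "[O:1][H:3].[H:2]")
  expect_identical(t_water, t_water2)
  # methanol O-H homolysis: same center, extra spectator methyl
  t_meoh <- extract_template(
    "[C:1]([H:4])([H:5])([H:6])[O:2][H:3]",
    "[C:1]([H:4])([H:5])([H:6])[O:2].[H:3]")
  expect_identical(t_water, t_meoh)
  # element identity in the center distinguishes templates
  t_ch <- extract_template(rsmi_ch4, psmi_ch4)
  expect_false(identical(t_water, t_ch))
})

test_that("template ranking is count-descending with string tie-break", {
  tbl <- tibble::tibble(
    rsmi = c(rsmi_water, rsmi_water, rsmi_water, rsmi_ch4),
    psmi = c(psmi_water, psmi_water, psmi_water, psmi_ch4)
  )
  rk <- template_ranking(tbl)
  expect_equal(rk$n, c(3L, 1L))
  expect_equal(rk$template[1], extract_template(rsmi_water, psmi_water))
  expect_equal(nrow(template_ranking(tbl[0, ])), 0)
})

test_that("grouped activation-energy densities integrate to one", {
  tbl <- tibble::tibble(
    rsmi = c(rep(rsmi_water, 8), rep(rsmi_ch4, 5), rsmi_ethane),
    psmi = c(rep(psmi_water, 8), rep(psmi_ch4, 5), psmi_ethene),
    ea = c(rnorm(8, 40, 8), rnorm(5, 70, 10), 95)
  )
  groups <- ea_by_change_count(tbl)
  expect_equal(sort(groups$n_changes), c(1L, 3L))
  for (d in groups$density) {
    area <- sum(diff(d$ea) * (head(d$dens, -1) + tail(d$dens, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-6)
  }
})

test_that("the bivariate Gaussian KDE has the closed-form point mass", {
  k1 <- kde2d_reactions(data.frame(dh = 0, ea = 0), h = 2,
                        lims = c(-8, 8, -8, 8), gridsize = 101)
  center <- k1$z[51, 51]
  expect_equal(center, 1 / (2 * pi * 4), tolerance = 1e-12)
  # mass integrates to 1 within grid truncation
  set.seed(3)
  tbl <- data.frame(dh = rnorm(60, 0, 12), ea = rnorm(60, 50, 20))
  k <- kde2d_reactions(tbl)
  mass <- sum(k$z) * diff(k$x[1:2]) * diff(k$y[1:2])
  expect_equal(mass, 1, tolerance = 0.01)
  expect_error(kde2d_reactions(data.frame(dh = 1, ea = 1)),
               class = "rxnforge_invalid_input")
})

test_that("analysis plots build without evaluation errors", {
  tbl <- tibble::tibble(
    rsmi = c(rep(rsmi_water, 3), rsmi_ch4),
    psmi = c(rep(psmi_water, 3), psmi_ch4),
    ea = c(40, 42, 44, 70), dh = c(10, 12, 9, 35)
  )
  expect_s3_class(autoplot(kde2d_reactions(tbl, h = c(5, 5))), "ggplot")
  expect_s3_class(plot_ea_by_change_count(ea_by_change_count(tbl)), "ggplot")
  expect_s3_class(plot_bond_change_types(tbl), "ggplot")
  expect_s3_class(plot_template_ranking(template_ranking(tbl)), "ggplot")
})

test_that("analyses run off a written dataset CSV", {
  cfg <- generation_config(seed = 7)
  res <- run_generation(c("C", "CO"), cfg)
  d <- withr::local_tempdir()
  write_dataset(res$dataset, d)
  tbl <- read_dataset(file.path(d, "reactions.csv"))
  counts <- purrr::map2_int(tbl$rsmi, tbl$psmi, count_bond_changes)
  expect_true(all(counts >= 2 & counts <= 3))
  rk <- template_ranking(tbl)
  expect_gt(nrow(rk), 0)
  expect_true(all(grepl(">>", rk$template, fixed = TRUE)))
})
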