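test_that("presets reproduce the study conditions", {
  sc <- preset("thermal-35")
  expect_equal(sc$beam$energy_eV, 0.025)
  expect_equal(sc$boron_ppm, 35)
  expect_equal(sc$length_cm, 10)
  expect_equal(sc$diameter_cm, 5)
  expect_equal(sc$bin_cm, 0.25)
  # all thermal and epithermal presets exist at 35/50/100 ppm
  expect_true(all(c("thermal-35", "thermal-50", "thermal-100",
                    "epi-1eV", "epi-10eV", "epi-100eV", "epi-1keV",
                    "epi-10keV", "epi-1eV-50", "epi-10keV-100") %in%
                    preset_names()))
  # epithermal band: 0.4 eV - 10 keV
  for (nm in grep("^epi-", preset_names(), value = TRUE)) {
    e <- preset(nm)$beam$energy_eV
    expect_gte(e, 0.4); expect_lte(e, 1e4)
  }
  expect_error(preset("thermal-17"), "available")
})

test_that("scenarios round-trip through the YAML run-config format", {
  for (nm in c("thermal-50", "epi-1keV", "no-boron", "toy-absorber")) {
    sc <- preset(nm)
    path <- tempfile(fileext = ".yaml")
    scenario_write(sc, path)
    expect_equal(scenario_read(path), sc)
    unlink(path)
  }
})

test_that("toy absorber captures at the analytic mean depth", {
  pr <- cached_run("toy-1e5",
                   run_scenario(toy_absorber(1, 1e24), histories = 1e5,
                                seed = 17))
  d <- pr$data
  mc_mean <- sum(d$depth_cm * d$captures) / sum(d$captures)
  expect_equal(mc_mean, 1.0, tolerance = 0.02)
  # zero density: all neutrons traverse without interacting
  p0 <- run_scenario(toy_absorber(1, 0), histories = 500, seed = 4)
  expect_true(all(p0$data$total_Gy == 0))
  expect_equal(p0$meta$n_escaped, 500)
  expect_true(summarize_profile(p0)$empty)
  # two seeds give statistically compatible attenuation
  pr2 <- run_scenario(toy_absorber(1, 1e24), histories = 2e4, seed = 18)
  m2 <- sum(pr2$data$depth_cm * pr2$data$captures) / sum(pr2$data$captures)
  expect_equal(m2, mc_mean, tolerance = 0.03)
})

test_that("every tissue preset runs end to end at reduced scale", {
  for (nm in c("thermal-35", "epi-10eV", "epi-1keV")) {
    pr <- run_scenario(preset(nm), histories = 1000, seed = 5)
    expect_s3_class(pr, "dose_profile")
    expect_identical(nrow(pr$data), 40L)
    expect_gt(sum(pr$data$total_Gy), 0)
    expect_lt(pr$meta$max_ledger_residual, 1e-6)
  }
})
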