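test_that("embedded masses are consistent with A and with printed Q-values", {
  tab <- nuclide_table()
  expect_true(all(tab$mass_u > 0))
  expect_true(all(tab$Z <= tab$A))
  # nuclear masses differ from A * u by the mass excess, < 1%
  expect_true(all(abs(tab$mass_MeV / (tab$A * 931.494) - 1) < 0.01))

  # fusion-source Q-values reproduce the quoted 3.27 and 17.6 MeV within 1%
  expect_equal(reaction_channels("d+d")$Q_MeV, 3.27, tolerance = 0.01)
  expect_equal(reaction_channels("d+t")$Q_MeV, 17.6, tolerance = 0.01)
  # capture ground-state channel energy from masses matches the printed 2.79
  b10 <- reaction_channels("n+B10")
  expect_equal(b10$Q_MeV[b10$channel == "ground"], 2.79, tolerance = 0.002)
  # excited channel = ground minus the 0.478 MeV level
  expect_equal(diff(rev(b10$Q_MeV)), -0.47761, tolerance = 1e-9)
})

test_that("capture branching fractions are 93.9/6.1 and sum to one", {
  b10 <- reaction_channels("n+B10")
  expect_identical(sort(b10$branching), c(0.061, 0.939))
  expect_lt(abs(sum(b10$branching) - 1), 1e-12)
})

test_that("build_tissue loads B-10 at the requested ppm", {
  t0 <- build_tissue(0)
  expect_equal(t0$composition$number_density[t0$composition$symbol == "B-10"],
               0)
  expect_lt(abs(sum(t0$composition$mass_fraction) - 1), 1e-9)

  t35 <- build_tissue(35)
  n_b <- t35$composition$number_density[t35$composition$symbol == "B-10"]
  # hand evaluation: 35e-6 * 1.0 * N_A / 10.013
  expect_equal(n_b, 35e-6 * 6.02214076e23 / 10.01293695, tolerance = 1e-12)
  expect_equal(n_b, 2.1e18, tolerance = 0.01)
  expect_lt(abs(sum(t35$composition$mass_fraction) - 1), 1e-9)

  # linearity of the loading
  n100 <- build_tissue(100)$composition
  n50 <- build_tissue(50)$composition
  expect_equal(n100$number_density[n100$symbol == "B-10"] /
                 n50$number_density[n50$symbol == "B-10"], 2,
               tolerance = 1e-4)

  expect_error(build_tissue(-1), "non-negative")
  expect_error(build_tissue(2e4), "loading range")
})

test_that("macroscopic cross sections sum channels and follow 1/v", {
  # pure B-10 absorber: N = 1e20, sigma = 3837 b -> Sigma = 0.3837 /cm
  m <- toy_material(3837, 1e20)
  expect_equal(macroscopic_xs(m, 0.025, "capture"), 1e20 * 3837e-24,
               tolerance = 1e-12)

  # capture Sigma(E) * sqrt(E) constant over 7 decades (1/v law)
  ti <- build_tissue(35)
  e <- 10^seq(-4, 3, length.out = 15)
  s <- vapply(e, function(x) macroscopic_xs(ti, x, "capture"), 0)
  expect_lt(diff(range(s * sqrt(e))) / mean(s * sqrt(e)), 1e-12)

  # channel additivity and filtering
  tot <- macroscopic_xs(ti, 0.025, "total")
  expect_equal(macroscopic_xs(ti, 0.025, "capture") +
                 macroscopic_xs(ti, 0.025, "elastic"), tot,
               tolerance = 1e-12)
  expect_equal(macroscopic_xs(ti, 0.025, "B10_nalpha") +
                 macroscopic_xs(ti, 0.025, "H_ngamma") +
                 macroscopic_xs(ti, 0.025, "N14_np"),
               macroscopic_xs(ti, 0.025, "capture"), tolerance = 1e-12)
  expect_error(macroscopic_xs(ti, 0.025, "fission"), "unknown channel")

  # empty material
  expect_equal(macroscopic_xs(toy_material(0, 0), 1, "total"), 0)

  # non-negative over the full energy range of interest
  e_wide <- 10^seq(-5, log10(2e7), length.out = 25)
  expect_true(all(vapply(e_wide,
                         function(x) macroscopic_xs(ti, x, "total"), 0) >= 0))
})

test_that("atoms_per_cell matches the hand-evaluated number density", {
  # (pi/6) (10 um)^3 * 1 g/cm^3 * 35e-6 * N_A / M(B-10) ~ 1.1e9
  expect_equal(atoms_per_cell(35, 10), 1.1e9, tolerance = 0.01)
  expect_identical(atoms_per_cell(0, 12), 0)
  expect_equal(atoms_per_cell(70, 7), 2 * atoms_per_cell(35, 7),
               tolerance = 1e-12)
})
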