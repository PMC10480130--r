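test_that("two-body partition reproduces the printed product energies", {
  m_a <- nuclide_mass_u("He-4"); m_li <- nuclide_mass_u("Li-7")
  m_n <- nuclide_mass_u("n")
  b10 <- reaction_channels("n+B10")
  # excited branch: alpha 1.47 / Li-7 0.84 MeV
  exc <- partition_at_rest(b10$Q_MeV[b10$channel == "excited"], m_a, m_li)
  expect_equal(unname(round(exc, 2)), c(1.47, 0.84))
  # ground branch: alpha 1.78 / Li-7 1.01 MeV
  gnd <- partition_at_rest(b10$Q_MeV[b10$channel == "ground"], m_a, m_li)
  expect_equal(unname(round(gnd, 2)), c(1.78, 1.01))
  # D-D: n 2.45 / He-3 0.82; D-T: n 14.05 / He-4 3.54
  dd <- partition_at_rest(reaction_channels("d+d")$Q_MeV, m_n,
                          nuclide_mass_u("He-3"))
  expect_equal(unname(round(dd, 2)), c(2.45, 0.82))
  dt <- partition_at_rest(reaction_channels("d+t")$Q_MeV, m_n,
                          nuclide_mass_u("He-4"))
  expect_equal(unname(round(dt, 2)), c(14.05, 3.54))
})

test_that("partition respects momentum balance and the degenerate cases", {
  p <- partition_at_rest(5, 3, 7)
  # E_light/E_heavy = m_heavy/m_light exactly; sum = Q exactly
  expect_equal(p[["E_light"]] / p[["E_heavy"]], 7 / 3, tolerance = 1e-15)
  expect_identical(sum(p), 5)
  # equal momenta: p^2 = 2 m E
  expect_equal(2 * 3 * p[["E_light"]], 2 * 7 * p[["E_heavy"]],
               tolerance = 1e-12)
  expect_identical(unname(partition_at_rest(0, 1, 2)), c(0, 0))
  expect_error(partition_at_rest(-0.1, 1, 2), "non-negative")
})

test_that("neutron emission-angle formula matches limits and printed bounds", {
  # E_d = 0: angle-independent, equals the at-rest partition
  for (r in c("dd", "dt")) {
    ch <- reaction_channels(if (r == "dd") "d+d" else "d+t")
    p0 <- partition_at_rest(ch$Q_MeV, nuclide_mass_u("n"),
                            nuclide_mass_u(ch$heavy))
    th <- c(0, 0.7, pi / 2, 2.5, pi)
    expect_equal(neutron_energy(0, th, r), rep(p0[["E_light"]], 5),
                 tolerance = 1e-12)
    # continuous limit E_d -> 0: at theta = pi/2 the linear sqrt(E_d) term
    # vanishes and convergence is first order in E_d
    expect_equal(neutron_energy(1e-12, pi / 2, r), p0[["E_light"]],
                 tolerance = 1e-9)
    # at a general angle the approach is O(sqrt(E_d))
    expect_equal(neutron_energy(1e-12, 1, r), p0[["E_light"]],
                 tolerance = 1e-5)
  }
  # design-envelope endpoint: D-D at 0.5 MeV, forward
  expect_equal(signif(neutron_energy(0.5, 0, "dd"), 2), 3.5)
  # monotone decreasing in angle at fixed E_d
  th <- seq(0, pi, length.out = 200)
  for (ed in c(0.2, 0.35, 0.5)) {
    en <- neutron_energy(ed, th, "dd")
    expect_true(all(diff(en) < 0))
    en_t <- neutron_energy(ed, th, "dt")
    expect_true(all(diff(en_t) < 0))
  }
})

test_that("closed form agrees with the numeric conservation oracle", {
  # spot value derived from the numeric solver
  expect_equal(conservation_oracle(0.2, pi / 2, "dd")$E_light, 2.50,
               tolerance = 2e-3)
  # D-T at rest reproduces 14.05 / 3.54
  o <- conservation_oracle(0, 0.3, "dt")
  expect_equal(round(c(o$E_light, o$E_heavy), 2), c(14.05, 3.54))

  # grid equivalence: max relative deviation < 1e-6
  set.seed(11)
  ed <- runif(12, 0.01, 0.5)
  th <- runif(12, 0, pi)
  for (r in c("dd", "dt")) {
    dev <- vapply(seq_along(ed), function(i) {
      en <- neutron_energy(ed[i], th[i], r)
      abs(conservation_oracle(ed[i], th[i], r)$E_light - en) / en
    }, 0)
    expect_lt(max(dev), 1e-6)
  }
  # energy + momentum closure of the oracle result
  o2 <- conservation_oracle(0.4, 1.1, "dd")
  rs <- reaction_channels("d+d")
  expect_equal(o2$E_light + o2$E_heavy, 0.4 + rs$Q_MeV, tolerance = 1e-9)
})

test_that("energy envelope attains its extremes at the stated corners", {
  ev <- energy_envelope(c(0.2, 0.5), "dd")
  expect_equal(signif(ev$max, 2), 3.5)
  # scan minimum ~1.89 MeV at (0.5 MeV, pi); the printed 1.8 is not forced
  expect_equal(ev$min, 1.89, tolerance = 0.005)
  expect_equal(unname(ev$argmax), c(0.5, 0), tolerance = 1e-9)
  expect_equal(unname(ev$argmin), c(0.5, pi), tolerance = 1e-9)
  # degenerate range: a 1-D curve in theta
  ev1 <- energy_envelope(c(0.3, 0.3), "dd", n_ed = 1, n_theta = 50)
  expect_identical(dim(ev1$E_n), c(1L, 50L))
  expect_error(energy_envelope(c(0, 0.5)), "ed_range")
  tab <- as.data.frame(ev1)
  expect_identical(nrow(tab), 50L)
})
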