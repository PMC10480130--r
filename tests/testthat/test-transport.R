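test_that("free-path sampling is exponential with mean 1/Sigma", {
  # Sigma = 0.5 /cm -> mean 2.0 cm
  m <- toy_material(5000, 1e20)  # 5000 b * 1e20 = 0.5 /cm at 0.025 eV
  fp <- sample_free_path(m, 0.025, n = 1e5, seed = 5)
  expect_equal(mean(fp), 2.0, tolerance = 0.02)
  # doubling the number density halves the mean free path
  fp2 <- sample_free_path(toy_material(5000, 2e20), 0.025, n = 1e5, seed = 5)
  expect_equal(mean(fp2), 1.0, tolerance = 0.02)
  # fixed seed -> identical sequence; zero cross section -> infinite path
  expect_identical(fp, sample_free_path(m, 0.025, n = 1e5, seed = 5))
  expect_identical(sample_free_path(toy_material(0, 0), 1, n = 3, seed = 1),
                   rep(Inf, 3))
})

test_that("collision channel frequencies follow the cross-section ratios", {
  # single-nuclide material: that nuclide always
  m1 <- toy_material(100, 1e20, sigma_elastic_b = 50)
  draws <- sample_collision(m1, 0.025, n = 500, seed = 2)
  expect_identical(nrow(draws), 500L)
  expect_true(all(draws$symbol == "X"))
  # capture fraction = sigma_cap / (sigma_cap + sigma_el) at the thermal point
  p_cap <- 100 / 150
  n_cap <- sum(draws$channel == "capture")
  expect_lt(abs(n_cap / 500 - p_cap), 3 * sqrt(p_cap * (1 - p_cap) / 500))
  # tissue at 10 keV: capture nearly vanishes (1/v), H elastic dominates
  ti <- build_tissue(35)
  d2 <- sample_collision(ti, 1e4, n = 2000, seed = 3)
  expect_lt(mean(d2$channel == "capture"), 0.005)
  expect_gt(mean(d2$symbol == "H-1"), 0.7)
})

test_that("elastic scattering on hydrogen gives a uniform energy spectrum", {
  s <- elastic_scatter(1000, "H-1", n = 2e4, seed = 31, free_gas = FALSE)
  expect_equal(mean(s$E_out_eV) / 1000, 0.5, tolerance = 0.01)
  ks <- stats::ks.test(s$E_out_eV / 1000, "punif")
  expect_gt(ks$p.value, 0.01)
  # forward-peaked lab cosine: mean mu = 2/(3A), A = 1.0078 for H-1
  expect_equal(mean(s$mu_lab), 2 / (3 * nuclide_mass_u("H-1")),
               tolerance = 0.01)
})

test_that("mean logarithmic energy decrement matches the textbook xi", {
  # xi = 1 + alpha ln(alpha) / (1 - alpha), alpha = ((A-1)/(A+1))^2
  a_o <- nuclide_mass_u("O-16")
  alpha <- ((a_o - 1) / (a_o + 1))^2
  xi_th <- 1 + alpha * log(alpha) / (1 - alpha)
  s <- elastic_scatter(100, "O-16", n = 1e5, seed = 32, free_gas = FALSE)
  expect_equal(mean(log(100 / s$E_out_eV)), xi_th, tolerance = 0.01)
  expect_equal(xi_th, 0.120, tolerance = 0.01)
})

test_that("free-gas scattering thermalizes to the medium temperature", {
  kT <- 8.617333262e-5 * 293.6
  e <- thermalization_chain(1.0, "H-1", n_collisions = 60,
                            n_chains = 10000, seed = 7)
  # the post-collision chain is collision-rate biased; weight by
  # 1/(sigma_eff(E) v) to estimate the population (density) mean, 3/2 kT
  x2 <- e / kT
  x <- sqrt(x2)
  g <- (1 + 0.5 / x2) * (2 * stats::pnorm(x * sqrt(2)) - 1) +
    exp(-x2) / (x * sqrt(pi))
  w <- 1 / (g * sqrt(e))
  expect_equal(sum(w * e) / sum(w) / kT, 1.5, tolerance = 0.05)
  # up-scatter occurs: starting at kT/10, some chains end above kT
  e2 <- thermalization_chain(kT / 10, "H-1", n_collisions = 20,
                             n_chains = 2000, seed = 8)
  expect_gt(mean(e2 > kT), 0.2)
})

test_that("capture events deposit the correct channel energies", {
  ev <- capture_event("B-10", n = 2e4, seed = 12)
  # branch frequency ~93.9% within 3 sigma binomial
  p_hat <- mean(ev$branch == "excited")
  expect_lt(abs(p_hat - 0.939), 3 * sqrt(0.939 * 0.061 / 2e4))
  # excited branch: 1.47 + 0.84 MeV charged + 0.478 gamma (thermal limit)
  exc <- ev[ev$branch == "excited", ][1, ]
  expect_equal(round(c(exc$boron_alpha, exc$boron_li7), 2), c(1.47, 0.84))
  expect_equal(exc$gamma_MeV, 0.47761, tolerance = 1e-9)
  gnd <- ev[ev$branch == "ground", ][1, ]
  expect_equal(round(c(gnd$boron_alpha, gnd$boron_li7), 2), c(1.78, 1.01))
  expect_identical(gnd$gamma_MeV, 0)
  # N-14(n,p): proton ~0.584 MeV from the Q = 0.626 partition
  np <- capture_event("N-14", n = 1, seed = 1)
  expect_equal(np$n14_proton, 0.584, tolerance = 0.002)
  # H(n,gamma): 2.22 MeV photon, keV-scale deuteron recoil
  hg <- capture_event("H-1", n = 1, seed = 1)
  expect_equal(hg$gamma_MeV, 2.2233, tolerance = 1e-3)
  expect_lt(hg$other_recoil, 0.002)
})

test_that("transport runs are reproducible and conserve energy per history", {
  pr1 <- run_scenario(preset("thermal-35"), histories = 3000, seed = 99)
  pr2 <- run_scenario(preset("thermal-35"), histories = 3000, seed = 99)
  expect_identical(pr1$data, pr2$data)
  # 1e4-history energy-ledger audit closes to 1e-6 relative per history
  audit <- ci_run("thermal-35")
  expect_lt(audit$meta$max_ledger_residual, 1e-6)
  # no boron -> boron dose identically zero; total dose still positive
  p0 <- ci_run("no-boron")
  expect_true(all(p0$data$boron_Gy == 0))
  expect_gt(sum(p0$data$total_Gy), 0)
  # boron dose never exceeds total dose
  pt <- ci_run("thermal-35")
  expect_true(all(pt$data$boron_Gy <= pt$data$total_Gy + 1e-30))
  expect_true(all(pt$data$total_Gy >= 0))
})

test_that("pure-absorber capture density follows exp(-Sigma z)", {
  # Sigma_a = 1 /cm toy absorber, no scattering
  pr <- cached_run("toy-1e5",
                   run_scenario(toy_absorber(1, 1e24), histories = 1e5,
                                seed = 17))
  d <- pr$data
  # Poisson log-linear fit of the capture counts over the first 6 cm
  sel <- d$depth_cm < 6 & d$captures > 0
  fit <- stats::glm(captures ~ depth_cm, family = stats::poisson,
                    data = d[sel, ])
  expect_equal(unname(-1 / stats::coef(fit)[2]), 1.0, tolerance = 0.02)
  # binned mean capture depth matches the truncated-exponential oracle
  edges <- seq(0, 10, by = 0.25)
  p_bin <- exp(-edges[-length(edges)]) - exp(-edges[-1])
  oracle_mean <- sum(d$depth_cm * p_bin) / sum(p_bin)
  mc_mean <- sum(d$depth_cm * d$captures) / sum(d$captures)
  expect_equal(mc_mean, oracle_mean, tolerance = 0.02)
})

test_that("gamma policies redistribute but never create energy", {
  sc <- preset("thermal-35")
  doses <- vapply(c("discard", "local", "kernel"), function(gp) {
    pr <- run_scenario(sc, histories = 5000, seed = 21, gamma_policy = gp)
    sum(pr$data$total_Gy)
  }, 0)
  # discarding photons gives the least dose; local deposit the most
  expect_lt(doses[["discard"]], doses[["kernel"]])
  expect_lt(doses[["kernel"]], doses[["local"]])
  # boron dose is photon-policy independent
  b <- vapply(c("discard", "local"), function(gp) {
    pr <- run_scenario(sc, histories = 5000, seed = 21, gamma_policy = gp)
    sum(pr$data$boron_Gy)
  }, 0)
  expect_equal(b[["discard"]], b[["local"]], tolerance = 1e-12)
})
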