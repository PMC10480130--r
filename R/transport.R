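#' Monoenergetic, monodirectional neutron beam
#'
#' The idealised source used throughout: monoenergetic neutrons entering the
#' phantom entry face along the cylinder axis. The default is a pencil beam
#' on axis; a disc beam of finite radius (uniform over the disc) is
#' available.
#'
#' @param energy_eV Neutron kinetic energy in eV (> 0).
#' @param radius_cm Beam radius in cm; 0 = pencil beam.
#' @return A `beam_spec` object.
#' @export
#' @examples
#' beam_spec(0.025)
beam_spec <- function(energy_eV, radius_cm = 0) {
  if (!is.finite(energy_eV) || energy_eV <= 0)
    stop("beam energy must be positive")
  stopifnot(radius_cm >= 0)
  structure(list(energy_eV = energy_eV, radius_cm = radius_cm),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> %g eV, %s\n", x$energy_eV,
              if (x$radius_cm > 0) paste0("disc r = ", x$radius_cm, " cm")
              else "pencil beam"))
  invisible(x)
}

#' Cylindrical scoring phantom
#'
#' A homogeneous cylinder; the beam enters the flat face at depth 0 and the
#' cylinder axis is the depth axis. The default 10 cm x 5 cm-diameter
#' geometry is the standard tissue target of this package ("5 cm wide" read
#' as diameter).
#'
#' @param material A `material` object (e.g. [build_tissue()]).
#' @param length_cm Cylinder length (depth extent), cm.
#' @param diameter_cm Cylinder diameter, cm.
#' @return A `cylinder_phantom` object.
#' @export
#' @examples
#' cylinder_phantom(build_tissue(35))
cylinder_phantom <- function(material, length_cm = 10, diameter_cm = 5) {
  stopifnot(inherits(material, "material"), length_cm > 0, diameter_cm > 0)
  structure(list(material = material, length_cm = length_cm,
                 diameter_cm = diameter_cm),
            class = "cylinder_phantom")
}

#' @export
print.cylinder_phantom <- function(x, ...) {
  cat(sprintf("<cylinder_phantom> %g cm x %g cm diameter, %s\n",
              x$length_cm, x$diameter_cm, x$material$name))
  invisible(x)
}

# internal: capture-channel constants handed to the C++ kernel
capture_constants <- function() {
  if (!is.null(.bnct$cap_const)) return(.bnct$cap_const)
  k <- nuclear_constants()
  b10 <- reaction_channels("n+B10")
  m_a <- nuclide_mass_u("He-4"); m_li <- nuclide_mass_u("Li-7")
  h <- reaction_channels("n+H1")
  m_d_mev <- nuclide("H-2")$mass_MeV
  n14 <- reaction_channels("n+N14")
  m_p <- nuclide_mass_u("H-1"); m_c14 <- nuclide_mass_u("C-14")
  .bnct$cap_const <- list(
    b10_p_excited = b10$branching[b10$channel == "excited"],
    b10_Q_excited = b10$Q_MeV[b10$channel == "excited"],
    b10_Q_ground = b10$Q_MeV[b10$channel == "ground"],
    b10_gamma = k$excited_levels_MeV[["Li-7"]],
    b10_frac_light = m_li / (m_a + m_li),
    h_Q = h$Q_MeV,
    h_recoil = h$Q_MeV^2 / (2 * m_d_mev),
    n14_Q = n14$Q_MeV,
    n14_frac_light = m_c14 / (m_p + m_c14),
    mu_gamma_478 = k$gamma_attenuation_per_cm[["0.478"]],
    mu_gamma_2224 = k$gamma_attenuation_per_cm[["2.224"]])
  .bnct$cap_const
}

.capture_kind_codes <- c(negligible = 0L, B10_nalpha = 1L, H_ngamma = 2L,
                         N14_np = 3L, generic = 4L)

# internal: material -> kernel argument list
material_arrays <- function(material) {
  comp <- material$composition
  codes <- .capture_kind_codes[comp$capture_kind]
  if (anyNA(codes))
    stop("unknown capture kind: ",
         paste(comp$capture_kind[is.na(codes)], collapse = ", "))
  list(N = comp$number_density, sigma_el = comp$sigma_elastic_b,
       sigma_cap = comp$sigma_capture_b, cap_kind = unname(codes),
       A_u = comp$mass_u)
}

.dose_components <- c("boron_alpha", "boron_li7", "capture_gamma",
                      "proton_recoil", "n14_proton", "c14_recoil",
                      "other_recoil")

#' Run the Monte Carlo neutron transport and dose scoring
#'
#' Tracks `n_histories` source neutrons through the phantom with analog
#' Monte Carlo: exponential free flights on the total macroscopic cross
#' section, isotropic centre-of-mass elastic scattering (free-gas target
#' motion at `temperature_K` below `free_gas_cutoff_eV`, allowing
#' up-scatter), and 1/v capture, which terminates the history. Charged
#' capture and recoil products deposit locally (their ranges are microns
#' against the bin width). Capture photons (0.478 MeV from the dominant
#' B-10 branch, 2.22 MeV from H(n,gamma)) follow `gamma_policy`:
#' `"discard"` (default; logged, excluded from dose, so the boron dose and
#' its depth structure are photon-independent), `"local"`, or `"kernel"`
#' (one exponential first-interaction flight with embedded water
#' attenuation coefficients).
#'
#' Doses are scored per depth slab over the full cylinder cross-section and
#' normalised to Gy per source neutron; standard errors come from
#' per-history statistics. Each history owns an independent PRNG stream
#' seeded from `(seed, history index)`, so results are reproducible and
#' independent of batching.
#'
#' @param beam A [beam_spec()].
#' @param phantom A [cylinder_phantom()].
#' @param n_histories Number of source neutrons (>= 1).
#' @param seed Integer seed (mandatory).
#' @param bin_cm Depth bin width, cm (default 0.25).
#' @param gamma_policy `"discard"`, `"local"`, or `"kernel"`.
#' @param free_gas_cutoff_eV Thermal-scattering cutoff (default 4 eV).
#' @param temperature_K Medium temperature (default 293.6 K).
#' @param effective_sigma If `TRUE`, path lengths and channel selection
#'   below the cutoff use the free-gas effective (Doppler-averaged) elastic
#'   cross section instead of the constant free-atom value. Default
#'   `FALSE`: the embedded elastic constants are used as-is, matching the
#'   constant-below-10-keV cross-section model; the free-gas treatment then
#'   applies to the scattering kinematics only.
#' @return A `dose_profile` object: data frame `data` with per-bin depth
#'   centres, total and boron dose (Gy per source neutron), the seven
#'   component doses, standard errors and capture counts; plus run
#'   metadata (`meta`) including the energy-ledger audit.
#' @export
#' @examples
#' pr <- run_transport(beam_spec(0.025),
#'                     cylinder_phantom(build_tissue(35)),
#'                     n_histories = 2000, seed = 1)
#' summarize_profile(pr)
run_transport <- function(beam, phantom, n_histories, seed, bin_cm = 0.25,
                          gamma_policy = c("discard", "local", "kernel"),
                          free_gas_cutoff_eV = 4, temperature_K = 293.6,
                          effective_sigma = FALSE) {
  gamma_policy <- match.arg(gamma_policy)
  stopifnot(inherits(beam, "beam_spec"), inherits(phantom, "cylinder_phantom"))
  if (length(n_histories) != 1 || !is.finite(n_histories) || n_histories < 1)
    stop("n_histories must be >= 1")
  if (missing(seed) || length(seed) != 1 || !is.finite(seed))
    stop("a scalar seed is mandatory")
  stopifnot(bin_cm > 0, bin_cm <= phantom$length_cm)

  k <- nuclear_constants()
  kT <- k$physical$boltzmann_eV_per_K * temperature_K
  ma <- material_arrays(phantom$material)
  policy_code <- match(gamma_policy, c("discard", "local", "kernel")) - 1L

  res <- mc_run_cpp(ma$N, ma$sigma_el, ma$sigma_cap, ma$cap_kind, ma$A_u,
                    beam$energy_eV, beam$radius_cm,
                    phantom$diameter_cm / 2, phantom$length_cm, bin_cm,
                    as.integer(n_histories), as.double(seed), policy_code,
                    free_gas_cutoff_eV, kT, k$cross_sections$E_ref_eV,
                    isTRUE(effective_sigma), capture_constants())

  nb <- res$n_bins
  centers <- (seq_len(nb) - 0.5) * bin_cm
  bin_mass_g <- pi * (phantom$diameter_cm / 2)^2 * bin_cm *
    phantom$material$density
  # massless (zero-density) fixtures carry no dose by definition
  mev_to_gy <- if (bin_mass_g > 0)
    k$physical$J_per_MeV * 1e3 / bin_mass_g / n_histories else 0

  comp <- res$tally_MeV * mev_to_gy
  colnames(comp) <- .dose_components
  tot_mean <- res$sum_tot / n_histories
  tot_var <- pmax(res$sumsq_tot / n_histories - tot_mean^2, 0)
  bor_mean <- res$sum_bor / n_histories
  bor_var <- pmax(res$sumsq_bor / n_histories - bor_mean^2, 0)
  se_scale <- if (bin_mass_g > 0) k$physical$J_per_MeV * 1e3 / bin_mass_g
              else 0
  dat <- data.frame(
    depth_cm = centers,
    total_Gy = rowSums(comp),
    boron_Gy = comp[, "boron_alpha"] + comp[, "boron_li7"],
    comp,
    total_se = sqrt(tot_var / n_histories) * se_scale,
    boron_se = sqrt(bor_var / n_histories) * se_scale,
    captures = as.numeric(res$capture_counts))

  structure(list(
    data = dat,
    meta = list(
      beam = beam, phantom_length_cm = phantom$length_cm,
      phantom_diameter_cm = phantom$diameter_cm,
      material = phantom$material$name,
      boron_ppm = phantom$material$boron_ppm,
      tissue_model = "ICRU four-component soft tissue (assumed composition)",
      n_histories = n_histories, seed = seed, bin_cm = bin_cm,
      gamma_policy = gamma_policy,
      free_gas_cutoff_eV = free_gas_cutoff_eV,
      temperature_K = temperature_K,
      effective_sigma = isTRUE(effective_sigma),
      n_escaped = res$n_escaped, n_absorbed = res$n_absorbed,
      n_collisions = res$n_collisions,
      escaped_MeV = res$escaped_MeV,
      gamma_discarded_MeV = res$gamma_discarded_MeV,
      bath_gain_MeV = res$bath_gain_MeV,
      max_ledger_residual = res$max_ledger_residual,
      constants_version = constants_version(),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<dose_profile> %g eV beam, %g ppm B-10, %g histories (seed %g)\n",
    m$beam$energy_eV, m$boron_ppm, m$n_histories, m$seed))
  s <- summarize_profile(x)
  if (!is.null(s$boron_max_depth_cm))
    cat(sprintf(
      "  boron dose max %.3e Gy/n at %.3g cm; total max %.3e Gy/n at %.3g cm\n",
      s$boron_max_Gy, s$boron_max_depth_cm, s$total_max_Gy,
      s$total_max_depth_cm))
  cat(sprintf("  max energy-ledger residual: %.2e (relative)\n",
              m$max_ledger_residual))
  invisible(x)
}

#' @export
as.data.frame.dose_profile <- function(x, ...) x$data

#' Summary statistics of a depth-dose profile
#'
#' Reports the bin-centre depth of the maximum total and boron dose, and
#' the depth at which the boron dose first falls two orders of magnitude
#' below its maximum (NA if it never does within the phantom).
#'
#' @param profile A `dose_profile`.
#' @return A list; `empty = TRUE` (and nothing else) if the profile is
#'   identically zero.
#' @export
summarize_profile <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  d <- profile$data
  if (nrow(d) == 0 || all(d$total_Gy == 0)) return(list(empty = TRUE))
  i_tot <- which.max(d$total_Gy)
  out <- list(empty = FALSE,
              total_max_depth_cm = d$depth_cm[i_tot],
              total_max_Gy = d$total_Gy[i_tot])
  if (any(d$boron_Gy > 0)) {
    i_bor <- which.max(d$boron_Gy)
    below <- which(d$depth_cm > d$depth_cm[i_bor] &
                     d$boron_Gy <= d$boron_Gy[i_bor] / 100)
    out$boron_max_depth_cm <- d$depth_cm[i_bor]
    out$boron_max_Gy <- d$boron_Gy[i_bor]
    out$boron_2orders_depth_cm <-
      if (length(below)) d$depth_cm[min(below)] else NA_real_
  }
  out
}

#' @export
summary.dose_profile <- function(object, ...) summarize_profile(object)

#' Sample neutron free paths in a material
#'
#' Exponential free-flight distances with mean `1/Sigma_total(E)`, drawn
#' from the transport kernel's own generator. The total cross section uses
#' the same evaluation as the kernel (free-gas-broadened elastic below
#' 4 eV).
#'
#' @param material A `material`.
#' @param E_eV Neutron energy, eV.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @param free_gas_cutoff_eV,temperature_K As in [run_transport()].
#' @return Numeric vector of path lengths in cm.
#' @export
sample_free_path <- function(material, E_eV, n = 1, seed,
                             free_gas_cutoff_eV = 4, temperature_K = 293.6,
                             effective_sigma = FALSE) {
  sig <- macroscopic_xs(material, E_eV, "total",
                        broaden = isTRUE(effective_sigma) &&
                          E_eV <= free_gas_cutoff_eV,
                        temperature_K = temperature_K)
  if (sig <= 0) return(rep(Inf, n))  # straight transport to the boundary
  mc_exp_samples(sig, as.integer(n), as.double(seed))
}

#' Sample the collision nuclide and channel
#'
#' Draws `(nuclide, channel)` pairs with probability proportional to each
#' channel's macroscopic cross section at energy `E_eV`, using the kernel's
#' channel-selection code.
#'
#' @inheritParams sample_free_path
#' @return Data frame with columns `symbol`, `channel`
#'   (`"elastic"`/`"capture"`).
#' @export
sample_collision <- function(material, E_eV, n = 1, seed,
                             free_gas_cutoff_eV = 4, temperature_K = 293.6,
                             effective_sigma = FALSE) {
  k <- nuclear_constants()
  ma <- material_arrays(material)
  kT <- k$physical$boltzmann_eV_per_K * temperature_K
  res <- mc_collision_samples(ma$N, ma$sigma_el, ma$sigma_cap, ma$cap_kind,
                              ma$A_u, E_eV, free_gas_cutoff_eV, kT,
                              k$cross_sections$E_ref_eV,
                              isTRUE(effective_sigma),
                              as.integer(n), as.double(seed))
  data.frame(symbol = material$composition$symbol[res$nuclide],
             channel = ifelse(res$capture, "capture", "elastic"))
}

#' Sample elastic scattering outcomes
#'
#' Post-collision neutron energies and laboratory scattering cosines for
#' elastic scattering on one nuclide, from the kernel's scattering code:
#' stationary target above the thermal cutoff, free-gas target motion below.
#'
#' @param E_eV Incident neutron energy, eV.
#' @param target Nuclide symbol (e.g. `"H-1"`, `"O-16"`) or a mass in u.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param free_gas If `NULL` (default), decided by `E_eV <= 4`;
#'   otherwise forced.
#' @param temperature_K Medium temperature for the free-gas model.
#' @return Data frame with columns `E_out_eV`, `mu_lab`.
#' @export
elastic_scatter <- function(E_eV, target, n = 1, seed, free_gas = NULL,
                            temperature_K = 293.6) {
  a <- if (is.character(target)) nuclide_mass_u(target) else as.numeric(target)
  if (is.null(free_gas)) free_gas <- E_eV <= 4
  kT <- nuclear_constants()$physical$boltzmann_eV_per_K * temperature_K
  out <- mc_scatter_samples(E_eV, a, kT, as.integer(n), as.double(seed),
                            isTRUE(free_gas))
  as.data.frame(out)
}

#' Capture-event energy deposits
#'
#' Samples the exit channel (for B-10: excited versus ground Li-7 branch,
#' via the kernel's generator) and returns the local charged-particle
#' deposits and photon emission per event, from the embedded channel
#' constants. B-10 splits `Q + E_n` between the alpha and Li-7 by momentum
#' conservation; N-14(n,p) likewise between proton and C-14; H(n,gamma)
#' yields a 2.22 MeV photon and a ~1.3 keV deuteron recoil.
#'
#' @param target `"B-10"`, `"H-1"`, or `"N-14"`.
#' @param E_n_eV Neutron energy at capture, eV (default thermal 0.025).
#' @param n Number of events.
#' @param seed Integer seed.
#' @return Data frame, one row per event: `branch`, component deposits in
#'   MeV (`boron_alpha`, `boron_li7`, `n14_proton`, `c14_recoil`,
#'   `other_recoil`), and `gamma_MeV` (emitted photon energy, 0 if none).
#' @export
#' @examples
#' capture_event("B-10", n = 5, seed = 1)
capture_event <- function(target = c("B-10", "H-1", "N-14"),
                          E_n_eV = 0.025, n = 1, seed) {
  target <- match.arg(target)
  cc <- capture_constants()
  en <- E_n_eV * 1e-6
  zero <- numeric(n)
  if (target == "B-10") {
    exc <- mc_bernoulli(cc$b10_p_excited, as.integer(n), as.double(seed)) == 1
    avail <- ifelse(exc, cc$b10_Q_excited, cc$b10_Q_ground) + en
    data.frame(branch = ifelse(exc, "excited", "ground"),
               boron_alpha = avail * cc$b10_frac_light,
               boron_li7 = avail * (1 - cc$b10_frac_light),
               n14_proton = zero, c14_recoil = zero, other_recoil = zero,
               gamma_MeV = ifelse(exc, cc$b10_gamma, 0))
  } else if (target == "H-1") {
    data.frame(branch = rep("ground", n), boron_alpha = zero,
               boron_li7 = zero, n14_proton = zero, c14_recoil = zero,
               other_recoil = rep(cc$h_recoil, n),
               gamma_MeV = rep(cc$h_Q + en - cc$h_recoil, n))
  } else {
    avail <- rep(cc$n14_Q + en, n)
    data.frame(branch = rep("ground", n), boron_alpha = zero,
               boron_li7 = zero,
               n14_proton = avail * cc$n14_frac_light,
               c14_recoil = avail * (1 - cc$n14_frac_light),
               other_recoil = zero, gamma_MeV = zero)
  }
}

#' Free-gas thermalization chains
#'
#' Repeatedly scatters neutrons on a free-gas target (no absorption, no
#' geometry) and returns the energy after a fixed number of collisions;
#' used to check that the scattering kernel drives neutrons to thermal
#' equilibrium at the medium temperature.
#'
#' @param E0_eV Starting energy, eV.
#' @param target Nuclide symbol or mass in u (default `"H-1"`).
#' @param n_collisions Collisions per chain.
#' @param n_chains Number of independent chains.
#' @param seed Integer seed.
#' @param temperature_K Medium temperature.
#' @return Numeric vector of final energies (eV), one per chain.
#' @export
thermalization_chain <- function(E0_eV, target = "H-1", n_collisions = 50,
                                 n_chains = 1000, seed,
                                 temperature_K = 293.6) {
  a <- if (is.character(target)) nuclide_mass_u(target) else as.numeric(target)
  kT <- nuclear_constants()$physical$boltzmann_eV_per_K * temperature_K
  mc_chain_energies(E0_eV, a, kT, as.integer(n_collisions),
                    as.integer(n_chains), as.double(seed))
}
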