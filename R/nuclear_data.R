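#' Look up a nuclide
#'
#' Returns the embedded record for one nuclide: charge number, mass number,
#' atomic mass in u and in MeV/c^2.
#'
#' @param symbol Nuclide symbol, one of `"n"`, `"H-1"`, `"H-2"`, `"H-3"`,
#'   `"He-3"`, `"He-4"`, `"Li-7"`, `"B-10"`, `"B-11"`, `"C-12"`, `"C-14"`,
#'   `"N-14"`, `"O-16"`.
#' @return A list with elements `symbol`, `Z`, `A`, `mass_u`, `mass_MeV`.
#' @export
#' @examples
#' nuclide("B-10")$mass_u
nuclide <- function(symbol) {
  k <- nuclear_constants()
  rec <- k$nuclides[[symbol]]
  if (is.null(rec)) {
    stop("unknown nuclide '", symbol, "'; known: ",
         paste(names(k$nuclides), collapse = ", "))
  }
  list(symbol = symbol, Z = rec$Z, A = rec$A, mass_u = rec$mass_u,
       mass_MeV = rec$mass_u * k$physical$amu_MeV)
}

#' @rdname nuclide
#' @export
nuclide_table <- function() {
  k <- nuclear_constants()
  do.call(rbind, lapply(names(k$nuclides), function(s) {
    n <- nuclide(s)
    data.frame(symbol = s, Z = n$Z, A = n$A, mass_u = n$mass_u,
               mass_MeV = n$mass_MeV)
  }))
}

#' Mass of a nuclide in atomic mass units
#' @inheritParams nuclide
#' @return Numeric scalar (u).
#' @export
nuclide_mass_u <- function(symbol) nuclide(symbol)$mass_u

#' Reaction Q-value from embedded masses
#'
#' Q = sum of ingoing minus outgoing rest masses, in MeV. Atomic masses are
#' used throughout; electron masses cancel for these charge-conserving
#' reactions.
#'
#' @param inputs,outputs Character vectors of nuclide symbols.
#' @return Q in MeV (positive = exothermic).
#' @export
#' @examples
#' q_value(c("H-2", "H-2"), c("He-3", "n"))  # ~3.27 MeV
q_value <- function(inputs, outputs) {
  amu <- nuclear_constants()$physical$amu_MeV
  (sum(vapply(inputs, nuclide_mass_u, 0)) -
     sum(vapply(outputs, nuclide_mass_u, 0))) * amu
}

#' Reaction channel table
#'
#' The reaction channels the package models, with Q-values recomputed from
#' the embedded masses at call time. For neutron capture on B-10 the
#' compound nucleus decays to alpha + Li-7 either in the Li-7 ground state
#' (branching 6.1%, all energy to the charged pair) or through the Li-7
#' first excited level (branching 93.9%, followed by a 0.478 MeV
#' de-excitation photon).
#'
#' @param reaction One of `"n+B10"`, `"d+d"`, `"d+t"`, `"n+H1"`, `"n+N14"`.
#' @return A data frame, one row per exit channel: `projectile`, `target`,
#'   `light`, `heavy`, `Q_MeV` (energy available to the two products),
#'   `branching`, `gamma_MeV` (de-excitation photon, `NA` if none).
#' @export
#' @examples
#' reaction_channels("n+B10")
reaction_channels <- function(reaction = c("n+B10", "d+d", "d+t",
                                           "n+H1", "n+N14")) {
  reaction <- match.arg(reaction)
  k <- nuclear_constants()
  switch(reaction,
    "n+B10" = {
      q_gnd <- q_value(c("n", "B-10"), c("He-4", "Li-7"))
      e_star <- k$excited_levels_MeV[["Li-7"]]
      data.frame(
        projectile = "n", target = "B-10",
        light = "He-4", heavy = "Li-7",
        Q_MeV = c(q_gnd - e_star, q_gnd),
        branching = c(k$b10_capture$branching_excited,
                      k$b10_capture$branching_ground),
        gamma_MeV = c(e_star, NA_real_),
        channel = c("excited", "ground"))
    },
    "d+d" = data.frame(
      projectile = "H-2", target = "H-2", light = "n", heavy = "He-3",
      Q_MeV = q_value(c("H-2", "H-2"), c("He-3", "n")),
      branching = 1, gamma_MeV = NA_real_, channel = "ground"),
    "d+t" = data.frame(
      projectile = "H-2", target = "H-3", light = "n", heavy = "He-4",
      Q_MeV = q_value(c("H-2", "H-3"), c("He-4", "n")),
      branching = 1, gamma_MeV = NA_real_, channel = "ground"),
    "n+H1" = data.frame(
      projectile = "n", target = "H-1", light = "gamma", heavy = "H-2",
      Q_MeV = q_value(c("n", "H-1"), "H-2"),
      branching = 1, gamma_MeV = q_value(c("n", "H-1"), "H-2"),
      channel = "ground"),
    "n+N14" = data.frame(
      projectile = "n", target = "N-14", light = "H-1", heavy = "C-14",
      Q_MeV = q_value(c("n", "N-14"), c("H-1", "C-14")),
      branching = 1, gamma_MeV = NA_real_, channel = "ground")
  )
}

#' Microscopic cross section
#'
#' Capture follows the 1/v law anchored at the embedded 0.025 eV thermal
#' point; elastic scattering is treated as constant (free-atom value) in the
#' sub-10 keV regime this package addresses.
#'
#' @inheritParams nuclide
#' @param E_eV Neutron kinetic energy in eV (> 0); vectorised.
#' @param channel `"capture"` or `"elastic"`.
#' @return Cross section(s) in barns.
#' @export
#' @examples
#' micro_xs("B-10", 0.025)          # 3837 b
#' micro_xs("B-10", 0.1)            # 1/v falloff
micro_xs <- function(symbol, E_eV, channel = c("capture", "elastic")) {
  channel <- match.arg(channel)
  stopifnot(all(E_eV > 0))
  xs <- nuclear_constants()$cross_sections
  if (channel == "capture") {
    s0 <- xs$capture_thermal_barns[[symbol]]
    if (is.null(s0)) s0 <- 0
    s0 * sqrt(xs$E_ref_eV / E_eV)
  } else {
    s0 <- xs$elastic_barns[[symbol]]
    if (is.null(s0)) s0 <- 0
    rep_len(s0, length(E_eV))
  }
}

# internal: assemble the material class from a composition table
new_material <- function(name, density, comp, boron_ppm = 0) {
  stopifnot(is.data.frame(comp),
            all(c("symbol", "mass_fraction", "number_density",
                  "sigma_elastic_b", "sigma_capture_b", "capture_kind",
                  "mass_u") %in% names(comp)))
  structure(list(name = name, density = density, boron_ppm = boron_ppm,
                 composition = comp),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat("<material> ", x$name, "  (", x$density, " g/cm^3",
      if (x$boron_ppm > 0) paste0(", ", x$boron_ppm, " ppm B-10"), ")\n",
      sep = "")
  print(x$composition, row.names = FALSE)
  invisible(x)
}

#' Boron-loaded ICRU soft tissue
#'
#' Builds the four-component ICRU soft-tissue material (H 10.1%, C 11.1%,
#' N 2.6%, O 76.2% by mass, density 1.0 g/cm^3) with B-10 added at the given
#' mass loading; the four base fractions are renormalised so all mass
#' fractions sum to one. Number densities are derived per nuclide as
#' `rho * w_i * N_A / M_i`.
#'
#' @param boron_ppm B-10 loading in mass ppm (micrograms of B-10 per gram of
#'   tissue); 0 to 1e4.
#' @return A `material` object whose `composition` data frame carries, per
#'   nuclide: mass fraction, number density (cm^-3), elastic and thermal
#'   capture cross sections (barns), and the capture channel tag.
#' @export
#' @examples
#' build_tissue(35)
build_tissue <- function(boron_ppm = 0) {
  if (!is.finite(boron_ppm) || boron_ppm < 0)
    stop("boron_ppm must be a non-negative number")
  if (boron_ppm > 1e4)
    stop("boron_ppm above 1e4 is outside the supported loading range")
  k <- nuclear_constants()
  t <- k$tissue
  f_b <- boron_ppm * 1e-6
  sym <- c(names(t$mass_fractions), "B-10")
  w <- c(unlist(t$mass_fractions) * (1 - f_b), "B-10" = f_b)
  comp <- material_composition(sym, w, t$density_g_cm3)
  new_material(t$name, t$density_g_cm3, comp, boron_ppm = boron_ppm)
}

# internal: composition table from mass fractions of known nuclides
material_composition <- function(symbols, mass_fractions, density) {
  k <- nuclear_constants()
  xs <- k$cross_sections
  m_u <- vapply(symbols, nuclide_mass_u, 0)
  n_dens <- density * mass_fractions * k$physical$avogadro / m_u
  kind <- vapply(symbols, function(s) {
    kk <- xs$capture_kind[[s]]
    if (is.null(kk)) "negligible" else kk
  }, "")
  data.frame(
    symbol = symbols,
    mass_fraction = unname(mass_fractions),
    number_density = unname(n_dens),
    sigma_elastic_b = vapply(symbols, function(s) {
      v <- xs$elastic_barns[[s]]; if (is.null(v)) 0 else v
    }, 0),
    sigma_capture_b = vapply(symbols, function(s) {
      v <- xs$capture_thermal_barns[[s]]; if (is.null(v)) 0 else v
    }, 0),
    capture_kind = unname(kind),
    mass_u = unname(m_u),
    row.names = NULL)
}

#' Single-nuclide toy material
#'
#' A synthetic one-nuclide material with directly specified cross sections,
#' for analytic-oracle fixtures (e.g. a pure absorber with no scattering,
#' whose capture depth profile is exactly exponential).
#'
#' @param sigma_capture_b Capture cross section at 0.025 eV, barns.
#' @param number_density Atoms per cm^3.
#' @param sigma_elastic_b Elastic cross section, barns (default 0).
#' @param mass_u Target mass in u (default 10, irrelevant if no scattering).
#' @param capture_kind Channel tag; `"generic"` deposits the incident
#'   neutron energy and releases no Q.
#' @param name Material name.
#' @return A `material` object.
#' @export
toy_material <- function(sigma_capture_b, number_density,
                         sigma_elastic_b = 0, mass_u = 10,
                         capture_kind = "generic", name = "toy") {
  stopifnot(sigma_capture_b >= 0, number_density >= 0, sigma_elastic_b >= 0)
  comp <- data.frame(
    symbol = "X", mass_fraction = 1, number_density = number_density,
    sigma_elastic_b = sigma_elastic_b, sigma_capture_b = sigma_capture_b,
    capture_kind = capture_kind, mass_u = mass_u)
  new_material(name, density = number_density * mass_u /
                 nuclear_constants()$physical$avogadro, comp)
}

#' Macroscopic cross section of a material
#'
#' Sums `N_i * sigma_i(E)` over the selected channels. Capture channels use
#' the 1/v law; elastic channels the constant free-atom values, optionally
#' multiplied by the free-gas Doppler factor used by the transport kernel
#' below its thermal-scattering cutoff.
#'
#' @param material A `material` object.
#' @param E_eV Neutron energy in eV (> 0), scalar.
#' @param channel `"total"`, `"capture"`, `"elastic"`, or a specific capture
#'   tag (`"B10_nalpha"`, `"H_ngamma"`, `"N14_np"`).
#' @param broaden Apply the free-gas effective elastic factor (as the
#'   transport kernel does below 4 eV)? Default `FALSE`: bare constants.
#' @param temperature_K Medium temperature for `broaden = TRUE`.
#' @return Macroscopic cross section in 1/cm.
#' @export
#' @examples
#' macroscopic_xs(build_tissue(35), 0.025, "capture")
macroscopic_xs <- function(material, E_eV, channel = "total",
                           broaden = FALSE, temperature_K = 293.6) {
  stopifnot(inherits(material, "material"), length(E_eV) == 1, E_eV > 0)
  comp <- material$composition
  k <- nuclear_constants()
  e_ref <- k$cross_sections$E_ref_eV
  sig_cap <- comp$sigma_capture_b * sqrt(e_ref / E_eV)
  sig_el <- comp$sigma_elastic_b
  if (broaden) {
    kT <- k$physical$boltzmann_eV_per_K * temperature_K
    sig_el <- sig_el * free_gas_factor(comp$mass_u * E_eV / kT)
  }
  barn <- 1e-24
  tot_cap <- sum(comp$number_density * sig_cap * barn)
  tot_el <- sum(comp$number_density * sig_el * barn)
  known_tags <- c("B10_nalpha", "H_ngamma", "N14_np", "generic")
  if (channel == "total") tot_cap + tot_el
  else if (channel == "capture") tot_cap
  else if (channel == "elastic") tot_el
  else if (channel %in% known_tags) {
    sel <- comp$capture_kind == channel
    sum(comp$number_density[sel] * sig_cap[sel] * barn)
  } else stop("unknown channel tag '", channel, "'")
}

# free-gas effective elastic factor g(x), x^2 = A E / kT
# g = (1 + 1/(2x^2)) erf(x) + exp(-x^2)/(x sqrt(pi)); -> 1 for x >> 1
free_gas_factor <- function(x2) {
  x2 <- pmax(x2, 1e-12)
  x <- sqrt(x2)
  ifelse(x2 > 250, 1 + 0.5 / x2,
         (1 + 0.5 / x2) * erf_vec(x) + exp(-x2) / (x * sqrt(pi)))
}

erf_vec <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' B-10 atoms per cell at a given tissue loading
#'
#' For a spherical cell of the given diameter at soft-tissue density, the
#' number of B-10 atoms implied by a mass loading in ppm:
#' `(pi/6) d^3 rho * ppm*1e-6 * N_A / M(B-10)`.
#'
#' @param boron_ppm Mass ppm of B-10.
#' @param cell_diameter_um Cell diameter in micrometres.
#' @return Number of B-10 atoms (numeric).
#' @export
#' @examples
#' atoms_per_cell(35, 10)   # ~1.1e9
atoms_per_cell <- function(boron_ppm, cell_diameter_um) {
  stopifnot(boron_ppm >= 0, cell_diameter_um > 0)
  k <- nuclear_constants()
  vol_cm3 <- pi / 6 * (cell_diameter_um * 1e-4)^3
  mass_g <- vol_cm3 * nuclear_constants()$tissue$density_g_cm3
  mass_g * boron_ppm * 1e-6 * k$physical$avogadro / nuclide_mass_u("B-10")
}
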