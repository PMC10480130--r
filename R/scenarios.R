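#' Scenario: a named beam + phantom + run-defaults bundle
#'
#' @param name Scenario name.
#' @param beam A [beam_spec()].
#' @param boron_ppm B-10 loading for the tissue phantom (ignored if
#'   `material` given).
#' @param length_cm,diameter_cm Phantom geometry.
#' @param material Optional `material` overriding the tissue builder.
#' @param histories,seed,bin_cm Run defaults.
#' @return A `scenario` object.
#' @export
scenario <- function(name, beam, boron_ppm = 0, length_cm = 10,
                     diameter_cm = 5, material = NULL,
                     histories = 1e4, seed = 20260101, bin_cm = 0.25) {
  structure(list(name = name, beam = beam, boron_ppm = boron_ppm,
                 length_cm = length_cm, diameter_cm = diameter_cm,
                 material = material, histories = histories, seed = seed,
                 bin_cm = bin_cm),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %g eV beam, %g ppm B-10, %g x %g cm cylinder\n",
              x$name, x$beam$energy_eV, x$boron_ppm, x$length_cm,
              x$diameter_cm))
  cat(sprintf("  defaults: %g histories, seed %g, %g cm bins\n",
              x$histories, x$seed, x$bin_cm))
  invisible(x)
}

# preset registry: thermal and epithermal sources x boron loadings, plus
# analytic toy fixtures. The study conditions: 0.025 eV thermal source;
# epithermal sources 1 eV - 10 keV; 35/50/100 ppm; 10 cm x 5 cm cylinder.
.preset_registry <- function() {
  ppms <- c(35, 50, 100)
  epi <- c("1eV" = 1, "10eV" = 10, "100eV" = 100, "1keV" = 1e3,
           "10keV" = 1e4)
  reg <- list()
  for (p in ppms)
    reg[[paste0("thermal-", p)]] <-
      list(energy = 0.025, ppm = p)
  for (i in seq_along(epi)) {
    for (p in ppms)
      reg[[paste0("epi-", names(epi)[i], "-", p)]] <-
        list(energy = unname(epi[i]), ppm = p)
    # bare epi name = 35 ppm reference loading
    reg[[paste0("epi-", names(epi)[i])]] <-
      list(energy = unname(epi[i]), ppm = 35)
  }
  reg
}

#' Names of the registered scenario presets
#' @return Character vector.
#' @export
preset_names <- function() {
  c(names(.preset_registry()), "no-boron", "toy-absorber")
}

#' Retrieve a scenario preset
#'
#' Presets reproduce the study conditions: `thermal-{35,50,100}` are
#' 0.025 eV beams into the 10 cm x 5 cm-diameter tissue cylinder at the
#' given B-10 ppm; `epi-{1eV,10eV,100eV,1keV,10keV}[-ppm]` are the
#' epithermal sources (bare epi names default to 35 ppm). `no-boron` is
#' plain tissue; `toy-absorber` is the scattering-free pure absorber with
#' `Sigma_a = 1 /cm` used by the exponential-attenuation oracle.
#'
#' @param name Preset name; see [preset_names()].
#' @return A `scenario`.
#' @export
#' @examples
#' preset("thermal-35")
preset <- function(name) {
  reg <- .preset_registry()
  if (name == "no-boron")
    return(scenario("no-boron", beam_spec(0.025), boron_ppm = 0))
  if (name == "toy-absorber")
    return(toy_absorber(1, 1e24))
  rec <- reg[[name]]
  if (is.null(rec))
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "))
  scenario(name, beam_spec(rec$energy), boron_ppm = rec$ppm)
}

#' Pure-absorber toy scenario
#'
#' A scattering-free single-nuclide absorber in the standard cylinder, so
#' the capture-event depth density is exactly `Sigma_a * exp(-Sigma_a z)`:
#' the analytic oracle for the transport sampler. `Sigma_a` (1/cm) is
#' `sigma_a_barns * 1e-24 * number_density`.
#'
#' @param sigma_a_barns Capture cross section at 0.025 eV, barns.
#' @param number_density Atoms per cm^3.
#' @param length_cm Cylinder length (default 10; use longer for small
#'   `Sigma_a`).
#' @return A `scenario` whose material is a [toy_material()].
#' @export
#' @examples
#' toy_absorber(1, 1e24)  # Sigma_a = 1 /cm
toy_absorber <- function(sigma_a_barns, number_density, length_cm = 10) {
  stopifnot(sigma_a_barns > 0 || number_density == 0)
  scenario("toy-absorber", beam_spec(0.025),
           material = toy_material(sigma_a_barns, number_density),
           length_cm = length_cm)
}

#' Run a scenario end to end
#'
#' Builds the material and phantom, applies the run profile (`"ci"`:
#' reduced 1e4 histories for fast checks; `"paper"`: 2e5 histories, the
#' scale used for the depth-of-maximum results), and calls
#' [run_transport()].
#'
#' @param sc A `scenario`.
#' @param profile `"ci"` or `"paper"`.
#' @param histories,seed,bin_cm Optional overrides.
#' @param ... Passed to [run_transport()] (e.g. `gamma_policy`).
#' @return A `dose_profile`.
#' @export
run_scenario <- function(sc, profile = c("ci", "paper"), histories = NULL,
                         seed = NULL, bin_cm = NULL, ...) {
  stopifnot(inherits(sc, "scenario"))
  profile <- match.arg(profile)
  mat <- if (!is.null(sc$material)) sc$material else build_tissue(sc$boron_ppm)
  ph <- cylinder_phantom(mat, sc$length_cm, sc$diameter_cm)
  nh <- if (!is.null(histories)) histories
        else if (profile == "paper") max(sc$histories, 2e5) else sc$histories
  run_transport(sc$beam, ph, n_histories = nh,
                seed = if (!is.null(seed)) seed else sc$seed,
                bin_cm = if (!is.null(bin_cm)) bin_cm else sc$bin_cm, ...)
}

#' Serialize / deserialize a scenario as a YAML run config
#'
#' The round trip is lossless for the preset scenarios. Toy materials are
#' serialized by their defining cross sections.
#'
#' @param sc A `scenario`.
#' @param path File path; if missing, `scenario_write` returns the YAML
#'   string.
#' @return `scenario_write`: the path (or YAML string) invisibly;
#'   `scenario_read`: a `scenario`.
#' @export
scenario_write <- function(sc, path) {
  stopifnot(inherits(sc, "scenario"))
  x <- list(
    name = sc$name,
    beam = list(energy_eV = sc$beam$energy_eV,
                radius_cm = sc$beam$radius_cm),
    phantom = list(length_cm = sc$length_cm, diameter_cm = sc$diameter_cm,
                   boron_ppm = sc$boron_ppm),
    run = list(histories = sc$histories, seed = sc$seed,
               bin_cm = sc$bin_cm))
  if (!is.null(sc$material)) {
    comp <- sc$material$composition
    x$material <- list(kind = "toy",
                       sigma_capture_b = comp$sigma_capture_b[1],
                       number_density = comp$number_density[1],
                       sigma_elastic_b = comp$sigma_elastic_b[1],
                       mass_u = comp$mass_u[1],
                       capture_kind = comp$capture_kind[1])
  }
  txt <- yaml::as.yaml(x, precision = 15)
  if (missing(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname scenario_write
#' @export
scenario_read <- function(path) {
  x <- yaml::yaml.load(if (file.exists(path)) paste(readLines(path),
                                                    collapse = "\n")
                       else path)
  mat <- NULL
  if (!is.null(x$material))
    mat <- toy_material(x$material$sigma_capture_b, x$material$number_density,
                        x$material$sigma_elastic_b, x$material$mass_u,
                        x$material$capture_kind)
  scenario(x$name, beam_spec(x$beam$energy_eV, x$beam$radius_cm),
           boron_ppm = x$phantom$boron_ppm, length_cm = x$phantom$length_cm,
           diameter_cm = x$phantom$diameter_cm, material = mat,
           histories = x$run$histories, seed = x$run$seed,
           bin_cm = x$run$bin_cm)
}
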