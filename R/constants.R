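.bnct <- new.env(parent = emptyenv())

#' Embedded nuclear and physical constants
#'
#' Loads (once per session) the versioned constants file shipped with the
#' package: AME2020 atomic masses, CODATA physical constants, thermal-point
#' cross sections, B-10 capture branching, and the ICRU soft-tissue recipe.
#' Provenance is documented in `inst/extdata/README.md`.
#'
#' @return A nested list mirroring `nuclear_constants.json`.
#' @export
#' @examples
#' nuclear_constants()$physical$amu_MeV
nuclear_constants <- function() {
  if (is.null(.bnct$constants)) {
    path <- system.file("extdata", "nuclear_constants.json",
                        package = "bnctsim", mustWork = TRUE)
    .bnct$constants <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  .bnct$constants
}

#' Version string of the embedded constants file
#' @return Character scalar, e.g. `"1.0.0"`.
#' @export
constants_version <- function() nuclear_constants()$version
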