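#' Align depth-dose profiles into one comparison table
#'
#' Joins several profiles (e.g. the three boron loadings) on their common
#' depth grid, one `total_Gy` and `boron_Gy` column pair per profile.
#' Profiles with differing bin grids are rejected.
#'
#' @param profiles A list of `dose_profile` objects (length >= 1).
#' @param labels Column labels; defaults to `"<ppm>ppm_<energy>eV"`.
#' @return A data frame: `depth_cm`, then `total_Gy.<label>` and
#'   `boron_Gy.<label>` for each profile.
#' @export
report <- function(profiles, labels = NULL) {
  if (inherits(profiles, "dose_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "dose_profile")))
  ref <- profiles[[1]]$data$depth_cm
  for (p in profiles[-1]) {
    if (length(p$data$depth_cm) != length(ref) ||
        any(abs(p$data$depth_cm - ref) > 1e-12))
      stop("profiles have mismatched depth-bin grids")
  }
  if (is.null(labels))
    labels <- vapply(profiles, function(p)
      sprintf("%gppm_%geV", p$meta$boron_ppm, p$meta$beam$energy_eV), "")
  out <- data.frame(depth_cm = ref)
  for (i in seq_along(profiles)) {
    out[[paste0("total_Gy.", labels[i])]] <- profiles[[i]]$data$total_Gy
    out[[paste0("boron_Gy.", labels[i])]] <- profiles[[i]]$data$boron_Gy
  }
  out
}

#' Write a depth-dose profile as CSV (+ JSON summary)
#'
#' The canonical tabular output: one row per depth bin with total, boron
#' and component doses and their standard errors. A JSON sidecar carries
#' the run record (config snapshot, seed, constants version, summary).
#'
#' @param profile A `dose_profile`.
#' @param path CSV output path.
#' @param summary_path JSON summary path; default `<path>.json`; `NA` to
#'   skip.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path,
                          summary_path = paste0(path, ".json")) {
  stopifnot(inherits(profile, "dose_profile"))
  utils::write.csv(profile$data, path, row.names = FALSE)
  if (!is.na(summary_path)) {
    m <- profile$meta
    rec <- list(
      config = list(
        beam = list(energy_eV = m$beam$energy_eV,
                    radius_cm = m$beam$radius_cm),
        phantom = list(length_cm = m$phantom_length_cm,
                       diameter_cm = m$phantom_diameter_cm,
                       boron_ppm = m$boron_ppm,
                       tissue_model = m$tissue_model),
        run = list(histories = m$n_histories, seed = m$seed,
                   bin_cm = m$bin_cm, gamma_policy = m$gamma_policy)),
      constants_version = m$constants_version,
      timestamp = m$timestamp,
      audit = list(n_escaped = m$n_escaped, n_absorbed = m$n_absorbed,
                   max_ledger_residual = m$max_ledger_residual),
      summary = summarize_profile(profile),
      output_csv = path)
    jsonlite::write_json(rec, summary_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Plot depth-dose profiles
#'
#' Base-graphics depth-dose plot (log dose axis): total dose solid, boron
#' dose dashed, one colour per profile.
#'
#' @param x A `dose_profile` or list of them.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dose_profile <- function(x, ...) {
  profiles <- if (inherits(x, "dose_profile")) list(x) else x
  tab <- report(profiles)
  y <- as.matrix(tab[-1])
  y[y <= 0] <- NA
  graphics::matplot(tab$depth_cm, y, type = "l",
                    lty = rep(c(1, 2), length(profiles)),
                    col = rep(seq_along(profiles), each = 2),
                    log = "y", xlab = "depth (cm)",
                    ylab = "dose (Gy per source neutron)", ...)
  graphics::legend("topright", legend = colnames(y), cex = 0.7,
                   lty = rep(c(1, 2), length(profiles)),
                   col = rep(seq_along(profiles), each = 2))
  invisible(x)
}
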