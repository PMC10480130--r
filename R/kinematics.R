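#' Two-body energy partition for a reaction at rest
#'
#' When a reaction releases energy `Q_eff` with the centre of mass at rest,
#' momentum conservation fixes the split between the two products:
#' the light product carries `Q_eff * m_heavy / (m_light + m_heavy)` and the
#' heavy product the remainder (non-relativistic). This is how the
#' B-10 capture channel energies (alpha 1.47 / Li-7 0.84 MeV and
#' 1.78 / 1.01 MeV) and the zero-energy D-D / D-T product energies
#' (2.45 / 0.82 and 14.05 / 3.54 MeV) arise.
#'
#' @param Q_eff Energy shared by the two products, MeV (>= 0).
#' @param m_light,m_heavy Product masses (any common unit, e.g. u).
#' @return Named numeric vector `c(E_light =, E_heavy =)` in MeV.
#' @export
#' @examples
#' ch <- reaction_channels("n+B10")
#' partition_at_rest(ch$Q_MeV[1], nuclide_mass_u("He-4"), nuclide_mass_u("Li-7"))
partition_at_rest <- function(Q_eff, m_light, m_heavy) {
  stopifnot(m_light > 0, m_heavy > 0)
  if (!is.finite(Q_eff) || Q_eff < 0)
    stop("Q_eff must be non-negative (capture below threshold not modeled)")
  e_light <- Q_eff * m_heavy / (m_light + m_heavy)
  c(E_light = e_light, E_heavy = Q_eff - e_light)
}

# internal: masses + Q for the two fusion source reactions (u / MeV)
reaction_spec <- function(reaction = c("dd", "dt")) {
  reaction <- match.arg(reaction)
  ch <- reaction_channels(if (reaction == "dd") "d+d" else "d+t")
  list(m_d = nuclide_mass_u("H-2"),
       m_n = nuclide_mass_u("n"),
       m_B = nuclide_mass_u(ch$heavy),
       Q = ch$Q_MeV)
}

#' Neutron energy versus deuteron energy and emission angle
#'
#' Closed-form non-relativistic two-body kinematics for the D-D and D-T
#' fusion sources: for deuteron kinetic energy `E_d` and laboratory neutron
#' emission angle `theta`,
#' \deqn{\sqrt{E_n} = \frac{\sqrt{m_d m_n E_d}\cos\theta \pm
#'  \sqrt{m_d m_n E_d \cos^2\theta + (m_B + m_n)\,[m_B Q + (m_B - m_d) E_d]}}
#'  {m_B + m_n}}
#' with `m_B` the heavy product (He-3 or He-4). For these exothermic
#' reactions only the `+` root is physical; the `-` root is exposed for
#' completeness but yields a negative \eqn{\sqrt{E_n}} here and is returned
#' as `NA`. Kinematically forbidden combinations (negative discriminant,
#' impossible for Q > 0) also return `NA`.
#'
#' @param E_d Deuteron kinetic energy, MeV (>= 0); vectorised.
#' @param theta Laboratory emission angle, radians; vectorised.
#' @param reaction `"dd"` (D + H-2 -> He-3 + n) or `"dt"` (D + H-3 -> He-4 + n).
#' @param branch `"plus"` (physical) or `"minus"`.
#' @return Neutron kinetic energy in MeV (vector, recycled over inputs).
#' @export
#' @examples
#' neutron_energy(0.5, 0, "dd")       # ~3.5 MeV, the design-envelope maximum
#' neutron_energy(0, pi / 3, "dd")    # 2.45 MeV, angle-independent at E_d = 0
neutron_energy <- function(E_d, theta, reaction = c("dd", "dt"),
                           branch = c("plus", "minus")) {
  reaction <- match.arg(reaction)
  branch <- match.arg(branch)
  stopifnot(all(E_d >= 0))
  rs <- reaction_spec(reaction)
  n <- max(length(E_d), length(theta))
  E_d <- rep_len(E_d, n); theta <- rep_len(theta, n)
  a <- sqrt(rs$m_d * rs$m_n * E_d) * cos(theta) / (rs$m_B + rs$m_n)
  disc <- rs$m_d * rs$m_n * E_d * cos(theta)^2 +
    (rs$m_B + rs$m_n) * (rs$m_B * rs$Q + (rs$m_B - rs$m_d) * E_d)
  out <- rep(NA_real_, n)
  ok <- disc >= 0
  root <- sqrt(pmax(disc, 0)) / (rs$m_B + rs$m_n)
  s <- if (branch == "plus") a + root else a - root
  out[ok & s >= 0] <- s[ok & s >= 0]^2
  out
}

#' Numeric four-momentum conservation oracle
#'
#' Independent check on [neutron_energy()]: solves energy and planar
#' momentum conservation numerically, with no use of the closed-form
#' expression. For emission angle `theta` the recoil angle `phi` is the
#' root-finding variable: the momentum triangle gives
#' `p_n = p_d sin(phi) / sin(theta + phi)` and
#' `p_B = p_d sin(theta) / sin(theta + phi)`, and `phi` is found where total
#' kinetic energy balances `E_d + Q`. Collinear emission (`theta` near 0 or
#' pi) is solved by one-dimensional momentum balance instead. When the
#' quadratic nature of the problem yields two crossings, the larger-energy
#' crossing is the `"plus"` branch.
#'
#' @inheritParams neutron_energy
#' @param tol Convergence tolerance passed to [stats::uniroot()].
#' @return A list of class `two_body_result`: `E_light` (neutron, MeV),
#'   `E_heavy` (recoil, MeV), `theta`, `phi` (recoil angle, `NA` for the
#'   collinear path), `branch`, and `residual` (energy-balance residual).
#' @export
#' @examples
#' conservation_oracle(0.2, pi / 2, "dd")$E_light   # ~2.50 MeV
conservation_oracle <- function(E_d, theta, reaction = c("dd", "dt"),
                                branch = c("plus", "minus"), tol = 1e-12) {
  reaction <- match.arg(reaction)
  branch <- match.arg(branch)
  stopifnot(length(E_d) == 1, E_d >= 0, length(theta) == 1)
  rs <- reaction_spec(reaction)
  e_tot <- E_d + rs$Q

  if (E_d == 0) {
    p <- partition_at_rest(rs$Q, rs$m_n, rs$m_B)
    return(structure(list(E_light = unname(p["E_light"]),
                          E_heavy = unname(p["E_heavy"]),
                          theta = theta, phi = NA_real_, branch = branch,
                          residual = 0), class = "two_body_result"))
  }

  p_d <- sqrt(2 * rs$m_d * E_d)
  if (abs(sin(theta)) < 1e-9) {
    # collinear: recoil momentum fixed by 1-D balance, root-find on E_n
    resid <- function(en) {
      p_n <- sqrt(2 * rs$m_n * en)
      en + (p_d - p_n * cos(theta))^2 / (2 * rs$m_B) - e_tot
    }
    grid <- seq(0, e_tot, length.out = 4001)
    vals <- vapply(grid, resid, 0)
    idx <- which(vals[-1] * vals[-length(vals)] <= 0)
    if (length(idx) == 0) stop("conservation oracle: no root bracketed for ",
                               "E_d=", E_d, " theta=", theta)
    roots <- vapply(idx, function(i)
      stats::uniroot(resid, c(grid[i], grid[i + 1]), tol = tol)$root, 0)
    en <- if (branch == "plus") max(roots) else min(roots)
    return(structure(list(E_light = en, E_heavy = e_tot - en,
                          theta = theta, phi = NA_real_, branch = branch,
                          residual = resid(en)), class = "two_body_result"))
  }

  st <- sin(theta)
  resid_phi <- function(phi) {
    s <- sin(theta + phi)
    p_n <- p_d * sin(phi) / s
    p_b <- p_d * st / s
    p_n^2 / (2 * rs$m_n) + p_b^2 / (2 * rs$m_B) - e_tot
  }
  eps <- 1e-9
  hi <- pi - theta - eps
  if (hi <= eps) stop("conservation oracle: degenerate angle ", theta)
  grid <- seq(eps, hi, length.out = 4001)
  vals <- vapply(grid, resid_phi, 0)
  idx <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (length(idx) == 0) stop("conservation oracle: no recoil-angle root for ",
                             "E_d=", E_d, " theta=", theta,
                             " (kinematically forbidden?)")
  roots <- vapply(idx, function(i)
    stats::uniroot(resid_phi, c(grid[i], grid[i + 1]), tol = tol)$root, 0)
  ens <- vapply(roots, function(phi) {
    p_n <- p_d * sin(phi) / sin(theta + phi)
    p_n^2 / (2 * rs$m_n)
  }, 0)
  pick <- if (branch == "plus") which.max(ens) else which.min(ens)
  en <- ens[pick]
  structure(list(E_light = en, E_heavy = e_tot - en, theta = theta,
                 phi = roots[pick], branch = branch,
                 residual = resid_phi(roots[pick])),
            class = "two_body_result")
}

#' @export
print.two_body_result <- function(x, ...) {
  cat(sprintf(
    "<two_body_result> E_n = %.6f MeV, E_recoil = %.6f MeV (theta = %.4f rad, %s branch)\n",
    x$E_light, x$E_heavy, x$theta, x$branch))
  invisible(x)
}

#' Neutron-energy design envelope over deuteron energy and angle
#'
#' Scans [neutron_energy()] on a grid over a deuteron-energy interval and
#' emission angles in `[0, pi]`, returning the full surface and its
#' extremes. For the D-D source over 0.2-0.5 MeV this is the design
#' envelope of a compact generator: maximum ~3.5 MeV at (0.5 MeV, 0) and
#' minimum ~1.89 MeV at (0.5 MeV, pi).
#'
#' @param ed_range Length-2 numeric, MeV, `0 < lo <= hi`.
#' @param reaction `"dd"` or `"dt"`.
#' @param n_ed,n_theta Grid resolution.
#' @return An object of class `envelope_scan`: `E_d`, `theta` (grid
#'   vectors), `E_n` (matrix `n_ed` x `n_theta`), `min`, `max`, `argmin`,
#'   `argmax` (named vectors `E_d`, `theta`).
#' @export
#' @examples
#' ev <- energy_envelope(c(0.2, 0.5), "dd")
#' c(ev$min, ev$max)
energy_envelope <- function(ed_range, reaction = c("dd", "dt"),
                            n_ed = 61, n_theta = 181) {
  reaction <- match.arg(reaction)
  stopifnot(length(ed_range) == 2, ed_range[1] > 0,
            ed_range[1] <= ed_range[2])
  ed <- seq(ed_range[1], ed_range[2], length.out = n_ed)
  th <- seq(0, pi, length.out = n_theta)
  en <- outer(ed, th, function(e, t) neutron_energy(e, t, reaction))
  imax <- arrayInd(which.max(en), dim(en))
  imin <- arrayInd(which.min(en), dim(en))
  structure(list(
    reaction = reaction, E_d = ed, theta = th, E_n = en,
    min = min(en), max = max(en),
    argmin = c(E_d = ed[imin[1]], theta = th[imin[2]]),
    argmax = c(E_d = ed[imax[1]], theta = th[imax[2]])),
    class = "envelope_scan")
}

#' @export
print.envelope_scan <- function(x, ...) {
  cat(sprintf(
    "<envelope_scan> %s: E_n in [%.4f, %.4f] MeV over E_d in [%g, %g] MeV\n",
    toupper(x$reaction), x$min, x$max, min(x$E_d), max(x$E_d)))
  cat(sprintf("  max at (E_d = %g MeV, theta = %.3f rad); min at (E_d = %g, theta = %.3f)\n",
              x$argmax["E_d"], x$argmax["theta"],
              x$argmin["E_d"], x$argmin["theta"]))
  invisible(x)
}

#' @rdname energy_envelope
#' @param x An `envelope_scan`.
#' @param ... Unused.
#' @export
as.data.frame.envelope_scan <- function(x, ...) {
  data.frame(E_d = rep(x$E_d, times = length(x$theta)),
             theta = rep(x$theta, each = length(x$E_d)),
             E_n = as.vector(x$E_n))
}
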