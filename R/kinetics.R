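# Forward in-droplet binding model: secretion, beadline capture, and 1:1
# equilibrium binding of the two fluorescent reporters to the captured IgG.

#' Bound complex concentration for 1:1 binding with depletion
#'
#' Solves the mass-conservation quadratic for the equilibrium complex
#' concentration of a 1:1 interaction between binding sites at total
#' concentration `b_total` and a ligand at total concentration `l_total`
#' with dissociation constant `kd`:
#' \deqn{(B - x)(L - x) = K_D x, \quad 0 \le x \le \min(B, L).}
#' The numerically stable root (no catastrophic cancellation for small
#' complex concentrations) is used. All arguments are vectorised.
#'
#' @param b_total total binding-site concentration (molar).
#' @param l_total total ligand concentration (molar).
#' @param kd dissociation constant (molar).
#' @return equilibrium complex concentration (molar).
#' @export
bound_1to1 <- function(b_total, l_total, kd) {
  stopifnot(all(b_total >= 0), all(l_total >= 0), all(kd > 0))
  s <- b_total + l_total + kd
  disc <- s^2 - 4 * b_total * l_total
  disc[disc < 0] <- 0
  # stable form of the smaller quadratic root
  2 * b_total * l_total / (s + sqrt(disc))
}

# molar concentration of captured IgG sites at time t (seconds), given a
# secretion rate s (molecules/s), droplet volume (liters), and beadline
# capture capacity (molecules)
captured_sites_molar <- function(rate, t_sec, volume, capacity = Inf) {
  n <- pmin(rate * t_sec, capacity)
  n / (.N_AVOGADRO * volume)
}

#' Forward relocation kinetics for one secreting cell
#'
#' The generative model inverted by the calibration stage. A cell secreting
#' IgG at `rate` molecules/s inside a closed droplet of volume `volume`
#' accumulates N(t) = rate * t molecules, all captured on the beadline (up to
#' the capture capacity). At each frame the captured IgG sites equilibrate
#' independently with the red anti-IgG detector (dissociation constant
#' `chem$kd_detector`) and with the green labelled antigen (the cell's own
#' `kd`), each by the 1:1 conservation quadratic. The relocation in channel c
#' is \eqn{R_c(t) = 1 + \kappa_c \cdot bound_c(t) / free_c(t)}; it equals 1
#' at t = 0 and is non-decreasing in time.
#'
#' @param rate secretion rate, molecules/s (0 for a non-secretor).
#' @param kd dissociation constant of the secreted IgG for the labelled
#'   antigen, molar.
#' @param chem an [assay_chemistry()].
#' @param sched an [acquisition_schedule()].
#' @param volume droplet volume, liters.
#' @return an object of class `relocation_trace`: a list with `times_min`,
#'   `r_red`, `r_green`, and the per-frame free fluorophore fractions
#'   `free_frac_red`, `free_frac_green` used by the renderer.
#' @export
forward_kinetics <- function(rate, kd, chem, sched, volume = 1e-11) {
  stopifnot(inherits(chem, "assay_chemistry"),
            inherits(sched, "acquisition_schedule"),
            rate >= 0, kd > 0, volume > 0)
  t_sec <- sched$times_min * 60
  sites <- captured_sites_molar(rate, t_sec, volume, chem$capture_capacity)
  relocation_from_sites(sites, kd, chem, sched$times_min)
}

# shared core: relocation trace from a vector of captured-site concentrations
relocation_from_sites <- function(sites, kd, chem, times_min) {
  bound_red <- bound_1to1(sites, chem$detector_total, chem$kd_detector)
  bound_green <- bound_1to1(sites, chem$gpi_total, kd)
  free_red <- chem$detector_total - bound_red
  free_green <- chem$gpi_total - bound_green
  structure(list(
    times_min = times_min,
    r_red = 1 + chem$kappa_red * bound_red / free_red,
    r_green = 1 + chem$kappa_green * bound_green / free_green,
    free_frac_red = free_red / chem$detector_total,
    free_frac_green = free_green / chem$gpi_total
  ), class = "relocation_trace")
}

#' @export
print.relocation_trace <- function(x, ...) {
  cat("Relocation trace over", length(x$times_min), "frames (",
      min(x$times_min), "-", max(x$times_min), "min )\n")
  print(data.frame(time_min = x$times_min,
                   r_red = round(x$r_red, 4),
                   r_green = round(x$r_green, 4)), row.names = FALSE)
  invisible(x)
}
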