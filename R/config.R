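# Validated configuration objects for the synthetic assay and the analysis.

#' Emulsion configuration
#'
#' Geometry and loading statistics of a droplet emulsion immobilised in a 2D
#' observation chamber. Cell loading follows Poisson statistics with mean
#' `mean_occupancy` cells per droplet; the default 0.3 corresponds to a cell
#' suspension at 30e6 cells/mL encapsulated in 10 pL droplets. The droplet
#' radius is derived from the (spherical) droplet volume.
#'
#' @param n_droplets number of droplets in the acquisition.
#' @param mean_occupancy mean number of cells per droplet (Poisson lambda).
#' @param droplet_volume droplet volume in liters; default 1e-11 (10 pL).
#' @param pixel_size microns per pixel of the rendered images.
#' @param chamber_size optional c(height, width) in pixels. When `NULL` a
#'   chamber just large enough to hold `n_droplets` on a packed grid is used.
#' @param seed optional integer seed making emulsion sampling and rendering
#'   deterministic.
#' @return an object of class `emulsion_config`.
#' @export
emulsion_config <- function(n_droplets = 2000, mean_occupancy = 0.3,
                            droplet_volume = 1e-11, pixel_size = 1,
                            chamber_size = NULL, seed = NULL) {
  stopifnot(n_droplets >= 1, mean_occupancy >= 0, droplet_volume > 0,
            pixel_size > 0)
  radius_um <- (3 * droplet_volume * 1e-3 / (4 * pi))^(1 / 3) * 1e6
  radius_px <- max(3L, as.integer(round(radius_um / pixel_size)))
  cfg <- structure(list(
    n_droplets = as.integer(n_droplets),
    mean_occupancy = mean_occupancy,
    droplet_volume = droplet_volume,
    droplet_radius_um = radius_um,
    droplet_radius_px = radius_px,
    pixel_size = pixel_size,
    chamber_size = chamber_size,
    seed = seed
  ), class = "emulsion_config")
  cfg
}

#' In-droplet assay chemistry
#'
#' Concentrations of the two fluorescent reporters co-encapsulated with the
#' cells, the detector affinity, the beadline capture capacity, and the
#' channel gains that map a bound:free fluorophore ratio to a relocation
#' increment.
#'
#' The green channel carries fluorescently labelled antigen (default 30 nM)
#' whose beadline binding reports the affinity of the secreted IgG; the red
#' channel carries a fluorescent anti-IgG detector (default 75 nM, detector
#' K_D 1 nM) whose binding reports the amount of secreted IgG.
#'
#' @param gpi_total in-droplet labelled antigen concentration, molar.
#' @param detector_total in-droplet anti-IgG detector concentration, molar.
#' @param kd_detector detector/IgG dissociation constant, molar.
#' @param capture_capacity maximum number of IgG molecules the beadline can
#'   capture; effectively unlimited by default.
#' @param kappa_red,kappa_green dimensionless channel gains: relocation
#'   R = 1 + kappa * bound/free.
#' @return an object of class `assay_chemistry`.
#' @export
assay_chemistry <- function(gpi_total = 30e-9, detector_total = 75e-9,
                            kd_detector = 1e-9, capture_capacity = 1e7,
                            kappa_red = 15, kappa_green = 15) {
  stopifnot(gpi_total > 0, detector_total > 0, kd_detector > 0,
            capture_capacity > 0, kappa_red > 0, kappa_green > 0)
  structure(list(gpi_total = gpi_total, detector_total = detector_total,
                 kd_detector = kd_detector, capture_capacity = capture_capacity,
                 kappa_red = kappa_red, kappa_green = kappa_green),
            class = "assay_chemistry")
}

#' Time-lapse acquisition schedule
#'
#' @param frame_interval minutes between frames (default 7.5).
#' @param n_frames number of frames (default 6, spanning 37.5 minutes).
#' @return an object of class `acquisition_schedule` with a `times_min`
#'   vector starting at 0.
#' @export
acquisition_schedule <- function(frame_interval = 7.5, n_frames = 6) {
  stopifnot(frame_interval > 0, n_frames >= 2)
  n_frames <- as.integer(n_frames)
  structure(list(frame_interval = frame_interval, n_frames = n_frames,
                 total_time = frame_interval * (n_frames - 1),
                 times_min = frame_interval * (seq_len(n_frames) - 1)),
            class = "acquisition_schedule")
}

#' Imaging noise and artifact model
#'
#' Controls the imperfections added when rendering image stacks: Gaussian
#' read noise, Poisson shot noise, droplet movement between frames, and
#' spurious bright specks. All are off by default (noiseless rendering).
#'
#' @param read_noise_sd Gaussian read noise standard deviation, in 16-bit
#'   intensity counts.
#' @param shot_noise logical; replace pixel values by Poisson draws.
#' @param movement_fraction fraction of droplets whose centers are jittered
#'   by 3 px between frames (these should be caught by the MOVED QC flag).
#' @param artifact_fraction fraction of droplets receiving a bright
#'   off-beadline speck in one frame (ARTIFACT QC flag).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(read_noise_sd = 0, shot_noise = FALSE,
                        movement_fraction = 0, artifact_fraction = 0) {
  stopifnot(read_noise_sd >= 0,
            movement_fraction >= 0, movement_fraction <= 1,
            artifact_fraction >= 0, artifact_fraction <= 1)
  structure(list(read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 movement_fraction = movement_fraction,
                 artifact_fraction = artifact_fraction),
            class = "noise_model")
}

#' Ground-truth cohort model
#'
#' Distributions from which the synthetic generator draws per-cell ground
#' truth. Defaults emulate an arthritic-mouse spleen cohort: half of the
#' encapsulated cells secrete IgG; secretion rates are log-normal
#' (meanlog 3.317, sdlog 0.6, mean about 33 molecules/s) truncated to the
#' 4-800 molecules/s assay window; 40% of secretors are antigen-specific
#' with K_D drawn mostly in the low-affinity 10-100 nM decade (88%), some
#' at 1-10 nM (10%) and a small high-affinity tail at 0.1-1 nM (2%), while
#' nonspecific secretors get K_D log-uniform on 0.3-30 uM (no detectable
#' antigen binding).
#'
#' @param secretor_fraction probability that an encapsulated cell secretes
#'   IgG.
#' @param rate_sampler function(n) returning n secretion rates (molecules/s).
#' @param kd_sampler function(n) returning n dissociation constants (molar).
#' @return an object of class `cohort_model`.
#' @export
cohort_model <- function(secretor_fraction = 0.5,
                         rate_sampler = NULL, kd_sampler = NULL) {
  stopifnot(secretor_fraction >= 0, secretor_fraction <= 1)
  if (is.null(rate_sampler)) {
    rate_sampler <- function(n) rlnorm_truncated(n, 3.317, 0.6, .RATE_RANGE)
  }
  if (is.null(kd_sampler)) {
    kd_sampler <- function(n) {
      specific <- runif(n) < 0.4
      kd <- runif_log(n, 0.3e-6, 30e-6)
      u <- runif(n)
      kd_sp <- ifelse(u < 0.88, runif_log(n, 10e-9, 100e-9),
               ifelse(u < 0.98, runif_log(n, 1e-9, 10e-9),
                      runif_log(n, 0.1e-9, 1e-9)))
      ifelse(specific, kd_sp, kd)
    }
  }
  stopifnot(is.function(rate_sampler), is.function(kd_sampler))
  structure(list(secretor_fraction = secretor_fraction,
                 rate_sampler = rate_sampler, kd_sampler = kd_sampler),
            class = "cohort_model")
}

#' Positivity filter thresholds for secretor calling
#'
#' The three filters applied to the red (anti-IgG) relocation trace of each
#' QC-passing droplet: a minimum achieved relocation, a net first-to-last
#' difference, and a minimal least-squares slope per frame interval.
#'
#' @param min_relocation the trace maximum must exceed this (default 1.2).
#' @param net_difference last minus first relocation must exceed this
#'   (default 0.025).
#' @param slope least-squares slope of relocation versus frame index must be
#'   at least this, in relocation units per frame interval (default 0.004).
#' @param channel channel used for calling; the red anti-IgG channel.
#' @return an object of class `secretor_call_config`.
#' @export
secretor_call_config <- function(min_relocation = 1.2, net_difference = 0.025,
                                 slope = 0.004, channel = "red") {
  stopifnot(min_relocation > 0, net_difference > 0, slope > 0)
  channel <- match.arg(channel, c("red", "green"))
  structure(list(min_relocation = min_relocation,
                 net_difference = net_difference,
                 slope = slope, channel = channel),
            class = "secretor_call_config")
}

#' @export
print.emulsion_config <- function(x, ...) {
  cat("Emulsion:", x$n_droplets, "droplets,",
      format(x$mean_occupancy), "cells/droplet,",
      format(x$droplet_volume * 1e12), "pL (radius",
      round(x$droplet_radius_um, 1), "um =", x$droplet_radius_px, "px)\n")
  invisible(x)
}

#' @export
print.assay_chemistry <- function(x, ...) {
  cat("Assay chemistry: antigen", x$gpi_total * 1e9,
      "nM; anti-IgG detector", x$detector_total * 1e9,
      "nM (Kd", x$kd_detector * 1e9, "nM); gains red/green",
      x$kappa_red, "/", x$kappa_green, "\n")
  invisible(x)
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat("Acquisition:", x$n_frames, "frames every", x$frame_interval,
      "min over", x$total_time, "min\n")
  invisible(x)
}

# --- internal helpers ------------------------------------------------------

# evaluate expr under a local RNG seed, restoring the global RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# log-uniform draw on [lo, hi]
runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Truncated log-normal secretion-rate sampler
#'
#' Log-normal draws truncated (by rejection) to a closed range; with the
#' default cohort parameters (meanlog 3.317, sdlog 0.6, range 4-800
#' molecules/s) the mean is about 33 molecules/s.
#'
#' @param n number of draws.
#' @param meanlog,sdlog log-normal parameters (natural log).
#' @param range c(lo, hi) truncation window.
#' @return n draws inside `range`.
#' @export
rlnorm_truncated <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}
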