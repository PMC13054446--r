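# Calibration of the channel gains from a known-mAb anchor panel, and
# inversion of measured relocation traces into secretion rates and K_D.

#' Synthetic calibration anchor panel
#'
#' A panel of monoclonal antibodies of known affinity for the antigen,
#' encapsulated (without cells) at known in-droplet concentrations. Each
#' clone/concentration pair is one anchor. The default panel uses four
#' clones at 0.1, 1, 10 and 100 nM spanning the assay's working K_D window,
#' each at three concentrations.
#'
#' @param kds clone affinities (molar), one per clone.
#' @param clones clone labels.
#' @param concentrations in-droplet mAb concentrations (molar) at which each
#'   clone is encapsulated.
#' @return data.frame with one row per anchor: `clone`, `kd`,
#'   `concentration`.
#' @export
calibration_panel <- function(kds = c(0.1, 1, 10, 100) * 1e-9,
                              clones = c("B10.8", "D24.9", "D24.4", "E4.6"),
                              concentrations = c(2.5, 10, 40) * 1e-9) {
  stopifnot(length(kds) == length(clones), all(kds > 0),
            all(concentrations > 0))
  out <- expand.grid(clone = clones, concentration = concentrations,
                     stringsAsFactors = FALSE)
  out$kd <- kds[match(out$clone, clones)]
  out[c("clone", "kd", "concentration")]
}

#' Simulate relocation traces for a calibration panel
#'
#' Anchors contain a fixed mAb concentration (no secretion), so the captured
#' IgG on the beadline is constant over time and the forward model yields a
#' flat relocation trace per channel. Optional Gaussian noise emulates
#' measurement scatter.
#'
#' @param panel a [calibration_panel()].
#' @param chem an [assay_chemistry()] (its gains are the ground truth).
#' @param sched an [acquisition_schedule()].
#' @param noise_sd relative Gaussian noise on the relocation values.
#' @param seed optional seed.
#' @return the panel data.frame with list-columns `r_red` and `r_green`
#'   holding per-frame relocation vectors.
#' @export
simulate_anchor_traces <- function(panel, chem = assay_chemistry(),
                                   sched = acquisition_schedule(),
                                   noise_sd = 0, seed = NULL) {
  with_seed(seed, {
    tr <- lapply(seq_len(nrow(panel)), function(i) {
      sites <- rep(panel$concentration[i], sched$n_frames)
      t <- relocation_from_sites(sites, panel$kd[i], chem, sched$times_min)
      if (noise_sd > 0) {
        t$r_red <- t$r_red * (1 + rnorm(sched$n_frames, 0, noise_sd))
        t$r_green <- t$r_green * (1 + rnorm(sched$n_frames, 0, noise_sd))
      }
      t
    })
    panel$r_red <- lapply(tr, `[[`, "r_red")
    panel$r_green <- lapply(tr, `[[`, "r_green")
    panel
  })
}

#' Fit the calibration model from anchor traces
#'
#' Estimates the two channel gains by least squares between the anchors'
#' measured relocations and the forward-model bound:free ratios implied by
#' each anchor's known concentration and affinity: since
#' R = 1 + kappa * bound/free, the gain is the through-origin regression of
#' (R - 1) on the predicted ratio, pooled over anchors and frames.
#'
#' @param anchors a [simulate_anchor_traces()] result (or any data.frame
#'   with `kd`, `concentration`, and list-columns `r_red`, `r_green`).
#' @param chem an [assay_chemistry()]; its concentrations and detector K_D
#'   define the forward model (its gains are ignored — they are what is
#'   being fitted).
#' @return an object of class `calibration_model` with fitted gains, the
#'   residual RMS per channel, and the assay working ranges (secretion
#'   4-800 molecules/s; K_D 2.3-100 nM).
#' @export
fit_calibration <- function(anchors, chem = assay_chemistry()) {
  if (is.null(anchors) || nrow(anchors) == 0) {
    stop("empty anchor panel: at least 2 anchors are required")
  }
  if (length(unique(anchors$concentration)) < 2) {
    stop("degenerate calibration panel: anchors at a single concentration ",
         "cannot constrain the gains; provide >= 2 distinct concentrations")
  }
  if (length(unique(anchors$kd)) < 2) {
    stop("degenerate calibration panel: >= 2 distinct K_D values required")
  }
  ratio_red <- ratio_green <- obs_red <- obs_green <- numeric(0)
  for (i in seq_len(nrow(anchors))) {
    sites <- anchors$concentration[i]
    b_r <- bound_1to1(sites, chem$detector_total, chem$kd_detector)
    b_g <- bound_1to1(sites, chem$gpi_total, anchors$kd[i])
    nf <- length(anchors$r_red[[i]])
    ratio_red <- c(ratio_red, rep(b_r / (chem$detector_total - b_r), nf))
    ratio_green <- c(ratio_green, rep(b_g / (chem$gpi_total - b_g), nf))
    obs_red <- c(obs_red, anchors$r_red[[i]] - 1)
    obs_green <- c(obs_green, anchors$r_green[[i]] - 1)
  }
  k_red <- sum(ratio_red * obs_red) / sum(ratio_red^2)
  k_green <- sum(ratio_green * obs_green) / sum(ratio_green^2)
  structure(list(
    kappa_red = k_red, kappa_green = k_green,
    rms_red = sqrt(mean((obs_red - k_red * ratio_red)^2)),
    rms_green = sqrt(mean((obs_green - k_green * ratio_green)^2)),
    secretion_range = .RATE_RANGE,
    kd_range = c(.KD_EXTRAPOLATION_BOUND, .KD_SPECIFIC_BOUND),
    chem = chem, n_anchors = nrow(anchors)
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Calibration model (", x$n_anchors, "anchors )\n")
  cat("  gains: red", signif(x$kappa_red, 6), "( rms",
      signif(x$rms_red, 3), ") green", signif(x$kappa_green, 6),
      "( rms", signif(x$rms_green, 3), ")\n")
  cat("  working ranges:", x$secretion_range[1], "-", x$secretion_range[2],
      "molecules/s;", x$kd_range[1] * 1e9, "-", x$kd_range[2] * 1e9,
      "nM K_D\n")
  invisible(x)
}

#' @export
coef.calibration_model <- function(object, ...) {
  c(kappa_red = object$kappa_red, kappa_green = object$kappa_green)
}

#' Predict relocation traces from a fitted calibration model
#'
#' @param object a `calibration_model`.
#' @param rate secretion rate, molecules/s.
#' @param kd dissociation constant, molar.
#' @param sched an [acquisition_schedule()].
#' @param volume droplet volume, liters.
#' @param ... unused.
#' @return a `relocation_trace` under the fitted gains.
#' @export
predict.calibration_model <- function(object, rate, kd,
                                      sched = acquisition_schedule(),
                                      volume = 1e-11, ...) {
  chem <- object$chem
  chem$kappa_red <- object$kappa_red
  chem$kappa_green <- object$kappa_green
  forward_kinetics(rate, kd, chem, sched, volume)
}

# invert red relocations into captured-site concentrations (molar/frame)
.sites_from_red <- function(r_red, model) {
  chem <- model$chem
  x <- (r_red - 1) / model$kappa_red
  x[x < 0] <- 0
  bound <- chem$detector_total * x / (1 + x)
  free <- chem$detector_total / (1 + x)
  bound * (1 + chem$kd_detector / free)
}

#' Infer a secretion rate from a red-channel relocation trace
#'
#' Inverts the relocation trace through the calibrated equilibrium model:
#' each frame's relocation gives the bound:free detector ratio, hence (by
#' the 1:1 isotherm with the detector K_D) the molar concentration of
#' captured IgG, hence the number of secreted molecules. The rate is the
#' mean slope of molecules versus time using the first frame as baseline
#' (frames 2..n), damping any capture-lag transient. Estimates outside the
#' 4-800 molecules/s calibration window are censored to the boundary and
#' flagged `BELOW_4` / `ABOVE_800`; a non-positive slope yields `NO_RATE`.
#'
#' @param r_red per-frame red relocation values.
#' @param times_min frame times in minutes.
#' @param model a [fit_calibration()] model.
#' @param volume droplet volume, liters.
#' @return list with `rate` (molecules/s, censored) and `flag` (one of
#'   IN_RANGE, BELOW_4, ABOVE_800, NO_RATE).
#' @export
infer_secretion_rate <- function(r_red, times_min, model, volume = 1e-11) {
  stopifnot(inherits(model, "calibration_model"),
            length(r_red) == length(times_min), length(r_red) >= 2)
  sites <- .sites_from_red(r_red, model)
  n_mol <- sites * .N_AVOGADRO * volume
  t_sec <- times_min * 60
  k <- seq_along(r_red)[-1]
  s_hat <- mean((n_mol[k] - n_mol[1]) / (t_sec[k] - t_sec[1]))
  if (!is.finite(s_hat) || s_hat <= 0) {
    return(list(rate = NA_real_, flag = "NO_RATE"))
  }
  rng <- model$secretion_range
  if (s_hat < rng[1]) list(rate = rng[1], flag = "BELOW_4")
  else if (s_hat > rng[2]) list(rate = rng[2], flag = "ABOVE_800")
  else list(rate = s_hat, flag = "IN_RANGE")
}

#' Infer the antigen dissociation constant from a two-channel trace
#'
#' Combines both channels: the red channel fixes the captured IgG site
#' concentration per frame; the green channel gives the bound and free
#' labelled-antigen concentrations. The dissociation constant follows from
#' the depletion-corrected equilibrium
#' \deqn{K_D = (B - bound_g) \cdot free_g / bound_g}
#' per frame, summarised as the median over informative frames (2..n).
#' Values below 2.3 nM are returned as algebraic extrapolations flagged
#' `EXTRAPOLATED_LT_2.3`; values at or above 100 nM are flagged
#' `NONSPECIFIC_GE_100` (not antigen-specific); an absent green signal
#' yields `NO_GREEN_SIGNAL` (treated as nonspecific).
#'
#' @param r_red,r_green per-frame relocation values.
#' @param model a [fit_calibration()] model.
#' @return list with `kd` (molar; NA for NO_GREEN_SIGNAL) and `flag` (one
#'   of IN_RANGE, EXTRAPOLATED_LT_2.3, NONSPECIFIC_GE_100,
#'   NO_GREEN_SIGNAL).
#' @export
infer_kd <- function(r_red, r_green, model) {
  stopifnot(inherits(model, "calibration_model"),
            length(r_red) == length(r_green), length(r_red) >= 2)
  chem <- model$chem
  sites <- .sites_from_red(r_red, model)
  y <- (r_green - 1) / model$kappa_green
  y[y < 0] <- 0
  bound_g <- chem$gpi_total * y / (1 + y)
  free_g <- chem$gpi_total / (1 + y)
  k <- seq_along(r_red)[-1]
  valid <- k[bound_g[k] > 1e-13 & sites[k] > 0]
  if (length(valid) == 0) {
    return(list(kd = NA_real_, flag = "NO_GREEN_SIGNAL"))
  }
  kd_k <- (sites[valid] - bound_g[valid]) * free_g[valid] / bound_g[valid]
  kd_k[kd_k < 1e-12] <- 1e-12  # theta >= 1 numerically: beyond resolution
  kd_hat <- median(kd_k)
  flag <- if (kd_hat >= .KD_SPECIFIC_BOUND) "NONSPECIFIC_GE_100"
  else if (kd_hat < .KD_EXTRAPOLATION_BOUND) "EXTRAPOLATED_LT_2.3"
  else "IN_RANGE"
  list(kd = kd_hat, flag = flag)
}

#' Classify affinity and antigen specificity from a computed K_D
#'
#' A cell is antigen-specific iff its computed K_D is below 100 nM.
#' Specific cells are classed LOW (K_D >= 10 nM), HIGH (K_D < 1 nM) or
#' MEDIUM (between).
#'
#' @param kd computed dissociation constant(s), molar (NA allowed).
#' @param kd_flag the flag(s) from [infer_kd()]; `NO_GREEN_SIGNAL` forces
#'   nonspecific.
#' @return data.frame with `is_gpi_specific` and `affinity_class`
#'   (LOW/MEDIUM/HIGH, NA for nonspecific).
#' @export
classify_affinity <- function(kd, kd_flag = NULL) {
  specific <- !is.na(kd) & kd < .KD_SPECIFIC_BOUND
  if (!is.null(kd_flag)) {
    specific <- specific & kd_flag != "NO_GREEN_SIGNAL" &
      kd_flag != "NONSPECIFIC_GE_100"
  }
  cls <- ifelse(!specific, NA_character_,
                ifelse(kd >= .KD_LOW_BOUND, "LOW",
                       ifelse(kd < .KD_HIGH_BOUND, "HIGH", "MEDIUM")))
  data.frame(is_gpi_specific = specific, affinity_class = cls)
}

#' Build the master single-cell table from traces and calls
#'
#' For every positive call, inverts the trace into a secretion rate and a
#' K_D with censoring flags and attaches specificity, affinity class, and
#' optional sample metadata. This is the analysis' primary deliverable.
#'
#' @param traces data.frame from [compute_relocation()].
#' @param calls data.frame from [call_secretors()].
#' @param model a [fit_calibration()] model.
#' @param volume droplet volume, liters.
#' @param organ,age_weeks,mouse_id optional metadata recycled across
#'   records.
#' @return data.frame with one row per called IgG-secreting cell:
#'   droplet_id, secretion_rate, rate_flag, kd, kd_flag, is_gpi_specific,
#'   affinity_class, organ, age_weeks, mouse_id.
#' @export
infer_cells <- function(traces, calls, model, volume = 1e-11,
                        organ = NA_character_, age_weeks = NA_real_,
                        mouse_id = NA_character_) {
  pos_ids <- calls$droplet_id[calls$positive]
  tr <- traces[traces$droplet_id %in% pos_ids, , drop = FALSE]
  sp <- split(tr, tr$droplet_id)
  rows <- lapply(sp, function(g) {
    g <- g[order(g$frame), ]
    rate <- infer_secretion_rate(g$r_red, g$time_min, model, volume)
    kd <- infer_kd(g$r_red, g$r_green, model)
    data.frame(droplet_id = g$droplet_id[1],
               secretion_rate = rate$rate, rate_flag = rate$flag,
               kd = kd$kd, kd_flag = kd$flag)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(droplet_id = integer(0), secretion_rate = numeric(0),
                      rate_flag = character(0), kd = numeric(0),
                      kd_flag = character(0))
  }
  cl <- classify_affinity(out$kd, out$kd_flag)
  out$is_gpi_specific <- cl$is_gpi_specific
  out$affinity_class <- cl$affinity_class
  out$organ <- organ
  out$age_weeks <- age_weeks
  out$mouse_id <- mouse_id
  out
}
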