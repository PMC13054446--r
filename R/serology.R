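# Serum-level computations: steady-state SPR affinity, anti-antigen IgG
# percentage, and censored ELISA ED50.

#' Fit a 1:1 steady-state SPR binding model
#'
#' Least-squares fit of the equilibrium response against analyte
#' concentration, \eqn{R_{eq}(C) = R_{max} C / (K_D + C)}, as in standard
#' "steady state affinity" evaluation of capture-format SPR series. The fit
#' refuses to trust an extrapolated K_D: when the largest injected
#' concentration is below the fitted K_D the binding curve has not
#' approached saturation and the fit is flagged `extrapolated` with a
#' warning.
#'
#' @param concentrations analyte concentrations, molar (>= 3 distinct).
#' @param response equilibrium responses (response units).
#' @return an object of class `spr_fit` with `kd`, `rmax`, standard errors,
#'   the data, and the `extrapolated` flag.
#' @export
fit_steady_state <- function(concentrations, response) {
  stopifnot(length(concentrations) == length(response))
  keep <- is.finite(concentrations) & is.finite(response)
  C <- concentrations[keep]; r <- response[keep]
  if (length(unique(C)) < 3) stop("need >= 3 distinct concentrations")
  if (any(C <= 0)) stop("concentrations must be positive")
  if (all(r <= 0)) stop("no positive responses: nothing to fit")
  fit <- minpack.lm::nlsLM(
    r ~ rmax * C / (kd + C),
    start = list(rmax = max(r) * 1.5, kd = median(C)),
    lower = c(rmax = 1e-12, kd = 1e-15),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(rmax = NA_real_, kd = NA_real_))
  extrapolated <- max(C) < est[["kd"]]
  if (extrapolated) {
    warning("largest concentration (", signif(max(C) * 1e9, 3),
            " nM) is below the fitted K_D: fitted K_D ",
            signif(est[["kd"]] * 1e9, 3), " nM is an extrapolation")
  }
  structure(list(kd = est[["kd"]], rmax = est[["rmax"]],
                 se_kd = unname(se["kd"]), se_rmax = unname(se["rmax"]),
                 extrapolated = extrapolated,
                 concentrations = C, response = r, fit = fit),
            class = "spr_fit")
}

#' @export
print.spr_fit <- function(x, ...) {
  cat("Steady-state 1:1 SPR fit (", length(x$concentrations), "points )\n")
  cat("  K_D  =", signif(x$kd * 1e9, 4), "nM ( se",
      signif(x$se_kd * 1e9, 3), ")\n")
  cat("  Rmax =", signif(x$rmax, 4), "RU ( se", signif(x$se_rmax, 3), ")\n")
  if (x$extrapolated) cat("  [flagged: K_D above measured range]\n")
  invisible(x)
}

#' @export
coef.spr_fit <- function(object, ...) c(kd = object$kd, rmax = object$rmax)

#' @export
predict.spr_fit <- function(object, concentrations = object$concentrations,
                            ...) {
  object$rmax * concentrations / (object$kd + concentrations)
}

#' Simulate an equilibrium SPR response series
#'
#' @param kd dissociation constant, molar.
#' @param rmax maximal response, response units.
#' @param concentrations analyte series, molar; default is the five-point
#'   capture-format series 2000, 667, 222, 74, 25 nM.
#' @param noise_sd Gaussian noise sd on the responses.
#' @param seed optional seed.
#' @return data.frame with `concentration` and `response`.
#' @export
simulate_spr <- function(kd, rmax,
                         concentrations = c(2000, 667, 222, 74, 25) * 1e-9,
                         noise_sd = 0, seed = NULL) {
  with_seed(seed, {
    r <- rmax * concentrations / (kd + concentrations)
    if (noise_sd > 0) r <- r + rnorm(length(r), 0, noise_sd)
    data.frame(concentration = concentrations, response = r)
  })
}

#' Percentage of anti-antigen IgG among captured IgG
#'
#' Computed from the fitted SPR Rmax and the IgG capture level as
#' \deqn{\% = \frac{R_{max}}{capture} \times \frac{M_{antigen}}{M_{IgG}}
#'   \times 100,}
#' the molar-mass ratio converting the response-unit (mass-based) ratio into
#' a molar fraction of binding-competent IgG. Default molar masses: antigen
#' (glucose-6-phosphate isomerase monomer) 63 kDa, IgG 150 kDa.
#'
#' @param rmax fitted maximal response (response units).
#' @param capture_level IgG capture response (response units), > 0.
#' @param m_antigen,m_igg molar masses, g/mol.
#' @return percentage (may exceed 100 with a warning).
#' @export
percent_anti_gpi <- function(rmax, capture_level, m_antigen = 63000,
                             m_igg = 150000) {
  stopifnot(rmax >= 0, m_antigen > 0, m_igg > 0)
  if (capture_level <= 0) stop("capture_level must be positive")
  pct <- rmax / capture_level * (m_antigen / m_igg) * 100
  if (any(pct > 100)) warning("computed percentage exceeds 100%")
  pct
}

#' Fit a censored ELISA ED50 from a dilution series
#'
#' Four-parameter logistic fit of optical density against log10 reciprocal
#' dilution; the ED50 is the reciprocal dilution at the inflection
#' (half-maximal OD). The standard assay covers threefold serum dilutions
#' 1:300 through 1:218,700; ED50 estimates outside that window are censored
#' to the boundary with flags `LT_300` / `GT_218700`. A flat series cannot
#' be fitted and is censored by its level: uniformly low OD means no
#' detectable titer (`LT_300`), uniformly high OD means the titer exceeds
#' the largest dilution (`GT_218700`). A series whose OD increases with
#' dilution fails the orientation sanity check.
#'
#' @param dilutions reciprocal dilution factors, strictly increasing.
#' @param od optical densities.
#' @param dilution_range the assay window; default c(300, 218700).
#' @param flat_tol OD range below which a series is considered flat.
#' @param flat_high OD above which a flat series is called saturated.
#' @return an object of class `ed50_fit` with `ed50`, `censor` (IN_RANGE,
#'   LT_300, GT_218700), and the 4PL coefficients (NA when censored without
#'   a fit).
#' @export
fit_ed50 <- function(dilutions, od, dilution_range = c(300, 218700),
                     flat_tol = 0.1, flat_high = 0.5) {
  stopifnot(length(dilutions) == length(od))
  if (is.unsorted(dilutions, strictly = TRUE)) {
    stop("dilutions must be strictly increasing reciprocal factors")
  }
  if (length(dilutions) < 4) stop("need >= 4 dilution points")
  censor_labels <- c(paste0("LT_", dilution_range[1]),
                     paste0("GT_", dilution_range[2]))
  mk <- function(ed50, censor, pars = c(a = NA_real_, d = NA_real_,
                                        b = NA_real_)) {
    structure(list(ed50 = ed50, censor = censor, pars = pars,
                   dilutions = dilutions, od = od,
                   dilution_range = dilution_range), class = "ed50_fit")
  }
  if (diff(range(od)) < flat_tol) {
    return(mk(NA_real_,
              if (mean(od) >= flat_high) censor_labels[2] else censor_labels[1]))
  }
  if (stats::cor(log(dilutions), od, method = "spearman") > 0) {
    stop("OD increases with dilution: series orientation check failed")
  }
  mid <- (max(od) + min(od)) / 2
  le0 <- log(dilutions[which.min(abs(od - mid))])
  fit <- minpack.lm::nlsLM(
    od ~ d + (a - d) / (1 + (dilutions / exp(le))^b),
    start = list(a = max(od), d = min(od), b = 1.2, le = le0),
    lower = c(a = 0, d = 0, b = 0.05, le = log(dilution_range[1]) - 8),
    upper = c(a = Inf, d = Inf, b = 20, le = log(dilution_range[2]) + 8),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  p <- coef(fit)
  ed50 <- exp(p[["le"]])
  pars <- c(a = p[["a"]], d = p[["d"]], b = p[["b"]])
  if (ed50 < dilution_range[1]) mk(dilution_range[1], censor_labels[1], pars)
  else if (ed50 > dilution_range[2]) mk(dilution_range[2], censor_labels[2],
                                        pars)
  else mk(ed50, "IN_RANGE", pars)
}

#' @export
print.ed50_fit <- function(x, ...) {
  cat("ELISA ED50 fit:",
      if (x$censor == "IN_RANGE") format(round(x$ed50))
      else paste0(x$censor, " (censored)"), "\n")
  invisible(x)
}

#' @export
coef.ed50_fit <- function(object, ...) {
  c(ed50 = object$ed50, object$pars)
}

#' Simulate a 4PL ELISA dilution series
#'
#' @param ed50 reciprocal dilution at the inflection.
#' @param dilutions reciprocal dilution grid; default the threefold series
#'   300 x 3^(0..6) = 300 ... 218,700.
#' @param a,d upper and lower OD asymptotes.
#' @param b Hill slope.
#' @param noise_sd Gaussian OD noise.
#' @param seed optional seed.
#' @return data.frame with `dilution` and `od`.
#' @export
simulate_elisa <- function(ed50, dilutions = 300 * 3^(0:6), a = 2, d = 0.05,
                           b = 1.2, noise_sd = 0, seed = NULL) {
  with_seed(seed, {
    od <- d + (a - d) / (1 + (dilutions / ed50)^b)
    if (noise_sd > 0) od <- od + rnorm(length(od), 0, noise_sd)
    data.frame(dilution = dilutions, od = od)
  })
}
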