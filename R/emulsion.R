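# Sampling of droplet emulsions with Poisson cell loading and ground truth.

#' Sample a droplet emulsion with ground-truth cells
#'
#' Places `config$n_droplets` non-overlapping droplets on a jittered grid
#' inside the observation chamber, draws per-droplet cell counts from
#' Poisson(`mean_occupancy`) (or exactly one cell per droplet when
#' `occupancy = "single"`), and attaches ground-truth secretion rates and
#' affinities from the `cohort` model. At most one cell per droplet is a
#' secretor, so every secreting droplet has a single well-defined ground
#' truth (rate, K_D); the assay itself only analyses droplets with one or
#' two cells.
#'
#' @param config an [emulsion_config()].
#' @param cohort a [cohort_model()] providing the ground-truth distributions.
#' @param occupancy `"poisson"` (default) or `"single"` (exactly one cell in
#'   every droplet, useful for calibration-style cohorts).
#' @return an object of class `emulsion`: a list with
#'   \describe{
#'     \item{droplets}{data.frame, one row per droplet: `droplet_id`, center
#'       `cx`,`cy` (px), `radius_px`, `n_cells`, `secretion_rate`
#'       (molecules/s; 0 for no secretor), `kd` (molar; NA for no secretor).}
#'     \item{cells}{data.frame, one row per encapsulated cell with its
#'       droplet id and ground truth.}
#'     \item{chamber}{c(height, width) in px.}
#'     \item{config}{the emulsion config.}
#'   }
#' @export
sample_emulsion <- function(config, cohort = cohort_model(),
                            occupancy = c("poisson", "single")) {
  stopifnot(inherits(config, "emulsion_config"),
            inherits(cohort, "cohort_model"))
  occupancy <- match.arg(occupancy)
  with_seed(config$seed, {
    n <- config$n_droplets
    r <- config$droplet_radius_px
    # gap wide enough that a 3 px movement jitter cannot merge neighbours
    spacing <- 2L * r + 8L
    margin <- r + 4L
    if (is.null(config$chamber_size)) {
      ncol_grid <- ceiling(sqrt(n))
      nrow_grid <- ceiling(n / ncol_grid)
      chamber <- c(2L * margin + (nrow_grid - 1L) * spacing,
                   2L * margin + (ncol_grid - 1L) * spacing)
    } else {
      chamber <- as.integer(config$chamber_size)
      ncol_grid <- (chamber[2] - 2L * margin) %/% spacing + 1L
      nrow_grid <- (chamber[1] - 2L * margin) %/% spacing + 1L
      if (ncol_grid < 1 || nrow_grid < 1 || ncol_grid * nrow_grid < n) {
        stop("chamber of ", chamber[1], "x", chamber[2],
             " px too small to place ", n,
             " droplets of radius ", r, " px without overlap")
      }
    }
    idx <- seq_len(n) - 1L
    row_i <- idx %/% ncol_grid
    col_i <- idx %% ncol_grid
    # +/-1 px jitter keeps droplets well separated but off a perfect grid
    cy <- margin + row_i * spacing + sample(-1:1, n, replace = TRUE)
    cx <- margin + col_i * spacing + sample(-1:1, n, replace = TRUE)

    n_cells <- if (occupancy == "single") rep(1L, n) else
      rpois(n, config$mean_occupancy)

    droplets <- data.frame(droplet_id = seq_len(n), cx = cx, cy = cy,
                           radius_px = r, n_cells = n_cells,
                           secretion_rate = 0, kd = NA_real_)

    total_cells <- sum(n_cells)
    cells <- data.frame(
      cell_id = seq_len(total_cells),
      droplet_id = rep(droplets$droplet_id, n_cells),
      n_cells_in_droplet = rep(n_cells, n_cells),
      is_igg_secretor = rep(FALSE, total_cells),
      secretion_rate = rep(0, total_cells),
      kd = rep(NA_real_, total_cells)
    )
    if (total_cells > 0) {
      # first cell of each droplet may secrete; one secretor max per droplet
      first_of_droplet <- !duplicated(cells$droplet_id)
      sec <- first_of_droplet & (runif(total_cells) < cohort$secretor_fraction)
      n_sec <- sum(sec)
      if (n_sec > 0) {
        cells$is_igg_secretor[sec] <- TRUE
        cells$secretion_rate[sec] <- cohort$rate_sampler(n_sec)
        cells$kd[sec] <- cohort$kd_sampler(n_sec)
        m <- match(cells$droplet_id[sec], droplets$droplet_id)
        droplets$secretion_rate[m] <- cells$secretion_rate[sec]
        droplets$kd[m] <- cells$kd[sec]
      }
    }
    structure(list(droplets = droplets, cells = cells,
                   chamber = chamber, config = config),
              class = "emulsion")
  })
}

#' @export
print.emulsion <- function(x, ...) {
  d <- x$droplets
  cat("Emulsion of", nrow(d), "droplets in a", x$chamber[1], "x",
      x$chamber[2], "px chamber\n")
  cat("  cells:", sum(d$n_cells), " (",
      sum(d$n_cells == 1), "single,", sum(d$n_cells == 2), "double,",
      sum(d$n_cells > 2), "multi )\n")
  cat("  secreting droplets:", sum(d$secretion_rate > 0), "\n")
  invisible(x)
}
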