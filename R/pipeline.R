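# End-to-end orchestration: synthesize -> render -> segment -> call ->
# invert -> summarize, with optional on-disk artifacts.

#' Assemble a full run configuration
#'
#' Bundles the per-stage configuration objects with a single seed from
#' which every stage's randomness derives, so a run is reproducible from
#' its config alone. Defaults give a small "demo" cohort: 2,000 droplets
#' at 0.3 cells/droplet with mild imaging noise and the default
#' spleen-like ground-truth distributions.
#'
#' @param n_droplets droplets in the acquisition.
#' @param seed integer seed.
#' @param emulsion,chemistry,schedule,noise,cohort,calling per-stage
#'   configuration objects; sensible defaults when omitted.
#' @param base_intensity rendering background intensity, counts.
#' @param occupancy `"poisson"` cell loading (default) or `"single"`
#'   (exactly one cell per droplet, for calibration-style cohorts).
#' @param organ,age_weeks,mouse_id metadata attached to the single-cell
#'   records.
#' @return an object of class `dropmap_config`.
#' @export
dropmap_config <- function(n_droplets = 2000, seed = 1L,
                           occupancy = c("poisson", "single"),
                           emulsion = NULL,
                           chemistry = assay_chemistry(),
                           schedule = acquisition_schedule(),
                           noise = noise_model(read_noise_sd = 3,
                                               shot_noise = TRUE,
                                               movement_fraction = 0.02,
                                               artifact_fraction = 0.01),
                           cohort = cohort_model(),
                           calling = secretor_call_config(),
                           base_intensity = 2000,
                           organ = "spleen", age_weeks = 10,
                           mouse_id = "sim01") {
  occupancy <- match.arg(occupancy)
  if (is.null(emulsion)) {
    emulsion <- emulsion_config(n_droplets = n_droplets, seed = seed)
  } else {
    emulsion$seed <- seed
  }
  structure(list(seed = as.integer(seed), occupancy = occupancy,
                 emulsion = emulsion,
                 chemistry = chemistry, schedule = schedule, noise = noise,
                 cohort = cohort, calling = calling,
                 base_intensity = base_intensity,
                 organ = organ, age_weeks = age_weeks, mouse_id = mouse_id),
            class = "dropmap_config")
}

#' Run the full droplet immunoassay pipeline
#'
#' Executes every stage on a synthetic acquisition: emulsion sampling,
#' forward kinetics and rendering, segmentation and QC, relocation
#' extraction, secretor calling, calibration fitting and inversion, and
#' cohort summary. Row counts of every stage are collected in the run
#' report. With `out_dir` set, the stage tables (intensities, relocation,
#' calls, master single-cell table, summary) are written as TSV, a
#' machine-readable run report as JSON, and optionally the image stacks as
#' 16-bit TIFF.
#'
#' @param config a [dropmap_config()].
#' @param out_dir optional output directory.
#' @param write_images also write the TIFF stacks (large); default FALSE.
#' @return an object of class `dropmap_run`: list with `truth`,
#'   `observations`, `traces`, `calls`, `calibration`, `records`, `summary`
#'   and `report`.
#' @export
run_dropmap <- function(config = dropmap_config(), out_dir = NULL,
                        write_images = FALSE) {
  stopifnot(inherits(config, "dropmap_config"))
  emu <- sample_emulsion(config$emulsion, cohort = config$cohort,
                         occupancy = config$occupancy)
  stack <- render_stack(emu, chem = config$chemistry,
                        sched = config$schedule, noise = config$noise,
                        base_intensity = config$base_intensity)
  obs <- extract_observations(stack)
  traces <- compute_relocation(obs)
  # restrict calling to QC-passing droplets with 1-2 detected cells
  eligible <- obs$droplets$droplet_id[obs$droplets$qc_pass &
                                        obs$droplets$n_cells_detected %in% 1:2]
  calls <- call_secretors(traces[traces$droplet_id %in% eligible, ,
                                 drop = FALSE], cfg = config$calling)
  anchors <- simulate_anchor_traces(calibration_panel(),
                                    chem = config$chemistry,
                                    sched = config$schedule,
                                    seed = config$seed + 2L)
  cal <- fit_calibration(anchors, chem = config$chemistry)
  records <- infer_cells(traces, calls, cal,
                         volume = config$emulsion$droplet_volume,
                         organ = config$organ, age_weeks = config$age_weeks,
                         mouse_id = config$mouse_id)
  summary <- summarize_cohort(records)

  report <- list(
    seed = config$seed,
    n_droplets_config = config$emulsion$n_droplets,
    counts = c(obs$counts,
               list(called_positive = sum(calls$positive),
                    records = nrow(records),
                    gpi_specific = sum(records$is_gpi_specific))),
    censor_tally = lapply(summary$censor_tally, function(tb) {
      as.list(setNames(as.integer(tb), names(tb)))
    }),
    calibration = list(kappa_red = cal$kappa_red,
                       kappa_green = cal$kappa_green))

  run <- structure(list(truth = stack$truth, observations = obs,
                        traces = traces, calls = calls, calibration = cal,
                        records = records, summary = summary,
                        report = report, config = config),
                   class = "dropmap_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(obs$intensities, "intensities.tsv")
    wt(traces, "relocation.tsv")
    wt(calls, "calls.tsv")
    wt(records, "single_cells.tsv")
    if (!is.null(summary$by_stratum)) wt(summary$by_stratum, "summary.tsv")
    wt(stack$truth, "truth.tsv")
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (write_images) write_stack(stack, file.path(out_dir, "stacks"))
  }
  run
}

#' @export
print.dropmap_run <- function(x, ...) {
  cat("dropmap run (seed", x$report$seed, ")\n")
  cat("  droplets:", x$report$n_droplets_config, "configured,",
      x$report$counts$segmented, "segmented,",
      x$report$counts$analyzed, "analyzed\n")
  cat("  positive calls:", x$report$counts$called_positive,
      "| antigen-specific:", x$report$counts$gpi_specific, "\n")
  print(x$summary)
  invisible(x)
}
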