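# Rendering of two-channel 16-bit time-lapse image stacks from an emulsion
# plus forward-model relocation traces, and TIFF/TSV round-trip I/O.

#' Render a two-channel image stack from an emulsion
#'
#' Each droplet is rendered as a disk of background fluorescence proportional
#' to the free fluorophore concentration in that channel (fluorophore is
#' conserved inside the closed droplet, so the background dims as label
#' relocates to the beadline), with a central horizontal beadline bar
#' (3 px tall, 0.6 droplet diameters wide; all beadlines share the magnetic
#' field axis) whose mean intensity is background times the relocation
#' R_c(t). Cells appear as small dark disks away from the beadline. Optional
#' imperfections from the [noise_model()]: shot and read noise, jittered
#' droplet centers, bright artifact specks. Pixel depth is 16 bits; values
#' that would overflow are clipped with a warning.
#'
#' @param emulsion an [sample_emulsion()] result.
#' @param chem an [assay_chemistry()].
#' @param sched an [acquisition_schedule()].
#' @param noise a [noise_model()].
#' @param base_intensity background intensity (counts) of a droplet with all
#'   fluorophore free.
#' @param traces optional list of [forward_kinetics()] traces indexed by
#'   droplet id (character); computed from the emulsion ground truth when
#'   omitted.
#' @param seed optional seed for the rendering randomness (noise, cell
#'   placement, jitter); defaults to the emulsion seed + 1.
#' @return an object of class `dropmap_stack`: list with `red` and `green`
#'   (lists of HxW integer matrices, one per frame), `times_min`, and a
#'   `truth` data.frame (droplet geometry, cell counts, ground-truth rate
#'   and K_D, and the rendered `moved`/`artifact` flags).
#' @export
render_stack <- function(emulsion, chem = assay_chemistry(),
                         sched = acquisition_schedule(),
                         noise = noise_model(),
                         base_intensity = 2000, traces = NULL, seed = NULL) {
  stopifnot(inherits(emulsion, "emulsion"), inherits(chem, "assay_chemistry"),
            inherits(sched, "acquisition_schedule"),
            inherits(noise, "noise_model"), base_intensity > 0)
  if (is.null(seed) && !is.null(emulsion$config$seed)) {
    seed <- emulsion$config$seed + 1L
  }
  with_seed(seed, {
    d <- emulsion$droplets
    H <- emulsion$chamber[1]; W <- emulsion$chamber[2]
    nf <- sched$n_frames
    r <- d$radius_px[1]
    volume <- emulsion$config$droplet_volume

    # per-droplet relocation traces (flat trace for non-secretors)
    if (is.null(traces)) {
      traces <- lapply(seq_len(nrow(d)), function(i) {
        if (d$secretion_rate[i] > 0) {
          forward_kinetics(d$secretion_rate[i], d$kd[i], chem, sched, volume)
        } else NULL
        })
    } else {
      traces <- traces[as.character(d$droplet_id)]
    }
    flat <- list(r_red = rep(1, nf), r_green = rep(1, nf),
                 free_frac_red = rep(1, nf), free_frac_green = rep(1, nf))

    # disk / beadline pixel offsets shared by all droplets
    off <- expand.grid(dy = -r:r, dx = -r:r)
    off <- off[off$dy^2 + off$dx^2 <= r^2, ]
    half_w <- max(2L, as.integer(round(0.6 * r)))
    bar <- abs(off$dy) <= 1 & abs(off$dx) <= half_w

    # fixed cell positions per droplet (off-beadline, inside the disk)
    cell_off <- off[abs(off$dy) > 4 & (off$dy^2 + off$dx^2) <= (r - 3)^2, ]
    cells_of <- split(seq_len(nrow(emulsion$cells)),
                      factor(emulsion$cells$droplet_id, levels = d$droplet_id))
    cell_pos <- lapply(cells_of, function(ix) {
      k <- length(ix)
      if (k == 0) return(NULL)
      # greedy placement with >= 5 px separation so cell bodies stay
      # resolvable as distinct dark disks
      cand <- cell_off[sample.int(nrow(cell_off)), , drop = FALSE]
      chosen <- cand[1, , drop = FALSE]
      for (j in seq_len(nrow(cand))[-1]) {
        if (nrow(chosen) >= k) break
        d2 <- (chosen$dy - cand$dy[j])^2 + (chosen$dx - cand$dx[j])^2
        if (all(d2 >= 25)) chosen <- rbind(chosen, cand[j, ])
      }
      chosen
    })
    cell_r2 <- 2^2

    moved <- runif(nrow(d)) < noise$movement_fraction
    artifact <- runif(nrow(d)) < noise$artifact_fraction
    art_off <- cell_off[sample.int(nrow(cell_off), nrow(d), replace = TRUE), ]

    channels <- list(red = vector("list", nf), green = vector("list", nf))
    overflow <- FALSE
    for (k in seq_len(nf)) {
      for (ch in c("red", "green")) {
        img <- matrix(0, H, W)
        rcol <- if (ch == "red") "r_red" else "r_green"
        fcol <- if (ch == "red") "free_frac_red" else "free_frac_green"
        for (i in seq_len(nrow(d))) {
          tr <- traces[[i]]; if (is.null(tr)) tr <- flat
          bg <- base_intensity * tr[[fcol]][k]
          val <- rep(bg, nrow(off))
          val[bar] <- bg * tr[[rcol]][k]
          # dark cell bodies
          cp <- cell_pos[[i]]
          if (!is.null(cp)) {
            for (j in seq_len(nrow(cp))) {
              in_cell <- (off$dy - cp$dy[j])^2 + (off$dx - cp$dx[j])^2 <= cell_r2
              val[in_cell] <- val[in_cell] * 0.2
            }
          }
          # transient bright speck in frame 3
          if (artifact[i] && k == 3L) {
            in_art <- (off$dy - art_off$dy[i])^2 +
              (off$dx - art_off$dx[i])^2 <= 1
            val[in_art] <- 3 * base_intensity
          }
          cx <- d$cx[i] + if (moved[i] && k %% 2L == 0L) 3L else 0L
          img[cbind(d$cy[i] + off$dy, cx + off$dx)] <- val
        }
        if (noise$shot_noise) {
          img[] <- rpois(length(img), img)
        }
        if (noise$read_noise_sd > 0) {
          img <- img + rnorm(length(img), 0, noise$read_noise_sd)
        }
        if (any(img > 65535)) overflow <- TRUE
        img <- round(pmin(pmax(img, 0), 65535))
        storage.mode(img) <- "integer"
        channels[[ch]][[k]] <- img
      }
    }
    if (overflow) warning("rendered intensities exceeded 16-bit range; clipped")

    truth <- d
    truth$moved <- moved
    truth$artifact <- artifact
    structure(list(red = channels$red, green = channels$green,
                   times_min = sched$times_min, truth = truth,
                   chamber = emulsion$chamber,
                   base_intensity = base_intensity),
              class = "dropmap_stack")
  })
}

#' @export
print.dropmap_stack <- function(x, ...) {
  cat("dropmap_stack:", length(x$red), "frames x 2 channels,",
      x$chamber[1], "x", x$chamber[2], "px,",
      nrow(x$truth), "droplets\n")
  invisible(x)
}

#' Write a rendered stack to disk
#'
#' One multi-page 16-bit grayscale TIFF per channel (frame order = time),
#' the ground-truth table as TSV, and the acquisition times as JSON.
#'
#' @param stack a [render_stack()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "dropmap_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(red = file.path(dir, "red.tif"),
             green = file.path(dir, "green.tif"),
             truth = file.path(dir, "truth.tsv"),
             meta = file.path(dir, "meta.json"))
  for (ch in c("red", "green")) {
    tiff::writeTIFF(lapply(stack[[ch]], function(m) m / 65535),
                    paths[[ch]], bits.per.sample = 16, compression = "none")
  }
  write.table(stack$truth, paths[["truth"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(times_min = stack$times_min,
                            chamber = stack$chamber,
                            base_intensity = stack$base_intensity),
                       paths[["meta"]], auto_unbox = FALSE, digits = NA)
  invisible(paths)
}

#' Read a stack written by [write_stack()]
#'
#' @param dir directory containing `red.tif`, `green.tif`, `meta.json` and
#'   optionally `truth.tsv`.
#' @return a `dropmap_stack` (with `truth = NULL` if absent on disk).
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  read_ch <- function(path) {
    if (!file.exists(path)) stop("missing stack file: ", path)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) stop("corrupted TIFF '", path,
                                               "': ", conditionMessage(e)))
    lapply(seq_along(pages), function(k) {
      m <- pages[[k]]
      if (length(dim(m)) != 2) {
        stop("corrupted TIFF '", path, "': frame ", k, " is not grayscale")
      }
      m <- round(m * 65535)
      storage.mode(m) <- "integer"
      m
    })
  }
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    read.table(truth_path, header = TRUE, sep = "\t")
  } else NULL
  structure(list(red = read_ch(file.path(dir, "red.tif")),
                 green = read_ch(file.path(dir, "green.tif")),
                 times_min = meta$times_min, truth = truth,
                 chamber = meta$chamber,
                 base_intensity = meta$base_intensity),
            class = "dropmap_stack")
}
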