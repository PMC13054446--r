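# Droplet and beadline segmentation, per-frame intensity extraction, and
# droplet-level quality control.

# centroid/area table from a labelled matrix
.region_centroids <- function(lab) {
  w <- which(lab > 0)
  if (length(w) == 0) {
    return(data.frame(label = integer(0), area = numeric(0),
                      cy = numeric(0), cx = numeric(0)))
  }
  H <- nrow(lab)
  v <- as.integer(lab[w])
  rows <- (w - 1L) %% H + 1L
  cols <- (w - 1L) %/% H + 1L
  agg <- rowsum(cbind(n = 1, r = rows, c = cols), v)
  data.frame(label = as.integer(rownames(agg)), area = agg[, "n"],
             cy = agg[, "r"] / agg[, "n"], cx = agg[, "c"] / agg[, "n"])
}

.edge_labels <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  b <- c(lab[1, ], lab[H, ], lab[, 1], lab[, W])
  unique(b[b > 0])
}

#' Segment droplets in one grayscale frame
#'
#' Thresholding plus connected-component labelling: droplets are bright
#' disks on a dark (oil) background, so a fixed fraction of the upper
#' intensity quantile separates them cleanly in monodisperse emulsions.
#' Regions are returned with area, equivalent radius, circularity
#' (4 pi A / P^2, capped at 1), and an `edge` flag for regions touching the
#' image border (excluded downstream).
#'
#' @param frame 2D numeric/integer matrix.
#' @param threshold intensity threshold; default 0.2 x the 99.9th intensity
#'   percentile of the frame.
#' @param min_radius minimum equivalent radius (px) for a region to be kept.
#' @return data.frame with one row per detected region: `label`, `cx`, `cy`,
#'   `radius`, `area`, `circularity`, `edge`. Zero rows (with a warning) if
#'   nothing is found.
#' @export
segment_droplets <- function(frame, threshold = NULL, min_radius = 4) {
  stopifnot(is.matrix(frame))
  if (is.null(threshold)) {
    threshold <- 0.2 * as.numeric(quantile(frame, 0.999))
  }
  mask <- frame > threshold
  if (!any(mask)) {
    warning("no droplets found in frame")
    return(data.frame(label = integer(0), cx = numeric(0), cy = numeric(0),
                      radius = numeric(0), area = numeric(0),
                      circularity = numeric(0), edge = logical(0)))
  }
  lab <- EBImage::bwlabel(mask)
  cen <- .region_centroids(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  per <- shp[cen$label, "s.perimeter"]
  out <- data.frame(label = cen$label, cx = cen$cx, cy = cen$cy,
                    radius = sqrt(cen$area / pi), area = cen$area,
                    circularity = pmin(1, 4 * pi * cen$area / pmax(per, 1)^2),
                    edge = cen$label %in% .edge_labels(lab))
  out <- out[out$radius >= min_radius, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the beadline inside a segmented droplet
#'
#' The beadline is an elongated horizontal bar (the magnetic field axis is
#' horizontal and known from the chamber geometry) through the droplet
#' center. A 3-row window is slid over the central rows of the droplet and
#' the window with the highest mean intensity is chosen when its contrast
#' against the droplet median exceeds 5%; otherwise (pre-secretion frames,
#' no contrast) the geometric center bar is returned. The bar is 3 px tall
#' and 0.6 droplet diameters wide, aspect ratio >= 3 for any droplet of
#' radius >= 8 px.
#'
#' @param frame 2D image matrix.
#' @param cx,cy droplet center (px).
#' @param radius droplet radius (px).
#' @param search half-range of center rows searched (px).
#' @return list with `rows`, `cols` (pixel index vectors of the bar) and
#'   `center_row`.
#' @export
locate_beadline <- function(frame, cx, cy, radius, search = 3) {
  cx <- round(cx); cy <- round(cy); r <- floor(radius)
  half_w <- max(2L, as.integer(round(0.6 * r)))
  cols <- (cx - half_w):(cx + half_w)
  cols <- cols[cols >= 1 & cols <= ncol(frame)]
  disk_rows <- (cy - r):(cy + r)
  disk_rows <- disk_rows[disk_rows >= 1 & disk_rows <= nrow(frame)]
  med <- median(frame[disk_rows, cols])
  best_dy <- 0L; best_mean <- -Inf
  for (dy in -search:search) {
    rr <- (cy + dy - 1L):(cy + dy + 1L)
    if (min(rr) < 1 || max(rr) > nrow(frame)) next
    m <- mean(frame[rr, cols])
    if (m > best_mean) { best_mean <- m; best_dy <- dy }
  }
  center_row <- if (med > 0 && best_mean / med > 1.05) cy + best_dy else cy
  list(rows = (center_row - 1L):(center_row + 1L), cols = cols,
       center_row = center_row)
}

#' Extract per-droplet, per-frame beadline and background intensities
#'
#' Runs the full imaging front-end on a rendered (or read-from-disk) stack:
#' segments droplets on the first red frame, re-segments every frame to
#' detect droplet movement, locates each droplet's beadline per frame,
#' counts cells (dark disks in the red channel), detects bright artifact
#' specks, and extracts beadline and background mean intensities in both
#' channels. The background of a droplet is its disk minus the beadline
#' mask and minus detected cell pixels.
#'
#' QC flags per droplet: `EDGE` (touches image border), `MOVED` (center
#' displacement > `movement_tol` px between consecutive frames),
#' `MULTI_CELL` (more than two cells detected), `ARTIFACT` (bright speck
#' outside the beadline), `BG_NONPOS` (non-positive background mean).
#' Droplets failing circularity (< `circularity_min`) are dropped outright.
#'
#' @param stack a `dropmap_stack`.
#' @param circularity_min minimum circularity of a kept region.
#' @param movement_tol movement tolerance in px (default 2: the assay
#'   requires "no droplet movement", operationalised as <= 2 px).
#' @param min_radius minimum droplet radius in px.
#' @return an object of class `droplet_observations`: list with `droplets`
#'   (per-droplet geometry, cell count and QC flags), `intensities` (long
#'   data.frame: droplet_id, frame, time_min, channel, beadline_mean,
#'   background_mean) and `counts` (segmentation/exclusion tallies).
#' @export
extract_observations <- function(stack, circularity_min = 0.8,
                                 movement_tol = 2, min_radius = 4) {
  stopifnot(inherits(stack, "dropmap_stack"))
  nf <- length(stack$red)
  ref <- segment_droplets(stack$red[[1]], min_radius = min_radius)
  n_segmented <- nrow(ref)
  ref <- ref[ref$circularity >= circularity_min, , drop = FALSE]
  n_low_circ <- n_segmented - nrow(ref)
  if (nrow(ref) == 0) {
    warning("no droplets pass circularity filter")
  }
  H <- nrow(stack$red[[1]]); W <- ncol(stack$red[[1]])

  # movement: match each reference droplet to its nearest centroid per frame
  disp_max <- rep(0, nrow(ref))
  if (nrow(ref) > 0 && nf > 1) {
    prev_cx <- ref$cx; prev_cy <- ref$cy
    for (k in 2:nf) {
      lab <- EBImage::bwlabel(stack$red[[k]] >
                                0.2 * as.numeric(quantile(stack$red[[k]], 0.999)))
      cen <- .region_centroids(lab)
      cen <- cen[cen$area >= pi * min_radius^2, , drop = FALSE]
      cur_cx <- prev_cx; cur_cy <- prev_cy
      if (nrow(cen) > 0) {
        for (i in seq_len(nrow(ref))) {
          d2 <- (cen$cx - prev_cx[i])^2 + (cen$cy - prev_cy[i])^2
          j <- which.min(d2)
          # reject merged blobs (area far from one droplet's area)
          if (d2[j] <= (2 * ref$radius[i])^2 &&
              cen$area[j] <= 1.5 * ref$area[i]) {
            cur_cx[i] <- cen$cx[j]; cur_cy[i] <- cen$cy[j]
          }
        }
      }
      disp <- sqrt((cur_cx - prev_cx)^2 + (cur_cy - prev_cy)^2)
      disp_max <- pmax(disp_max, disp)
      prev_cx <- cur_cx; prev_cy <- cur_cy
    }
  }

  n <- nrow(ref)
  n_cells <- integer(n)
  artifact <- logical(n)
  bg_nonpos <- logical(n)
  rows_out <- vector("list", n)

  for (i in seq_len(n)) {
    cx <- round(ref$cx[i]); cy <- round(ref$cy[i])
    r <- floor(ref$radius[i])
    rr <- max(1, cy - r):min(H, cy + r)
    cc <- max(1, cx - r):min(W, cx + r)
    dy <- rr - cy; dx <- cc - cx
    disk <- outer(dy^2, dx^2, "+") <= r^2

    # cell bodies: dark components off the beadline rows, frame 1 red
    sub1 <- stack$red[[1]][rr, cc]
    off_bar <- disk & (abs(dy) > 2)
    med1 <- median(sub1[off_bar])
    dark <- off_bar & (sub1 < 0.5 * med1)
    if (any(dark)) {
      dl <- EBImage::bwlabel(dark)
      areas <- tabulate(dl[dl > 0])
      n_cells[i] <- sum(areas >= 3)
    }

    per_frame <- vector("list", nf)
    for (k in seq_len(nf)) {
      bead <- locate_beadline(stack$red[[k]], ref$cx[i], ref$cy[i],
                              ref$radius[i])
      mask_from <- function(rows, cols) {
        m <- matrix(FALSE, length(rr), length(cc))
        lr <- match(rows, rr); lc <- match(cols, cc)
        m[lr[!is.na(lr)], lc[!is.na(lc)]] <- TRUE
        m & disk
      }
      # measurement mask: shrink columns by 1 px so a sub-pixel centroid
      # error cannot pull background pixels into the beadline mean
      bead_mask <- mask_from(bead$rows,
                             bead$cols[-c(1, length(bead$cols))])
      # exclusion mask: beadline dilated by 1 row / 2 cols, so the bar
      # never leaks into the background or the artifact detector
      bead_excl <- mask_from((min(bead$rows) - 1L):(max(bead$rows) + 1L),
                             (min(bead$cols) - 2L):(max(bead$cols) + 2L))
      bg_mask <- disk & !bead_excl & !dark

      vals <- numeric(0)
      for (ch in c("red", "green")) {
        sub <- stack[[ch]][[k]][rr, cc]
        bm <- mean(sub[bead_mask])
        gm <- mean(sub[bg_mask])
        vals <- c(vals, bm, gm)
        if (ch == "red") {
          # bright speck well above background, off the beadline
          if (gm > 0 && any(sub[bg_mask] > 2 * gm + 6 * sqrt(max(gm, 1)))) {
            artifact[i] <- TRUE
          }
        }
        if (!is.finite(gm) || gm <= 0) bg_nonpos[i] <- TRUE
      }
      per_frame[[k]] <- vals
    }
    pf <- do.call(rbind, per_frame)
    rows_out[[i]] <- data.frame(
      droplet_id = i, frame = rep(seq_len(nf), 2),
      time_min = rep(stack$times_min, 2),
      channel = rep(c("red", "green"), each = nf),
      beadline_mean = c(pf[, 1], pf[, 3]),
      background_mean = c(pf[, 2], pf[, 4]))
  }

  droplets <- data.frame(
    droplet_id = seq_len(n), cx = ref$cx, cy = ref$cy, radius = ref$radius,
    circularity = ref$circularity, n_cells_detected = n_cells,
    edge = ref$edge, moved = disp_max > movement_tol,
    multi_cell = n_cells > 2, artifact = artifact, bg_nonpos = bg_nonpos)
  droplets$qc_pass <- !(droplets$edge | droplets$moved | droplets$multi_cell |
                          droplets$artifact | droplets$bg_nonpos)
  flag_mat <- cbind(EDGE = droplets$edge, MOVED = droplets$moved,
                    MULTI_CELL = droplets$multi_cell,
                    ARTIFACT = droplets$artifact,
                    BG_NONPOS = droplets$bg_nonpos)
  droplets$flags <- vapply(seq_len(n), function(i) {
    paste(colnames(flag_mat)[flag_mat[i, ]], collapse = ",")
  }, character(1))

  counts <- list(
    segmented = n_segmented, low_circularity = n_low_circ,
    edge = sum(droplets$edge), moved = sum(droplets$moved),
    multi_cell = sum(droplets$multi_cell),
    artifact = sum(droplets$artifact), bg_nonpos = sum(droplets$bg_nonpos),
    zero_cell = sum(droplets$n_cells_detected == 0),
    analyzed = sum(droplets$qc_pass & droplets$n_cells_detected %in% 1:2))

  structure(list(droplets = droplets,
                 intensities = do.call(rbind, rows_out),
                 counts = counts),
            class = "droplet_observations")
}

#' @export
print.droplet_observations <- function(x, ...) {
  cat("droplet_observations:", nrow(x$droplets), "droplets,",
      x$counts$analyzed, "analyzable (1-2 cells, QC pass)\n")
  cat("  excluded: edge", x$counts$edge, "| moved", x$counts$moved,
      "| multi-cell", x$counts$multi_cell, "| artifact", x$counts$artifact,
      "| zero-cell", x$counts$zero_cell, "\n")
  invisible(x)
}

#' Compute relocation traces from extracted intensities
#'
#' Relocation in each channel and frame is the beadline mean intensity
#' divided by the background mean intensity of the same droplet. Droplets
#' with a non-positive background in any frame are dropped (they carry the
#' `BG_NONPOS` flag in the observations).
#'
#' @param obs a [extract_observations()] result.
#' @return data.frame: droplet_id, frame, time_min, r_red, r_green.
#' @export
compute_relocation <- function(obs) {
  stopifnot(inherits(obs, "droplet_observations"))
  int <- obs$intensities
  bad <- obs$droplets$droplet_id[obs$droplets$bg_nonpos]
  int <- int[!(int$droplet_id %in% bad), , drop = FALSE]
  if (nrow(int) == 0) {
    return(data.frame(droplet_id = integer(0), frame = integer(0),
                      time_min = numeric(0), r_red = numeric(0),
                      r_green = numeric(0)))
  }
  int$r <- int$beadline_mean / int$background_mean
  red <- int[int$channel == "red", c("droplet_id", "frame", "time_min", "r")]
  green <- int[int$channel == "green", c("droplet_id", "frame", "r")]
  out <- merge(red, green, by = c("droplet_id", "frame"),
               suffixes = c("_red", "_green"))
  names(out)[names(out) == "r_red"] <- "r_red"
  out <- out[order(out$droplet_id, out$frame), ]
  rownames(out) <- NULL
  names(out) <- c("droplet_id", "frame", "time_min", "r_red", "r_green")
  out
}

#' Match observed droplets to generator ground truth
#'
#' Nearest-center matching (within one droplet radius) between segmented
#' droplets and the ground-truth table of a rendered stack; used to evaluate
#' recovery on synthetic data.
#'
#' @param obs a [extract_observations()] result.
#' @param truth the `truth` data.frame of a [render_stack()] result.
#' @return `obs$droplets` with appended `true_*` ground-truth columns (NA
#'   where unmatched).
#' @export
match_truth <- function(obs, truth) {
  d <- obs$droplets
  idx <- vapply(seq_len(nrow(d)), function(i) {
    d2 <- (truth$cx - d$cx[i])^2 + (truth$cy - d$cy[i])^2
    j <- which.min(d2)
    if (d2[j] <= d$radius[i]^2) j else NA_integer_
  }, integer(1))
  d$true_droplet_id <- truth$droplet_id[idx]
  d$true_n_cells <- truth$n_cells[idx]
  d$true_secretion_rate <- truth$secretion_rate[idx]
  d$true_kd <- truth$kd[idx]
  d$true_moved <- truth$moved[idx]
  d$true_artifact <- truth$artifact[idx]
  d
}
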