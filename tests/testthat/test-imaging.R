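# Droplet segmentation, beadline location, relocation extraction, and QC.

test_that("segmentation recovers non-overlapping disks exactly", {
  grid <- expand.grid(cx = seq(25, 225, by = 40), cy = seq(25, 225, by = 40))
  pick <- grid[1:36, ]
  img <- draw_disks(250, 250, pick$cx, pick$cy, r = 10)
  seg <- segment_droplets(img)
  expect_equal(nrow(seg), 36)
  # centers within 1 px of truth
  for (i in seq_len(nrow(pick))) {
    d <- sqrt((seg$cx - pick$cx[i])^2 + (seg$cy - pick$cy[i])^2)
    expect_lt(min(d), 1)
  }
  expect_true(all(seg$circularity >= 0.8))
  expect_false(any(seg$edge))
})

test_that("blank frames yield an empty segmentation with a warning", {
  expect_warning(seg <- segment_droplets(matrix(0, 50, 50)), "no droplets")
  expect_equal(nrow(seg), 0)
})

test_that("border-touching droplets are flagged EDGE", {
  img <- draw_disks(100, 100, cx = c(5, 50), cy = c(50, 50), r = 10)
  seg <- segment_droplets(img)
  expect_equal(sum(seg$edge), 1)
  expect_equal(seg$edge[which.min(abs(seg$cx - 5))], TRUE)
})

test_that("beadline localisation hits the rendered bar", {
  emu <- sample_emulsion(emulsion_config(4, seed = 6),
                         cohort = cohort_model(
                           secretor_fraction = 1,
                           rate_sampler = function(n) rep(50, n),
                           kd_sampler = function(n) rep(30e-9, n)),
                         occupancy = "single")
  st <- render_stack(emu, noise = noise_model())
  d <- emu$droplets[1, ]
  bl <- locate_beadline(st$red[[6]], d$cx, d$cy, d$radius_px)

  # IoU against the true rendered bar (3 rows x 0.6 diameter at center)
  half_w <- round(0.6 * d$radius_px)
  truth <- expand.grid(row = (d$cy - 1):(d$cy + 1),
                       col = (d$cx - half_w):(d$cx + half_w))
  got <- expand.grid(row = bl$rows, col = bl$cols)
  key <- function(x) paste(x$row, x$col)
  inter <- length(intersect(key(truth), key(got)))
  union <- length(union(key(truth), key(got)))
  expect_gte(inter / union, 0.7)
})

test_that("contrast-free droplets fall back to the geometric center bar", {
  img <- draw_disks(60, 60, cx = 30, cy = 30, r = 13)
  bl <- locate_beadline(img, 30, 30, 13)
  expect_equal(bl$center_row, 30)
  expect_equal(length(bl$rows), 3)
  # elongated: aspect ratio >= 3
  expect_gte(length(bl$cols) / length(bl$rows), 3)
})

test_that("bright off-center specks set ARTIFACT but not the beadline", {
  emu <- sample_emulsion(emulsion_config(4, mean_occupancy = 0, seed = 8))
  st <- render_stack(emu, noise = noise_model())
  d <- emu$droplets[1, ]
  # paint a bright speck away from the beadline rows
  for (k in seq_along(st$red)) {
    st$red[[k]][d$cy + 7, d$cx + c(-1, 0, 1)] <- 30000L
  }
  obs <- extract_observations(st)
  i <- which.min((obs$droplets$cx - d$cx)^2 + (obs$droplets$cy - d$cy)^2)
  expect_true(obs$droplets$artifact[i])
  bl <- locate_beadline(st$red[[1]], d$cx, d$cy, d$radius_px)
  expect_lte(abs(bl$center_row - d$cy), 3)
})

test_that("relocation is beadline over background and flags bad background", {
  obs1 <- make_obs(beadline = rep(1500, 6), background = rep(1500, 6))
  tr1 <- compute_relocation(obs1)
  expect_equal(tr1$r_red, rep(1, 6))

  obs2 <- make_obs(beadline = rep(3000, 6), background = rep(1500, 6))
  expect_equal(compute_relocation(obs2)$r_red, rep(2, 6))

  obs3 <- make_obs(beadline = rep(1500, 6), background = rep(0, 6))
  expect_true(obs3$droplets$bg_nonpos)
  expect_equal(nrow(compute_relocation(obs3)), 0)
})

test_that("relocation is invariant to a global intensity rescale", {
  emu <- sample_emulsion(emulsion_config(4, seed = 10),
                         cohort = cohort_model(
                           secretor_fraction = 1,
                           rate_sampler = function(n) rep(40, n),
                           kd_sampler = function(n) rep(50e-9, n)),
                         occupancy = "single")
  st <- render_stack(emu, noise = noise_model(), base_intensity = 800)
  tr <- compute_relocation(extract_observations(st))
  for (const in c(3, 17.5)) {
    st2 <- st
    for (ch in c("red", "green")) {
      st2[[ch]] <- lapply(st[[ch]], function(m) {
        m2 <- round(m * const); storage.mode(m2) <- "integer"; m2
      })
    }
    tr2 <- compute_relocation(extract_observations(st2))
    expect_equal(tr2$r_red, tr$r_red, tolerance = 0.005)
    expect_equal(tr2$r_green, tr$r_green, tolerance = 0.005)
  }
})

test_that("noiseless recall and precision are perfect and counts reconcile", {
  cfg <- dropmap_config(n_droplets = 150, seed = 31,
                        noise = noise_model(movement_fraction = 0.05,
                                            artifact_fraction = 0.05))
  emu <- sample_emulsion(cfg$emulsion, cohort = cfg$cohort)
  st <- render_stack(emu, noise = cfg$noise)
  obs <- extract_observations(st)

  # recall & precision vs ground truth positions (radius >= 8 px disks)
  m <- match_truth(obs, st$truth)
  expect_equal(nrow(obs$droplets), nrow(st$truth))
  expect_false(any(is.na(m$true_droplet_id)))

  # flagged movement/artifacts match construction
  expect_equal(m$moved, m$true_moved)
  expect_true(all(m$artifact[m$true_artifact]))

  # exclusion accounting: analyzed = QC-pass droplets with 1-2 cells
  d <- obs$droplets
  expect_equal(obs$counts$analyzed,
               sum(d$qc_pass & d$n_cells_detected %in% 1:2))
  expect_equal(obs$counts$segmented,
               nrow(d) + obs$counts$low_circularity)
})

test_that("cell counting flags multi-cell droplets for exclusion", {
  found <- FALSE
  for (seed in 31:40) {
    emu <- sample_emulsion(emulsion_config(100, mean_occupancy = 1.2,
                                           seed = seed))
    if (any(emu$droplets$n_cells > 2)) { found <- TRUE; break }
  }
  expect_true(found)
  st <- render_stack(emu, noise = noise_model())
  obs <- extract_observations(st)
  m <- match_truth(obs, st$truth)
  expect_equal(m$n_cells_detected, m$true_n_cells)
  expect_true(all(m$multi_cell[m$true_n_cells > 2]))
  expect_true(all(m$qc_pass[m$true_n_cells == 1 & !m$true_moved &
                              !m$true_artifact & !m$edge]))
})
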