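# Independent oracles and small fixture builders shared across tests.

# brute-force equilibrium complex concentration by bisection on
# (B - x)(L - x) - kd * x = 0 over x in [0, min(B, L)]
solve_bound_bisect <- function(b_total, l_total, kd, tol = 1e-15) {
  f <- function(x) (b_total - x) * (l_total - x) - kd * x
  lo <- 0
  hi <- min(b_total, l_total)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if ((hi - lo) <= tol * max(hi, 1e-300)) break
  }
  (lo + hi) / 2
}

# a noiseless rendered mini-cohort with one cell per droplet and explicit
# ground-truth samplers; returns the full run object
run_noiseless_cohort <- function(n, rate_sampler, kd_sampler, seed) {
  run_dropmap(dropmap_config(
    n_droplets = n, seed = seed, occupancy = "single",
    noise = noise_model(),
    cohort = cohort_model(secretor_fraction = 1,
                          rate_sampler = rate_sampler,
                          kd_sampler = kd_sampler)))
}

# draw a frame of ideal disks directly (no emulsion machinery): returns a
# matrix with disks of constant intensity `value` at given centers
draw_disks <- function(H, W, cx, cy, r, value = 2000) {
  img <- matrix(0, H, W)
  for (i in seq_along(cx)) {
    for (dy in -r:r) {
      row <- cy[i] + dy
      if (row < 1 || row > H) next
      half <- floor(sqrt(r^2 - dy^2))
      cols <- max(1, cx[i] - half):min(W, cx[i] + half)
      img[row, cols] <- value
    }
  }
  img
}

# minimal droplet_observations object from explicit per-frame intensities
make_obs <- function(beadline, background, times_min = (0:5) * 7.5) {
  nf <- length(times_min)
  structure(list(
    droplets = data.frame(droplet_id = 1L, cx = 20, cy = 20, radius = 13,
                          circularity = 1, n_cells_detected = 1L,
                          edge = FALSE, moved = FALSE, multi_cell = FALSE,
                          artifact = FALSE, bg_nonpos = any(background <= 0),
                          qc_pass = all(background > 0), flags = ""),
    intensities = data.frame(
      droplet_id = 1L, frame = rep(seq_len(nf), 2),
      time_min = rep(times_min, 2),
      channel = rep(c("red", "green"), each = nf),
      beadline_mean = rep(beadline, 2),
      background_mean = rep(background, 2)),
    counts = list()), class = "droplet_observations")
}
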