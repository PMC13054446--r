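# Synthetic emulsion sampling, forward binding kinetics, and rendering.

test_that("droplet volume default follows from cell density and occupancy", {
  # 0.3 cells/droplet at 30e6 cells/mL implies 10 pL droplets
  expect_equal(0.3 / (30e6 * 1000), 1e-11)
  expect_equal(emulsion_config()$droplet_volume, 1e-11)
  # spherical 10 pL droplet has a ~13.4 um radius
  expect_equal(emulsion_config()$droplet_radius_um, 13.37, tolerance = 1e-3)
})

test_that("emulsion occupancy follows Poisson statistics", {
  cfg <- emulsion_config(n_droplets = 1e5, mean_occupancy = 0.3, seed = 42)
  emu <- sample_emulsion(cfg)
  counts <- emu$droplets$n_cells

  # chi-square against Poisson(0.3) pooling the tail
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
           sum(counts >= 3))
  p <- c(dpois(0:2, 0.3), 1 - ppois(2, 0.3))
  chi <- sum((obs - 1e5 * p)^2 / (1e5 * p))
  expect_lt(chi, qchisq(0.99, df = 3))

  # closed-form expected droplets with exactly 1-2 cells at n = 80,000
  expected_12 <- 80000 * (0.3 * exp(-0.3) + 0.3^2 / 2 * exp(-0.3))
  expect_equal(expected_12, 20446, tolerance = 1e-4)
  n12 <- sum(counts %in% 1:2) * 80000 / 1e5
  sd12 <- sqrt(80000 * 0.2556 * (1 - 0.2556))
  expect_lt(abs(n12 - expected_12), 4 * sd12)
})

test_that("zero occupancy yields an empty emulsion and sampling is seeded", {
  emu0 <- sample_emulsion(emulsion_config(100, mean_occupancy = 0, seed = 1))
  expect_true(all(emu0$droplets$n_cells == 0))
  expect_equal(nrow(emu0$cells), 0)

  a <- sample_emulsion(emulsion_config(500, seed = 9))
  b <- sample_emulsion(emulsion_config(500, seed = 9))
  expect_identical(a$droplets, b$droplets)
  expect_identical(a$cells, b$cells)
})

test_that("an undersized chamber is refused explicitly", {
  cfg <- emulsion_config(n_droplets = 1000, chamber_size = c(100, 100))
  expect_error(sample_emulsion(cfg), "too small")
})

test_that("equilibrium occupancy matches the Langmuir isotherm limits", {
  # negligible-depletion occupancy theta = L / (kd + L) at L = 30 nM
  tiny <- 1e-15
  theta <- function(kd) bound_1to1(tiny, 30e-9, kd) / tiny
  expect_equal(theta(30e-9), 0.5, tolerance = 1e-6)
  expect_equal(theta(100e-9), 30 / 130, tolerance = 1e-6)
  expect_equal(theta(2.3e-9), 30 / 32.3, tolerance = 1e-6)
})

test_that("conservation quadratic agrees with bisection oracle", {
  set.seed(101)
  for (i in 1:1000) {
    b <- 10^runif(1, -12, -6)
    l <- 10^runif(1, -12, -6)
    kd <- 10^runif(1, -12, -6)
    x_closed <- bound_1to1(b, l, kd)
    x_brute <- solve_bound_bisect(b, l, kd)
    expect_equal(x_closed, x_brute, tolerance = 1e-9)
  }
})

test_that("relocation traces start at 1, are monotone, and rank by kd", {
  chem <- assay_chemistry(); sched <- acquisition_schedule()
  expect_equal(sched$total_time,
               sched$frame_interval * (sched$n_frames - 1))

  tr0 <- forward_kinetics(0, 1e-9, chem, sched)
  expect_true(all(tr0$r_red == 1) && all(tr0$r_green == 1))

  set.seed(7)
  for (i in 1:25) {
    s <- 10^runif(1, log10(4), log10(800))
    kd <- 10^runif(1, -10.5, -7)
    tr <- forward_kinetics(s, kd, chem, sched)
    expect_equal(tr$r_red[1], 1)
    expect_equal(tr$r_green[1], 1)
    expect_true(all(diff(tr$r_red) > 0))
    expect_true(all(diff(tr$r_green) >= 0))
  }

  # green:red bound-fraction ratio decreases with kd at fixed s, t
  kds <- c(0.5, 2, 10, 50, 90) * 1e-9
  ratio <- vapply(kds, function(kd) {
    tr <- forward_kinetics(50, kd, chem, sched)
    (tr$r_green[6] - 1) / (tr$r_red[6] - 1)
  }, numeric(1))
  expect_true(all(diff(ratio) < 0))
})

test_that("rendering is deterministic and ratio-faithful", {
  cfg <- emulsion_config(n_droplets = 9, seed = 5)
  emu <- sample_emulsion(cfg, cohort = cohort_model(
    secretor_fraction = 1,
    rate_sampler = function(n) rep(33, n),
    kd_sampler = function(n) rep(65e-9, n)), occupancy = "single")

  s1 <- render_stack(emu, noise = noise_model())
  s2 <- render_stack(emu, noise = noise_model())
  expect_identical(s1$red, s2$red)
  expect_identical(s1$green, s2$green)

  # noiseless round trip: measured beadline/background ratio matches the
  # forward trace within 1%
  obs <- extract_observations(s1)
  traces <- compute_relocation(obs)
  truth_tr <- forward_kinetics(33, 65e-9, assay_chemistry(),
                               acquisition_schedule())
  for (id in unique(traces$droplet_id)) {
    g <- traces[traces$droplet_id == id, ]
    expect_equal(g$r_red, truth_tr$r_red, tolerance = 0.01)
    expect_equal(g$r_green, truth_tr$r_green, tolerance = 0.01)
  }
})

test_that("non-secreting droplets render with beadline equal to background", {
  emu <- sample_emulsion(emulsion_config(9, mean_occupancy = 0, seed = 3))
  st <- render_stack(emu, noise = noise_model())
  obs <- extract_observations(st)
  traces <- compute_relocation(obs)
  expect_true(all(abs(traces$r_red - 1) < 0.01))
  expect_true(all(abs(traces$r_green - 1) < 0.01))
})

test_that("all-jittered emulsions are fully flagged as moved", {
  emu <- sample_emulsion(emulsion_config(9, seed = 4))
  st <- render_stack(emu, noise = noise_model(movement_fraction = 1))
  obs <- extract_observations(st)
  expect_true(all(obs$droplets$moved))
})
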