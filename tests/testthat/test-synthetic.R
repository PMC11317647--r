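test_that("drift generator plants the requested crossings and is seed-reproducible", {
  ## zero diffusion: ground truth exact by construction
  for (pc in c(0, 3)) {
    sim <- generateDriftTrajectory(n_ions = 5, n_waters = 5, drift = 0,
                                   diffusion = 0, n_frames = 40, seed = 2,
                                   planted_crossings = pc)
    expect_equal(sim$truth$planted_crossings, pc)
    ev <- suppressWarnings(detectPermeationEvents(sim$trajectory, sim$pore))
    expect_equal(sum(ev$direction == 1), pc)
    if (pc) expect_setequal(unique(ev$atom), sim$truth$crosser_atoms)
  }
  ## static system: no crossings at all
  sim0 <- generateDriftTrajectory(n_ions = 4, n_waters = 4, drift = 0,
                                  diffusion = 0, n_frames = 20, seed = 5)
  ev0 <- detectPermeationEvents(sim0$trajectory, sim0$pore)
  expect_equal(nrow(ev0), 0)
  ## same seed, diffusive: identical trajectories and counts
  a <- generateDriftTrajectory(n_frames = 60, seed = 42, diffusion = 5,
                               drift = 25)
  b <- generateDriftTrajectory(n_frames = 60, seed = 42, diffusion = 5,
                               drift = 25)
  expect_identical(a$trajectory@positions, b$trajectory@positions)
  expect_equal(nrow(detectPermeationEvents(a$trajectory, a$pore)),
               nrow(detectPermeationEvents(b$trajectory, b$pore)))
})

test_that("umbrella sampler reproduces closed-form target densities", {
  ## flat PMF, no bias: uniform on the domain (KS at alpha = 0.01 on a
  ## decorrelated subsample)
  wf <- sampleUmbrellaWindows(pmfFlat(c(-5, 5)), centers = 0, k = 0,
                              n_samples = 4000, seed = 31, thin = 10)
  ks <- stats::ks.test(wf[[1]]@samples[seq(1, 4000, 4)], "punif", -5, 5)
  expect_gt(ks$p.value, 0.01)
  expect_gte(min(wf[[1]]@samples), -5)
  expect_lte(max(wf[[1]]@samples), 5)

  ## harmonic PMF + harmonic bias at the same center: Gaussian with
  ## variance kBT / (k0 + k)
  k0 <- 2; kb <- 3
  wh <- sampleUmbrellaWindows(pmfHarmonic(k0 = k0, domain = c(-6, 6)),
                              centers = 0, k = kb, n_samples = 20000,
                              seed = 8, thin = 5)
  v_target <- permConstants$kB * 310 / (k0 + kb)
  v_hat <- var(wh[[1]]@samples)
  ## sample variance of n correlated draws: allow 10% relative slack
  expect_lt(abs(v_hat - v_target) / v_target, 0.10)

  ## channel-scale tabulated double-well: adjacent windows overlap
  dw <- doubleWellWindows(seed = 3, n_samples = 400)
  cs <- vapply(dw$windows, function(w) w@center, 0)
  o <- order(cs)
  for (i in seq_len(length(o) - 1)) {
    a <- dw$windows[[o[i]]]@samples
    b <- dw$windows[[o[i + 1]]]@samples
    expect_gt(min(max(a), max(b)) - max(min(a), min(b)), 0)
  }
  ## biased sample mean sits at the minimum of the biased potential
  ## (flat region window): xi0 = -20, U flat there -> mean ~ -20
  w20 <- dw$windows[[which(cs == -20)]]
  se <- sd(w20@samples) / sqrt(length(w20@samples) / 10)
  expect_lt(abs(mean(w20@samples) + 20), 3 * se + 0.05)
})

test_that("toy pore construction matches its analytic profile contract", {
  toy <- buildToyPore(function(z) rep(3.5, length(z)), atom_radius = 1.5)
  expect_true(all(toy$truth$radius == 3.5))
  ## step profile recorded in ground truth; exact on-axis radius follows
  ## the step except where the narrow rings shadow the wide side
  stepf <- function(z) ifelse(z < 0, 4, 1)
  toys <- buildToyPore(stepf, z_range = c(-6, 6), spacing = 1)
  expect_equal(toys$truth$radius_requested, stepf(toys$truth$z))
  expect_true(all(toys$truth$radius <= toys$truth$radius_requested + 1e-9))
  expect_equal(toys$truth$radius[toys$truth$z >= 0],
               rep(1, sum(toys$truth$z >= 0)))
  ## hourglass minimum at z = 0
  hg <- buildToyPore(function(z) 1 + 0.08 * z^2, z_range = c(-8, 8))
  expect_equal(hg$truth$z[which.min(hg$truth$radius)], 0)
  ## non-positive profile refused
  expect_error(buildToyPore(function(z) z, z_range = c(-5, 5)), "positive")
})

test_that("hydration frames place waters at exact distances, deterministically", {
  d <- c(3, 3, 3, 3, 3)
  fr <- buildHydrationFrame(d, seed = 9)
  ion <- framePositions(fr, 1)[1, ]
  wd <- sqrt(rowSums(sweep(framePositions(fr, 1)[-1, , drop = FALSE], 2,
                           ion)^2))
  expect_equal(wd, d, tolerance = 1e-9)
  ## boundary probe pair
  fb <- buildHydrationFrame(c(4.49, 4.51), seed = 10)
  ionb <- framePositions(fb, 1)[1, ]
  wdb <- sort(sqrt(rowSums(sweep(framePositions(fb, 1)[-1, , drop = FALSE],
                                 2, ionb)^2)))
  expect_equal(wdb, c(4.49, 4.51), tolerance = 1e-9)
  ## seeded rebuilds give the identical distance multiset; waters >= 2 A apart
  for (i in 1:10) {
    fi <- buildHydrationFrame(c(2.5, 3.5, 4.4, 6), seed = 77)
    pi_ <- framePositions(fi, 1)
    expect_equal(sort(sqrt(rowSums(sweep(pi_[-1, ], 2, pi_[1, ])^2))),
                 c(2.5, 3.5, 4.4, 6), tolerance = 1e-9)
    expect_gte(min(dist(pi_[-1, ])), 2)
  }
})
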