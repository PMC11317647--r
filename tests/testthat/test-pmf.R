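test_that("WHAM recovers an analytic harmonic PMF by self-consistent iteration", {
  kA <- permConstants$kJnm2_to_kcalA2
  spec <- pmfHarmonic(k0 = 1, domain = c(-6, 6))
  win <- sampleUmbrellaWindows(spec, centers = seq(-5, 5, 1), k = 1000 * kA,
                               n_samples = 3000, seed = 7)
  prof <- wham(win, bin = 0.2)
  sel <- abs(prof@xi) <= 4
  truth <- 0.5 * prof@xi[sel]^2
  truth <- truth - min(truth)
  w <- prof@W[sel] - min(prof@W[sel])
  expect_lt(sqrt(mean((w - truth)^2)), 0.15)
  expect_equal(min(prof@W), 0)           # minimum-zero convention
  expect_true(prof@meta$residual < 1e-7)
})

test_that("WHAM is invariant to window order and shrugs off a duplicate window", {
  dw <- doubleWellWindows(seed = 4, n_samples = 800)
  p1 <- wham(dw$windows, bin = 0.25)
  p2 <- wham(rev(dw$windows), bin = 0.25)
  expect_equal(p2@W, p1@W, tolerance = 1e-6)
  expect_equal(p2@xi, p1@xi)
  ## duplicating one window leaves the profile essentially unchanged
  ## (it adds the same histogram information twice)
  p3 <- wham(c(dw$windows, dw$windows[30]), bin = 0.25)
  expect_lt(max(abs(p3@W - p1@W)), 0.2)
})

test_that("non-overlapping window chains error with the gap named", {
  spec <- pmfFlat(c(-10, 10))
  win <- sampleUmbrellaWindows(spec, centers = c(-8, 8), k = 10,
                               n_samples = 200, seed = 5)
  expect_warning(expect_error(wham(win, bin = 0.2), "gap between"),
                 "no histogram overlap")
  ## non-convergence reports the residual
  dw <- doubleWellWindows(seed = 4, n_samples = 300)
  expect_error(wham(dw$windows, bin = 0.25, max_iter = 3), "did not converge")
})

test_that("bootstrap errors behave statistically and deterministically", {
  dw <- doubleWellWindows(seed = 6, n_samples = 600)
  ## n_boot = 1: zero SD everywhere
  b1 <- whamBootstrap(dw$windows, n_boot = 1, seed = 3, bin = 0.25)
  expect_true(all(b1@err == 0))
  ## fixed seed: identical error bars
  b2 <- whamBootstrap(dw$windows, n_boot = 12, seed = 3, bin = 0.25)
  b3 <- whamBootstrap(dw$windows, n_boot = 12, seed = 3, bin = 0.25)
  expect_identical(b2@err, b3@err)
  expect_true(any(b2@err > 0))
  ## doubling the samples per window shrinks the median bootstrap SD
  ## (monotone trend over seeds)
  smaller <- larger <- numeric(3)
  for (s in 1:3) {
    lo <- doubleWellWindows(seed = s, n_samples = 300)
    hi <- doubleWellWindows(seed = s, n_samples = 1200)
    smaller[s] <- median(whamBootstrap(lo$windows, n_boot = 10, seed = s,
                                       bin = 0.25)@err)
    larger[s] <- median(whamBootstrap(hi$windows, n_boot = 10, seed = s,
                                      bin = 0.25)@err)
  }
  expect_true(all(larger < smaller))
})

test_that("observable profiles localize a planted dip and modes agree", {
  kA <- permConstants$kJnm2_to_kcalA2
  spec <- pmfFlat(c(-10, 10))
  centers <- seq(-9, 9, 1)
  win <- sampleUmbrellaWindows(spec, centers, k = 2500 * kA,
                               n_samples = 400, seed = 12)
  ## constant observable: flat profile
  obs <- lapply(win, function(w) rep(6, length(w@samples)))
  pw <- observableVsXi(win, obs)
  expect_true(all(pw$value == 6))
  ## planted dip to 2 in the window at xi0 = 0
  i0 <- which(centers == 0)
  obs[[i0]] <- rep(2, length(win[[i0]]@samples))
  pd <- observableVsXi(win, obs)
  expect_equal(pd$xi[which.min(pd$value)], 0)
  ## binned-by-xi mode agrees with per-window means for narrow windows
  pb <- observableVsXi(win, obs, mode = "binned", bin = 0.2)
  near0 <- abs(pb$xi) < 0.2
  expect_lt(min(pb$value[near0]), 3.5)
  far <- abs(pb$xi) > 3
  expect_equal(mean(pb$value[far]), 6, tolerance = 0.2)
})

test_that("umbrella windows round-trip through manifest files with unit handling", {
  td <- withr::local_tempdir()
  dwdir <- file.path(td, "win")
  spec <- pmfHarmonic(k0 = 1, domain = c(-4, 4))
  win <- sampleUmbrellaWindows(spec, centers = c(-1, 0, 1), k = 5,
                               n_samples = 200, seed = 14)
  man <- writeUmbrellaWindows(win, dwdir)
  back <- readUmbrellaWindows(man)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_equal(back[[i]]@center, win[[i]]@center)
    expect_equal(back[[i]]@k, win[[i]]@k)
    expect_equal(back[[i]]@samples, win[[i]]@samples, tolerance = 1e-6)
  }
  ## kJ/nm^2 and nm units are converted on ingest; equilibration cut applies
  f <- file.path(td, "w1.dat")
  writeLines(c("# comment", "@ xvg header",
               sprintf("%g %g", seq(0, 5000, 500), seq(0, 1, 0.1) / 10)), f)
  man2 <- file.path(td, "man.csv")
  write.csv(data.frame(path = "w1.dat", center = 0.5, k = 1000,
                       k_unit = "kJ_nm2", xi_unit = "nm",
                       equilibration_cut = 2),
            man2, row.names = FALSE)
  w2 <- readUmbrellaWindows(man2)[[1]]
  expect_equal(w2@k, 1000 * permConstants$kJnm2_to_kcalA2)
  ## times 0..5 ns at 0.5 ns spacing; cut at 2 ns keeps t >= 2 (7 samples)
  expect_equal(length(w2@samples), 7)
  expect_equal(w2@samples, seq(0.4, 1, 0.1), tolerance = 1e-9)  # nm -> A
})
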