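test_that("coordination counts are exact, including the cutoff boundary", {
  fr <- buildHydrationFrame(rep(3, 5), seed = 21)
  cn <- coordinationNumber(fr, "species cation")
  expect_equal(cn$count, 5L)
  ## strict '<' at the boundary: 4.49 in, 4.51 out
  fb <- buildHydrationFrame(c(4.49, 4.51), seed = 22)
  expect_equal(coordinationNumber(fb, "species cation")$count, 1L)
  ## series attributes
  expect_equal(attr(cn, "mean"), 5)
  expect_equal(attr(cn, "min"), 5L)
})

test_that("coordination equals the brute-force 27-image count on random frames", {
  for (seed in 1:12) {
    set.seed(seed + 100)
    nw <- sample(5:25, 1)
    box <- c(18, 18, 18)   # small box so periodicity matters
    topo <- data.frame(name = c("NA", rep("OW", nw)),
                       resname = c("NA", rep("SOL", nw)),
                       resid = seq_len(nw + 1), chain = "A")
    pos <- matrix(runif((nw + 1) * 3, 0, 18), ncol = 3)
    tr <- makeTrajectory(topo, list(pos), 0, box)
    got <- coordinationNumber(tr, "species cation")$count
    want <- bruteCoordination(tr, 1, 1, 2:(nw + 1), 4.5)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("RDF is flat for an ideal gas and locates a planted shell", {
  set.seed(17)
  box <- c(30, 30, 30)
  n <- 300
  frames <- lapply(1:10, function(i) matrix(runif(n * 3, 0, 30), ncol = 3))
  topo <- data.frame(name = rep("OW", n), resname = "SOL",
                     resid = seq_len(n), chain = "A")
  tr <- makeTrajectory(topo, frames, (0:9) * 0.1, box)
  g <- rdf(tr, "species water-oxygen", "species water-oxygen",
           r_max = 10, bin = 0.25)
  expect_true(all(g$g >= 0))
  core <- g$g[g$r > 2]           # tiny-r bins have few counts
  expect_lt(max(abs(core - 1)), 0.2)
  expect_equal(mean(core), 1, tolerance = 0.02)

  ## shell at 2.4 A around a central ion + uniform background
  set.seed(18)
  n_sh <- 40; n_bg <- 200
  ion <- c(15, 15, 15)
  dirs <- matrix(rnorm(n_sh * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  frames2 <- lapply(1:20, function(i) {
    sh <- sweep(dirs * (2.4 + rnorm(n_sh, 0, 0.05)), 2, ion, "+")
    bg <- matrix(runif(n_bg * 3, 0, 30), ncol = 3)
    rbind(ion, sh, bg)
  })
  topo2 <- data.frame(name = c("NA", rep("OW", n_sh + n_bg)),
                      resname = c("NA", rep("SOL", n_sh + n_bg)),
                      resid = seq_len(n_sh + n_bg + 1), chain = "A")
  tr2 <- makeTrajectory(topo2, frames2, (0:19) * 0.1, box)
  g2 <- rdf(tr2, "species cation", "species water-oxygen", r_max = 8,
            bin = 0.1)
  expect_equal(g2$r[which.max(g2$g)], 2.4, tolerance = 0.15)
  fm <- rdfFirstMinimum(g2)
  expect_true(fm > 2.5 && fm < 6)
  ## few samples: warning
  expect_warning(rdf(tr2[1], "species cation", "species cation", r_max = 5),
                 "fewer than 100")
})

test_that("contact fractions count frames in contact", {
  ## ion alternates between 3 A and 8 A from a residue atom
  topo <- data.frame(name = c("NA", "OD1"), resname = c("NA", "ASP"),
                     resid = c(1, 276), chain = "A")
  mk <- function(ds) lapply(ds, function(d)
    matrix(c(10, 10, 10, 10, 10, 10 + d), ncol = 3, byrow = TRUE))
  box <- c(40, 40, 40)
  always <- makeTrajectory(topo, mk(rep(3, 4)), (0:3) * 0.1, box)
  never <- makeTrajectory(topo, mk(rep(8, 4)), (0:3) * 0.1, box)
  alt <- makeTrajectory(topo, mk(c(3, 8, 3, 8)), (0:3) * 0.1, box)
  expect_equal(contactFraction(always, "species cation", "resid 276")$fraction, 1)
  expect_equal(contactFraction(never, "species cation", "resid 276")$fraction, 0)
  cf <- contactFraction(alt, "species cation", "resid 276")
  expect_equal(cf$fraction, 0.5)
  expect_equal(cf$per_residue$fraction, 0.5)
})

test_that("nearest-luminal-ion distributions report exact planted statistics", {
  pore <- defaultPore()
  ## bound ion fixed at the SF; luminal neighbour always at 6 A above it
  nfr <- 10
  lum <- lapply(seq_len(nfr), function(f) matrix(c(20, 20, 52 + 6), 1, 3))
  tr <- makeIonPath(matrix(12, nfr, 1), box = c(40, 40, 80),
                    extra_ion_pos = lum)
  nd <- nearestIonDistribution(tr, pore, sf_band = c(10, 14))
  expect_equal(nd$P_below, 1)
  expect_equal(nd$mode, 6, tolerance = 0.25)
  expect_equal(nd$n_frames_used, nfr)
  expect_equal(sum(nd$density * 0.25), 1, tolerance = 1e-9)
  ## no luminal ion at all: not-available
  tr0 <- makeIonPath(matrix(12, nfr, 1))
  nd0 <- suppressWarnings(tryCatch(
    nearestIonDistribution(tr0, pore, sf_band = c(10, 14)),
    error = function(e) NULL))
  expect_null(nd0)   # only one ion of the species: contract error
  ## second ion on the cytosolic side only: frames skipped, P is NA
  cyt <- lapply(seq_len(nfr), function(f) matrix(c(20, 20, 40 - 20), 1, 3))
  trc <- makeIonPath(matrix(12, nfr, 1), extra_ion_pos = cyt)
  ndc <- nearestIonDistribution(trc, pore, sf_band = c(10, 14))
  expect_true(is.na(ndc$P_below))
  ## planted half/half mixture at 5 and 9 A: P(<7) exactly 0.5
  mix <- lapply(seq_len(nfr), function(f)
    matrix(c(20, 20, 52 + ifelse(f %% 2, 5, 9)), 1, 3))
  trm <- makeIonPath(matrix(12, nfr, 1), extra_ion_pos = mix)
  ndm <- nearestIonDistribution(trm, pore, sf_band = c(10, 14))
  expect_equal(ndm$P_below, 0.5)
  ## invariance to relabeling of the ion atoms
  perm <- c(1:4, 6, 5)   # swap the two NA rows (atoms 5 and 6)
  trs <- makeTrajectory(topology(trm)[perm, ],
                        lapply(seq_len(nfr), function(f)
                          framePositions(trm, f)[perm, ]),
                        frameTimes(trm), boxLengths(trm))
  expect_equal(nearestIonDistribution(trs, pore, sf_band = c(10, 14))$P_below,
               0.5)
})
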