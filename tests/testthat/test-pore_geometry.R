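test_that("maximal-inscribed-sphere radius matches analytic toy pores", {
  ## constant profile
  toy <- buildToyPore(function(z) rep(3.5, length(z)), atom_radius = 1.5)
  pr <- radiusProfile(toy$trajectory, vdw_table = toy$vdw_table,
                      z_range = c(-8, 8), z_step = 1)
  expect_lt(max(abs(pr$radius - 3.5)), 0.05)
  ## two atoms of radius 1.5 straddling the axis 8 A apart -> 2.5 A
  topo <- data.frame(name = c("O", "O"), resname = c("POR", "POR"),
                     resid = 1:2, chain = "A", element = "X",
                     species = "protein")
  p <- matrix(c(21, 25, 25, 29, 25, 25), ncol = 3, byrow = TRUE)
  tr2 <- makeTrajectory(topo, list(p), 0, c(50, 50, 50))
  ## sphere pinned to the axis (two atoms do not bound a pore laterally)
  pr2 <- radiusProfile(tr2, vdw_table = c(X = 1.5), center = c(25, 25, 25),
                       z_range = c(0, 0), z_step = 1, search_radius = 0)
  expect_equal(pr2$radius, 2.5, tolerance = 0.02)
  ## hourglass: minimum at the constructed constriction (within one level;
  ## the quadratic waist is flat to < 0.05 A over the two central levels)
  hg <- buildToyPore(function(z) 1 + 0.08 * z^2, z_range = c(-8, 8),
                     spacing = 0.5)
  prh <- radiusProfile(hg$trajectory, vdw_table = hg$vdw_table,
                       z_range = c(-6, 6), z_step = 0.5)
  expect_lte(abs(prh$z[which.min(prh$radius)]), 0.5)
  truth_h <- hg$truth$radius[match(prh$z, hg$truth$z)]
  expect_lt(max(abs(prh$radius - truth_h)), 0.05)
  ## empty slice reports the cap, flagged
  pre <- radiusProfile(tr2, vdw_table = c(X = 1.5), center = c(25, 25, 25),
                       z_range = c(40, 40), z_step = 1)
  expect_equal(pre$radius, 10)
  expect_true(pre$capped)
})

test_that("radius profile is invariant under rotation about the axis and never negative", {
  toy <- buildToyPore(function(z) 2 + 0.5 * sin(z), z_range = c(-6, 6))
  tr <- toy$trajectory
  pr <- radiusProfile(tr, vdw_table = toy$vdw_table, z_range = c(-5, 5),
                      z_step = 1)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ctr <- toy$center
  rot <- sweep(sweep(framePositions(tr, 1), 2, ctr) %*% R, 2, ctr, "+")
  tr2 <- makeTrajectory(topology(tr), list(rot), 0, boxLengths(tr)[1, ])
  pr2 <- radiusProfile(tr2, vdw_table = toy$vdw_table, z_range = c(-5, 5),
                       z_step = 1, center = ctr)
  expect_equal(pr2$radius, pr$radius, tolerance = 0.02)
  expect_true(all(pr$radius >= 0))
  ## adding atoms can only shrink the radius
  extra <- rbind(framePositions(tr, 1), ctr + c(1.2, 0, 0))
  topo3 <- rbind(topology(tr), topology(tr)[1, ])
  tr3 <- makeTrajectory(topo3, list(extra), 0, boxLengths(tr)[1, ])
  pr3 <- radiusProfile(tr3, vdw_table = toy$vdw_table, z_range = c(-5, 5),
                       z_step = 1, center = ctr)
  expect_true(all(pr3$radius <= pr$radius + 1e-6))
})

test_that("mean radius profile averages frames and repeats with correct SD", {
  toy <- buildToyPore(function(z) rep(3, length(z)), z_range = c(-4, 4))
  tr1 <- toy$trajectory
  ## static pore replicated over 5 frames: SD = 0
  tr5 <- makeTrajectory(topology(tr1),
                        rep(list(framePositions(tr1, 1)), 5),
                        (0:4) * 0.1, boxLengths(tr1)[1, ])
  mp <- meanRadiusProfile(tr5, z_range = c(-3, 3), z_step = 1,
                          vdw_table = toy$vdw_table)
  expect_equal(mp@sd, rep(0, length(mp@z)))
  ## two repeats with constant radii 3 and 5: mean 4, SD sqrt(2)
  toy5 <- buildToyPore(function(z) rep(5, length(z)), z_range = c(-4, 4))
  ## put both pores in identical boxes so profiles share the grid
  mp2 <- meanRadiusProfile(list(tr1, toy5$trajectory), z_range = c(-3, 3),
                           z_step = 1, vdw_table = toy$vdw_table)
  expect_equal(mp2@mean, rep(4, length(mp2@mean)), tolerance = 0.05)
  expect_equal(mp2@sd, rep(sqrt(2), length(mp2@sd)), tolerance = 0.05)
  ## 'last 60%' of a 10-frame run uses exactly 6 frames
  prof_list <- meanRadiusProfile(makeTrajectory(topology(tr1),
                                                rep(list(framePositions(tr1, 1)), 10),
                                                (0:9) * 0.1,
                                                boxLengths(tr1)[1, ]),
                                 window = "last 60%", z_range = c(0, 0),
                                 z_step = 1, vdw_table = toy$vdw_table)
  expect_s4_class(prof_list, "RadiusProfile")
})

test_that("minimum pair distances respect the minimum-image convention", {
  topo <- data.frame(name = c("CG", "CG", "CB", "CB"),
                     resname = "ASN", resid = c(653, 654, 653, 654),
                     chain = c("A", "B", "A", "B"), element = "C",
                     species = "protein")
  box <- c(50, 50, 50)
  ## closest heavy atoms 4.0 A apart
  p <- matrix(c(10, 10, 10,  14, 10, 10,  10, 16, 10,  30, 30, 30),
              ncol = 3, byrow = TRUE)
  tr <- makeTrajectory(topo, list(p), 0, box)
  ds <- minPairDistance(tr, "resid 653", "resid 654")
  expect_equal(ds$value, 4.0)
  expect_equal(minPairDistance(tr, "resid 654", "resid 653")$value, 4.0)
  expect_error(minPairDistance(tr, "resid 653", "resid 653"), "identical")
  ## straddling the periodic boundary: wrapped 47, true 3
  p2 <- p; p2[2, ] <- c(48.5, 10, 10); p2[1, ] <- c(1.5, 10, 10)
  tr2 <- makeTrajectory(topo, list(p2), 0, box)
  got <- minPairDistance(tr2, "resid 653", "resid 654")$value
  expect_equal(got, 3.0)
  expect_equal(got, bruteMinDist27(tr2, 1, c(1, 3), c(2, 4)))
})

test_that("distance distributions normalize and detect bimodality", {
  ## constant distance: single occupied bin of mass 1
  dd <- distanceDistribution(rep(4, 100), bin = 0.25)
  expect_equal(sum(dd$density * 0.25), 1)
  expect_equal(sum(dd$density > 0), 1)
  ## two-state series at 4 and 12 A, equal occupancy
  set.seed(4)
  x <- rep(c(4, 12), each = 500) + rnorm(1000, 0, 0.1)
  d2 <- distanceDistribution(x, bin = 0.25)
  expect_equal(sum(d2$density * 0.25), 1)
  expect_equal(d2$n_modes, 2)
  expect_equal(sort(d2$modes), c(4, 12), tolerance = 0.3)
  m_lo <- sum(d2$density[d2$mids < 8] * 0.25)
  expect_equal(m_lo, 0.5, tolerance = 0.05)
  ## joint 2D density integrates to 1
  dj <- distanceDistribution(x, rev(x), bin = 0.5)
  expect_equal(sum(dj$density * 0.25), 1)
})
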