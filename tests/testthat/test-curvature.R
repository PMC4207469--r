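# grid_frame() (helper-oracles.R) builds box-piecewise-constant frames.

test_that("grid decomposition: flat surface, edge convention, counts sum", {
  fr <- grid_frame(counts = rep(2, 16), z_surface = rep(0, 16))
  gd <- grid_decompose(fr, "outer", c(4, 4), exclude_species = "GM3")
  expect_equal(unname(gd$z), rep(60, 16))
  expect_equal(sum(gd$counts["GM3", ]), 32)
  expect_equal(sum(gd$n_in_box), n_molecules(fr))

  # a lipid exactly on a box edge belongs to the higher-index box
  xy <- rbind(c(20, 10), c(5, 5))     # x = 20 is the 0/1 box boundary
  fr2 <- minimal_frame(xy, c("GM3", "POPC"), c(60, 60),
                       box = c(80, 80, 120))
  gd2 <- grid_decompose(fr2, "outer", c(4, 4))
  expect_equal(which(gd2$counts["GM3", ] > 0),
               lipidorg:::grid_box_index(20, 10, c(80, 80, 120), c(4, 4)))
  expect_equal(lipidorg:::grid_box_index(20, 10, c(80, 80, 120), c(4, 4)),
               1L * 4L + 0L + 1L)     # box (1, 0), 0-based -> index 5
})

test_that("sinusoidal surfaces are recovered box-wise to ~2A amplitude", {
  A <- 20
  fr <- make_curved_frame(n_per_leaflet = 2000, amplitude = A,
                          modes = rbind(c(1, 0)),
                          coupling = list(outer = NULL, inner = NULL),
                          seed = 7)
  gd <- grid_decompose(fr, "outer", c(8, 8))
  rng <- max(gd$z, na.rm = TRUE) - min(gd$z, na.rm = TRUE)
  # box-averaging attenuates a wavelength-L sinusoid by sinc(pi/8) ~ 0.97
  expect_gt(rng, 2 * A * 0.85)
  expect_lt(rng, 2 * A * 1.1)
})

test_that("R is +/-1 for exactly linear counts and matches cor() to 1e-12", {
  z <- seq(-7.5, 7.5, length.out = 16)
  counts <- round(2 * z + 20)
  fr <- grid_frame(counts, z)
  cc <- curvature_composition_correlation(fr, "GM3", dims = c(4, 4))
  expect_equal(cc$mean, 1, tolerance = 1e-9)
  ccm <- curvature_composition_correlation(
    grid_frame(round(-2 * z + 20), z), "GM3", dims = c(4, 4))
  expect_equal(ccm$mean, -1, tolerance = 1e-9)

  # formula equals brute-force Pearson on noisy data
  set.seed(3)
  counts2 <- rpois(16, 5)
  z2 <- rnorm(16, sd = 4)
  fr2 <- grid_frame(counts2, z2)
  cc2 <- curvature_composition_correlation(fr2, "GM3", dims = c(4, 4))
  gd <- grid_decompose(fr2, "outer", c(4, 4), exclude_species = "GM3")
  expect_equal(cc2$mean, cor(gd$counts["GM3", ], gd$z), tolerance = 1e-12)
})

test_that("R is invariant to rigid translations of the frame", {
  set.seed(13)
  counts <- rpois(16, 6); z <- rnorm(16, sd = 3)
  fr <- grid_frame(counts, z)
  cc <- curvature_composition_correlation(fr, "GM3", dims = c(4, 4))
  sh <- fr
  sh$atoms$z <- sh$atoms$z + 11.3            # uniform z shift
  sh$atoms$x <- sh$atoms$x + 2 * 20          # whole-box lateral shift (wraps)
  cc2 <- curvature_composition_correlation(sh, "GM3", dims = c(4, 4))
  expect_equal(cc2$mean, cc$mean, tolerance = 1e-12)
})

test_that("negative planted coupling yields strongly negative R with the right sign", {
  frs <- make_curved_frames(n_frames = 8, n_per_leaflet = 2000, seed = 17)
  cc <- curvature_composition_correlation(frs, "GM3")
  expect_lt(cc$mean, -0.5)
  expect_true(all(cc$per_frame < 0))
  expect_gte(cc$sd, 0)
  expect_true(all(abs(cc$per_frame) <= 1))
})

test_that("interleaflet correlation: copies give unit diagonal, opposed couplings anti-correlate", {
  # inner leaflet an exact copy of the outer counts
  set.seed(19)
  counts <- rpois(16, 5); z <- rep(0, 16)
  fro <- grid_frame(counts, z)
  inner <- fro$atoms
  inner$z <- 120 - inner$z
  inner$mol <- inner$mol + max(inner$mol)
  both <- membrane_frame(rbind(fro$atoms, inner), fro$box,
                         leaflet = c(fro$molecules$leaflet,
                                     rep("inner", nrow(fro$molecules))))
  il <- interleaflet_correlation(both, dims = c(4, 4))
  expect_equal(il["GM3", "GM3"], 1, tolerance = 1e-12)

  # opposite-sign coupling to the same surface -> negative cross entry
  frs <- make_curved_frames(n_frames = 6, n_per_leaflet = 2000,
                            coupling = list(outer = c(GM3 = -0.9),
                                            inner = c(PIP2 = 0.9)),
                            composition = c(POPC = 0.5, GM3 = 0.25,
                                            PIP2 = 0.25),
                            seed = 23)
  il2 <- interleaflet_correlation(frs)
  expect_lt(il2["GM3", "PIP2"], -0.2)

  # independent random leaflets decorrelate
  il3 <- interleaflet_correlation(
    make_curved_frames(n_frames = 6, n_per_leaflet = 1500, amplitude = 0,
                       coupling = list(outer = NULL, inner = NULL),
                       seed = 29))
  expect_lt(max(abs(il3)), 0.2)
})

test_that("congruent displacement keeps thickness flat; planted thinning shows up", {
  frs <- make_curved_frames(n_frames = 5, n_per_leaflet = 2000,
                            coupling = list(outer = NULL, inner = NULL),
                            seed = 31)
  th <- local_thickness(frs)
  expect_lt(th$sd_thickness / th$mean_thickness, 0.1)
  expect_lt(abs(th$height_correlation), 0.15)

  # flat bilayer: thickness exactly constant
  flat <- make_curved_frame(n_per_leaflet = 500, amplitude = 0, seed = 37)
  th0 <- local_thickness(flat)
  expect_equal(th0$sd_thickness, 0, tolerance = 1e-9)

  # planted thinning at crests: compress the outer surface by half
  thin <- make_curved_frame(n_per_leaflet = 2000,
                            coupling = list(outer = NULL, inner = NULL),
                            seed = 41)
  at <- thin$atoms
  outer_ids <- thin$molecules$mol[thin$molecules$leaflet == "outer"]
  sel <- at$mol %in% outer_ids
  at$z[sel] <- 60 + (at$z[sel] - 60) * 0.5   # halve outer-side displacement
  thin2 <- membrane_frame(at, thin$box, leaflet = thin$molecules$leaflet)
  th2 <- local_thickness(thin2)
  expect_lt(th2$height_correlation, -0.5)    # thinner where the surface is high
})
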