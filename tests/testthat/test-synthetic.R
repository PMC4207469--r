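test_that("random leaflet respects hard-core spacing, composition and seeding", {
  fr <- make_random_leaflet(n = 400, seed = 13)
  pts <- lipidorg:::mol_points(fr, "head")
  close <- lipidorg:::close_molecule_pairs(
    cbind(pts$x, pts$y, pts$z), pts$mol, fr$box, 7, lateral = TRUE)
  expect_equal(nrow(close), 0L)  # no pair below the 7 A hard core
  expect_equal(sum(composition_counts(fr)), 400L)

  fr2 <- make_random_leaflet(n = 400, seed = 13)
  expect_identical(fr$atoms, fr2$atoms)
  fr3 <- make_random_leaflet(n = 400, seed = 14)
  expect_false(identical(fr$atoms$x, fr3$atoms$x))

  # density beyond the hard-core jamming limit must error, not hang
  expect_error(make_random_leaflet(n = 200, apl = 40, seed = 1),
               "packing failed")
})

test_that("planted clusters match their manifest and degenerate plantings work", {
  fr <- make_clustered_leaflet(cluster_sizes = c(10, 25, 50),
                               n_singletons = 5, seed = 17)
  man <- attr(fr, "manifest")$membership
  pts <- lipidorg:::mol_points(fr, "head")
  tgt <- pts[pts$species == "GM3", ]
  labels <- dbscan_periodic(cbind(tgt$x, tgt$y), fr$box)
  expect_equal(canonical_partition(labels),
               canonical_partition(ifelse(man$cluster == 0,
                                          100 + seq_len(nrow(man)),
                                          man$cluster)))
  sizes <- table(labels)
  expect_setequal(as.integer(sizes), c(10L, 25L, 50L, 1L))

  # all singletons -> everything non-clustered
  solo <- make_clustered_leaflet(cluster_sizes = integer(0),
                                 n_singletons = 30, n_filler = 30, seed = 19)
  ct <- cluster_timeseries(solo, "GM3")
  expect_equal(ct$series$nonclustered, 1)

  # one disc holding every target lipid -> a single cluster of n
  all_one <- make_clustered_leaflet(cluster_sizes = 40, n_singletons = 0,
                                    n_filler = 40, seed = 23)
  ct2 <- cluster_timeseries(all_one, "GM3")
  expect_equal(ct2$series$largest, 40)
})

test_that("curvature generator: null coupling is flat in R and amplitude 0 is degenerate", {
  frs <- make_curved_frames(n_frames = 50, n_per_leaflet = 800,
                            coupling = list(outer = NULL, inner = NULL),
                            seed = 29)
  cc <- curvature_composition_correlation(frs, "GM3")
  expect_lt(abs(cc$mean), 0.1)

  flat <- make_curved_frame(n_per_leaflet = 400, amplitude = 0, seed = 31)
  cc0 <- curvature_composition_correlation(flat, "GM3")
  expect_equal(cc0$mean, 0)
  expect_equal(cc0$zero_variance_frames, 1L)

  expect_error(make_curved_frame(n_per_leaflet = 100,
                                 coupling = list(outer = c(GM3 = -1.5),
                                                 inner = NULL),
                                 seed = 1),
               "intensity")
})

test_that("diffusion generator: D = 0 freezes lipids; manifest records D", {
  tr <- make_diffusion_trajectory(n_per_species = c(POPC = 20),
                                  D = c(POPC = 0), n_frames = 50, seed = 37)
  m <- lateral_msd(tr)
  expect_lt(max(abs(m$POPC)), 1e-8)   # zero up to FFT roundoff
  expect_equal(attr(tr, "manifest")$D[["POPC"]], 0)
})

test_that("flip-flop generator: zero rate means zero events, occupancy stratified", {
  tr <- make_flipflop_trajectory(n_chol = 50, n_other = 20, rate = 0,
                                 duration = 20, seed = 41)
  expect_equal(nrow(attr(tr, "manifest")$events), 0L)
  r <- detect_flipflops(tr)
  expect_equal(r$n_events, 0L)
  expect_equal(r$rate, 0)
  expect_error(make_flipflop_trajectory(occupancy = c(0.5, 0.1, 0.5)),
               "sum to 1")
})

test_that("generators emit frames satisfying the core invariants", {
  for (fr in list(make_random_leaflet(n = 100, seed = 1),
                  make_clustered_leaflet(cluster_sizes = c(10),
                                         n_singletons = 3, n_filler = 20,
                                         seed = 2),
                  make_curved_frame(n_per_leaflet = 100, seed = 3))) {
    expect_true(all(is.finite(fr$atoms$x)))
    expect_true(all(fr$box > 0))
    expect_false(anyDuplicated(fr$molecules$mol) > 0)
    tags <- fr$molecules$leaflet
    expect_true(all(tags %in% c("outer", "inner", "core")))
  }
})
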