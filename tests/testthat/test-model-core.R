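test_that("minimum-image distance handles identity, wrapping and lateral mode", {
  box <- c(100, 100, 100)
  expect_equal(minimum_image_distance(c(0, 0, 0), c(0, 0, 0), box), 0)
  expect_equal(minimum_image_distance(c(1, 0, 0), c(99, 0, 0), box), 2)
  # lateral mode ignores z and wraps only x, y; expected value derived by
  # enumerating the 9 lateral images of (90, 10): min distance is 20
  expect_equal(
    minimum_image_distance(c(10, 10, 5), c(90, 10, 5), box, mode = "xy"), 20)
  expect_error(minimum_image_distance(c(NA, 0, 0), c(0, 0, 0), box),
               "finite")
})

test_that("minimum-image distance equals brute-force image enumeration", {
  set.seed(42)
  box <- c(37, 61, 50)
  for (rep in 1:50) {
    p1 <- runif(3) * box
    p2 <- runif(3) * box
    d2 <- Inf
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      s <- c(sx, sy, sz) * box
      d2 <- min(d2, sum((p1 - p2 - s)^2))
    }
    expect_equal(minimum_image_distance(p1, p2, box), sqrt(d2))
    expect_equal(minimum_image_distance(p1, p2, box),
                 minimum_image_distance(p2, p1, box))
    expect_lte(minimum_image_distance(p1, p2, box),
               sqrt(sum((p1 - p2)^2)) + 1e-12)
    # invariant under whole-box translations of either point
    expect_equal(minimum_image_distance(p1 + 3 * box, p2, box),
                 minimum_image_distance(p1, p2, box))
  }
})

test_that("species registry holds all ten species with consistent topologies", {
  reg <- default_lipid_registry()
  expect_setequal(names(reg),
                  c("POPC", "POPE", "POPS", "DOPC", "DOPE", "DOPS",
                    "PPCS", "GM3", "PIP2", "CHOL"))
  for (s in reg) {
    expect_true(all(c(s$head_beads, s$linker_beads, s$interface_bead)
                    %in% s$bead_names))
    expect_true(all(s$tail_lengths >= 1))
  }
  # sphingolipids carry two 4-bead tails; PIP2 a 4- and a 5-bead tail
  expect_equal(reg$PPCS$tail_lengths, c(4L, 4L))
  expect_equal(reg$GM3$tail_lengths, c(4L, 4L))
  expect_setequal(reg$PIP2$tail_lengths, c(4L, 5L))
  expect_true("PO3" %in% reg$PIP2$head_beads)
  expect_equal(resolve_species("Sph"), "PPCS")
  expect_error(resolve_species("XXXX"), "unknown")
})

test_that("leaflet assignment: flat bilayer splits outer/inner, core slab catches cholesterol", {
  fr <- generate_template_bilayer(100, seed = 1)
  fr2 <- assign_leaflets(fr, core_half_width = 10)
  tags <- fr2$molecules$leaflet
  expect_equal(sum(tags == "outer"), 100)
  expect_equal(sum(tags == "inner"), 100)
  expect_equal(sum(tags == "core"), 0)

  # a cholesterol with its ROH reference bead 2 A above the midplane is core
  at <- fr$atoms
  chol <- data.frame(mol = max(at$mol) + 1L, species = "CHOL",
                     bead = c("ROH", "R1", "R2"),
                     x = 10, y = 10, z = 50 + c(2, 0, -2))
  fr3 <- assign_leaflets(membrane_frame(rbind(at[, names(chol)], chol),
                                        fr$box))
  expect_equal(fr3$molecules$leaflet[nrow(fr3$molecules)], "core")
  # partition property: every lipid gets exactly one of the three tags
  expect_true(all(fr3$molecules$leaflet %in% c("outer", "inner", "core")))
})

test_that("leaflet occupancy of planted three-state placements is recovered exactly", {
  # 50 / 48 / 2 % planted outer/inner/core cholesterol among a POPC bath
  tr <- make_flipflop_trajectory(n_chol = 100, n_other = 100, rate = 0,
                                 occupancy = c(outer = 0.50, core = 0.02,
                                               inner = 0.48),
                                 duration = 10, dt = 1, seed = 5)
  states <- attr(tr, "manifest")$states[, 1]
  occ <- leaflet_occupancy_timeseries(tr)
  expect_equal(occ$outer[1], mean(states == 1))
  expect_equal(occ$core[1], mean(states == 0))
  expect_equal(occ$inner[1], mean(states == -1))
  expect_equal(mean(states == 1), 0.50)
  expect_equal(mean(states == 0), 0.02)
})

test_that("composition counts are exact and empty selections give zeros", {
  pm <- build_membrane(seed = 7)
  outer <- composition_counts(pm, "outer")
  expect_equal(unname(outer["GM3"]), 75L)
  expect_equal(sum(outer), 750L)
  # equal 4-species leaflet: largest-remainder rounding forces 100 each
  fr <- make_random_leaflet(n = 400, seed = 1)
  cc <- composition_counts(fr, "outer")
  expect_true(all(cc[c("POPC", "POPE", "PPCS", "GM3")] == 100L))
  expect_true(all(composition_counts(fr, "inner") == 0L))
  expect_error(composition_counts(fr, "sideways"), "unknown leaflet")
})

test_that("largest-remainder rounding lands within one lipid of every target", {
  fr <- c(a = 0.137, b = 0.251, c = 0.312, d = 0.3)
  for (n in c(7, 53, 750, 1001)) {
    cts <- largest_remainder(fr, n)
    expect_equal(sum(cts), n)
    expect_true(all(abs(cts - fr * n) < 1))
  }
  expect_error(largest_remainder(c(a = 0.6, b = 0.6), 10), "sum to 1")
})
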