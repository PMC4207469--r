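test_that("template bilayer has the requested geometry and composition", {
  fr <- generate_template_bilayer(750, apl = 53.3, seed = 3)
  expect_equal(fr$box[1], sqrt(750 * 53.3))            # ca. 200 A edge
  expect_equal(round(fr$box[1]), 200)
  expect_equal(unname(composition_counts(fr)["POPC"]), 1500L)
  expect_equal(area_per_lipid(fr, "outer"), 53.3, tolerance = 1e-9)
  expect_equal(area_per_lipid(fr, "outer"), area_per_lipid(fr, "inner"))

  tiny <- generate_template_bilayer(1, seed = 1)
  expect_equal(n_molecules(tiny), 2L)
  # mirrored across the midplane: head-z offsets are symmetric
  z <- tiny$atoms$z
  mid <- tiny$box[3] / 2
  expect_equal(sort(z[1:12] - mid), sort(mid - z[13:24]), tolerance = 1e-9)
  expect_error(generate_template_bilayer(10, apl = -1), "apl")
})

test_that("PM recipe exchange yields the printed outer-leaflet composition", {
  pm <- build_membrane(seed = 11)
  outer <- composition_counts(pm, "outer")
  inner <- composition_counts(pm, "inner")
  expect_equal(unname(outer["GM3"]), 75L)
  expect_equal(unname(inner["PIP2"]), 75L)
  expect_equal(sum(outer), sum(inner))
  tgt_o <- pm_composition()$outer * 750
  for (sp in names(tgt_o))
    expect_lt(abs(outer[sp] - tgt_o[sp]), 1)
  # cholesterol split equally between leaflets
  expect_equal(unname(outer["CHOL"]), unname(inner["CHOL"]))
})

test_that("100% POPC recipe is the identity and seeds control reproducibility", {
  tpl <- generate_template_bilayer(50, seed = 2)
  same <- exchange_lipids(tpl, composition_spec(c(POPC = 1)), seed = 9)
  expect_equal(same$atoms[, c("x", "y", "z")], tpl$atoms[, c("x", "y", "z")])
  expect_equal(same$atoms$bead, tpl$atoms$bead)

  a <- build_membrane(n_lipids = 200, seed = 4)
  b <- build_membrane(n_lipids = 200, seed = 4)
  c <- build_membrane(n_lipids = 200, seed = 5)
  expect_identical(a$atoms, b$atoms)                    # bit-identical
  expect_false(identical(a$atoms$species, c$atoms$species))
  expect_equal(composition_counts(a), composition_counts(c))  # same targets
})

test_that("exchanged lipids stay anchored and sterically sane", {
  pm <- build_membrane(n_lipids = 300, seed = 6)
  # no two beads of distinct molecules closer than 1 A
  at <- pm$atoms
  clashes <- lipidorg:::close_molecule_pairs(
    as.matrix(at[, c("x", "y", "z")]), at$mol, pm$box, 1, lateral = FALSE)
  expect_equal(nrow(clashes), 0L)
  # superimposed molecules sit near their anchor site: every bead within
  # one template length of the molecule centroid
  for (sp in c("GM3", "PIP2")) {
    tpl <- lipid_template(sp)
    max_ext <- max(dist(tpl))
    sub <- at[at$species == sp, ]
    spread <- tapply(seq_len(nrow(sub)), sub$mol, function(i) {
      xyz <- as.matrix(sub[i, c("x", "y", "z")])
      max(sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
    })
    expect_true(all(spread <= max_ext))
  }
})

test_that("protein grid spacing is exact and exclusion radius controls deletion", {
  pm <- build_membrane(n_lipids = 1500, seed = 8)    # 200 A box
  pp <- place_protein_grid(pm, n_proteins = 9, spacing = 60,
                           exclusion_radius = 3)
  prot <- pp$atoms[pp$atoms$species == "PROT", ]
  centers <- cbind(tapply(prot$x, prot$mol, mean),
                   tapply(prot$y, prot$mol, mean))
  dmin <- Inf
  for (i in 1:8) for (j in (i + 1):9)
    dmin <- min(dmin, minimum_image_distance(centers[i, ], centers[j, ],
                                             pp$box, mode = "xy"))
  expect_equal(dmin, 60)

  one <- place_protein_grid(pm, n_proteins = 1, spacing = 60,
                            exclusion_radius = 0)
  expect_equal(sum(one$molecules$species == "PROT"), 1L)
  expect_equal(sum(one$molecules$species != "PROT"), 1500L)  # nothing deleted
  expect_error(place_protein_grid(pm, n_proteins = 16, spacing = 60),
               "does not fit")
})

test_that("lateral replication scales counts and the box", {
  pm <- build_membrane(n_lipids = 1500, seed = 10)
  big <- replicate_frame(pm, 2, 2)
  expect_equal(n_molecules(big), 6000L)
  expect_equal(composition_counts(big), composition_counts(pm) * 4L)
  expect_equal(unname(composition_counts(big, "outer")["GM3"]), 300L)
  expect_equal(big$box[1:2], pm$box[1:2] * 2)
  expect_false(anyDuplicated(big$molecules$mol) > 0)
  expect_identical(replicate_frame(pm, 1, 1), pm)
})

test_that("area per lipid is box area over leaflet count", {
  fr <- generate_template_bilayer(750, apl = 160/3, box_z = 90, seed = 1)
  expect_equal(area_per_lipid(fr, "outer"), 160/3, tolerance = 1e-12)
  expect_error(area_per_lipid(fr, "core"), "no lipids")
})
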