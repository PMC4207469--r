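# hand-built frame: lipids with linker beads at prescribed positions
linker_frame <- function(centers, species, box = c(100, 100, 100)) {
  reg <- default_lipid_registry()
  rows <- lapply(seq_len(nrow(centers)), function(i) {
    s <- reg[[species[i]]]
    data.frame(mol = i, species = species[i],
               bead = c(s$head_beads[1], s$linker_beads),
               x = centers[i, 1] + c(0, -1.5, 1.5),
               y = centers[i, 2],
               z = c(66, 60, 60), stringsAsFactors = FALSE)
  })
  membrane_frame(do.call(rbind, rows), box = box,
                 leaflet = rep("outer", nrow(centers)))
}

test_that("a lipid pair is counted once however many bead pairs touch", {
  # linker beads at +-1.5 around centers 5 A apart: all 4 bead pairs < 11 A
  fr <- linker_frame(rbind(c(50, 50), c(55, 50)), c("POPC", "POPC"))
  pc <- lipid_pair_contacts(fr)
  expect_equal(nrow(pc), 1L)

  # centers 14 A apart -> nearest bead pair exactly 11 A: strict < excludes
  fr2 <- linker_frame(rbind(c(50, 50), c(64, 50)), c("POPC", "POPE"))
  expect_equal(nrow(lipid_pair_contacts(fr2)), 0L)
  # a hair closer counts
  fr3 <- linker_frame(rbind(c(50, 50), c(63.99, 50)), c("POPC", "POPE"))
  expect_equal(nrow(lipid_pair_contacts(fr3)), 1L)

  # three mutually adjacent lipids -> 3 distinct pairs
  fr4 <- linker_frame(rbind(c(50, 50), c(56, 50), c(53, 55)),
                      rep("PPCS", 3))
  expect_equal(nrow(lipid_pair_contacts(fr4)), 3L)
})

test_that("pair contacts equal the brute-force periodic oracle on small frames", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    box <- c(60, 60, 100)
    fr <- linker_frame(cbind(runif(n, 0, 60), runif(n, 0, 60)),
                       sample(c("POPC", "GM3"), n, replace = TRUE),
                       box = box)
    sub <- fr$atoms[fr$atoms$bead %in% c("GL1", "GL2", "AM1", "AM2"), ]
    ours <- lipid_pair_contacts(fr)
    ref <- contacts_reference(as.matrix(sub[, c("x", "y", "z")]), sub$mol,
                              box, 11, lateral = TRUE)
    expect_equal(nrow(ours), nrow(ref))
    if (nrow(ref))
      expect_equal(ours[, c("mol_i", "mol_j")],
                   data.frame(mol_i = ref[, 1], mol_j = ref[, 2]),
                   ignore_attr = TRUE)
  }
})

test_that("fractional interactions are row-stochastic and composition-invariant", {
  frames <- lapply(1:25, function(k)
    make_random_leaflet(n = 600,
                        composition = c(POPC = 0.1, POPE = 0.2,
                                        PPCS = 0.3, GM3 = 0.4),
                        seed = 100 + k))
  fi <- fractional_interactions(frames)
  expect_equal(unname(rowSums(fi$fractions)), rep(1, 4), tolerance = 1e-9)
  expect_true(all(fi$fractions >= 0 & fi$fractions <= 1))
  # abundance correction: skewed composition still gives ~1/k everywhere
  expect_true(all(abs(fi$fractions - 0.25) < 0.03))
})

test_that("a species contacting only itself has unit self-fraction", {
  # two GM3 close together, two POPC close together, groups far apart
  fr <- linker_frame(rbind(c(10, 10), c(16, 10), c(60, 60), c(66, 60)),
                     c("GM3", "GM3", "POPC", "POPC"))
  fi <- suppressWarnings(fractional_interactions(fr))
  expect_equal(fi$fractions["GM3", "GM3"], 1)
  expect_equal(fi$fractions["POPC", "POPC"], 1)
})

test_that("lateral RDF: CSR null is flat, a planted ring shows as a single peak", {
  frames <- lapply(1:30, function(k)
    make_random_leaflet(n = 1000, composition = c(POPC = 1), seed = 200 + k))
  ctr <- cbind(c(60, 150, 240, 60, 150, 240), c(60, 60, 60, 240, 240, 240))
  g <- lateral_rdf(frames, center = ctr, target_species = "POPC",
                   bin_width = 5, r_max = 60)
  # fixed points are not particles: no hard core applies, g ~ 1 throughout
  expect_true(all(abs(g$g - 1) < 0.1))

  # all targets on a ring at r = 20.5 from the center
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  ring <- data.frame(mol = seq_along(ang), species = "GM3",
                     bead = "GC1",
                     x = 50 + 20.5 * cos(ang), y = 50 + 20.5 * sin(ang),
                     z = 66)
  fr <- membrane_frame(ring, box = c(100, 100, 100),
                       leaflet = rep("outer", length(ang)))
  g2 <- lateral_rdf(list(fr), center = matrix(c(50, 50), ncol = 2),
                    target_species = "GM3", bin_width = 2, r_max = 40)
  expect_equal(g2$r[which.max(g2$g)], 21)  # the 20-22 A bin
  expect_true(all(g2$g[g2$r > 23] == 0))

  expect_error(lateral_rdf(list(fr), center = ctr, target_species = "GM3",
                           r_max = 60), "half the smallest")
})

test_that("per-residue protein contacts count means, persistence and the >50% flag", {
  # straight backbone rod, residues 4.5 A apart: a lipid bead 5 A laterally
  # from residue 10 is 6.7 A from residues 9 and 11 (outside the cutoff)
  prot <- data.frame(mol = 1L, species = "PROT", bead = "BB",
                     x = 50, y = 50, z = 30 + 4.5 * (1:10), residue = 1:10)
  res10_z <- prot$z[10]
  mk <- function(lipid_z) {
    lip <- data.frame(mol = 2L, species = "PIP2", bead = "PO3",
                      x = 55, y = 50, z = lipid_z, residue = 1L)
    membrane_frame(rbind(prot, lip), box = c(120, 120, 120),
                   leaflet = c("protein", "inner"))
  }
  # lipid bead within 6 A of residue 10 in 60 of 100 frames
  frames <- lapply(1:100, function(k) mk(if (k <= 60) res10_z else
                                           res10_z + 40))
  tab <- residue_lipid_contacts(frames, "PIP2", "PO3")
  r10 <- tab[tab$residue == 10, ]
  expect_equal(r10$persistence, 0.6)
  expect_true(r10$persistent)
  expect_equal(r10$mean_contacts, 0.6)
  expect_false(any(tab$persistent[tab$residue <= 8]))

  # always present -> persistence 1, mean 1
  always <- lapply(1:20, function(k) mk(res10_z))
  tab2 <- residue_lipid_contacts(always, "PIP2", "PO3")
  expect_equal(tab2$persistence[tab2$residue == 10], 1)
  expect_equal(tab2$mean_contacts[tab2$residue == 10], 1)

  # never within 6 A -> all zeros
  far <- lapply(1:5, function(k) mk(res10_z + 40))
  tab3 <- residue_lipid_contacts(far, "PIP2", "PO3")
  expect_true(all(tab3$mean_contacts == 0))
  expect_true(all(!tab3$persistent))
})
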