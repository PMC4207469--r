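test_that("DBSCAN basics: chains, isolated points, boundary straddling", {
  box <- c(200, 200, 100)
  # 3 collinear points 10 A apart: middle point is core, one cluster of 3
  p <- cbind(c(50, 60, 70), 50)
  l <- dbscan_periodic(p, box, eps = 15, min_elements = 3)
  expect_equal(length(unique(l)), 1L)

  # two isolated points -> two noise singletons
  l2 <- dbscan_periodic(cbind(c(10, 110), 50), box)
  expect_equal(length(unique(l2)), 2L)
  expect_equal(attr(l2, "n_dense"), 0L)

  # cluster straddling the periodic boundary is one cluster
  l3 <- dbscan_periodic(cbind(c(1, 199, 195), 50), box)
  expect_equal(length(unique(l3)), 1L)

  expect_equal(length(dbscan_periodic(matrix(0, 0, 2), box)), 0L)
})

test_that("periodic DBSCAN equals the brute-force-with-images reference", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(5:100, 1)
    box <- c(runif(1, 60, 120), runif(1, 60, 120), 100)
    # mixture of a few dense blobs and background to exercise borders
    ncl <- sample(0:3, 1)
    pts <- NULL
    for (c in seq_len(ncl)) {
      ctr <- runif(2) * box[1:2]
      m <- sample(3:10, 1)
      pts <- rbind(pts, cbind(ctr[1] + rnorm(m, sd = 6),
                              ctr[2] + rnorm(m, sd = 6)))
    }
    extra <- n - NROW(pts)
    if (extra > 0)
      pts <- rbind(pts, cbind(runif(extra) * box[1], runif(extra) * box[2]))
    ours <- dbscan_periodic(pts, box, eps = 15, min_elements = 3)
    ref <- dbscan_reference(pts, box, eps = 15, min_elements = 3)
    expect_equal(canonical_partition(ours), canonical_partition(ref))
  }
})

test_that("DBSCAN labels are a permutation-invariant partition", {
  set.seed(21)
  box <- c(100, 100, 100)
  pts <- cbind(runif(60) * 100, runif(60) * 100)
  l <- dbscan_periodic(pts, box)
  perm <- sample(60)
  lp <- dbscan_periodic(pts[perm, ], box)
  # same partition: co-membership matrices agree
  expect_equal(outer(l[perm], l[perm], "=="), outer(lp, lp, "=="))
})

test_that("cluster size classes follow the planted ground truth", {
  fr <- make_clustered_leaflet(cluster_sizes = c(10, 25, 50),
                               n_singletons = 21, seed = 55)
  ct <- cluster_timeseries(fr, "GM3")
  n <- 10 + 25 + 50 + 21
  expect_equal(ct$series$nonclustered, 21 / n)
  expect_equal(ct$series$small, 10 / n)
  expect_equal(ct$series$medium, 25 / n)
  expect_equal(ct$series$large, 50 / n)
  expect_equal(ct$series$largest, 50)
  expect_equal(sum(ct$series[1, c("nonclustered", "small", "medium",
                                  "large")]), 1)
  # recovered partition equals the manifest partition exactly
  man <- attr(fr, "manifest")$membership
  rec <- ct$records[[1]]
  got <- rec$label[match(man$mol, rec$mol)]
  planted <- ifelse(man$cluster == 0, 1000 + seq_len(nrow(man)), man$cluster)
  expect_equal(canonical_partition(got), canonical_partition(planted))
})

test_that("protein connectivity clustering is transitive with an 8 A cutoff", {
  mk_frame <- function(xs) {
    prot <- do.call(rbind, lapply(seq_along(xs), function(i)
      data.frame(mol = i, species = "PROT", bead = "BB",
                 x = xs[i], y = 50, z = 50 + (1:5), residue = 1:5)))
    membrane_frame(prot, box = c(300, 300, 100),
                   leaflet = rep("protein", length(xs)))
  }
  # closest beads at 7 A -> one cluster of 2
  pc <- protein_clusters(mk_frame(c(50, 57)))
  expect_equal(pc$sizes[[1]], 2L)
  # chain A-B at 7, B-C at 7, A-C far -> transitivity gives one cluster of 3
  pc2 <- protein_clusters(mk_frame(c(50, 57, 64)))
  expect_equal(pc2$sizes[[1]], 3L)
  expect_equal(pc2$series$largest, 3L)
  # all farther than 8 A -> all singletons
  pc3 <- protein_clusters(mk_frame(seq(10, 10 + 15 * 9, by = 15)))
  expect_equal(pc3$series$n_clusters, 10L)
  expect_true(all(unlist(pc3$sizes) == 1L))
  # beads exactly at 8 A are linked ("within the cutoff distance")
  pc4 <- protein_clusters(mk_frame(c(50, 58)))
  expect_equal(pc4$sizes[[1]], 2L)
})
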