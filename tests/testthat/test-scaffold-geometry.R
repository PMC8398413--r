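test_that("voxel_grid validates input and porosity + solid fraction is exactly 1", {
  expect_error(voxel_grid(matrix(0, 2, 2), 10), "3D")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), -1), "positive")
  g <- voxel_grid(array(c(0, 1), c(4, 4, 4)), 25)
  expect_identical(sort(unique(as.vector(g$labels))), c(0L, 1L))
  expect_identical(porosity(g) + mean(g$labels), 1)
})

test_that("local thickness is exact (within a voxel) on analytic phantoms", {
  # slab: 10 voxels thick at 10 um -> 100 um
  g <- solid_slab_grid(n = 24, lo = 8, hi = 17, spacing = 10)
  th <- local_thickness(g, "solid")
  expect_lte(abs(mean(th[g$labels == 1L]) - 100), 10)

  # solid cylinder, radius 8 voxels at 10 um -> diameter 160 um
  n <- 30
  lab <- array(0L, c(n, n, n))
  cc <- 15.5
  for (j in 1:n) for (i in 1:n)
    if ((i - cc)^2 + (j - cc)^2 <= 64) lab[i, j, ] <- 1L
  g <- voxel_grid(lab, 10)
  th <- local_thickness(g, "solid")
  expect_lte(abs(mean(th[lab == 1L]) - 160), 10)

  # spherical solid ball, radius 6 voxels at 10 um -> diameter 120 um
  lab <- array(0L, c(21, 21, 21))
  for (k in 1:21) for (j in 1:21) for (i in 1:21)
    if ((i - 11)^2 + (j - 11)^2 + (k - 11)^2 <= 36) lab[i, j, k] <- 1L
  g <- voxel_grid(lab, 10)
  th <- local_thickness(g, "solid")
  expect_lte(abs(max(th) - 120), 10)
})

test_that("pore sampling recovers a single spherical pore diameter", {
  lab <- array(1L, c(31, 31, 31))
  for (k in 1:31) for (j in 1:31) for (i in 1:31)
    if ((i - 16)^2 + (j - 16)^2 + (k - 16)^2 <= 36) lab[i, j, k] <- 0L
  g <- voxel_grid(lab, 10)
  p <- sample_pores(g, 5, min_separation = 10)
  expect_gte(nrow(p), 1)
  expect_lte(abs(p$diameter[1] - 120), 10)
})

test_that("degenerate grids return porosity with thickness/pore stats undefined", {
  m <- measure_morphometry(voxel_grid(array(1L, c(6, 6, 6)), 10))
  expect_identical(m$porosity, 0)
  expect_true(is.na(m$tbth_mean))
  m <- measure_morphometry(voxel_grid(array(0L, c(6, 6, 6)), 10))
  expect_identical(m$porosity, 1)
  expect_true(is.na(m$pore_fit_mean))
})

test_that("clean_islands removes floating solids, seals dead pores, and is idempotent", {
  # one isolated solid voxel far from a large slab-with-channel
  lab <- array(0L, c(12, 12, 12))
  lab[, , 6] <- 1L           # full wall blocks flow ...
  lab[5:6, 5:6, 6] <- 0L     # ... except a channel
  lab[10, 10, 1] <- 1L       # floating island (not touching the wall)
  g <- clean_islands(voxel_grid(lab, 20))
  expect_identical(g$labels[10, 10, 1], 0L)
  expect_true(percolates(g))

  # enclosed pore gets sealed
  lab <- array(0L, c(12, 12, 12))
  lab[4:10, 4:10, 4:10] <- 1L
  lab[6:8, 6:8, 6:8] <- 0L   # cavity
  g <- clean_islands(voxel_grid(lab, 20))
  expect_identical(unique(as.vector(g$labels[6:8, 6:8, 6:8])), 1L)

  # fully connected grid returned unchanged; applying twice equals once
  g1 <- clean_islands(voxel_grid(array(0L, c(8, 8, 8)), 20))
  expect_identical(g1$labels, array(0L, c(8, 8, 8)))
  g2 <- clean_islands(g)
  expect_identical(g2$labels, g$labels)
})

test_that("clean_islands matches an exhaustive BFS flood-fill oracle on noise grids", {
  for (seed in 1:3) {
    lab <- array(withr::with_seed(seed, rbinom(16^3, 1, 0.5)), c(16, 16, 16))
    storage.mode(lab) <- "integer"
    got <- clean_islands(voxel_grid(lab, 20))
    want <- r_clean_oracle(lab)
    expect_identical(got$labels, want)
    # never increases the number of 26-connected solid components
    n_before <- max(r_label(lab, 26))
    n_after <- max(r_label(got$labels, 26))
    expect_lte(n_after, n_before)
  }
  # one larger case at 32^3
  lab <- array(withr::with_seed(99, rbinom(32^3, 1, 0.5)), c(32, 32, 32))
  storage.mode(lab) <- "integer"
  got <- clean_islands(voxel_grid(lab, 20))
  expect_identical(got$labels, r_clean_oracle(lab))
})

test_that("TIFF round-trip is lossless and thresholding matches a per-voxel scan", {
  lab <- array(withr::with_seed(7, rbinom(10 * 12 * 5, 1, 0.4)), c(10, 12, 5))
  g <- voxel_grid(lab, 15)
  tf <- tempfile(fileext = ".tif")
  write_grid(g, tf, "tiff")
  g2 <- read_image_stack(tf, spacing = 15)
  expect_identical(g2$labels, g$labels)
  expect_identical(g2$spacing, g$spacing)
  expect_identical(g2$dims, g$dims)

  # 8-bit graded stack, threshold 128
  vals <- withr::with_seed(8, sample(0:255, 8 * 8 * 3, replace = TRUE))
  pages <- lapply(1:3, function(k)
    matrix(vals[(k - 1) * 64 + 1:64] / 255, 8, 8))
  tf2 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, tf2, bits.per.sample = 8L)
  g3 <- read_image_stack(tf2, spacing = 10, threshold = 128)
  n_expected <- 0L
  for (v in vals) if (v >= 128) n_expected <- n_expected + 1L
  expect_identical(sum(g3$labels), n_expected)

  # error contracts
  empty <- tempfile(fileext = ".tif")
  file.create(empty)
  expect_error(read_image_stack(empty, spacing = 10))
  expect_error(read_image_stack(tf), "spacing")
})

test_that("generation is deterministic and recovers the preset morphometry across seeds", {
  sp <- paper_scaffold_spec(spacing = 40, seed = 3)
  g1 <- generate_scaffold(sp)
  g2 <- generate_scaffold(sp)
  expect_identical(g1$labels, g2$labels)

  for (seed in 1:5) {
    g <- small_paper_scaffold(seed = seed)
    m <- attr(g, "calibration")$measured
    expect_lte(abs(m$porosity - 0.90), 0.02)
    expect_lte(abs(m$tbth_mean / 120.7 - 1), 0.10)
    expect_true(percolates(g))
  }
})

test_that("porosity target near 1 yields an (almost) all-fluid grid", {
  sp <- scaffold_spec(porosity_target = 0.995, tbth_target = 100,
                      pore_mean = 400, domain_size = c(1600, 1600, 1600),
                      spacing = 40, seed = 2)
  g <- suppressWarnings(generate_scaffold(sp))
  expect_gte(porosity(g), 0.99)
})

test_that("invalid scaffold specs and undersized domains fail loudly", {
  expect_error(scaffold_spec(1.2, 120, 800), "porosity")
  expect_error(scaffold_spec(0.9, 30, 800, spacing = 20), "two voxels")
  expect_error(
    generate_scaffold(paper_scaffold_spec(domain_size = c(1000, 1000, 1000),
                                          spacing = 20)),
    "two mean pores")
})
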