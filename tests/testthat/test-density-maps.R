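test_that("grid statistics match hand arithmetic and a summation oracle", {
  g <- density_grid(array(0.2, c(3, 3, 3)))
  s <- grid_stats(g)
  expect_equal(s$mean, 0.2)
  expect_equal(s$std, 0)

  g2 <- density_grid(array(c(0, 2), c(2, 1, 1)))
  s2 <- grid_stats(g2)
  expect_equal(s2$mean, 1)
  expect_equal(s2$std, 1)
  expect_equal(s2$max, 2)

  blob <- make_blob_grid(blob_grid_spec(rbind(c(4, 4, 4)), 3, sigma = 1.2,
                                        noise_sd = 0.02), seed = 8)$grid
  v <- as.numeric(blob$values)
  mu <- sum(v) / length(v)                # two-pass oracle
  sd2 <- sum((v - mu)^2) / length(v)
  s3 <- grid_stats(blob)
  expect_equal(s3$mean, mu, tolerance = 1e-12)
  expect_equal(s3$std, sqrt(sd2), tolerance = 1e-12)

  # scaling: mean and std scale linearly
  gs <- density_grid(blob$values * 3.5, blob$origin, blob$spacing)
  ss <- grid_stats(gs)
  expect_equal(ss$mean, 3.5 * s3$mean, tolerance = 1e-12)
  expect_equal(ss$std, 3.5 * s3$std, tolerance = 1e-12)
})

test_that("an immobile gas atom accumulates into a single voxel", {
  ref <- matrix(rnorm(30), 10, 3)
  frames <- replicate(10, list(protein = ref, gas = matrix(c(1.1, 2.2, 3.3),
                                                           1)),
                      simplify = FALSE)
  traj <- trajectory_frames(ref, frames)
  g <- accumulate_density(traj, spacing = 0.5,
                          box = rbind(c(-5, -5, -5), c(5, 5, 5)))
  expect_equal(max(g$values), 1.0)
  expect_equal(sum(g$values > 0), 1)
  expect_equal(sum(g$values), 1.0)
})

test_that("accumulation conserves in-box observations and is frame-linear", {
  b <- make_bundle(bundle_spec(n_helices = 3, residues_per_helix = 10))
  sites <- rbind(c(8, 0, 0), c(-4, 6, 2))
  ht <- make_hop_trajectory(b, hop_trajectory_spec(sites, n_frames = 120,
                                                   jitter = 0.4, n_gas = 2),
                            seed = 6)
  box <- rbind(c(-15, -15, -12), c(15, 15, 12))
  g <- accumulate_density(ht$traj, spacing = 0.5, box = box)
  expect_equal(sum(g$values) * attr(g, "n_frames"), attr(g, "n_binned"))
  expect_equal(attr(g, "n_binned") + attr(g, "n_dropped"), 2 * 120)

  # linearity: the union of two frame sets equals the frame-count-weighted
  # average of the parts
  f1 <- ht$traj$frames[1:50]
  f2 <- ht$traj$frames[51:120]
  g1 <- accumulate_density(trajectory_frames(ht$traj$reference, f1),
                           spacing = 0.5, box = box)
  g2 <- accumulate_density(trajectory_frames(ht$traj$reference, f2),
                           spacing = 0.5, box = box)
  merged <- (50 * g1$values + 70 * g2$values) / 120
  expect_equal(merged, g$values, tolerance = 1e-12)
})

test_that("alignment removes a rigid transform applied to whole frames", {
  b <- make_bundle(bundle_spec(n_helices = 3, residues_per_helix = 10))
  sites <- rbind(c(8, 0, 0), c(-4, 6, 2))
  base <- make_hop_trajectory(b, hop_trajectory_spec(sites, n_frames = 80,
                                                     jitter = 0.3,
                                                     wobble = FALSE),
                              seed = 9)
  set.seed(31)
  rotated <- lapply(base$traj$frames, function(f) {
    rot <- random_rotation_fixture()
    tra <- rnorm(3, sd = 4)
    list(protein = apply_transform(f$protein, rot, tra),
         gas = apply_transform(f$gas, rot, tra))
  })
  box <- rbind(c(-15, -15, -12), c(15, 15, 12))
  g0 <- accumulate_density(base$traj, spacing = 0.5, box = box)
  g1 <- accumulate_density(trajectory_frames(base$traj$reference, rotated),
                           spacing = 0.5, box = box)
  expect_equal(g1$values, g0$values, tolerance = 1e-12)
})

test_that("zero frames and mismatched bead counts are rejected", {
  ref <- matrix(rnorm(30), 10, 3)
  expect_error(trajectory_frames(ref, list()), "at least one frame")
  expect_error(trajectory_frames(ref, list(list(protein = ref[1:5, ],
                                                gas = ref[1, , drop = FALSE]))),
               "bead count")
})

test_that("MRC and OpenDX maps round-trip and agree across formats", {
  set.seed(17)
  vals <- array(abs(rnorm(7 * 9 * 11)), c(7, 9, 11))
  g <- density_grid(vals, origin = c(-3.25, 2.5, 0.75), spacing = 0.5)

  fm <- withr::local_tempfile(fileext = ".mrc")
  write_map(g, fm)
  gm <- read_map(fm)
  expect_equal(gm$dims, g$dims, ignore_attr = TRUE)
  expect_equal(gm$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(gm$origin, g$origin, tolerance = 1e-5)
  expect_lt(max(abs(gm$values - g$values)), 1e-6)

  fd <- withr::local_tempfile(fileext = ".dx")
  write_map(g, fd)
  gd <- read_map(fd)
  expect_equal(gd$dims, g$dims, ignore_attr = TRUE)
  expect_lt(max(abs(gd$values - g$values)), 1e-6)

  # cross-format: stats preserved to float precision
  sm <- grid_stats(gm)
  sd <- grid_stats(gd)
  expect_equal(sm$mean, sd$mean, tolerance = 1e-6)
  expect_equal(sm$std, sd$std, tolerance = 1e-6)
})

test_that("unreadable map files fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".mrc")
  file.create(f)
  expect_error(read_map(f), "header")
  f2 <- withr::local_tempfile(fileext = ".dx")
  writeLines("not a map", f2)
  expect_error(read_map(f2), "gridpositions")
})

test_that("accumulated density converges to the stationary site weights", {
  b <- make_bundle(bundle_spec(n_helices = 3, residues_per_helix = 10))
  sites <- rbind(c(9, 0, 0), c(-9, 0, 0))
  w <- c(0.7, 0.3)
  box <- rbind(c(-14, -10, -10), c(14, 10, 10))
  l1 <- sapply(c(100, 1600), function(nf) {
    ht <- make_hop_trajectory(b, hop_trajectory_spec(sites, weights = w,
                                                     n_frames = nf,
                                                     mean_dwell = 5,
                                                     jitter = 0.2,
                                                     wobble = FALSE),
                              seed = 19)
    g <- accumulate_density(ht$traj, spacing = 0.5, box = box)
    # mass within 3 A of each site
    centres <- lapply(1:2, function(s) sites[s, ])
    mass <- sapply(centres, function(cc) {
      idx <- which(g$values > 0, arr.ind = TRUE)
      pos <- sweep((idx - 1) * g$spacing, 2, g$origin, `+`)
      sum(g$values[idx[sqrt(rowSums(sweep(pos, 2, cc)^2)) < 3, ,
                       drop = FALSE]])
    })
    sum(abs(mass / sum(mass) - w))
  })
  expect_lt(l1[2], l1[1])  # sampling error shrinks with more frames
  expect_lt(l1[2], 0.1)
})
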