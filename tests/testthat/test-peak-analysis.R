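test_that("constant grids yield no peaks", {
  g <- density_grid(array(0.3, c(8, 8, 8)))
  expect_equal(nrow(detect_peaks(g)), 0)
})

test_that("well-separated planted blobs are each recovered once", {
  sp <- blob_grid_spec(rbind(c(5, 6, 5), c(13, 6, 5)), c(1, 0.8),
                       sigma = 1, noise_sd = 0.01,
                       box = rbind(c(0, 0, 0), c(18, 12, 10)))
  made <- make_blob_grid(sp, seed = 2)
  pk <- detect_peaks(made$grid, k = 5, window = 2)
  expect_equal(nrow(pk), 2)
  for (m in 1:2) {
    d <- sqrt((pk$x - made$truth$x[m])^2 + (pk$y - made$truth$y[m])^2 +
                (pk$z - made$truth$z[m])^2)
    expect_lte(min(d), made$grid$spacing / 2 * sqrt(3) + 1e-9)
  }
})

test_that("peak detection equals the brute-force window-scan oracle", {
  set.seed(23)
  for (rep in 1:6) {
    dims <- sample(12:30, 3, replace = TRUE)
    vals <- array(abs(rnorm(prod(dims))), dims)
    if (rep %% 2 == 0) vals <- round(vals * 4) / 4  # force plateaus/ties
    g <- density_grid(vals, spacing = 0.5)
    k <- sample(c(0.5, 1, 1.5), 1)
    pk <- detect_peaks(g, k = k, window = 2)
    want <- oracle_peaks(g, k = k, window = 2)
    got <- as.matrix(pk[, c("i", "j", "k")])
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      ow <- want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE]
      og <- got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE]
      expect_equal(og, ow, ignore_attr = TRUE)
    }
  }
})

test_that("raising the threshold multiplier only thins peaks", {
  set.seed(29)
  g <- density_grid(array(abs(rnorm(20^3)), c(20, 20, 20)), spacing = 0.5)
  prev <- NULL
  for (k in c(0.5, 1, 2, 3)) {
    pk <- detect_peaks(g, k = k, window = 2)
    keys <- paste(pk$i, pk$j, pk$k)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("site matching is site-centric with a hard distance cutoff", {
  peaks <- data.frame(id = 1:2, x = c(0, 10), y = c(0, 0), z = c(0, 0))
  sites <- data.frame(x = c(0, 10, 20), y = c(0, 4.5, 0), z = c(0, 0, 0),
                      label = c("surface", "surface", "internal"))
  mm <- match_peaks(peaks, sites, cutoff = 4)
  expect_equal(mm$n_matches, 1)           # exact hit only; 4.5 A misses
  expect_true(mm$matched[1])
  expect_false(mm$matched[2])
  expect_false(mm$matched[3])
  pc <- mm$per_class
  expect_equal(pc$n_matches[pc$label == "surface"], 1)
  expect_equal(pc$n_matches[pc$label == "internal"], 0)

  # brute-force oracle on random sets
  set.seed(33)
  for (rep in 1:5) {
    p <- data.frame(id = 1:15, x = runif(15, 0, 30), y = runif(15, 0, 30),
                    z = runif(15, 0, 30))
    s <- data.frame(x = runif(10, 0, 30), y = runif(10, 0, 30),
                    z = runif(10, 0, 30))
    mm <- match_peaks(p, s, cutoff = 4)
    want_site <- logical(10)
    want_peak <- logical(15)
    for (a in 1:10) for (b in 1:15) {
      d <- sqrt(sum((as.numeric(s[a, c("x", "y", "z")]) -
                       as.numeric(p[b, c("x", "y", "z")]))^2))
      if (d <= 4) { want_site[a] <- TRUE; want_peak[b] <- TRUE }
    }
    expect_equal(mm$matched, want_site, ignore_attr = TRUE)
    expect_equal(mm$peak_matched, want_peak, ignore_attr = TRUE)
    expect_equal(mm$n_matches, sum(want_site))
  }
})

test_that("clustering handles empty, singleton and separated groups", {
  expect_length(cluster_peaks(data.frame(x = numeric(0), y = numeric(0),
                                         z = numeric(0))), 0)
  one <- cluster_peaks(data.frame(id = 7, x = 1, y = 2, z = 3))
  expect_length(one, 1)
  expect_equal(one[[1]]$members, 7)

  set.seed(37)
  grp1 <- cbind(rnorm(6, 0, 0.5), rnorm(6, 0, 0.5), rnorm(6, 0, 0.5))
  grp2 <- cbind(rnorm(5, 20, 0.5), rnorm(5, 0, 0.5), rnorm(5, 0, 0.5))
  pk <- data.frame(id = 1:11, x = c(grp1[, 1], grp2[, 1]),
                   y = c(grp1[, 2], grp2[, 2]), z = c(grp1[, 3], grp2[, 3]))
  cl <- cluster_peaks(pk, cutoff = 5)
  expect_length(cl, 2)
  expect_setequal(unlist(lapply(cl, `[[`, "members")), 1:11)
  # cross-check with hclust centroid linkage on this well-separated case
  hc <- stats::hclust(stats::dist(pk[, c("x", "y", "z")])^2,
                      method = "centroid")
  expect_equal(length(unique(stats::cutree(hc, h = 5^2))), 2)
})

test_that("clustering equals the exhaustive-merge oracle", {
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(5:40, 1)
    pos <- cbind(runif(n, 0, 25), runif(n, 0, 25), runif(n, 0, 25))
    pk <- data.frame(id = seq_len(n), x = pos[, 1], y = pos[, 2],
                     z = pos[, 3])
    got <- lapply(cluster_peaks(pk, cutoff = 5), `[[`, "members")
    want <- oracle_clusters(pos, cutoff = 5)
    norm <- function(l) sort(vapply(l, function(m)
      paste(sort(m), collapse = ","), character(1)))
    expect_equal(norm(got), norm(want))
  }
  # chaining on collinear peaks follows the deterministic merge order
  chain <- data.frame(id = 1:3, x = c(0, 4.9, 9.8), y = 0, z = 0)
  got <- lapply(cluster_peaks(chain, cutoff = 5), `[[`, "members")
  want <- oracle_clusters(as.matrix(chain[, c("x", "y", "z")]), cutoff = 5)
  expect_equal(lapply(got, as.integer), want)
})

test_that("cluster count is non-increasing in cutoff, singletons at 0+", {
  set.seed(43)
  pk <- data.frame(id = 1:20, x = runif(20, 0, 15), y = runif(20, 0, 15),
                   z = runif(20, 0, 15))
  counts <- sapply(c(1e-9, 1, 2, 4, 8, 16, 40),
                   function(cc) length(cluster_peaks(pk, cutoff = cc)))
  expect_equal(counts[1], 20)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1)
})

test_that("novel-cluster counting follows member match flags", {
  cl <- list(list(members = c(1, 2)), list(members = 3),
             list(members = c(4, 5)))
  expect_equal(count_novel_clusters(cl, c(TRUE, FALSE, TRUE, FALSE, FALSE)),
               1)
  expect_equal(count_novel_clusters(cl, rep(TRUE, 5)), 0)
  expect_equal(count_novel_clusters(list(), logical(0)), 0L)
})

test_that("the Boltzmann relation reproduces closed-form free energies", {
  p <- free_energy_params(temperature = 323.15, reference_density = 1)
  expect_equal(binding_free_energy(1, p), 0)
  expect_equal(binding_free_energy(exp(1), p),
               -8.314462 * 323.15 / 1000, tolerance = 1e-12)
  expect_equal(binding_free_energy(400, p), -16.09798, tolerance = 1e-5)
  # strictly decreasing in density, additive over ratios
  d <- binding_free_energy(c(1, 2, 5, 50), p)
  expect_true(all(diff(d) < 0))
  expect_equal(binding_free_energy(6, p),
               binding_free_energy(2, p) + binding_free_energy(3, p),
               tolerance = 1e-12)
  expect_error(binding_free_energy(0, p), "positive")
  expect_error(binding_free_energy(-1, p), "positive")
})

test_that("end-to-end matching on planted blobs recovers ground truth", {
  # S site blobs + N decoys, high amplitude, spacings >> cutoffs
  sites <- data.frame(x = c(5, 5, 25), y = c(5, 25, 5), z = c(8, 8, 8),
                      label = "surface")
  decoys <- rbind(c(25, 25, 8), c(15, 15, 20))
  sp <- blob_grid_spec(rbind(as.matrix(sites[, c("x", "y", "z")]), decoys),
                       amplitudes = rep(5, 5), sigma = 1, noise_sd = 0.01,
                       box = rbind(c(0, 0, 0), c(30, 30, 28)))
  g <- make_blob_grid(sp, seed = 3)$grid
  pk <- detect_peaks(g, k = 5, window = 2)
  rep5 <- match_report(pk, sites, match_cutoff = 4, cluster_cutoff = 5)
  expect_equal(rep5$matches, 3)
  expect_equal(rep5$clusters_not_present, 2)
  expect_equal(rep5$n_clusters, 5)
})
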