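test_that("a single-atom PDB parses with exact occupancy, B and cell", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 1)
  expect_equal(m$atoms$occ, 0.5)
  expect_equal(m$atoms$b, 20.0)
  expect_equal(coords(m)[1, ], c(11, 12, 13), ignore_attr = TRUE)
  expect_equal(m$atoms$element, "C")
  expect_equal(m$cell$a, 50)
})

test_that("write/read round-trip preserves atoms to format precision", {
  ps <- plant_sites(make_bundle(bundle_spec()), plant_site_spec(1, 2, 2),
                    seed = 11)
  m <- bundle_with_gas(ps)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(m2$atoms$name, m$atoms$name)
  expect_lt(max(abs(coords(m2) - coords(m))), 1e-3)
  expect_equal(m2$atoms$occ, m$atoms$occ, tolerance = 1e-2)
  expect_equal(m2$atoms$b, m$atoms$b, tolerance = 1e-2)
  expect_equal(m2$cell$a, m$cell$a, tolerance = 1e-3)
  expect_length(m2$symops, 1)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 20.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60 20.00           C",
    "ATOM      3  CB AALA A   1       2.000   0.000   0.000  0.50 20.00           C",
    "ATOM      4  CB BALA A   1       3.000   0.000   0.000  0.50 20.00           C",
    "ATOM      5  N   ALA A   2       4.000   0.000   0.000  1.00 15.00           N",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3)
  # CA: occupancy 0.6 wins; CB: tie broken by altloc letter (A)
  expect_equal(m$atoms$x[m$atoms$name == "CA"], 1.0)
  expect_equal(m$atoms$x[m$atoms$name == "CB"], 2.0)
})

test_that("selection predicates compose by conjunction and allow empties", {
  ps <- plant_sites(make_bundle(bundle_spec()), plant_site_spec(0, 3, 0),
                    seed = 3)
  m <- bundle_with_gas(ps)
  expect_equal(nrow(select_atoms(m, element = "KR")$atoms), 3)
  expect_equal(nrow(select_atoms(m, ca_only = TRUE)$atoms), 175)
  expect_equal(nrow(select_atoms(m, protein = TRUE, chain = "A")$atoms), 175)
  expect_equal(nrow(select_atoms(m, element = "KR", chain = "A")$atoms), 0)
  expect_equal(nrow(select_atoms(m, hetero = TRUE, element = "KR")$atoms), 3)
  expect_equal(count_protein_residues(m), 175)
})

test_that("superpose recovers known rigid transforms and is optimal", {
  b <- make_bundle(bundle_spec(n_helices = 3, residues_per_helix = 8))
  x <- coords(b)
  fit0 <- superpose(x, x)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)

  set.seed(42)
  for (rep in 1:5) {
    rot <- random_rotation_fixture()
    tra <- rnorm(3, sd = 10)
    y <- apply_transform(x, rot, tra)
    fit <- superpose(y, x)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(fit$rotation %*% rot, diag(3), tolerance = 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }

  # optimality: no random rotation beats the Kabsch fit (N <= 6 points)
  set.seed(7)
  p <- matrix(rnorm(18), 6, 3)
  q <- matrix(rnorm(18), 6, 3)
  best <- superpose(p, q)$rmsd
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  for (i in 1:10000) {
    r <- random_rotation_fixture()
    expect_gte(sqrt(mean(rowSums((pc %*% t(r) - qc)^2))), best - 1e-9)
  }
})

test_that("superpose rmsd is invariant under common rigid pre-transforms", {
  set.seed(12)
  p <- matrix(rnorm(30), 10, 3)
  q <- p + matrix(rnorm(30, sd = 0.3), 10, 3)
  base <- superpose(p, q)$rmsd
  for (rep in 1:5) {
    rot <- random_rotation_fixture()
    tra <- rnorm(3, sd = 5)
    r2 <- superpose(apply_transform(p, rot, tra),
                    apply_transform(q, rot, tra))$rmsd
    expect_lt(abs(r2 - base), 1e-9)
  }
})

test_that("superpose rejects degenerate inputs", {
  expect_error(superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(0:4, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("superposed RMSD agrees with an independent implementation", {
  set.seed(5)
  p <- matrix(rnorm(60, sd = 4), 20, 3)
  q <- p + matrix(rnorm(60, sd = 0.5), 20, 3)
  mine <- superpose(p, q)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(q)), as.numeric(t(p)), fit = TRUE)
  expect_equal(mine, ref, tolerance = 1e-3)
})

test_that("atom pairing by chain/resno/name drives the model RMSD", {
  b <- make_bundle(bundle_spec())
  m2 <- b
  rot <- random_rotation_fixture()
  m2$atoms[, c("x", "y", "z")] <- apply_transform(coords(b), rot, c(3, -2, 5))
  # drop some residues from one side: pairing must use the common set
  m2$atoms <- m2$atoms[-(1:10), ]
  res <- suppressMessages(rmsd_structures(m2, b))
  expect_equal(res$n_pairs, 165)
  expect_equal(res$n_dropped, 10)
  expect_lt(res$rmsd, 1e-6)
})

test_that("symmetry expansion matches hand geometry in P1", {
  cell <- unit_cell(50, 50, 50)
  one <- structure_model(
    data.frame(serial = 1, name = "CA", element = "C", resname = "ALA",
               resno = 1, chain = "A", x = 1, y = 25, z = 25, occ = 1,
               b = 20, type = "ATOM"),
    cell = cell, symops = list(symop_identity()))
  # a single atom in P1: nearest image is a full lattice translation away
  expect_length(symmetry_expand(one, 5), 0)
  expect_length(symmetry_expand(one, 55), 6)    # face neighbours at 50
  expect_length(symmetry_expand(one, 75), 18)   # + edge neighbours at 70.7
  expect_length(symmetry_expand(one, 90), 26)   # + corner neighbours at 86.6

  # two atoms across the cell wall make a 2 A cross-boundary contact
  two <- one
  two$atoms <- rbind(two$atoms, within(two$atoms, {
    serial <- 2; resno <- 2; x <- 49
  }))
  imgs <- symmetry_expand(two, 5)
  expect_gt(length(imgs), 0)
  expect_equal(min(vapply(imgs, `[[`, numeric(1), "min_dist")), 2.0,
               tolerance = 1e-9)
})

test_that("symmetry expansion equals brute-force enumeration", {
  set.seed(21)
  ops <- symops_from_strings(c("x,y,z", "-x,-y,z+1/2"))
  for (rep in 1:5) {
    cell <- unit_cell(15 + runif(1, 0, 5), 18 + runif(1, 0, 5),
                      20 + runif(1, 0, 5))
    atoms <- data.frame(serial = 1:6, name = "CA", element = "C",
                        resname = "ALA", resno = 1:6, chain = "A",
                        x = runif(6, 2, 10), y = runif(6, 2, 10),
                        z = runif(6, 2, 10), occ = 1, b = 20, type = "ATOM")
    m <- structure_model(atoms, cell = cell, symops = ops)
    radius <- runif(1, 3, 12)
    got <- symmetry_expand(m, radius)
    got_keys <- sort(vapply(got, function(i)
      paste(i$op_index, paste(i$shift, collapse = ","), sep = "|"),
      character(1)))
    # oracle: direct enumeration with explicit per-atom distance loops
    orth <- orth_matrix(cell)
    fr <- coords(m) %*% t(frac_matrix(cell))
    want <- character(0)
    for (k in seq_along(m$symops)) {
      op <- m$symops[[k]]
      for (sa in -1:1) for (sb in -1:1) for (sc in -1:1) {
        if (k == 1 && sa == 0 && sb == 0 && sc == 0) next
        img <- (fr %*% t(op$rotation) +
                  matrix(op$translation + c(sa, sb, sc), 6, 3,
                         byrow = TRUE)) %*% t(orth)
        mind <- Inf
        for (a in 1:6) for (bb in 1:6)
          mind <- min(mind, sqrt(sum((coords(m)[a, ] - img[bb, ])^2)))
        if (mind < radius)
          want <- c(want, paste(k, paste(c(sa, sb, sc), collapse = ","),
                                sep = "|"))
      }
    }
    expect_setequal(got_keys, sort(want))
    # monotonicity: doubling the radius never removes an image
    got2 <- symmetry_expand(m, 2 * radius)
    keys2 <- vapply(got2, function(i)
      paste(i$op_index, paste(i$shift, collapse = ","), sep = "|"),
      character(1))
    expect_true(all(got_keys %in% keys2))
  }
})

test_that("identity-only operator sets give pure-translation images", {
  b <- make_bundle(bundle_spec(n_helices = 3, residues_per_helix = 8))
  b$cell <- make_p1_cell(b, gap = 4)
  b$symops <- list(symop_identity())
  imgs <- symmetry_expand(b, 6)
  expect_gt(length(imgs), 0)
  for (img in imgs) {
    expect_equal(img$op_index, 1)
    shift_cart <- as.numeric(orth_matrix(b$cell) %*% img$shift)
    expect_equal(coords(img$model), sweep(coords(b), 2, shift_cart, `+`),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("missing cell or symops fails with guidance", {
  b <- make_bundle(bundle_spec(n_helices = 3, residues_per_helix = 8))
  expect_error(symmetry_expand(b, 5), "unit cell and symmetry")
})
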