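# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different algorithms from the package code
# (explicit loops, dense enumeration, projection-based pseudo-inverse).

# brute-force peak scan: explicit window loop in index space
oracle_peaks <- function(grid, k = 5, window = 2) {
  v <- grid$values
  dims <- dim(v)
  thr <- mean(v) + k * sqrt(mean((v - mean(v))^2))
  w <- as.integer(floor(window / grid$spacing + 1e-9))
  cand <- which(v > thr, arr.ind = TRUE)
  hits <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]; kk <- cand[r, 3]
    ii <- max(1, i - w):min(dims[1], i + w)
    jj <- max(1, j - w):min(dims[2], j + w)
    kkk <- max(1, kk - w):min(dims[3], kk + w)
    sub <- v[ii, jj, kkk]
    if (v[i, j, kk] < max(sub)) next
    # plateau tie-break: smallest (i, j, k) lexicographically wins
    ties <- which(sub == v[i, j, kk], arr.ind = TRUE)
    tie_idx <- cbind(ii[ties[, 1]], jj[ties[, 2]], kkk[ties[, 3]])
    ord <- order(tie_idx[, 1], tie_idx[, 2], tie_idx[, 3])
    first <- tie_idx[ord[1], ]
    if (first[1] == i && first[2] == j && first[3] == kk)
      hits[[length(hits) + 1]] <- c(i, j, kk)
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 3))
  do.call(rbind, hits)
}

# exhaustive-merge centroid agglomeration, written independently:
# recompute the full centroid table from scratch each round
oracle_clusters <- function(pos, cutoff) {
  n <- nrow(pos)
  if (n == 0) return(list())
  assign <- seq_len(n)
  repeat {
    groups <- sort(unique(assign))
    cen <- t(vapply(groups, function(g)
      colMeans(pos[assign == g, , drop = FALSE]), numeric(3)))
    if (length(groups) < 2) break
    bestd <- Inf; bi <- bj <- NA
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      d <- sqrt(sum((cen[a, ] - cen[b, ])^2))
      if (d < bestd - 1e-12) { bestd <- d; bi <- a; bj <- b }
    }
    if (bestd >= cutoff - 1e-12) break
    assign[assign == groups[bj]] <- groups[bi]
  }
  lapply(sort(unique(assign)), function(g) sort(which(assign == g)))
}

# MSF via dense pseudo-inverse with explicit rigid-body projection
oracle_msf <- function(xyz, hess, kT = 1) {
  n <- nrow(xyz)
  tr <- kronecker(rep(1, n), diag(3))
  cen <- sweep(xyz, 2, colMeans(xyz))
  rot <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    r <- cen[i, ]
    rot[(3 * i - 2):(3 * i), ] <- rbind(c(0, r[3], -r[2]),
                                        c(-r[3], 0, r[1]),
                                        c(r[2], -r[1], 0))
  }
  rb <- qr.Q(qr(cbind(tr, rot)))
  p <- diag(3 * n) - rb %*% t(rb)
  covm <- p %*% solve(hess + rb %*% t(rb)) %*% p
  kT * rowSums(matrix(diag(covm), ncol = 3, byrow = TRUE))
}

random_rotation_fixture <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# a bundle with gas atoms merged in as HETATM records
bundle_with_gas <- function(ps) {
  m <- ps$model
  ga <- ps$sites
  if (nrow(ga)) {
    m$atoms <- rbind(m$atoms, data.frame(
      serial = max(m$atoms$serial) + ga$id, name = ga$element,
      element = ga$element, resname = ga$element, resno = 8000 + ga$id,
      chain = "G", x = ga$x, y = ga$y, z = ga$z, occ = ga$occ, b = ga$b,
      type = "HETATM", stringsAsFactors = FALSE))
  }
  m
}

# minimal hand-written PDB text for parser tests
toy_pdb_lines <- function() {
  c("CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA  ALA A   1      11.000  12.000  13.000  0.50 20.00           C",
    "END")
}
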