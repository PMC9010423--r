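# Anisotropic elastic-network model (ANM): Calpha beads plus optional
# noble-gas beads, uniform springs within a distance cutoff, normal modes
# and mean-square fluctuations in arbitrary units.

#' Build an elastic network from a model and optional gas sites
#'
#' One bead per protein residue at its CA atom; one extra bead per gas site
#' with the same spring constant and cutoff. Two beads are connected iff
#' their distance is strictly less than `cutoff`.
#'
#' @param model A [structure_model()] with >= 2 CA atoms, or an N x 3
#'   coordinate matrix of beads.
#' @param gas_sites Optional gas site table with `x`, `y`, `z` columns (or
#'   an M x 3 matrix).
#' @param cutoff Connection cutoff in angstroms (default 15, strict `<`).
#' @param gamma Uniform spring constant, arbitrary units (default 1).
#' @param gas_weights Optional per-gas-bead spring weights (e.g. site
#'   occupancies): springs touching gas bead `g` use
#'   `gamma * gas_weights[g]`. Default: all resolved sites at weight 1.
#' @return Object of class `elastic_network` with `xyz`, `kind`
#'   (`"residue"`/`"gas"`), `adjacency` (logical), `cutoff`, `gamma`,
#'   `bead_weight` and per-residue bookkeeping (`resno`, `chain`).
#' @export
build_network <- function(model, gas_sites = NULL, cutoff = 15, gamma = 1,
                          gas_weights = NULL) {
  if (inherits(model, "structure_model")) {
    ca <- select_atoms(model, ca_only = TRUE)$atoms
    if (nrow(ca) < 2) stop("model must contain at least 2 CA atoms")
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    resno <- ca$resno
    chain <- ca$chain
  } else {
    xyz <- as.matrix(model)
    if (nrow(xyz) < 2) stop("at least 2 beads are required")
    resno <- seq_len(nrow(xyz))
    chain <- rep("A", nrow(xyz))
  }
  kind <- rep("residue", nrow(xyz))
  weight <- rep(1, nrow(xyz))
  if (!is.null(gas_sites) &&
      (is.matrix(gas_sites) || nrow(as.data.frame(gas_sites)) > 0)) {
    g <- if (is.matrix(gas_sites)) gas_sites else
      as.matrix(as.data.frame(gas_sites)[, c("x", "y", "z")])
    if (is.null(gas_weights)) gas_weights <- rep(1, nrow(g))
    stopifnot(length(gas_weights) == nrow(g), all(gas_weights >= 0))
    xyz <- rbind(xyz, g)
    kind <- c(kind, rep("gas", nrow(g)))
    weight <- c(weight, gas_weights)
    resno <- c(resno, rep(NA_integer_, nrow(g)))
    chain <- c(chain, rep(NA_character_, nrow(g)))
  }
  n <- nrow(xyz)
  d2 <- cross_dist2(xyz, xyz)
  adj <- d2 < cutoff^2
  diag(adj) <- FALSE
  comp <- graph_components(adj)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop("elastic network is disconnected under cutoff ", cutoff,
         " A: component sizes ", paste(sizes, collapse = ", "))
  }
  structure(list(xyz = xyz, kind = kind, adjacency = adj, cutoff = cutoff,
                 gamma = gamma, bead_weight = weight, resno = resno,
                 chain = chain),
            class = "elastic_network")
}

# connected components of a logical adjacency matrix (BFS)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' ANM Hessian of an elastic network
#'
#' For each spring (i, j) the off-diagonal 3x3 super-element is
#' `-gamma * d d^T` with `d` the unit vector between the beads; diagonal
#' super-elements are minus the row sums, so uniform translations are in
#' the null space exactly.
#'
#' @param net An [build_network()] object.
#' @return Symmetric positive semidefinite 3N x 3N matrix.
#' @export
enm_hessian <- function(net) {
  xyz <- net$xyz
  n <- nrow(xyz)
  h <- matrix(0, 3 * n, 3 * n)
  pairs <- which(net$adjacency & upper.tri(net$adjacency), arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]
    j <- pairs[p, 2]
    d <- xyz[j, ] - xyz[i, ]
    len <- sqrt(sum(d^2))
    if (len < 1e-6)
      stop("coincident connected beads ", i, " and ", j,
           " (distance < 1e-6 A)")
    u <- d / len
    g <- net$gamma * net$bead_weight[i] * net$bead_weight[j]
    blk <- -g * tcrossprod(u)
    ri <- (3 * i - 2):(3 * i)
    rj <- (3 * j - 2):(3 * j)
    h[ri, rj] <- blk
    h[rj, ri] <- blk
    h[ri, ri] <- h[ri, ri] - blk
    h[rj, rj] <- h[rj, rj] - blk
  }
  h
}

#' Normal modes of an ANM Hessian
#'
#' Full eigendecomposition with eigenvalues in ascending order. Modes with
#' eigenvalue below `zero_tol` times the largest eigenvalue are classified
#' as rigid-body (zero) modes; a connected 3-D network must yield exactly
#' six (a connected collinear bead geometry, e.g. a dimer, yields five),
#' otherwise an error reports the count, signalling disconnection or
#' degeneracy.
#'
#' @param hessian Symmetric 3N x 3N matrix from [enm_hessian()].
#' @param zero_tol Relative zero-mode tolerance (default 1e-8).
#' @return Object of class `mode_set`: `values` (ascending), `vectors`
#'   (columns, orthonormal), `n_zero`.
#' @export
normal_modes <- function(hessian, zero_tol = 1e-8) {
  if (max(abs(hessian - t(hessian))) > 1e-8)
    stop("hessian must be symmetric")
  eig <- eigen((hessian + t(hessian)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  n_zero <- sum(values < zero_tol * max(values))
  if (n_zero != 6 && n_zero != 5)
    stop("expected 6 zero modes for a connected 3-D network, found ",
         n_zero, " (disconnected or degenerate network?)")
  structure(list(values = values, vectors = vectors, n_zero = n_zero),
            class = "mode_set")
}

#' Per-bead mean-square fluctuations from a mode set
#'
#' `MSF_i = kT * trace` of the i-th 3x3 diagonal block of the Hessian
#' pseudo-inverse, summed over all non-zero modes. Arbitrary units (the
#' spring constant sets the scale).
#'
#' @param modes A [normal_modes()] result.
#' @param kT Thermal factor (default 1, arbitrary units).
#' @return Numeric vector of per-bead MSF values.
#' @export
fluctuations <- function(modes, kT = 1) {
  nz <- (modes$n_zero + 1):length(modes$values)
  v <- modes$vectors[, nz, drop = FALSE]
  w <- 1 / modes$values[nz]
  msf3 <- (v^2) %*% w  # per-coordinate diagonal of the pseudo-inverse
  kT * as.numeric(rowSums(matrix(msf3, ncol = 3, byrow = TRUE)))
}

# symmetric pseudo-inverse via eigendecomposition
pinv_sym <- function(m, tol = 1e-10) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), 1e-300)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Effective residue Hessian with gas beads integrated out
#'
#' Gaussian marginalization of the gas coordinates: the Schur complement
#' `H_rr - H_rg pinv(H_gg) H_gr` of the with-gas network Hessian. The
#' result shares the six rigid-body zero modes of the gas-free network and
#' dominates the gas-free Hessian in the positive-semidefinite order, which
#' is what makes the damping inequality of [fluctuation_difference()]
#' exact.
#'
#' @param net An [build_network()] object containing gas beads.
#' @return Symmetric PSD matrix over the residue-bead coordinates.
#' @export
effective_residue_hessian <- function(net) {
  h <- enm_hessian(net)
  res <- which(net$kind == "residue")
  gas <- which(net$kind == "gas")
  ri <- as.numeric(t(outer(3 * res - 3, 1:3, `+`)))
  gi <- as.numeric(t(outer(3 * gas - 3, 1:3, `+`)))
  if (!length(gi)) return(h)
  h[ri, ri] - h[ri, gi] %*% pinv_sym(h[gi, gi]) %*% h[gi, ri]
}

#' Per-residue fluctuation change induced by bound gas atoms
#'
#' Compares the mean-square fluctuations of the residue beads without gas
#' against those of the with-gas network after integrating out the gas
#' coordinates (Schur complement, see [effective_residue_hessian()]). The
#' gas springs can only stiffen the effective residue Hessian, so the
#' difference (with minus without) is non-positive at every residue: bound
#' gas damps, never amplifies, the harmonic dynamics.
#'
#' @param model A [structure_model()] (or bead coordinate matrix).
#' @param gas_sites Gas site table / matrix passed to [build_network()].
#' @param cutoff Network cutoff in angstroms (default 15).
#' @param gamma Spring constant (default 1).
#' @param kT Thermal factor (default 1).
#' @param occupancy_weighted Scale each gas bead's springs by its site
#'   occupancy (`occ` column) instead of weight 1 (default FALSE).
#' @return data.frame with `resno`, `chain`, `msf_without`, `msf_with`,
#'   `delta`.
#' @export
fluctuation_difference <- function(model, gas_sites = NULL, cutoff = 15,
                                   gamma = 1, kT = 1,
                                   occupancy_weighted = FALSE) {
  net0 <- build_network(model, gas_sites = NULL, cutoff = cutoff,
                        gamma = gamma)
  msf0 <- fluctuations(normal_modes(enm_hessian(net0)), kT = kT)
  if (is.null(gas_sites) ||
      nrow(as.data.frame(gas_sites)) == 0) {
    msf1 <- msf0
  } else {
    gw <- NULL
    if (occupancy_weighted) {
      gs <- as.data.frame(gas_sites)
      if (!"occ" %in% names(gs))
        stop("occupancy_weighted = TRUE requires an 'occ' column")
      gw <- gs$occ
    }
    net1 <- build_network(model, gas_sites = gas_sites, cutoff = cutoff,
                          gamma = gamma, gas_weights = gw)
    heff <- effective_residue_hessian(net1)
    msf1 <- fluctuations(normal_modes(heff), kT = kT)
  }
  data.frame(resno = net0$resno, chain = net0$chain, msf_without = msf0,
             msf_with = msf1, delta = msf1 - msf0)
}
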