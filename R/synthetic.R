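# Synthetic ground-truth generators: 7-helix CA bundles, planted gas sites
# per class, Gaussian-blob density grids with calibrated noise, and
# dwell/hop gas trajectories. All generators are deterministic under an
# explicit seed and emulate the geometry of a 7-TM membrane protein with
# its membrane normal along +z.

#' Specification of a synthetic helical CA bundle
#'
#' Ideal alpha-helix CA traces (rise 1.5 A/residue, 100 deg/residue,
#' helix radius 2.3 A) give consecutive CA distances of 3.83 A, inside the
#' canonical 3.8 +/- 0.1 A band.
#'
#' @param n_helices Number of helices (default 7).
#' @param residues_per_helix Residues per helix (default 25).
#' @param bundle_radius Distance of helix axes from the bundle axis, A
#'   (default 10).
#' @param helix_radius CA helix radius, A (default 2.3).
#' @param rise Rise per residue along z, A (default 1.5).
#' @param seed RNG seed for the per-helix phase angles.
#' @export
bundle_spec <- function(n_helices = 7, residues_per_helix = 25,
                        bundle_radius = 10, helix_radius = 2.3,
                        rise = 1.5, seed = 1) {
  stopifnot(n_helices >= 1, residues_per_helix >= 2, bundle_radius > 0)
  if (n_helices > 1) {
    axis_sep <- 2 * bundle_radius * sin(pi / n_helices)
    if (axis_sep < 2 * (helix_radius + 0.2))
      stop("helices overlap: axis separation ", signif(axis_sep, 3),
           " A is below twice the helix radius")
  }
  structure(list(n_helices = n_helices,
                 residues_per_helix = residues_per_helix,
                 bundle_radius = bundle_radius, helix_radius = helix_radius,
                 rise = rise, seed = seed), class = "bundle_spec")
}

#' Generate a helical-bundle CA trace
#'
#' @param spec A [bundle_spec()].
#' @return A [structure_model()] of CA atoms (chain A, ALA residues),
#'   helix axes parallel to +z (the membrane normal convention).
#' @export
make_bundle <- function(spec = bundle_spec()) {
  stopifnot(inherits(spec, "bundle_spec"))
  withr_seed <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(if (!is.null(withr_seed)) assign(".Random.seed", withr_seed,
                                           envir = globalenv()))
  turn <- 100 * pi / 180
  rows <- list()
  serial <- 0L
  resno <- 0L
  for (h in seq_len(spec$n_helices)) {
    ang <- 2 * pi * (h - 1) / spec$n_helices
    cx <- spec$bundle_radius * cos(ang)
    cy <- spec$bundle_radius * sin(ang)
    phase <- stats::runif(1, 0, 2 * pi)
    i <- seq_len(spec$residues_per_helix)
    # antiparallel packing: alternate helix direction along z
    zdir <- if (h %% 2 == 1) 1 else -1
    x <- cx + spec$helix_radius * cos(phase + turn * (i - 1))
    y <- cy + spec$helix_radius * sin(phase + turn * (i - 1))
    z <- zdir * spec$rise * (i - 1) -
      zdir * spec$rise * (spec$residues_per_helix - 1) / 2
    rows[[h]] <- data.frame(
      serial = serial + i, name = "CA", element = "C", resname = "ALA",
      resno = resno + i, chain = "A", x = x, y = y, z = z, occ = 1,
      b = 20, type = "ATOM", stringsAsFactors = FALSE)
    serial <- serial + spec$residues_per_helix
    resno <- resno + spec$residues_per_helix
  }
  structure_model(do.call(rbind, rows), label = "synthetic-bundle")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

#' Build a P1 cell that packs a model with a fixed inter-image gap
#'
#' @param model A [structure_model()].
#' @param gap Closest-approach gap between lattice neighbours along each
#'   axis, angstroms (default 9).
#' @return A [unit_cell()].
#' @export
make_p1_cell <- function(model, gap = 9) {
  xyz <- coords(model)
  ext <- unname(apply(xyz, 2, max) - apply(xyz, 2, min))
  unit_cell(ext[1] + gap, ext[2] + gap, ext[3] + gap)
}

#' Specification of planted gas sites per class
#'
#' @param n_internal,n_surface,n_contact Per-class counts.
#' @param jitter Positional jitter sigma, angstroms (default 0.2).
#' @param element Gas element symbol (default `"KR"`).
#' @export
plant_site_spec <- function(n_internal = 0, n_surface = 0, n_contact = 0,
                            jitter = 0.2, element = "KR") {
  stopifnot(n_internal >= 0, n_surface >= 0, n_contact >= 0, jitter >= 0,
            element %in% GAS_ELEMENTS)
  structure(list(n_internal = n_internal, n_surface = n_surface,
                 n_contact = n_contact, jitter = jitter, element = element),
            class = "plant_site_spec")
}

# Fibonacci sphere of `n` points on radius r around centre
fib_sphere <- function(n, r, centre) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(centre[1] + r * cos(theta) * sin(phi),
        centre[2] + r * sin(theta) * sin(phi),
        centre[3] + r * cos(phi))
}

#' Plant gas sites with known class labels into a bundle model
#'
#' Surface sites go into inter-helix clefts on the bundle exterior (placed
#' so the nearest protein atom is 3.5 A away); internal sites sit at the
#' centre of sealed synthetic cages of pseudo-atoms added to the model;
#' crystal-contact sites are placed in the packing gap, within the contact
#' distance of a lattice image. The returned model carries the cage atoms
#' and (when contacts are requested) the P1 cell + identity operator set.
#'
#' @param model A bundle [structure_model()] (CA trace).
#' @param spec A [plant_site_spec()].
#' @param cell Optional [unit_cell()]; required for contact plants
#'   (defaults to [make_p1_cell()] when contacts are requested).
#' @param seed RNG seed for jitter and occupancies.
#' @return List with `sites` (data.frame id/element/x/y/z/occ/b/label),
#'   and `model` (augmented [structure_model()]).
#' @export
plant_sites <- function(model, spec = plant_site_spec(), cell = NULL,
                        seed = 1) {
  stopifnot(inherits(spec, "plant_site_spec"))
  old_seed <- .Random.seed_exists()
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  xyz <- coords(model)
  centre <- colMeans(xyz)
  atoms <- model$atoms
  sites <- list()
  jit <- function(p) p + stats::rnorm(3, 0, spec$jitter)

  if (spec$n_contact > 0 && is.null(cell)) cell <- make_p1_cell(model)

  # --- internal: sealed pseudo-atom cages around interior points ---------
  if (spec$n_internal > 0) {
    zspan <- range(xyz[, 3])
    if (spec$n_internal * 12 > diff(zspan) + 12)
      stop("no room for ", spec$n_internal, " internal cavities along the ",
           "bundle axis")
    zs <- seq(centre[3] - 6 * (spec$n_internal - 1),
              centre[3] + 6 * (spec$n_internal - 1),
              length.out = spec$n_internal)
    for (q in seq_len(spec$n_internal)) {
      p <- jit(c(centre[1], centre[2], zs[q]))
      cage <- fib_sphere(60, 4.0, p)
      atoms <- rbind(atoms, data.frame(
        serial = max(atoms$serial) + seq_len(nrow(cage)),
        name = sprintf("C%02d", seq_len(nrow(cage))),
        element = "C", resname = "CAG", resno = 9000 + q, chain = "X",
        x = cage[, 1], y = cage[, 2], z = cage[, 3], occ = 1, b = 20,
        type = "HETATM", stringsAsFactors = FALSE))
      sites[[length(sites) + 1]] <-
        c(p, stats::runif(1, 0.25, 0.5), stats::runif(1, 20, 35), 1)
    }
  }

  # --- surface: inter-helix clefts, nearest protein atom at 3.5 A --------
  if (spec$n_surface > 0) {
    angs <- seq(0, 2 * pi, length.out = 49)[-49]
    # prefer directions not facing a lattice neighbour along +/-x or +/-y
    face_penalty <- pmin(abs(cos(angs)), abs(sin(angs)))
    angs <- angs[order(face_penalty)]
    picked <- 0
    for (ang in angs) {
      if (picked >= spec$n_surface) break
      u <- c(cos(ang), sin(ang), 0)
      ztarget <- centre[3] + stats::runif(1, -3, 3)
      radial <- function(R) {
        p <- centre + u * R
        p[3] <- ztarget
        sqrt(min(cross_dist2(matrix(p, 1), xyz)))
      }
      # bracket the outermost crossing of clearance = 3.5 A (the bundle
      # core may be hollow, so scan outward first)
      scan <- seq(0, 40, by = 0.5)
      inside <- which(vapply(scan, radial, numeric(1)) < 3.5)
      if (!length(inside)) next
      lo <- scan[max(inside)]; hi <- 40
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (radial(mid) < 3.5) lo <- mid else hi <- mid
      }
      p <- centre + u * hi
      p[3] <- ztarget
      p <- jit(p)
      ok <- TRUE
      if (!is.null(cell)) {
        m2 <- model
        m2$atoms <- atoms
        m2$cell <- cell
        m2$symops <- list(symop_identity())
        ok <- nearest_symmetry_contact(m2, matrix(p, 1)) > 4.0 + 1.0
      }
      if (!ok) next
      picked <- picked + 1
      sites[[length(sites) + 1]] <-
        c(p, stats::runif(1, 0.2, 0.35), stats::runif(1, 25, 50), 2)
    }
    if (picked < spec$n_surface)
      stop("could not place ", spec$n_surface, " surface sites clear of ",
           "lattice contacts")
  }

  # --- crystal contacts: in the packing gap, 3.5 A from a lattice image --
  if (spec$n_contact > 0) {
    faces <- list(c(1, 1), c(1, -1), c(2, 1), c(2, -1), c(3, 1), c(3, -1))
    if (spec$n_contact > length(faces))
      stop("at most ", length(faces), " contact sites supported")
    edges <- c(cell$a, cell$b, cell$c)
    for (q in seq_len(spec$n_contact)) {
      axi <- faces[[q]][1]
      sgn <- faces[[q]][2]
      # closest-approach atom pair across this cell face
      shift <- c(0, 0, 0)
      shift[axi] <- sgn * edges[axi]
      img <- sweep(xyz, 2, shift, `+`)
      d2 <- cross_dist2(xyz, img)
      best <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      a0 <- xyz[best[1], ]
      a1 <- img[best[2], ]
      gapvec <- a1 - a0
      gaplen <- sqrt(sum(gapvec^2))
      # 3.0 A from the image atom: inside the 4 A contact cutoff with
      # headroom for the positional jitter
      p <- jit(a1 - gapvec / gaplen * 3.0)
      sites[[length(sites) + 1]] <-
        c(p, stats::runif(1, 0.15, 0.4), stats::runif(1, 25, 50), 3)
    }
  }

  labels <- c("internal", "surface", "crystal_contact")
  if (length(sites)) {
    m <- do.call(rbind, sites)
    site_df <- data.frame(id = seq_len(nrow(m)), element = spec$element,
                          x = m[, 1], y = m[, 2], z = m[, 3], occ = m[, 4],
                          b = m[, 5],
                          label = factor(labels[m[, 6]], levels = labels),
                          stringsAsFactors = FALSE)
  } else {
    site_df <- data.frame(id = integer(0), element = character(0),
                          x = numeric(0), y = numeric(0), z = numeric(0),
                          occ = numeric(0), b = numeric(0),
                          label = factor(character(0), levels = labels))
  }
  out_model <- structure_model(atoms, cell = cell,
                               symops = if (!is.null(cell))
                                 list(symop_identity()) else NULL,
                               label = model$label)
  list(sites = site_df, model = out_model)
}

#' Specification of a Gaussian-blob density grid
#'
#' Blob amplitudes are naturally expressed in units of the background noise
#' sigma so that threshold behaviour is known by construction.
#'
#' @param centres M x 3 matrix of blob centres, angstroms.
#' @param amplitudes Peak amplitude of each blob (atoms/voxel).
#' @param sigma Isotropic blob width, angstroms (default 1).
#' @param noise_sd Half-normal background noise scale (default 0).
#' @param spacing Grid spacing, angstroms (default 0.5).
#' @param box 2 x 3 `rbind(min, max)` sampling box; default pads the blob
#'   centres by 6 A (or a 10 A cube when there are no blobs).
#' @export
blob_grid_spec <- function(centres, amplitudes, sigma = 1, noise_sd = 0,
                           spacing = 0.5, box = NULL) {
  centres <- if (length(centres)) matrix(as.numeric(centres), ncol = 3)
    else matrix(numeric(0), ncol = 3)
  stopifnot(length(amplitudes) == nrow(centres), sigma > 0, noise_sd >= 0,
            spacing > 0)
  if (is.null(box)) {
    box <- if (nrow(centres))
      rbind(apply(centres, 2, min) - 6, apply(centres, 2, max) + 6)
    else rbind(c(0, 0, 0), c(10, 10, 10))
  }
  if (nrow(centres) && (any(sweep(centres, 2, box[1, ]) < 0) ||
                        any(sweep(centres, 2, box[2, ]) > 0)))
    stop("all blob centres must lie inside the box")
  structure(list(centres = centres, amplitudes = as.numeric(amplitudes),
                 sigma = sigma, noise_sd = noise_sd, spacing = spacing,
                 box = box), class = "blob_grid_spec")
}

#' Generate a Gaussian-blob density grid with half-normal background noise
#'
#' Values are `sum_m A_m exp(-|r - c_m|^2 / (2 sigma^2))` plus independent
#' per-voxel |N(0, noise_sd)| noise (half-normal, keeping the grid
#' non-negative; its mean is `noise_sd * sqrt(2/pi)`).
#'
#' @param spec A [blob_grid_spec()].
#' @param seed RNG seed for the noise.
#' @return List with `grid` (a [density_grid()]) and `truth` (data.frame
#'   of blob centres and amplitudes).
#' @export
make_blob_grid <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "blob_grid_spec"))
  old_seed <- .Random.seed_exists()
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  lo <- spec$box[1, ]
  dims <- as.integer(floor((spec$box[2, ] - lo) / spec$spacing)) + 1L
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 1) * spec$spacing)
  v <- array(0, dims)
  for (m in seq_len(nrow(spec$centres))) {
    cm <- spec$centres[m, ]
    gx <- exp(-(ax[[1]] - cm[1])^2 / (2 * spec$sigma^2))
    gy <- exp(-(ax[[2]] - cm[2])^2 / (2 * spec$sigma^2))
    gz <- exp(-(ax[[3]] - cm[3])^2 / (2 * spec$sigma^2))
    v <- v + spec$amplitudes[m] * outer(outer(gx, gy), gz)
  }
  if (spec$noise_sd > 0)
    v <- v + abs(array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims))
  truth <- data.frame(x = spec$centres[, 1], y = spec$centres[, 2],
                      z = spec$centres[, 3], amplitude = spec$amplitudes)
  list(grid = density_grid(v, origin = lo, spacing = spec$spacing),
       truth = truth)
}

#' Specification of a dwell/hop gas trajectory
#'
#' A gas atom dwells at a site and, at each frame, hops with probability
#' `1/mean_dwell` to a site drawn from the stationary weights (possibly
#' the one it already occupies), so the long-run occupancy equals the
#' normalized weights in expectation.
#'
#' @param sites M x 3 matrix of site positions.
#' @param weights Stationary site weights (normalized internally).
#' @param n_frames Number of frames (default 1000).
#' @param mean_dwell Mean dwell time in frames (default 20).
#' @param jitter Positional jitter sigma around the site, A (default 0.3).
#' @param n_gas Number of independent gas atoms (default 1).
#' @param wobble Apply a random rigid transform to each frame (exercises
#'   the alignment step; default TRUE).
#' @export
hop_trajectory_spec <- function(sites, weights = NULL, n_frames = 1000,
                                mean_dwell = 20, jitter = 0.3, n_gas = 1,
                                wobble = TRUE) {
  sites <- matrix(as.numeric(sites), ncol = 3)
  stopifnot(nrow(sites) >= 1, n_frames >= 1, mean_dwell >= 1, jitter >= 0,
            n_gas >= 1)
  if (is.null(weights)) weights <- rep(1, nrow(sites))
  stopifnot(length(weights) == nrow(sites), all(weights > 0))
  structure(list(sites = sites, weights = weights / sum(weights),
                 n_frames = n_frames, mean_dwell = mean_dwell,
                 jitter = jitter, n_gas = n_gas, wobble = wobble),
            class = "hop_trajectory_spec")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a dwell/hop gas trajectory around a protein model
#'
#' @param model A [structure_model()] whose CA atoms form the protein
#'   beads (falls back to all atoms when no CA present).
#' @param spec A [hop_trajectory_spec()].
#' @param seed RNG seed.
#' @return List with `traj` (a [trajectory_frames()]) and `truth`
#'   (per-site empirical occupancy fractions over all gas atoms).
#' @export
make_hop_trajectory <- function(model, spec, seed = 1) {
  stopifnot(inherits(spec, "hop_trajectory_spec"))
  old_seed <- .Random.seed_exists()
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  ca <- select_atoms(model, ca_only = TRUE)
  if (n_atoms(ca) == 0) ca <- model
  ref <- coords(ca)
  ns <- nrow(spec$sites)
  occ_counts <- numeric(ns)
  cur <- sample.int(ns, spec$n_gas, replace = TRUE, prob = spec$weights)
  frames <- vector("list", spec$n_frames)
  phop <- 1 / spec$mean_dwell
  for (f in seq_len(spec$n_frames)) {
    hop <- stats::runif(spec$n_gas) < phop
    if (any(hop))
      cur[hop] <- sample.int(ns, sum(hop), replace = TRUE,
                             prob = spec$weights)
    occ_counts <- occ_counts + tabulate(cur, ns)
    gas <- spec$sites[cur, , drop = FALSE] +
      matrix(stats::rnorm(3 * spec$n_gas, 0, spec$jitter), spec$n_gas, 3)
    prot <- ref
    if (spec$wobble) {
      rot <- random_rotation()
      tra <- stats::rnorm(3, 0, 2)
      prot <- apply_transform(ref, rot, tra)
      gas <- apply_transform(gas, rot, tra)
    }
    frames[[f]] <- list(protein = prot, gas = gas)
  }
  occ <- occ_counts / sum(occ_counts)
  list(traj = trajectory_frames(ref, frames, frame_interval = 1),
       truth = data.frame(site = seq_len(ns), weight = spec$weights,
                          occupancy = occ))
}
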