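# Peak detection on occupancy grids, matching of peaks to crystallographic
# gas sites, hierarchical clustering of peaks, and Boltzmann-relation
# binding free energies.

#' Detect local density maxima above mean + k * sigma
#'
#' A voxel is a peak iff its value exceeds the threshold `mean + k * std`
#' of the grid AND it is >= every in-grid voxel within Chebyshev radius
#' `window` (a cube of half-width `window` angstroms). Plateau ties are
#' resolved to the lexicographically smallest voxel index (by i, then j,
#' then k).
#'
#' @param grid A [density_grid()]; its spacing must not exceed `window`.
#' @param k Sigma multiplier for the detection threshold (default 5).
#' @param window Moving-window half-width in angstroms (default 2).
#' @return data.frame with columns `id`, `x`, `y`, `z` (voxel centre),
#'   `value`, `i`, `j`, `k` (voxel indices). Zero rows when nothing
#'   exceeds the threshold.
#' @export
detect_peaks <- function(grid, k = 5, window = 2) {
  if (grid$spacing > window)
    stop("grid spacing (", grid$spacing, " A) exceeds the window (",
         window, " A)")
  thr <- peak_threshold(grid, k)
  v <- grid$values
  dims <- grid$dims
  w <- as.integer(floor(window / grid$spacing + 1e-9))
  # sliding Chebyshev max: separable 1-D window max along each axis
  locmax <- v
  for (ax in 1:3) {
    shifted <- locmax
    for (off in seq_len(w)) {
      n <- dims[ax]
      idx_lo <- c(rep(1, off), seq_len(n - off))
      idx_hi <- c(seq_len(n - off) + off, rep(n, off))
      if (ax == 1)
        shifted <- pmax(shifted, locmax[idx_lo, , , drop = FALSE],
                        locmax[idx_hi, , , drop = FALSE])
      else if (ax == 2)
        shifted <- pmax(shifted, locmax[, idx_lo, , drop = FALSE],
                        locmax[, idx_hi, , drop = FALSE])
      else
        shifted <- pmax(shifted, locmax[, , idx_lo, drop = FALSE],
                        locmax[, , idx_hi, drop = FALSE])
    }
    locmax <- shifted
  }
  cand <- which(v > thr & v >= locmax, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), value = numeric(0), i = integer(0),
                      j = integer(0), k = integer(0)))
  }
  # plateau rule: a candidate survives iff it is the lexicographically
  # smallest (by i, then j, then k) among the equal-valued voxels of its
  # own window -- a local, order-independent tie-break
  ord <- order(cand[, 1], cand[, 2], cand[, 3])
  cand <- cand[ord, , drop = FALSE]
  keep <- vapply(seq_len(nrow(cand)), function(a) {
    i <- cand[a, 1]; j <- cand[a, 2]; kk <- cand[a, 3]
    ii <- max(1, i - w):min(dims[1], i + w)
    jj <- max(1, j - w):min(dims[2], j + w)
    kkk <- max(1, kk - w):min(dims[3], kk + w)
    ties <- which(v[ii, jj, kkk, drop = FALSE] == v[i, j, kk],
                  arr.ind = TRUE)
    tix <- cbind(ii[ties[, 1]], jj[ties[, 2]], kkk[ties[, 3]])
    first <- tix[order(tix[, 1], tix[, 2], tix[, 3])[1], ]
    all(first == c(i, j, kk))
  }, logical(1))
  cand <- cand[keep, , drop = FALSE]
  pos <- voxel_centre(grid, cand)
  data.frame(id = seq_len(nrow(cand)), x = pos[, 1], y = pos[, 2],
             z = pos[, 3], value = v[cand], i = cand[, 1], j = cand[, 2],
             k = cand[, 3])
}

#' Match density peaks to crystallographic gas sites
#'
#' Site-centric, non-exclusive matching: a site counts as an "atom match"
#' iff at least one peak lies within `cutoff` of it; one peak may match
#' several sites. Per-class tallies are reported when the sites carry a
#' `label` column (internal / surface / crystal_contact).
#'
#' @param peaks data.frame with `x`, `y`, `z` (from [detect_peaks()]).
#' @param sites data.frame with `x`, `y`, `z` and optionally `label`.
#' @param cutoff Match distance in angstroms (default 4).
#' @return List with `n_sites`, `n_matches`, `matched` (per-site logical),
#'   `peak_matched` (per-peak logical: within `cutoff` of any site),
#'   `per_class` (data.frame label/n_sites/n_matches) and `cutoff`.
#' @export
match_peaks <- function(peaks, sites, cutoff = 4) {
  stopifnot(cutoff > 0)
  ns <- nrow(sites)
  np <- nrow(peaks)
  if (ns == 0 || np == 0) {
    matched <- rep(FALSE, ns)
    peak_matched <- rep(FALSE, np)
  } else {
    d2 <- cross_dist2(as.matrix(sites[, c("x", "y", "z")]),
                      as.matrix(peaks[, c("x", "y", "z")]))
    matched <- apply(d2, 1, min) <= cutoff^2
    peak_matched <- apply(d2, 2, min) <= cutoff^2
  }
  per_class <- NULL
  if (ns > 0 && "label" %in% names(sites)) {
    per_class <- do.call(rbind, lapply(split(seq_len(ns), sites$label),
      function(idx) data.frame(label = sites$label[idx[1]],
                               n_sites = length(idx),
                               n_matches = sum(matched[idx]))))
    rownames(per_class) <- NULL
  }
  list(n_sites = ns, n_matches = sum(matched), matched = matched,
       peak_matched = peak_matched, per_class = per_class, cutoff = cutoff)
}

#' Agglomerative centroid-linkage clustering of peaks with a distance cutoff
#'
#' Greedy agglomeration: repeatedly merge the closest pair of cluster
#' centroids (ties broken by the smallest id pair) while the closest pair
#' is nearer than `cutoff`; centroids are recomputed as the mean of member
#' peak positions after each merge. Stops when all inter-centroid distances
#' are >= cutoff.
#'
#' @param peaks data.frame with `x`, `y`, `z` and `id` columns.
#' @param cutoff Merge cutoff between cluster centres in angstroms
#'   (default 5).
#' @return List of clusters, each with `members` (peak ids), `centre`
#'   (length-3) and `size`.
#' @export
cluster_peaks <- function(peaks, cutoff = 5) {
  np <- nrow(peaks)
  if (np == 0) return(list())
  ids <- if ("id" %in% names(peaks)) peaks$id else seq_len(np)
  pos <- as.matrix(peaks[, c("x", "y", "z")])
  members <- lapply(seq_len(np), function(i) ids[i])
  centres <- pos
  alive <- rep(TRUE, np)
  repeat {
    act <- which(alive)
    if (length(act) < 2) break
    cen <- centres[act, , drop = FALSE]
    d2 <- cross_dist2(cen, cen)
    diag(d2) <- Inf
    best <- min(d2)
    if (best >= cutoff^2 - 1e-12) break
    # smallest (row, col) pair among ties, row-major over original indices
    hit <- which(d2 <= best + 1e-12, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- act[hit[1, 1]]
    j <- act[hit[1, 2]]
    members[[i]] <- c(members[[i]], members[[j]])
    sel <- match(members[[i]], ids)
    centres[i, ] <- colMeans(pos[sel, , drop = FALSE])
    alive[j] <- FALSE
  }
  lapply(which(alive), function(i)
    list(members = sort(members[[i]]), centre = as.numeric(centres[i, ]),
         size = length(members[[i]])))
}

#' Count clusters with no matched member ("not present" in the model)
#'
#' @param clusters Output of [cluster_peaks()].
#' @param peak_matched Logical per-peak match flags aligned with the peak
#'   ids used for clustering (named by id or positional).
#' @param peak_ids Peak ids corresponding to `peak_matched` (defaults to
#'   `seq_along(peak_matched)`).
#' @return Integer count of clusters whose member peaks match no site.
#' @export
count_novel_clusters <- function(clusters, peak_matched,
                                 peak_ids = seq_along(peak_matched)) {
  if (!length(clusters)) return(0L)
  sum(vapply(clusters, function(cl) {
    !any(peak_matched[match(cl$members, peak_ids)])
  }, logical(1)))
}

#' Parameters for the Boltzmann free-energy relation
#'
#' @param temperature Temperature in kelvin (default 323.15).
#' @param reference_density Reference (bulk) density in atoms/voxel.
#' @param gas_constant Molar gas constant in J/mol/K.
#' @export
free_energy_params <- function(temperature = 323.15, reference_density,
                               gas_constant = 8.314462) {
  stopifnot(temperature > 0, reference_density > 0, gas_constant > 0)
  list(temperature = temperature, reference_density = reference_density,
       gas_constant = gas_constant)
}

#' Binding free energy from a density ratio (Boltzmann relation)
#'
#' `dG = -R T ln(rho_peak / rho_ref)`, in kJ/mol. A peak denser than the
#' bulk reference gives a negative (favourable) free energy.
#'
#' @param peak_density Peak density in atoms/voxel (> 0); vectorized.
#' @param params A [free_energy_params()] list.
#' @return Free energy (kJ/mol).
#' @export
binding_free_energy <- function(peak_density, params) {
  if (any(peak_density <= 0))
    stop("peak density must be positive for the Boltzmann relation")
  -params$gas_constant * params$temperature *
    log(peak_density / params$reference_density) / 1000
}

#' Table-style correspondence report between peaks and gas sites
#'
#' Bundles the peak/site correspondence into one report: total sites,
#' matches (overall and per class), peak count, cluster count and the
#' number of clusters absent from the crystallographic model.
#'
#' @param peaks Output of [detect_peaks()].
#' @param sites Site table with `x`, `y`, `z` and optionally `label`.
#' @param match_cutoff Site-peak match distance, angstroms (default 4).
#' @param cluster_cutoff Centroid merge cutoff, angstroms (default 5).
#' @return List mirroring the correspondence-table semantics:
#'   `noble_gas_atoms`, `matches`, `per_class_matches`,
#'   `n_peaks`, `n_clusters`, `clusters_not_present`.
#' @export
match_report <- function(peaks, sites, match_cutoff = 4, cluster_cutoff = 5) {
  mm <- match_peaks(peaks, sites, cutoff = match_cutoff)
  cl <- cluster_peaks(peaks, cutoff = cluster_cutoff)
  ids <- if (nrow(peaks)) peaks$id else integer(0)
  novel <- count_novel_clusters(cl, mm$peak_matched, peak_ids = ids)
  list(noble_gas_atoms = mm$n_sites,
       matches = mm$n_matches,
       per_class_matches = mm$per_class,
       n_peaks = nrow(peaks),
       n_clusters = length(cl),
       clusters_not_present = novel,
       clusters = cl)
}
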