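# End-to-end orchestration: structure + gas sites + density map (or
# trajectory frames) -> site classification, peak detection, matching,
# clustering, binding free energies and the ENM fluctuation difference,
# with a machine-readable JSON report and TSV tables.

#' Assemble a validated pipeline configuration
#'
#' Every threshold defaults to the value used throughout the analysis:
#' peak threshold multiplier 5 sigma, 2 A peak window, 4 A site-peak match
#' cutoff, 5 A cluster cutoff, 4 A crystal-contact cutoff, 15 A elastic
#' network cutoff, 323.15 K.
#'
#' @param model Path to a PDB/mmCIF file or a [structure_model()].
#' @param sites Optional site table (data.frame or TSV path with columns
#'   id, element, x, y, z, occ, b); when `NULL`, gas atoms are extracted
#'   from the model by element.
#' @param map Optional density map (path or [density_grid()]).
#' @param frames Optional [trajectory_frames()] to accumulate a map from
#'   when `map` is absent.
#' @param gas_element Gas element to extract from the model
#'   (default: first of `AR`, `KR`, `XE` found).
#' @param k,window Peak detection threshold multiplier and window (A).
#' @param match_cutoff,cluster_cutoff Peak matching / clustering cutoffs (A).
#' @param contact_cutoff Crystal-contact distance (A).
#' @param enm_cutoff Elastic-network cutoff (A).
#' @param temperature Temperature for the Boltzmann relation (K).
#' @param reference_density Reference density, atoms/voxel; `NULL` uses
#'   the map mean.
#' @param spacing Accumulation grid spacing (A).
#' @param seed RNG seed recorded in the provenance block.
#' @param outdir Optional output directory for report.json and TSVs.
#' @return A `run_config` list.
#' @export
run_config <- function(model, sites = NULL, map = NULL, frames = NULL,
                       gas_element = NULL, k = 5.0, window = 2.0,
                       match_cutoff = 4.0, cluster_cutoff = 5.0,
                       contact_cutoff = 4.0, enm_cutoff = 15.0,
                       temperature = 323.15, reference_density = NULL,
                       spacing = 0.5, seed = 1, outdir = NULL) {
  cfg <- list(model = model, sites = sites, map = map, frames = frames,
              gas_element = gas_element, k = k, window = window,
              match_cutoff = match_cutoff, cluster_cutoff = cluster_cutoff,
              contact_cutoff = contact_cutoff, enm_cutoff = enm_cutoff,
              temperature = temperature,
              reference_density = reference_density, spacing = spacing,
              seed = seed, outdir = outdir)
  stopifnot(k > 0, window > 0, match_cutoff > 0, cluster_cutoff > 0,
            contact_cutoff > 0, enm_cutoff > 0, temperature > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; relative input paths are resolved against
#' the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (key in c("model", "sites", "map")) {
    if (!is.null(y[[key]]) && is.character(y[[key]]) &&
        !file.exists(y[[key]]))
      y[[key]] <- file.path(dirname(path), y[[key]])
  }
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

pipeline_log <- function(fmt, ...) message(sprintf(paste0("[gasbind] ", fmt), ...))

#' Run the full gas-binding analysis pipeline
#'
#' Stages, in order: classify gas sites -> detect density peaks -> match
#' peaks to sites -> cluster peaks -> Boltzmann binding free energies ->
#' elastic-network fluctuation difference. Per-stage counts are logged to
#' stderr; when `outdir` is set, `report.json`, `sites.tsv`, `peaks.tsv`,
#' `clusters.tsv` and `fluct.tsv` are written (no timestamps, so repeated
#' runs are byte-identical).
#'
#' @param config A [run_config()] or a path to a YAML config file.
#' @return The analysis report (list), invisibly also written to disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  model <- stage("read_structure", {
    if (inherits(config$model, "structure_model")) config$model
    else read_structure(config$model)
  })
  checksums <- list()
  for (key in c("model", "sites", "map")) {
    if (is.character(config[[key]]) && file.exists(config[[key]]))
      checksums[[key]] <- unname(tools::md5sum(config[[key]]))
  }

  sites <- stage("load_sites", {
    if (is.null(config$sites)) {
      el <- config$gas_element
      if (is.null(el)) {
        present <- GAS_ELEMENTS[GAS_ELEMENTS %in% model$atoms$element]
        if (!length(present))
          stop("no noble-gas atoms (", paste(GAS_ELEMENTS, collapse = "/"),
               ") in the model and no site table supplied")
        el <- present[1]
      }
      ga <- select_atoms(model, element = el)$atoms
      data.frame(id = seq_len(nrow(ga)), element = ga$element, x = ga$x,
                 y = ga$y, z = ga$z, occ = ga$occ, b = ga$b)
    } else if (is.character(config$sites)) {
      utils::read.delim(config$sites, stringsAsFactors = FALSE)
    } else as.data.frame(config$sites)
  })

  classified <- stage("classify", {
    classify_sites(model, sites, contact_cutoff = config$contact_cutoff)
  })
  groups <- summarize_groups(classified)
  pipeline_log("classify: %d sites (%s)", nrow(classified),
               paste(groups$n[1:3], collapse = "/"))

  grid <- stage("density_map", {
    if (!is.null(config$map)) {
      if (inherits(config$map, "density_grid")) config$map
      else read_map(config$map)
    } else if (!is.null(config$frames)) {
      accumulate_density(config$frames, spacing = config$spacing)
    } else NULL
  })

  report <- list(
    group_summary = groups,
    sites = classified)
  peaks <- NULL
  if (!is.null(grid)) {
    peaks <- stage("peaks", detect_peaks(grid, k = config$k,
                                         window = config$window))
    pipeline_log("peaks: %d above mean + %g sigma", nrow(peaks), config$k)
    corr <- stage("match_cluster", {
      s2 <- classified
      match_report(peaks, s2, match_cutoff = config$match_cutoff,
                   cluster_cutoff = config$cluster_cutoff)
    })
    pipeline_log("match: %d/%d sites matched, %d clusters, %d not present",
                 corr$matches, corr$noble_gas_atoms, corr$n_clusters,
                 corr$clusters_not_present)
    dg <- stage("free_energy", {
      ref <- config$reference_density
      if (is.null(ref)) ref <- grid_stats(grid)$mean
      if (nrow(peaks) && ref > 0) {
        params <- free_energy_params(temperature = config$temperature,
                                     reference_density = ref)
        data.frame(peak_id = peaks$id,
                   dg_kj_mol = binding_free_energy(peaks$value, params),
                   reference_density = ref)
      } else NULL
    })
    report$correspondence <- corr[c("noble_gas_atoms", "matches", "n_peaks",
                                    "n_clusters", "clusters_not_present")]
    report$per_class_matches <- corr$per_class_matches
    report$clusters <- corr$clusters
    report$free_energy <- dg
  }

  fluct <- stage("enm", {
    fluctuation_difference(model, classified, cutoff = config$enm_cutoff)
  })
  pipeline_log("enm: %d residues, mean delta %.4g", nrow(fluct),
               mean(fluct$delta))
  report$enm <- list(n_residues = nrow(fluct),
                     min_delta = min(fluct$delta),
                     mean_delta = mean(fluct$delta))
  report$fluctuations <- fluct
  report$provenance <- list(
    package = "gasbind",
    version = as.character(utils::packageVersion("gasbind")),
    config = config[c("k", "window", "match_cutoff", "cluster_cutoff",
                      "contact_cutoff", "enm_cutoff", "temperature",
                      "spacing", "seed")],
    checksums = checksums)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, peaks, config$outdir)
  }
  invisible(report)
}

write_report <- function(report, peaks, outdir) {
  json <- report
  json$sites <- NULL
  json$fluctuations <- NULL
  json$clusters <- lapply(report$clusters, function(cl)
    list(members = cl$members, centre = cl$centre, size = cl$size))
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  wt <- function(df, f) utils::write.table(
    df, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$sites, "sites.tsv")
  if (!is.null(peaks)) wt(peaks, "peaks.tsv")
  if (length(report$clusters)) {
    cdf <- do.call(rbind, lapply(seq_along(report$clusters), function(i) {
      cl <- report$clusters[[i]]
      data.frame(cluster = i, x = cl$centre[1], y = cl$centre[2],
                 z = cl$centre[3], size = cl$size,
                 members = paste(cl$members, collapse = ","))
    }))
    wt(cdf, "clusters.tsv")
  }
  wt(report$fluctuations, "fluct.tsv")
  invisible(outdir)
}
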