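#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline in one object that round-trips
#' losslessly to YAML.
#'
#' @param ensemble path to the multi-model PDB ensemble.
#' @param labels path to a CSV with a `label` column (0/1 per frame, frame
#'   order).
#' @param workdir directory where every intermediate artifact is written.
#' @param site a `ph4_site`, or a list (`mode`, then `resno`/`chain` or
#'   `points`/`cutoff`) as parsed from YAML.
#' @param superpose_site optional separate site for the superposition fit
#'   (defaults to `site`).
#' @param cluster_radius consensus clustering radius, Angstrom.
#' @param band `c(low, high)` frequency band or `NULL` for no threshold.
#' @param k per-method top-k for voting.
#' @param feature_ids optional manual query override (consensus ids).
#' @param library optional SDF library path for the screening stage.
#' @param activity_tag SD tag with the activity class.
#' @param tolerance match tolerance, Angstrom.
#' @param seed RNG seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return list of class `ph4_config`.
#' @export
run_config <- function(ensemble, labels, workdir, site,
                       superpose_site = NULL, cluster_radius = 1.5,
                       band = NULL, k = 8L, feature_ids = NULL,
                       library = NULL, activity_tag = "ACTIVITY",
                       tolerance = 0, seed = 1L) {
  if (!is.null(band)) {
    if (length(band) != 2L || band[1] > band[2])
      stop("band must be c(low, high) with low <= high")
  }
  if (cluster_radius <= 0) stop("cluster_radius must be > 0")
  structure(list(ensemble = ensemble, labels = labels, workdir = workdir,
                 site = site, superpose_site = superpose_site,
                 cluster_radius = cluster_radius, band = band,
                 k = as.integer(k), feature_ids = feature_ids,
                 library = library, activity_tag = activity_tag,
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "ph4_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$site <- site_to_list(obj$site)
  if (!is.null(obj$superpose_site))
    obj$superpose_site <- site_to_list(obj$superpose_site)
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname run_config
#' @param config a `ph4_config` (for writing).
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$site <- site_from_list(obj$site)
  if (!is.null(obj$superpose_site))
    obj$superpose_site <- site_from_list(obj$superpose_site)
  do.call(run_config, obj)
}

site_to_list <- function(site) {
  if (!inherits(site, "ph4_site")) return(site)
  if (site$mode == "residue_list")
    list(mode = "residue_list", resno = site$residues$resno,
         chain = site$residues$chain)
  else
    list(mode = "ligand_proximity",
         points = lapply(seq_len(nrow(site$points)), function(i)
           as.numeric(site$points[i, ])),
         cutoff = site$cutoff)
}

site_from_list <- function(x) {
  if (inherits(x, "ph4_site")) return(x)
  if (x$mode == "residue_list")
    site_residues(unlist(x$resno), chain = unlist(x$chain))
  else
    site_proximity(do.call(rbind, lapply(x$points, as.numeric)),
                   cutoff = x$cutoff)
}

# polynomial rolling hash over the config YAML text, for provenance
# stamping (not cryptographic)
config_hash <- function(config) {
  txt <- yaml::as.yaml(site_strip(config), precision = 17L)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
site_strip <- function(config) {
  obj <- unclass(config)
  obj$site <- site_to_list(obj$site)
  if (!is.null(obj$superpose_site))
    obj$superpose_site <- site_to_list(obj$superpose_site)
  obj
}

#' Run the full pipeline, materializing every intermediate artifact
#'
#' Superpose -> perceive site features -> consensus clustering -> binary
#' encoding -> frequency band -> rank-and-vote -> query -> library screen
#' -> enrichment report. Each stage writes its artifact into `workdir`
#' (`aligned.pdb`, `features.json`, `occurrence.csv`, `votes.csv`,
#' `query.json`, `hits.sdf`, `hits.csv`, `report.json`) so any stage is
#' independently auditable; the report is stamped with the config hash
#' and seed, and rerunning an identical config reproduces identical
#' outputs. Stages after voting are skipped (and reported `NA`) when no
#' valid query can be built or no library is configured.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage count logging.
#' @return list: per-stage objects plus `summary` (also written as
#'   `report.json`).
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "ph4_config"))
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  art <- function(f) file.path(config$workdir, f)

  ens <- read_ensemble(config$ensemble)
  labels <- utils::read.csv(config$labels)$label
  site <- site_from_list(config$site)
  sup_site <- if (is.null(config$superpose_site)) site
              else site_from_list(config$superpose_site)
  say("ensemble: ", n_frames(ens), " frames x ", n_atoms(ens), " atoms")

  ens <- superpose_ensemble(ens, sup_site)
  write_ensemble(ens, art("aligned.pdb"))

  sf <- perceive_site(ens, site)
  write_features_json(sf, art("features.json"))
  say("features perceived: ",
      sum(vapply(sf, nrow, integer(1))), " across ", length(sf), " frames")

  cons <- build_consensus(sf, cluster_radius = config$cluster_radius)
  occ <- encode_binary(cons, labels)
  say("consensus features: ", nrow(cons$features))
  if (!is.null(config$band))
    occ <- threshold_by_frequency(occ, low = config$band[1],
                                  high = config$band[2])
  write_occurrence_csv(occ, art("occurrence.csv"))
  say("columns after band: ", ncol(occ$matrix))

  votes <- rank_and_vote(occ, k = config$k)
  utils::write.csv(votes, art("votes.csv"), row.names = FALSE)
  say("selected by vote: ", sum(votes$selected))

  query <- NULL; screen <- NULL; report <- NULL
  sel_ids <- if (!is.null(config$feature_ids)) config$feature_ids
             else votes$feature_id[votes$selected]
  if (length(sel_ids) >= 3L) {
    query <- build_query(occ, feature_ids = sel_ids)
    write_query(query, art("query.json"))
    if (!is.null(config$library)) {
      lib <- read_ligand_library(config$library,
                                 activity_tag = config$activity_tag)
      screen <- search_library(query, lib, tolerance = config$tolerance)
      utils::write.csv(screen$results, art("hits.csv"), row.names = FALSE)
      write_hits_sdf(screen, lib, art("hits.sdf"))
      report <- screening_report(screen)
      say("hits: ", length(report$active_hits), " actives / ",
          length(report$decoy_hits), " decoys; EF = ",
          format(report$ef, digits = 4), " (", report$flag, ")")
    }
  } else {
    say("no valid query (", length(sel_ids), " selected features)")
  }

  summary <- list(
    config_hash = config_hash(config), seed = config$seed,
    n_frames = n_frames(ens), n_consensus = nrow(cons$features),
    n_banded = ncol(occ$matrix), n_selected = length(sel_ids),
    query_features = if (is.null(query)) NULL else query$features$id,
    active_hits = if (is.null(report)) NA_integer_
                  else report$counts$active_hits,
    decoy_hits = if (is.null(report)) NA_integer_
                 else report$counts$decoy_hits,
    ef = if (is.null(report)) NA_real_ else report$ef,
    ef_flag = if (is.null(report)) "NA" else report$flag)
  jsonlite::write_json(summary, art("report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(list(ensemble = ens, site_features = sf, consensus = cons,
                 occurrence = occ, votes = votes, query = query,
                 screen = screen, report = report, summary = summary))
}

#' Sweep frequency bands and top-k cuts
#'
#' Runs the banding + voting + query + screening tail of the pipeline
#' over a grid of bands and k values, reusing one consensus build. Rows
#' where no query can be built, or where nothing hits, carry `NA`
#' enrichment, and the best row by EF is flagged.
#'
#' @param config a [run_config()]; its own `band`/`k` are ignored.
#' @param bands list of `c(low, high)` pairs and/or `NULL` (no
#'   threshold).
#' @param ks integer vector of per-method top-k cuts.
#' @return data.frame: `band_low`, `band_high`, `k`, `n_features`,
#'   `n_selected`, `active_hits`, `decoy_hits`, `ef`, `ef_flag`, `best`.
#' @export
band_sweep <- function(config, bands, ks) {
  stopifnot(inherits(config, "ph4_config"))
  if (length(bands) == 0L || length(ks) == 0L) stop("empty sweep grid")
  ens <- superpose_ensemble(
    read_ensemble(config$ensemble),
    if (is.null(config$superpose_site)) site_from_list(config$site)
    else site_from_list(config$superpose_site))
  labels <- utils::read.csv(config$labels)$label
  sf <- perceive_site(ens, site_from_list(config$site))
  cons <- build_consensus(sf, cluster_radius = config$cluster_radius)
  occ_full <- encode_binary(cons, labels)
  lib <- if (!is.null(config$library))
    read_ligand_library(config$library, activity_tag = config$activity_tag)
  rows <- list()
  for (band in bands) for (k in ks) {
    occ <- if (is.null(band)) occ_full
           else threshold_by_frequency(occ_full, band[1], band[2])
    n_feat <- ncol(occ$matrix)
    row <- data.frame(
      band_low = if (is.null(band)) NA_real_ else band[1],
      band_high = if (is.null(band)) NA_real_ else band[2],
      k = k, n_features = n_feat, n_selected = NA_integer_,
      active_hits = NA_integer_, decoy_hits = NA_integer_,
      ef = NA_real_, ef_flag = "NA")
    ok <- tryCatch({
      votes <- rank_and_vote(occ, k = k)
      sel <- votes$feature_id[votes$selected]
      row$n_selected <- length(sel)
      if (length(sel) >= 3L && !is.null(lib)) {
        query <- build_query(occ, feature_ids = sel)
        screen <- search_library(query, lib,
                                 tolerance = config$tolerance)
        rep <- screening_report(screen)
        row$active_hits <- rep$counts$active_hits
        row$decoy_hits <- rep$counts$decoy_hits
        row$ef <- rep$ef
        row$ef_flag <- rep$flag
      }
      TRUE
    }, error = function(e) FALSE)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  finite <- is.finite(out$ef)
  out$best <- FALSE
  if (any(out$ef_flag == "no-decoy-hits")) {
    out$best[which(out$ef_flag == "no-decoy-hits")[1]] <- TRUE
  } else if (any(finite) && max(out$ef[finite]) > 0) {
    out$best[which(finite)[which.max(out$ef[finite])]] <- TRUE
  }
  out
}
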