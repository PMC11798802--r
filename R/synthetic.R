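# class label -> probe residue name used in synthetic pockets
PROBE_RESID <- c("Don" = "DON", "Acc" = "ACC", "Cat" = "CAT",
                 "Ani" = "ANI", "Aro" = "ARO", "Hyd" = "HYD",
                 "Don|Acc" = "DOA", "Aro|PiR" = "PIR")

#' Specification of a synthetic conformational ensemble
#'
#' Describes a pocket of inert pseudo-atoms jittered across frames, a
#' minority of "binding" frames, planted features whose occurrence is
#' label dependent, and nuisance features at assorted frequencies. The
#' defaults are the study conditions the validation suite exercises: 200
#' frames, a 10% binding fraction, planted features present in 90% of
#' binding frames and 5% of the rest, nuisance features spanning rare to
#' ubiquitous.
#'
#' @param n_frames number of conformations.
#' @param n_site_atoms inert pocket pseudo-atoms.
#' @param binding_fraction fraction of binding-selected frames (0, 1).
#' @param jitter_sigma per-atom, per-frame Gaussian jitter, Angstrom.
#' @param planted data.frame `class`, `x`, `y`, `z`, `freq_binding`,
#'   `freq_nonbinding`; `NULL` for the default 4-feature arrangement.
#' @param nuisance data.frame `class`, `x`, `y`, `z`, `freq`; `NULL`
#'   for the default 6-feature arrangement.
#' @param seed RNG seed (integer).
#' @return list of class `ph4_ensemble_spec`.
#' @export
ensemble_spec <- function(n_frames = 200L, n_site_atoms = 20L,
                          binding_fraction = 0.1, jitter_sigma = 0.1,
                          planted = NULL, nuisance = NULL, seed = 1L) {
  if (binding_fraction <= 0 || binding_fraction >= 1)
    stop("binding_fraction must be in (0, 1)")
  if (binding_fraction * n_frames < 1)
    stop("binding_fraction * n_frames must be >= 1")
  if (is.null(planted))
    planted <- data.frame(
      class = c("Don", "Acc", "Aro", "Hyd"),
      x = c(4, -4, 0, 0), y = c(0, 0, 4, -4), z = c(2, 2, -2, -2),
      freq_binding = 0.9, freq_nonbinding = 0.05)
  if (is.null(nuisance))
    nuisance <- data.frame(
      class = c("Don", "Acc", "Hyd", "Aro", "Don|Acc", "Cat"),
      x = c(6, -6, 6, -6, 0, 3), y = c(6, -6, -6, 6, 6, -6),
      z = c(0, 0, 3, 3, -3, -3),
      freq = c(0.02, 0.08, 0.15, 0.30, 0.60, 0.95))
  bad <- c(planted$freq_binding, planted$freq_nonbinding, nuisance$freq)
  if (any(bad < 0 | bad > 1)) stop("feature frequencies must be in [0, 1]")
  if (!all(c(planted$class, nuisance$class) %in% names(PROBE_RESID)))
    stop("unsupported feature class for a probe residue")
  structure(list(n_frames = as.integer(n_frames),
                 n_site_atoms = as.integer(n_site_atoms),
                 binding_fraction = binding_fraction,
                 jitter_sigma = jitter_sigma, planted = planted,
                 nuisance = nuisance, seed = as.integer(seed)),
            class = "ph4_ensemble_spec")
}

#' Generate a synthetic conformational ensemble with planted features
#'
#' Pocket pseudo-atoms (residue `PKT`, untyped by the rule table) are
#' placed uniformly in a 12 A box and jittered i.i.d. per frame. Each
#' planted/nuisance feature is one probe residue whose single atom is
#' typed directly by the rule table; per frame the probe is either at its
#' nominal position (+ jitter) or displaced far outside the site (+999 A
#' in x), realizing a Bernoulli occupancy at the spec'd frequency. Labels
#' mark a seeded random subset of `ceiling(binding_fraction * n)` frames
#' as binding-selected. The returned ground truth records the exact
#' per-frame draws so downstream frequencies are checkable bit-exactly.
#'
#' The perception site is returned as a proximity site around the pocket
#' (displaced probes fall outside it); superposition should use the
#' returned `superpose_site` (the stable pocket residues only).
#'
#' @param spec an [ensemble_spec()].
#' @return list: `ensemble` ([ph4_ensemble()]), `labels` (0/1 per frame),
#'   `truth` (list `features` incl. roles and positions, `occupancy`
#'   frames x features 0/1 matrix), `site`, `superpose_site`.
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ph4_ensemble_spec"))
  set.seed(spec$seed)
  nfr <- spec$n_frames
  npk <- spec$n_site_atoms
  feats <- rbind(
    data.frame(class = spec$planted$class, x = spec$planted$x,
               y = spec$planted$y, z = spec$planted$z,
               role = "planted", freq_binding = spec$planted$freq_binding,
               freq_nonbinding = spec$planted$freq_nonbinding),
    data.frame(class = spec$nuisance$class, x = spec$nuisance$x,
               y = spec$nuisance$y, z = spec$nuisance$z,
               role = "nuisance", freq_binding = spec$nuisance$freq,
               freq_nonbinding = spec$nuisance$freq))
  nft <- nrow(feats)
  pocket <- matrix(stats::runif(npk * 3, -6, 6), ncol = 3)
  n_bind <- ceiling(spec$binding_fraction * nfr)
  labels <- integer(nfr)
  labels[sample.int(nfr, n_bind)] <- 1L
  # per-frame Bernoulli occupancy at the label-conditional frequency
  occupancy <- matrix(0L, nfr, nft)
  for (j in seq_len(nft)) {
    p <- ifelse(labels == 1L, feats$freq_binding[j],
                feats$freq_nonbinding[j])
    occupancy[, j] <- as.integer(stats::runif(nfr) < p)
  }
  natoms <- npk + nft
  xyz <- matrix(NA_real_, nfr, 3L * natoms)
  base <- rbind(pocket, as.matrix(feats[, c("x", "y", "z")]))
  for (i in seq_len(nfr)) {
    crd <- base + matrix(stats::rnorm(natoms * 3, 0, spec$jitter_sigma),
                         ncol = 3)
    off <- which(occupancy[i, ] == 0L)
    crd[npk + off, 1] <- crd[npk + off, 1] + 999
    xyz[i, ] <- as.vector(t(crd))
  }
  atoms <- data.frame(
    elety = c(rep("C", npk), rep("X", nft)),
    resid = c(rep("PKT", npk), PROBE_RESID[feats$class]),
    resno = seq_len(natoms),
    chain = "A",
    elesy = "C")
  ens <- ph4_ensemble(xyz, atoms)
  ctr <- colMeans(pocket)
  reach <- max(sqrt(rowSums(sweep(base, 2, ctr)^2)))
  site <- site_proximity(matrix(ctr, 1), cutoff = reach + 2)
  list(ensemble = ens, labels = labels,
       truth = list(features = feats, occupancy = occupancy,
                    pocket = pocket),
       site = site,
       superpose_site = site_residues(seq_len(npk), chain = "A"),
       spec = spec)
}

#' Specification of a synthetic active/decoy conformer library
#'
#' @param query a `ph4_query` the actives are built to match.
#' @param n_actives,n_decoys molecule counts.
#' @param conformers_per_molecule conformers per molecule (<= 100).
#' @param active_jitter radius of the uniform displacement applied to the
#'   matching conformer's points, Angstrom; at tolerance >=
#'   `active_jitter` every active is guaranteed to match.
#' @param decoy_mode `"drop-one"` (each decoy conformer omits one
#'   required feature point) or `"scramble"` (points at random positions).
#' @param extra_points optional data.frame (`class`, `x`, `y`, `z`) of
#'   additional annotation points every molecule carries (e.g. the
#'   pocket's nuisance-feature complement); decoys never drop these.
#' @param seed RNG seed.
#' @return list of class `ph4_library_spec`.
#' @export
library_spec <- function(query, n_actives = 50L, n_decoys = 500L,
                         conformers_per_molecule = 5L,
                         active_jitter = 0.3,
                         decoy_mode = c("drop-one", "scramble"),
                         extra_points = NULL, seed = 7L) {
  stopifnot(inherits(query, "ph4_query"))
  decoy_mode <- match.arg(decoy_mode)
  if (n_actives < 1L || n_decoys < 0L || conformers_per_molecule < 1L)
    stop("counts must be >= 1 (decoys may be 0)")
  if (conformers_per_molecule > 100L)
    stop("at most 100 conformers per molecule")
  if (active_jitter > min(query$features$radius))
    warning("active_jitter exceeds the smallest feature radius; ",
            "actives may legitimately fail at zero tolerance")
  structure(list(query = query, n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 conformers_per_molecule =
                   as.integer(conformers_per_molecule),
                 active_jitter = active_jitter, decoy_mode = decoy_mode,
                 extra_points = extra_points, seed = as.integer(seed)),
            class = "ph4_library_spec")
}

# uniform point in a sphere of radius r
runif_sphere <- function(n, r) {
  v <- matrix(stats::rnorm(n * 3), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v * r * stats::runif(n)^(1 / 3)
}

rigid_scatter <- function(points) {
  R <- random_rotation()
  sweep(points %*% t(R), 2, stats::runif(3, -20, 20), `+`)
}

#' Generate a synthetic active/decoy multi-conformer library
#'
#' Every active gets one conformer whose annotation points sit within
#' `active_jitter` of the query centers (after a random rigid motion, so
#' matching must be rigid-invariant to find it) plus decoy-like filler
#' conformers. Every decoy conformer misses at least one required feature
#' (`drop-one`) or scrambles the geometry. Pseudo-atoms carry their
#' feature class explicitly (the `FEATURE_CLASSES` SD tag on disk);
#' matching consumes annotation points, not chemistry.
#'
#' @param spec a [library_spec()].
#' @return list: `library` ([ph4_library()]), `truth` data.frame
#'   (`molecule_id`, `activity`, `must_match`).
#' @export
make_library <- function(spec) {
  stopifnot(inherits(spec, "ph4_library_spec"))
  set.seed(spec$seed)
  qf <- spec$query$features
  nq <- nrow(qf)
  qxyz <- as.matrix(qf[, c("x", "y", "z")])
  extra <- spec$extra_points
  ne <- if (is.null(extra)) 0L else nrow(extra)
  all_xyz <- rbind(qxyz,
                   if (ne > 0L) as.matrix(extra[, c("x", "y", "z")]))
  all_cls <- c(qf$class, if (ne > 0L) extra$class)
  chain_bonds <- function(n) {
    if (n < 2L) return(data.frame(a = integer(), b = integer(),
                                  order = integer()))
    data.frame(a = seq_len(n - 1L), b = 2:n, order = 1L)
  }
  scramble_conf <- function() {
    nn <- nq + ne
    pos <- matrix(stats::runif(nn * 3, -8, 8), ncol = 3)
    list(coords = pos, elem = rep("C", nn), bonds = chain_bonds(nn),
         classes = all_cls)
  }
  drop_one_conf <- function() {
    drop <- sample.int(nq, 1L)          # always drops a *required* feature
    keep <- setdiff(seq_len(nq + ne), drop)
    pos <- rigid_scatter(all_xyz[keep, , drop = FALSE] +
                           runif_sphere(length(keep), spec$active_jitter))
    list(coords = pos, elem = rep("C", length(keep)),
         bonds = chain_bonds(length(keep)), classes = all_cls[keep])
  }
  mols <- list()
  for (i in seq_len(spec$n_actives)) {
    confs <- list()
    good_at <- sample.int(spec$conformers_per_molecule, 1L)
    for (ci in seq_len(spec$conformers_per_molecule)) {
      if (ci == good_at) {
        nn <- nq + ne
        pos <- rigid_scatter(all_xyz + runif_sphere(nn, spec$active_jitter))
        confs[[ci]] <- list(coords = pos, elem = rep("C", nn),
                            bonds = chain_bonds(nn), classes = all_cls)
      } else {
        confs[[ci]] <- if (spec$decoy_mode == "drop-one") drop_one_conf()
                       else scramble_conf()
      }
    }
    # pad shorter (drop-one) conformers so all share one atom count
    nmax <- max(vapply(confs, function(cf) nrow(cf$coords), integer(1)))
    confs <- lapply(confs, pad_conformer, nmax = nmax)
    mols[[length(mols) + 1L]] <- list(
      id = sprintf("A%04d", i), activity = "active", conformers = confs)
  }
  for (i in seq_len(spec$n_decoys)) {
    confs <- lapply(seq_len(spec$conformers_per_molecule), function(ci)
      if (spec$decoy_mode == "drop-one") drop_one_conf()
      else scramble_conf())
    nmax <- max(vapply(confs, function(cf) nrow(cf$coords), integer(1)))
    confs <- lapply(confs, pad_conformer, nmax = nmax)
    mols[[length(mols) + 1L]] <- list(
      id = sprintf("D%04d", i), activity = "decoy", conformers = confs)
  }
  lib <- ph4_library(mols)
  truth <- data.frame(
    molecule_id = vapply(mols, `[[`, "", "id"),
    activity = vapply(mols, `[[`, "", "activity"))
  truth$must_match <- truth$activity == "active"
  list(library = lib, truth = truth)
}

# pad a conformer with inert far-away atoms so conformers of one molecule
# share an atom count (SDF-level invariant); padded atoms are untyped
pad_conformer <- function(cf, nmax) {
  n <- nrow(cf$coords)
  if (n >= nmax) return(cf)
  extra <- nmax - n
  cf$coords <- rbind(cf$coords,
                     matrix(rep(c(500, 500, 500), extra), ncol = 3,
                            byrow = TRUE) +
                       matrix(stats::runif(extra * 3), ncol = 3))
  cf$elem <- c(cf$elem, rep("C", extra))
  cf$classes <- c(cf$classes, rep("-", extra))
  cf
}

#' Run the whole pipeline on synthetic data and measure recovery
#'
#' Generates an ensemble with planted binding-associated features, runs
#' superpose -> perceive -> consensus -> encode -> band threshold ->
#' rank-and-vote -> query -> library screen, and reports how well the
#' planted features were recovered plus the screening enrichment factor.
#'
#' A planted feature counts as recovered when a selected consensus
#' feature of a compatible class lies within `cluster_radius` of its
#' planted position.
#'
#' @param ens_spec an [ensemble_spec()].
#' @param lib_spec a [library_spec()] or `NULL` to build one from the
#'   planted (ground-truth) feature arrangement.
#' @param band `c(low, high)` frequency band, or `NULL` for no threshold.
#' @param k per-method top-k for voting; default 2 x number of planted
#'   features.
#' @param cluster_radius consensus clustering radius, Angstrom.
#' @param tolerance match tolerance, Angstrom; default the library's
#'   active jitter plus 0.5 A of consensus-placement slack.
#' @param screen run the library-screening tail (set `FALSE` to measure
#'   recall only).
#' @return list: `recall`, `ef`, `ef_flag`, `n_consensus`, `n_banded`,
#'   `n_selected`, `votes`, `query` (or `NULL`), `report`, `screen`.
#' @export
end_to_end_recovery <- function(ens_spec, lib_spec = NULL, band = NULL,
                                k = NULL, cluster_radius = 1.5,
                                tolerance = NULL, screen = TRUE) {
  gen <- make_ensemble(ens_spec)
  ens <- superpose_ensemble(gen$ensemble, gen$superpose_site)
  sf <- perceive_site(ens, gen$site)
  cons <- build_consensus(sf, cluster_radius = cluster_radius)
  occ <- encode_binary(cons, gen$labels)
  if (!is.null(band))
    occ <- threshold_by_frequency(occ, low = band[1], high = band[2])
  planted <- gen$truth$features[gen$truth$features$role == "planted", ]
  if (is.null(k)) k <- 2L * nrow(planted)
  n_banded <- ncol(occ$matrix)
  votes <- if (n_banded >= max(k, 1L))
    rank_and_vote(occ, k = k) else NULL
  sel_ids <- if (is.null(votes)) character(0)
             else votes$feature_id[votes$selected]
  sel <- occ$features[occ$features$id %in% sel_ids, , drop = FALSE]
  recovered <- vapply(seq_len(nrow(planted)), function(j) {
    if (nrow(sel) == 0L) return(FALSE)
    d <- sqrt((sel$x - planted$x[j])^2 + (sel$y - planted$y[j])^2 +
                (sel$z - planted$z[j])^2)
    any(d <= cluster_radius &
          classes_compatible(sel$class, rep(planted$class[j], nrow(sel))))
  }, logical(1))
  recall <- mean(recovered)
  do_screen <- isTRUE(screen)
  query <- NULL; screen <- NULL; report <- NULL; libgen <- NULL
  ef <- NA_real_; ef_flag <- "NA"
  if (length(sel_ids) >= 3L && do_screen) {
    query <- build_query(occ, feature_ids = sel_ids)
    if (is.null(lib_spec)) {
      # actives complement the full pocket arrangement (planted plus
      # nuisance positions); decoys always miss one planted feature
      nuis <- gen$truth$features[gen$truth$features$role == "nuisance", ]
      truth_query <- structure(list(
        features = data.frame(
          id = paste0("T", seq_len(nrow(planted)), "_", planted$class),
          class = planted$class, x = planted$x, y = planted$y,
          z = planted$z,
          radius = unname(PH4_RADII[sub("\\|.*", "", planted$class)])),
        match_mode = "all", m = nrow(planted)), class = "ph4_query")
      lib_spec <- library_spec(
        truth_query,
        extra_points = nuis[, c("class", "x", "y", "z")],
        seed = ens_spec$seed + 1000L)
    }
    libgen <- make_library(lib_spec)
    if (is.null(tolerance))
      tolerance <- lib_spec$active_jitter + 0.5
    screen <- search_library(query, libgen$library, tolerance = tolerance)
    report <- screening_report(screen)
    ef <- report$ef; ef_flag <- report$flag
  }
  list(recall = recall, ef = ef, ef_flag = ef_flag,
       n_consensus = nrow(cons$features), n_banded = n_banded,
       n_selected = length(sel_ids), votes = votes, query = query,
       report = report, screen = screen,
       library = if (is.null(libgen)) NULL else libgen$library,
       consensus = cons, occurrence = occ, generated = gen)
}
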