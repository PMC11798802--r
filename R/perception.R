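#' Build radius-bearing pharmacophore features from annotation points
#'
#' Applies the merging rules of one conformation:
#' * class radii — donor/acceptor/charged 1.2 A, aromatic 1.4 A,
#'   hydrophobic 1.6 A;
#' * hydrophobic points within 1.0 A of one another are grouped
#'   transitively (single linkage) into one feature at the group centroid
#'   with radius `min(3.0, max distance to centroid + 1.6)`;
#' * a donor and an acceptor (or a donor and a cation) whose centers lie
#'   within `overlap_tol` collapse into a combined feature `Don|Acc`
#'   (`Don|Cat`);
#' * a merged hydrophobic group containing both an atom point and a
#'   centroid point is labelled `Hyd|HydA`.
#'
#' Output ordering is canonical: class, then lexicographic center, so
#' identical input coordinates give byte-identical feature tables.
#'
#' @param points annotation table from [perceive_annotations()].
#' @param radii named radii vector (Angstrom); see `PH4_RADII`.
#' @param hyd_merge_dist hydrophobic grouping distance, Angstrom.
#' @param hyd_max_radius cap on the merged hydrophobic radius, Angstrom.
#' @param overlap_tol donor/acceptor (donor/cation) center distance below
#'   which the two points merge into a combined class, Angstrom.
#' @return data.frame: `class`, `x`, `y`, `z`, `radius`.
#' @export
build_features <- function(points, radii = PH4_RADII,
                           hyd_merge_dist = 1.0, hyd_max_radius = 3.0,
                           overlap_tol = 0.5) {
  empty <- data.frame(class = character(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric())
  if (is.null(points) || nrow(points) == 0L) return(empty)
  feats <- list()
  base_class <- sub("\\|.*", "", points$class)   # Aro|PiR counts as Aro family

  # --- hydrophobic grouping (transitive closure = single linkage) ---
  hyd <- which(points$class == "Hyd")
  if (length(hyd) > 0L) {
    xyz <- as.matrix(points[hyd, c("x", "y", "z")])
    if (length(hyd) == 1L) {
      grp <- 1L
    } else {
      hc <- stats::hclust(stats::dist(xyz), method = "single")
      grp <- stats::cutree(hc, h = hyd_merge_dist)
    }
    for (g in unique(grp)) {
      ii <- which(grp == g)
      ctr <- colMeans(xyz[ii, , drop = FALSE])
      if (length(ii) == 1L) {
        rad <- radii[["Hyd"]]
        cls <- "Hyd"
      } else {
        dmax <- max(sqrt(rowSums(sweep(xyz[ii, , drop = FALSE], 2, ctr)^2)))
        rad <- min(hyd_max_radius, dmax + radii[["Hyd"]])
        cls <- if (length(unique(points$source[hyd][ii])) > 1L)
          "Hyd|HydA" else "Hyd"
      }
      feats[[length(feats) + 1L]] <- data.frame(
        class = cls, x = ctr[1], y = ctr[2], z = ctr[3], radius = rad)
    }
  }

  # --- donor/acceptor and donor/cation overlap merging ---
  don <- which(points$class == "Don")
  acc <- which(points$class == "Acc")
  cat_ <- which(points$class == "Cat")
  consumed <- logical(nrow(points))
  pair_merge <- function(ia, ib, combined) {
    for (i in ia) {
      if (consumed[i]) next
      for (j in ib) {
        if (consumed[j]) next
        d <- sqrt(sum((unlist(points[i, c("x", "y", "z")]) -
                       unlist(points[j, c("x", "y", "z")]))^2))
        if (d <= overlap_tol) {
          ctr <- (unlist(points[i, c("x", "y", "z")]) +
                  unlist(points[j, c("x", "y", "z")])) / 2
          feats[[length(feats) + 1L]] <<- data.frame(
            class = combined, x = ctr[1], y = ctr[2], z = ctr[3],
            radius = max(radii[["Don"]], radii[[sub(".*\\|", "", combined)]],
                         na.rm = TRUE))
          consumed[i] <<- TRUE; consumed[j] <<- TRUE
          break
        }
      }
    }
  }
  pair_merge(don, acc, "Don|Acc")
  pair_merge(don, cat_, "Don|Cat")

  # --- remaining point features at class radii ---
  rest <- which(!consumed & points$class != "Hyd")
  for (i in rest) {
    cls <- points$class[i]
    rad <- radii[[base_class[i]]]
    if (is.null(rad) || is.na(rad)) rad <- radii[["Don"]]
    feats[[length(feats) + 1L]] <- data.frame(
      class = cls, x = points$x[i], y = points$y[i], z = points$z[i],
      radius = rad)
  }

  if (length(feats) == 0L) return(empty)
  out <- do.call(rbind, feats)
  out <- out[order(out$class, out$x, out$y, out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Perceive pharmacophore features in the binding site of every frame
#'
#' Runs [perceive_annotations()] then [build_features()] on the site atom
#' set of each frame of a (superposed) ensemble. With a proximity site the
#' atom selection is re-evaluated per frame; with a residue-list site it
#' is fixed.
#'
#' @param ens a superposed `ph4_ensemble`.
#' @param site a `ph4_site`.
#' @param rules typing rule table.
#' @param ... merging parameters passed to [build_features()].
#' @return A list of per-frame feature data.frames, named by frame id.
#' @export
perceive_site <- function(ens, site, rules = typing_rules(), ...) {
  out <- vector("list", n_frames(ens))
  names(out) <- as.character(ens$frame_ids)
  fixed_idx <- if (site$mode == "residue_list")
    select_site_atoms(ens, site, frame = 1L) else NULL
  for (i in seq_len(n_frames(ens))) {
    idx <- if (is.null(fixed_idx)) select_site_atoms(ens, site, frame = i)
           else fixed_idx
    crd <- frame_coords(ens, i)[idx, , drop = FALSE]
    pts <- perceive_annotations(crd, ens$atoms[idx, , drop = FALSE], rules)
    out[[i]] <- build_features(pts, ...)
  }
  out
}

#' Serialize per-frame features to JSON
#'
#' @param site_features list of per-frame feature tables from
#'   [perceive_site()].
#' @param path output path.
#' @export
write_features_json <- function(site_features, path) {
  obj <- lapply(names(site_features), function(fid) {
    f <- site_features[[fid]]
    list(frame_id = fid,
         features = lapply(seq_len(nrow(f)), function(i)
           list(class = f$class[i],
                center = c(f$x[i], f$y[i], f$z[i]),
                radius = f$radius[i])))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
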