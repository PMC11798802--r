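# class-compatibility for matching: combined classes ("Don|Acc",
# "Aro|PiR", "Hyd|HydA") are satisfied by either member class
class_members <- function(cls) strsplit(cls, "|", fixed = TRUE)
classes_compatible <- function(a, b) {
  ma <- class_members(a); mb <- class_members(b)
  vapply(seq_along(ma), function(i) length(intersect(ma[[i]], mb[[i]])) > 0L,
         logical(1))
}

#' Assemble a pharmacophore query from selected consensus features
#'
#' Takes either the `selected` rows of a [rank_and_vote()] table or an
#' explicit id list (manual curation override), and looks the features up
#' in the consensus set. Geometric matching of fewer than 3 features is
#' underdetermined, so smaller queries are refused.
#'
#' @param consensus a `ph4_consensus` (or a `ph4_occurrence` carrying its
#'   feature table).
#' @param votes a [rank_and_vote()] result; its `selected` rows are used.
#' @param feature_ids explicit consensus ids; overrides `votes`.
#' @param match_mode `"all"` (every feature must match) or `"m-of-n"`.
#' @param m required feature count when `match_mode = "m-of-n"`.
#' @return An object of class `ph4_query` with a `features` data.frame
#'   (`id`, `class`, `x`, `y`, `z`, `radius`).
#' @export
build_query <- function(consensus, votes = NULL, feature_ids = NULL,
                        match_mode = c("all", "m-of-n"), m = NULL) {
  match_mode <- match.arg(match_mode)
  feats <- if (inherits(consensus, "ph4_consensus")) consensus$features
           else consensus$features
  if (is.null(feats)) stop("no consensus feature table available")
  if (is.null(feature_ids)) {
    if (is.null(votes)) stop("supply votes or feature_ids")
    feature_ids <- votes$feature_id[votes$selected]
  }
  if (length(feature_ids) < 3L)
    stop("a pharmacophore query needs >= 3 features (got ",
         length(feature_ids), ")")
  miss <- setdiff(feature_ids, feats$id)
  if (length(miss) > 0L)
    stop("unknown feature ids: ", paste(miss, collapse = ", "))
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  q <- feats[match(feature_ids, feats$id),
             c("id", "class", "x", "y", "z", "radius")]
  rownames(q) <- NULL
  if (match_mode == "m-of-n") {
    if (is.null(m) || m < 3L || m > nrow(q))
      stop("m must be between 3 and the number of query features")
  } else m <- nrow(q)
  structure(list(features = q, match_mode = match_mode, m = as.integer(m)),
            class = "ph4_query")
}

#' @export
print.ph4_query <- function(x, ...) {
  cat("ph4_query:", nrow(x$features), "features (",
      paste(x$features$class, collapse = ", "), "), match_mode =",
      x$match_mode, "\n")
  invisible(x)
}

#' Match one conformer's annotation points against a query
#'
#' Searches class-compatible one-to-one correspondences between query
#' features and annotation points, pruned by pairwise-distance
#' consistency (`|d_query(i,j) - d_points(i,j)| <= r_i + r_j` + twice the
#' tolerance). Each surviving correspondence is scored by least-squares
#' rigid superposition ([kabsch()]) of the points onto the query centers;
#' it is accepted iff every transformed point falls within its feature's
#' radius plus `tolerance`. The minimum-RMSD accepted correspondence is
#' returned. Chirality-inverting fits are never produced (the rotation
#' determinant is +1). An unmatched conformer is a normal result, not an
#' error.
#'
#' @param query a `ph4_query`.
#' @param points annotation table (`class`, `x`, `y`, `z`) for one
#'   conformer, e.g. from [annotate_conformer()].
#' @param tolerance extra acceptance slack beyond each feature radius,
#'   Angstrom (default 0).
#' @return list: `matched` (logical), `rmsd` (Angstrom, `NA` if
#'   unmatched), `correspondence` (data.frame `feature_id`,
#'   `point_index`), `rotation`, `translation` (point -> query frame).
#' @export
match_conformer <- function(query, points, tolerance = 0) {
  stopifnot(inherits(query, "ph4_query"))
  qf <- query$features
  nq <- nrow(qf)
  res_empty <- list(matched = FALSE, rmsd = NA_real_,
                    correspondence = NULL, rotation = NULL,
                    translation = NULL)
  if (is.null(points) || nrow(points) == 0L) return(res_empty)
  subsets <- if (query$match_mode == "all" || query$m == nq)
    list(seq_len(nq))
  else utils::combn(nq, query$m, simplify = FALSE)
  best <- res_empty
  for (sub in subsets) {
    r <- match_subset(qf[sub, , drop = FALSE], points, tolerance)
    if (r$matched && (!best$matched || r$rmsd < best$rmsd)) best <- r
  }
  best
}

# exact search over one required feature subset
match_subset <- function(qf, points, tolerance) {
  nq <- nrow(qf)
  np <- nrow(points)
  qxyz <- as.matrix(qf[, c("x", "y", "z")])
  pxyz <- as.matrix(points[, c("x", "y", "z")])
  qd <- as.matrix(stats::dist(qxyz))
  pd <- as.matrix(stats::dist(pxyz))
  compat <- matrix(FALSE, nq, np)
  for (i in seq_len(nq))
    compat[i, ] <- classes_compatible(rep(qf$class[i], np), points$class)
  best_rmsd <- Inf; best_assign <- NULL
  best_fit <- NULL
  assign <- integer(nq)
  used <- logical(np)
  recurse <- function(i) {
    if (i > nq) {
      fit <- kabsch(pxyz[assign, , drop = FALSE], qxyz)
      moved <- fit$transform(pxyz[assign, , drop = FALSE])
      resid <- sqrt(rowSums((moved - qxyz)^2))
      if (all(resid <= qf$radius + tolerance) && fit$rmsd < best_rmsd) {
        best_rmsd <<- fit$rmsd
        best_assign <<- assign
        best_fit <<- fit
      }
      return(invisible(NULL))
    }
    for (j in which(compat[i, ] & !used)) {
      ok <- TRUE
      if (i > 1L) {
        for (h in seq_len(i - 1L)) {
          slack <- qf$radius[i] + qf$radius[h] + 2 * tolerance
          if (abs(qd[i, h] - pd[j, assign[h]]) > slack) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      assign[i] <<- j; used[j] <<- TRUE
      recurse(i + 1L)
      used[j] <<- FALSE
    }
    invisible(NULL)
  }
  recurse(1L)
  if (is.null(best_assign))
    return(list(matched = FALSE, rmsd = NA_real_, correspondence = NULL,
                rotation = NULL, translation = NULL))
  list(matched = TRUE, rmsd = best_rmsd,
       correspondence = data.frame(feature_id = qf$id,
                                   point_index = best_assign),
       rotation = best_fit$rotation, translation = best_fit$translation)
}

#' Screen a multi-conformer library against a pharmacophore query
#'
#' Every conformer of every molecule is matched; per molecule only the
#' best (minimum-RMSD) matched conformer is retained. Molecules with no
#' matching conformer are not hits.
#'
#' @param query a `ph4_query`.
#' @param library a `ph4_library` (see [read_ligand_library()] or
#'   [make_library()]).
#' @param tolerance matching slack in Angstrom.
#' @return An object of class `ph4_screen`: `results` data.frame
#'   (`molecule_id`, `activity`, `matched`, `conformer`, `rmsd`) and
#'   `query`.
#' @export
search_library <- function(query, library, tolerance = 0) {
  stopifnot(inherits(library, "ph4_library"))
  if (length(library$molecules) == 0L) stop("empty ligand library")
  rows <- lapply(library$molecules, function(mol) {
    best <- list(matched = FALSE, rmsd = NA_real_)
    best_ci <- NA_integer_
    for (ci in seq_along(mol$conformers)) {
      pts <- annotate_conformer(mol$conformers[[ci]])
      r <- match_conformer(query, pts, tolerance)
      if (r$matched && (!best$matched || r$rmsd < best$rmsd)) {
        best <- r; best_ci <- ci
      }
    }
    data.frame(molecule_id = mol$id, activity = mol$activity,
               matched = best$matched, conformer = best_ci,
               rmsd = best$rmsd)
  })
  structure(list(results = do.call(rbind, rows), query = query,
                 tolerance = tolerance),
            class = "ph4_screen")
}

#' @export
print.ph4_screen <- function(x, ...) {
  cat("ph4_screen:", sum(x$results$matched), "of", nrow(x$results),
      "molecules matched\n")
  invisible(x)
}

#' Write / read a query as JSON
#' @param query a `ph4_query`.
#' @param path file path.
#' @export
write_query <- function(query, path) {
  qf <- query$features
  obj <- list(match_mode = query$match_mode, m = query$m,
              features = lapply(seq_len(nrow(qf)), function(i)
                list(id = qf$id[i], class = qf$class[i],
                     center = c(qf$x[i], qf$y[i], qf$z[i]),
                     radius = qf$radius[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_query
#' @export
read_query <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- do.call(rbind, lapply(obj$features, function(f)
    data.frame(id = f$id, class = f$class,
               x = f$center[[1]], y = f$center[[2]], z = f$center[[3]],
               radius = f$radius)))
  structure(list(features = feats, match_mode = obj$match_mode,
                 m = as.integer(obj$m)),
            class = "ph4_query")
}
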