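#' Multi-conformer ligand library
#'
#' `molecules` is a list of molecules; each has `id`, `activity`
#' ("active", "decoy", or another string for unknown) and `conformers`, a
#' list of conformers sharing one atom order: each conformer is a list
#' with `coords` (n x 3), `elem` (element symbols), `bonds` (data.frame
#' `a`, `b`, `order`) and optionally `classes` — explicit per-atom
#' pharmacophore classes ("-" for untyped atoms) that override graph
#' perception in [annotate_conformer()].
#'
#' @param molecules list as described above.
#' @return An object of class `ph4_library`.
#' @export
ph4_library <- function(molecules) {
  for (mol in molecules) {
    if (length(mol$conformers) < 1L)
      stop("molecule ", mol$id, " has no conformers")
    n0 <- nrow(mol$conformers[[1]]$coords)
    for (cf in mol$conformers)
      if (nrow(cf$coords) != n0)
        stop("conformers of ", mol$id, " differ in atom count")
  }
  structure(list(molecules = molecules), class = "ph4_library")
}

#' @export
print.ph4_library <- function(x, ...) {
  act <- vapply(x$molecules, function(m) m$activity, character(1))
  cat("ph4_library:", length(x$molecules), "molecules (",
      sum(act == "active"), "active /", sum(act == "decoy"), "decoy )\n")
  invisible(x)
}

#' Read a multi-conformer SDF (V2000) ligand library
#'
#' Records sharing a molecule name (SDF title line) are conformers of one
#' molecule. Activity is read from an SD tag (default `ACTIVITY`, values
#' "active"/"decoy"); alternatively read actives and decoys from separate
#' files and label them here via `activity`. A `FEATURE_CLASSES` tag, if
#' present, carries one pharmacophore class per atom (space separated,
#' "-" for untyped) and overrides graph-based perception.
#'
#' @param path SDF file.
#' @param activity_tag SD tag holding the activity class.
#' @param activity fixed class for every molecule in the file (overrides
#'   the tag); use when actives and decoys live in separate files.
#' @param class_tag SD tag holding explicit per-atom classes.
#' @return A [ph4_library()].
#' @export
read_ligand_library <- function(path, activity_tag = "ACTIVITY",
                                activity = NULL,
                                class_tag = "FEATURE_CLASSES") {
  sdfs <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfs)
  mols <- list()
  for (i in seq_along(ids)) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    db <- ChemmineR::datablock(sdf)
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    elem <- sub("_.*$", "", rownames(ab))
    bonds <- if (length(bb) == 0L || nrow(as.matrix(bb)) == 0L)
      data.frame(a = integer(), b = integer(), order = integer())
    else {
      bbm <- as.matrix(bb)
      data.frame(a = as.integer(bbm[, 1]), b = as.integer(bbm[, 2]),
                 order = as.integer(bbm[, 3]))
    }
    cls <- NULL
    if (!is.null(db) && class_tag %in% names(db)) {
      cls <- strsplit(trimws(db[[class_tag]]), "\\s+")[[1]]
      if (length(cls) != nrow(coords))
        stop("molecule ", ids[i], ": ", class_tag,
             " tag length does not match atom count")
    }
    act <- if (!is.null(activity)) activity
           else if (!is.null(db) && activity_tag %in% names(db))
             db[[activity_tag]]
           else "unknown"
    conf <- list(coords = coords, elem = elem, bonds = bonds,
                 classes = cls)
    key <- as.character(ids[i])
    if (!is.null(mols[[key]])) {
      mols[[key]]$conformers <- c(mols[[key]]$conformers, list(conf))
    } else {
      mols[[key]] <- list(id = key, activity = act,
                          conformers = list(conf))
    }
  }
  ph4_library(unname(mols))
}

#' Write a ligand library as SDF (V2000)
#'
#' One record per conformer; the record title is the molecule id, so
#' conformers group back together on read. Activity and explicit classes
#' are written as SD tags. Coordinates are emitted at 4 decimals (the
#' V2000 field precision).
#'
#' @param library a `ph4_library`.
#' @param path output path.
#' @param activity_tag,class_tag SD tag names.
#' @export
write_library <- function(library, path, activity_tag = "ACTIVITY",
                          class_tag = "FEATURE_CLASSES") {
  stopifnot(inherits(library, "ph4_library"))
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in library$molecules) {
    for (cf in mol$conformers) {
      n <- nrow(cf$coords); nb <- nrow(cf$bonds)
      lines <- c(mol$id, "  ph4ensemble", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
      for (i in seq_len(n)) {
        lines <- c(lines, sprintf(
          "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
          cf$coords[i, 1], cf$coords[i, 2], cf$coords[i, 3], cf$elem[i]))
      }
      for (j in seq_len(nb)) {
        lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                  cf$bonds$a[j], cf$bonds$b[j],
                                  cf$bonds$order[j]))
      }
      lines <- c(lines, "M  END",
                 paste0("> <", activity_tag, ">"), mol$activity, "")
      if (!is.null(cf$classes))
        lines <- c(lines, paste0("> <", class_tag, ">"),
                   paste(cf$classes, collapse = " "), "")
      lines <- c(lines, "$$$$")
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Write the best-matching conformers of a screen as SDF
#'
#' Hits only; each record carries `MATCH_RMSD` and `QUERY_SIZE` tags.
#'
#' @param screen a `ph4_screen`.
#' @param library the screened `ph4_library`.
#' @param path output path.
#' @export
write_hits_sdf <- function(screen, library, path) {
  r <- screen$results
  con <- file(path, "w")
  on.exit(close(con))
  by_id <- stats::setNames(library$molecules,
                           vapply(library$molecules, `[[`, "", "id"))
  for (i in which(r$matched)) {
    mol <- by_id[[r$molecule_id[i]]]
    cf <- mol$conformers[[r$conformer[i]]]
    n <- nrow(cf$coords); nb <- nrow(cf$bonds)
    lines <- c(mol$id, "  ph4ensemble", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    for (a in seq_len(n))
      lines <- c(lines, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        cf$coords[a, 1], cf$coords[a, 2], cf$coords[a, 3], cf$elem[a]))
    for (j in seq_len(nb))
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                cf$bonds$a[j], cf$bonds$b[j],
                                cf$bonds$order[j]))
    lines <- c(lines, "M  END",
               "> <ACTIVITY>", mol$activity, "",
               "> <MATCH_RMSD>", format(r$rmsd[i], digits = 10), "",
               "> <QUERY_SIZE>", nrow(screen$query$features), "",
               "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Perceive annotation points on a ligand conformer
#'
#' If the conformer carries explicit per-atom classes they are used
#' directly (one point per typed atom). Otherwise light bond-graph
#' perception applies:
#' * Don — N/O/S with at least one explicit hydrogen neighbour;
#' * Acc — any O; N with total degree <= 3 and no hydrogen deficit
#'   heuristics beyond that (protonation is taken as drawn);
#' * Cat — N with 4 connections;
#' * Ani — carboxylate-like C bonded to two terminal O: point at the
#'   group centroid;
#' * Aro — 5/6-rings whose every atom has total degree <= 3: ring
#'   centroid;
#' * Hyd — C/S atoms with no heteroatom neighbour, plus the centroid of
#'   every connected set of >= 3 such atoms.
#'
#' Co-located Don and Acc points (same atom) are merged to `Don|Acc`.
#'
#' @param conformer one conformer of a `ph4_library` molecule.
#' @return data.frame `class`, `x`, `y`, `z`.
#' @export
annotate_conformer <- function(conformer) {
  crd <- conformer$coords
  if (!is.null(conformer$classes)) {
    keep <- conformer$classes != "-"
    return(data.frame(class = conformer$classes[keep],
                      x = crd[keep, 1], y = crd[keep, 2],
                      z = crd[keep, 3]))
  }
  elem <- toupper(conformer$elem)
  n <- length(elem)
  adj <- vector("list", n)
  bonds <- conformer$bonds
  for (j in seq_len(nrow(bonds))) {
    adj[[bonds$a[j]]] <- c(adj[[bonds$a[j]]], bonds$b[j])
    adj[[bonds$b[j]]] <- c(adj[[bonds$b[j]]], bonds$a[j])
  }
  deg <- lengths(adj)
  is_h <- elem == "H"
  hetero <- !(elem %in% c("C", "H", "S"))   # for Hyd exclusion S is apolar
  pts <- list()
  add <- function(cls, xyz)
    pts[[length(pts) + 1L]] <<- data.frame(class = cls, x = xyz[1],
                                           y = xyz[2], z = xyz[3])
  don <- acc <- logical(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    if (elem[i] %in% c("N", "O", "S") && any(is_h[nb])) don[i] <- TRUE
    if (elem[i] == "O") acc[i] <- TRUE
    if (elem[i] == "N" && deg[i] <= 3L) acc[i] <- TRUE
    if (elem[i] == "N" && deg[i] == 4L) add("Cat", crd[i, ])
  }
  # carboxylate-like groups
  for (i in which(elem == "C")) {
    term_o <- adj[[i]][elem[adj[[i]]] == "O" & deg[adj[[i]]] == 1L]
    if (length(term_o) == 2L) {
      add("Ani", colMeans(crd[c(i, term_o), , drop = FALSE]))
      acc[term_o] <- TRUE
    }
  }
  for (i in seq_len(n)) {
    if (don[i] && acc[i]) add("Don|Acc", crd[i, ])
    else if (don[i]) add("Don", crd[i, ])
    else if (acc[i]) add("Acc", crd[i, ])
  }
  # aromatic rings: simple cycles of 5/6 atoms, all degree <= 3, no H
  for (ring in find_rings(adj, is_h)) {
    if (all(deg[ring] <= 3L))
      add("Aro", colMeans(crd[ring, , drop = FALSE]))
  }
  # hydrophobic atoms and contiguous-group centroids
  hyd <- vapply(seq_len(n), function(i)
    elem[i] %in% c("C", "S") && !any(hetero[adj[[i]]]), logical(1))
  for (i in which(hyd)) add("Hyd", crd[i, ])
  comp <- connected_components(adj, which(hyd))
  for (cc in comp) if (length(cc) >= 3L)
    add("Hyd", colMeans(crd[cc, , drop = FALSE]))
  if (length(pts) == 0L)
    return(data.frame(class = character(), x = numeric(), y = numeric(),
                      z = numeric()))
  do.call(rbind, pts)
}

# minimal 5/6-membered simple-cycle finder on the heavy-atom graph
find_rings <- function(adj, is_h) {
  n <- length(adj)
  rings <- list()
  seen <- character(0)
  path <- integer(0)
  dfs <- function(start, v, depth) {
    path[depth] <<- v
    for (w in adj[[v]]) {
      if (is_h[w]) next
      if (w == start && depth >= 5L) {
        ring <- sort(path[seq_len(depth)])
        key <- paste(ring, collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path[seq_len(depth)]
        }
      } else if (depth < 6L && !(w %in% path[seq_len(depth)]) && w > start) {
        dfs(start, w, depth + 1L)
      }
    }
  }
  for (s in seq_len(n)) {
    if (is_h[s]) next
    path <- integer(6)
    dfs(s, s, 1L)
  }
  rings
}

connected_components <- function(adj, nodes) {
  comp <- list()
  todo <- nodes
  while (length(todo) > 0L) {
    stack <- todo[1]
    cc <- integer(0)
    while (length(stack) > 0L) {
      v <- stack[1]; stack <- stack[-1]
      if (v %in% cc) next
      cc <- c(cc, v)
      stack <- c(stack, intersect(adj[[v]], todo))
    }
    comp[[length(comp) + 1L]] <- sort(cc)
    todo <- setdiff(todo, cc)
  }
  comp
}
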