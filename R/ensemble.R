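#' Conformational ensemble of a binding site
#'
#' Container for N conformations (frames) of the same set of atoms, in the
#' original trajectory order. Frame order is authoritative: the recurrence
#' analysis in [rank_and_vote()] treats rows of the occurrence matrix as a
#' time series.
#'
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns in
#'   bio3d order (x1, y1, z1, x2, ...), coordinates in Angstrom.
#' @param atoms data.frame with one row per atom: columns `elety` (atom
#'   name), `resid` (residue name), `resno` (residue number), `chain`,
#'   `elesy` (element symbol).
#' @param frame_ids optional identifiers, one per frame (default 1..N).
#' @return An object of class `ph4_ensemble`.
#' @export
ph4_ensemble <- function(xyz, atoms, frame_ids = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3L != 0L)
    stop("xyz must have 3 * n_atoms columns")
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in ensemble")
  natoms <- ncol(xyz) %/% 3L
  req <- c("elety", "resid", "resno", "chain", "elesy")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  if (nrow(atoms) != natoms)
    stop("atoms table (", nrow(atoms), ") does not match xyz (", natoms, " atoms)")
  if (is.null(frame_ids)) frame_ids <- seq_len(nrow(xyz))
  if (length(frame_ids) != nrow(xyz))
    stop("frame_ids length must equal the number of frames")
  structure(list(xyz = xyz, atoms = as.data.frame(atoms),
                 frame_ids = frame_ids),
            class = "ph4_ensemble")
}

#' @export
print.ph4_ensemble <- function(x, ...) {
  cat("ph4_ensemble:", n_frames(x), "frames x", n_atoms(x), "atoms\n")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ens a `ph4_ensemble`.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(ens) ncol(ens$xyz) %/% 3L

#' Coordinates of one frame as an n_atoms x 3 matrix
#' @param ens a `ph4_ensemble`.
#' @param i frame index.
#' @export
frame_coords <- function(ens, i) {
  matrix(ens$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' Each MODEL becomes one frame; atom ordering must be identical across
#' models. Models with a differing atom count abort with an error naming
#' the offending frame.
#'
#' @param path path to a multi-model PDB file.
#' @return A [ph4_ensemble()].
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    # check per-model atom counts before handing to the parser so the
    # error can name the frame
    model_id <- cumsum(model_starts)
    counts <- table(model_id[is_atom & model_id > 0])
    if (length(unique(as.integer(counts))) > 1L) {
      bad <- which(as.integer(counts) != as.integer(counts[1]))[1]
      stop("atom count mismatch at frame ", names(counts)[bad],
           " (", counts[bad], " atoms vs ", counts[1], " in frame 1)")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  atoms <- pdb$atom[, c("elety", "resid", "resno", "chain", "elesy")]
  atoms$elesy <- guess_elements(atoms$elesy, atoms$elety)
  ph4_ensemble(unclass(xyz), atoms)
}

# fall back to the first letter of the atom name when the element column
# is blank (common in minimal PDB files)
guess_elements <- function(elesy, elety) {
  blank <- is.na(elesy) | elesy == ""
  elesy[blank] <- sub("^[0-9]*([A-Za-z]).*", "\\1", elety[blank])
  toupper(elesy)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens a `ph4_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  at <- ens$atoms
  pdb_atoms <- data.frame(
    type = "ATOM", eleno = seq_len(nrow(at)), elety = at$elety,
    alt = "", resid = at$resid, chain = at$chain, resno = at$resno,
    insert = "", o = 1, b = 0, segid = "", elesy = at$elesy, charge = "",
    stringsAsFactors = FALSE)
  pdb <- list(atom = pdb_atoms, xyz = bio3d::as.xyz(ens$xyz),
              calpha = rep(FALSE, nrow(at)))
  class(pdb) <- c("pdb")
  bio3d::write.pdb(pdb, xyz = pdb$xyz, file = path)
  invisible(path)
}

#' Binding-site definitions
#'
#' Two ways to say which atoms belong to the binding site: an explicit
#' residue list, or proximity to reference points (e.g. a co-crystallized
#' ligand) within a distance cutoff. The proximity cutoff defaults to
#' 6.5 Angstrom, the radius conventionally used to carve a pocket region
#' around a detected site.
#'
#' @param resno integer vector of residue numbers.
#' @param chain optional chain identifiers, recycled against `resno`;
#'   `NA` matches any chain.
#' @return An object of class `ph4_site`.
#' @export
site_residues <- function(resno, chain = NA) {
  if (length(resno) < 1L) stop("at least one residue required")
  chain <- rep_len(chain, length(resno))
  structure(list(mode = "residue_list",
                 residues = data.frame(resno = as.integer(resno),
                                       chain = as.character(chain))),
            class = "ph4_site")
}

#' @rdname site_residues
#' @param points numeric matrix (m x 3) of reference coordinates, Angstrom.
#' @param cutoff inclusion distance in Angstrom (default 6.5).
#' @export
site_proximity <- function(points, cutoff = 6.5) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 1L) stop("at least one reference point required")
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  structure(list(mode = "ligand_proximity", points = points,
                 cutoff = cutoff),
            class = "ph4_site")
}

#' Select the binding-site atoms of one frame
#'
#' Residue-list mode selects every atom of the listed residues (frame
#' independent); proximity mode selects atoms within the cutoff of any
#' reference point, evaluated on the requested frame's coordinates.
#'
#' @param ens a `ph4_ensemble`.
#' @param site a `ph4_site`.
#' @param frame frame index (default 1).
#' @return Integer vector of atom indices (1-based).
#' @export
select_site_atoms <- function(ens, site, frame = 1L) {
  stopifnot(inherits(site, "ph4_site"))
  at <- ens$atoms
  if (site$mode == "residue_list") {
    keep <- rep(FALSE, nrow(at))
    for (j in seq_len(nrow(site$residues))) {
      hit <- at$resno == site$residues$resno[j]
      ch <- site$residues$chain[j]
      if (!is.na(ch) && ch != "NA") hit <- hit & at$chain == ch
      keep <- keep | hit
    }
    idx <- which(keep)
  } else {
    crd <- frame_coords(ens, frame)
    d2min <- rep(Inf, nrow(crd))
    for (j in seq_len(nrow(site$points))) {
      d2 <- (crd[, 1] - site$points[j, 1])^2 +
            (crd[, 2] - site$points[j, 2])^2 +
            (crd[, 3] - site$points[j, 3])^2
      d2min <- pmin(d2min, d2)
    }
    idx <- which(d2min <= site$cutoff^2)
  }
  if (length(idx) == 0L) stop("site selection is empty")
  idx
}

#' Superpose every frame onto the first on the site heavy atoms
#'
#' Rigid least-squares fit of each frame onto frame 1, using only the
#' heavy (non-hydrogen) atoms of the binding site. Frame 1 is left
#' unchanged; hydrogens ride along with the fitted transform but never
#' influence it.
#'
#' @param ens a `ph4_ensemble` with at least 2 frames.
#' @param site a `ph4_site` selecting at least 3 non-collinear heavy atoms.
#' @return The superposed `ph4_ensemble`.
#' @export
superpose_ensemble <- function(ens, site) {
  if (n_frames(ens) < 2L) stop("need at least 2 frames to superpose")
  idx <- select_site_atoms(ens, site, frame = 1L)
  heavy <- idx[!(ens$atoms$elesy[idx] %in% c("H", "D"))]
  if (length(heavy) < 3L)
    stop("superposition underdetermined: fewer than 3 site heavy atoms")
  ref <- frame_coords(ens, 1L)[heavy, , drop = FALSE]
  if (collinear(ref))
    stop("superposition underdetermined: site heavy atoms are collinear")
  out <- ens$xyz
  for (i in seq_len(n_frames(ens))[-1]) {
    crd <- frame_coords(ens, i)
    fit <- kabsch(crd[heavy, , drop = FALSE], ref)
    out[i, ] <- as.vector(t(fit$transform(crd)))
  }
  ens$xyz <- out
  ens
}

collinear <- function(X, tol = 1e-8) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Site RMSD of each frame to frame 1
#'
#' @inheritParams superpose_ensemble
#' @return Numeric vector (length = frames) of heavy-atom site RMSDs.
#' @export
site_rmsd <- function(ens, site) {
  idx <- select_site_atoms(ens, site, frame = 1L)
  heavy <- idx[!(ens$atoms$elesy[idx] %in% c("H", "D"))]
  ref <- frame_coords(ens, 1L)[heavy, , drop = FALSE]
  vapply(seq_len(n_frames(ens)), function(i) {
    rmsd_points(frame_coords(ens, i)[heavy, , drop = FALSE], ref)
  }, numeric(1))
}
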