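# Pharmacophore typing rule table, version 1.
#
# Protein-side typing is template driven: rules key on residue and atom
# names of the standard amino acids, so no bond perception or explicit
# hydrogens are needed (a donor is identified by its heavy-atom parent).
# The table is deliberately explicit and versioned — it documents its own
# choices rather than claiming equivalence to any proprietary scheme.
#
# Feature classes: Don, Acc, Cat, Ani, Aro, Hyd plus the combined classes
# Don|Acc, Don|Cat, Aro|PiR, Hyd|HydA produced by overlap merging.

PH4_CLASSES <- c("Don", "Acc", "Cat", "Ani", "Aro", "Hyd",
                 "Don|Acc", "Don|Cat", "Aro|PiR", "Hyd|HydA")

# default feature radii (Angstrom): 1.2 donor/acceptor, 1.4 aromatic,
# 1.6 hydrophobic; charged features share the donor/acceptor scale
PH4_RADII <- c(Don = 1.2, Acc = 1.2, Cat = 1.2, Ani = 1.2,
               Aro = 1.4, Hyd = 1.6)

#' The built-in protein typing rule table
#'
#' Returns the versioned rule table used by [perceive_annotations()] for
#' protein atoms. Single-atom rules place Don/Acc/Cat/Hyd points on named
#' atoms of named residues (`resid = "*"` matches any residue, for
#' backbone atoms); group rules place a point at the centroid of a named
#' atom set (aromatic rings, charged groups, hydrophobic side-chain
#' centroids). Probe residues (DON, ACC, CAT, ANI, ARO, HYD, DOA, PIR)
#' carry a single pseudo-atom typed directly with the named class; the
#' synthetic-data generator uses them to plant features.
#'
#' @return A list with data.frames `atom_rules` (resid, elety, class) and
#'   `group_rules` (resid, class, atoms = comma-separated names), plus
#'   `version`.
#' @export
typing_rules <- function() {
  ar <- function(resid, elety, class)
    data.frame(resid = resid, elety = elety, class = class)
  atom_rules <- rbind(
    # backbone
    ar("*", "N", "Don"),          # amide N-H (suppressed for PRO below)
    ar("*", "O", "Acc"),
    ar("*", "OXT", "Acc"),
    # side-chain donors
    ar("SER", "OG", "Don"),  ar("THR", "OG1", "Don"), ar("TYR", "OH", "Don"),
    ar("CYS", "SG", "Don"),  ar("TRP", "NE1", "Don"),
    ar("ASN", "ND2", "Don"), ar("GLN", "NE2", "Don"),
    ar("HIS", "ND1", "Don"), ar("HIS", "NE2", "Don"),
    ar("LYS", "NZ", "Don"),
    ar("ARG", "NE", "Don"), ar("ARG", "NH1", "Don"), ar("ARG", "NH2", "Don"),
    # side-chain acceptors
    ar("ASP", "OD1", "Acc"), ar("ASP", "OD2", "Acc"),
    ar("GLU", "OE1", "Acc"), ar("GLU", "OE2", "Acc"),
    ar("ASN", "OD1", "Acc"), ar("GLN", "OE1", "Acc"),
    ar("SER", "OG", "Acc"),  ar("THR", "OG1", "Acc"), ar("TYR", "OH", "Acc"),
    ar("HIS", "ND1", "Acc"), ar("HIS", "NE2", "Acc"),
    # cations (single atom)
    ar("LYS", "NZ", "Cat"),
    # hydrophobic atoms: C or S with no heteroatom neighbour
    ar("ALA", "CB", "Hyd"),
    ar("VAL", "CB", "Hyd"), ar("VAL", "CG1", "Hyd"), ar("VAL", "CG2", "Hyd"),
    ar("LEU", "CB", "Hyd"), ar("LEU", "CG", "Hyd"),
    ar("LEU", "CD1", "Hyd"), ar("LEU", "CD2", "Hyd"),
    ar("ILE", "CB", "Hyd"), ar("ILE", "CG1", "Hyd"),
    ar("ILE", "CG2", "Hyd"), ar("ILE", "CD1", "Hyd"),
    ar("PRO", "CB", "Hyd"), ar("PRO", "CG", "Hyd"),
    ar("MET", "SD", "Hyd"),
    ar("THR", "CG2", "Hyd"),
    ar("ASP", "CB", "Hyd"), ar("ASN", "CB", "Hyd"), ar("HIS", "CB", "Hyd"),
    ar("GLU", "CB", "Hyd"), ar("GLU", "CG", "Hyd"),
    ar("GLN", "CB", "Hyd"), ar("GLN", "CG", "Hyd"),
    ar("LYS", "CB", "Hyd"), ar("LYS", "CG", "Hyd"), ar("LYS", "CD", "Hyd"),
    ar("ARG", "CB", "Hyd"), ar("ARG", "CG", "Hyd"),
    ar("PHE", "CB", "Hyd"), ar("PHE", "CG", "Hyd"),
    ar("PHE", "CD1", "Hyd"), ar("PHE", "CD2", "Hyd"),
    ar("PHE", "CE1", "Hyd"), ar("PHE", "CE2", "Hyd"), ar("PHE", "CZ", "Hyd"),
    ar("TYR", "CB", "Hyd"), ar("TYR", "CG", "Hyd"),
    ar("TYR", "CD1", "Hyd"), ar("TYR", "CD2", "Hyd"),
    ar("TYR", "CE1", "Hyd"), ar("TYR", "CE2", "Hyd"),
    ar("TRP", "CB", "Hyd"), ar("TRP", "CG", "Hyd"), ar("TRP", "CD2", "Hyd"),
    ar("TRP", "CE3", "Hyd"), ar("TRP", "CZ2", "Hyd"),
    ar("TRP", "CZ3", "Hyd"), ar("TRP", "CH2", "Hyd"),
    # probe residues for synthetic pockets: one pseudo-atom, typed directly
    ar("DON", "X", "Don"), ar("ACC", "X", "Acc"),
    ar("CAT", "X", "Cat"), ar("ANI", "X", "Ani"),
    ar("ARO", "X", "Aro"), ar("HYD", "X", "Hyd"),
    ar("DOA", "X", "Don"), ar("DOA", "X", "Acc"),
    ar("PIR", "X", "Aro|PiR"))
  gr <- function(resid, class, atoms)
    data.frame(resid = resid, class = class, atoms = atoms)
  group_rules <- rbind(
    # anionic group centroids
    gr("ASP", "Ani", "CG,OD1,OD2"),
    gr("GLU", "Ani", "CD,OE1,OE2"),
    # cationic guanidinium: charge centroid plus planar pi system
    gr("ARG", "Cat", "CZ,NE,NH1,NH2"),
    gr("ARG", "Aro|PiR", "CZ,NE,NH1,NH2"),
    # aromatic ring centroids
    gr("PHE", "Aro", "CG,CD1,CD2,CE1,CE2,CZ"),
    gr("TYR", "Aro", "CG,CD1,CD2,CE1,CE2,CZ"),
    gr("HIS", "Aro", "CG,ND1,CD2,CE1,NE2"),
    gr("TRP", "Aro", "CG,CD1,CD2,NE1,CE2"),
    gr("TRP", "Aro", "CD2,CE2,CE3,CZ2,CZ3,CH2"),
    # hydrophobic side-chain centroids (>= 3 contiguous apolar atoms)
    gr("VAL", "Hyd", "CB,CG1,CG2"),
    gr("LEU", "Hyd", "CB,CG,CD1,CD2"),
    gr("ILE", "Hyd", "CB,CG1,CG2,CD1"),
    gr("LYS", "Hyd", "CB,CG,CD"),
    gr("PHE", "Hyd", "CG,CD1,CD2,CE1,CE2,CZ"),
    gr("TYR", "Hyd", "CG,CD1,CD2,CE1,CE2"),
    gr("TRP", "Hyd", "CD2,CE2,CE3,CZ2,CZ3,CH2"))
  list(version = "1", atom_rules = atom_rules, group_rules = group_rules)
}

#' Perceive pharmacophore annotation points on a set of protein atoms
#'
#' Applies the rule table to one conformation's atoms. One atom may yield
#' several points (e.g. a hydroxyl oxygen is both donor and acceptor;
#' overlap merging in [build_features()] later combines them). Returns an
#' empty table when nothing is typable.
#'
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param atoms data.frame with `elety`, `resid`, `resno`, `chain` for the
#'   same n atoms.
#' @param rules a rule table from [typing_rules()].
#' @return data.frame: `class`, `x`, `y`, `z`, `source` ("atom" or
#'   "centroid"), `source_atoms` (comma-separated 1-based indices into the
#'   input).
#' @export
perceive_annotations <- function(coords, atoms, rules = typing_rules()) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(atoms))
  out <- list()
  key_res <- as.character(atoms$resid)
  key_ele <- as.character(atoms$elety)
  # single-atom rules
  arl <- rules$atom_rules
  for (r in seq_len(nrow(arl))) {
    hit <- (arl$resid[r] == "*" | key_res == arl$resid[r]) &
      key_ele == arl$elety[r]
    if (arl$resid[r] == "*" && arl$elety[r] == "N")
      hit <- hit & key_res != "PRO"         # proline N has no H
    for (i in which(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        class = arl$class[r], x = coords[i, 1], y = coords[i, 2],
        z = coords[i, 3], source = "atom", source_atoms = as.character(i))
    }
  }
  # group (centroid) rules, applied per residue instance
  grl <- rules$group_rules
  resinst <- paste(atoms$chain, atoms$resno, key_res, sep = "|")
  for (r in seq_len(nrow(grl))) {
    members <- strsplit(grl$atoms[r], ",")[[1]]
    cand <- which(key_res == grl$resid[r] & key_ele %in% members)
    if (length(cand) == 0L) next
    for (inst in unique(resinst[cand])) {
      ii <- cand[resinst[cand] == inst]
      if (length(ii) < length(members)) next   # incomplete group: skip
      ctr <- colMeans(coords[ii, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        class = grl$class[r], x = ctr[1], y = ctr[2], z = ctr[3],
        source = "centroid", source_atoms = paste(ii, collapse = ","))
    }
  }
  if (length(out) == 0L)
    return(data.frame(class = character(), x = numeric(), y = numeric(),
                      z = numeric(), source = character(),
                      source_atoms = character()))
  do.call(rbind, out)
}
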