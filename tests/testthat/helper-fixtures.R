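# small structure fixtures built in code

# a toy two-residue peptide-like fragment: an alanine-ish residue and an
# aspartate-ish residue, coordinates arbitrary but fixed
toy_protein_atoms <- function() {
  data.frame(
    elety = c("N", "CA", "C", "O", "CB",
              "N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    resid = c(rep("ALA", 5), rep("ASP", 8)),
    resno = c(rep(10L, 5), rep(12L, 8)),
    chain = "A",
    elesy = c("N", "C", "C", "O", "C",
              "N", "C", "C", "O", "C", "C", "O", "O"))
}

toy_protein_coords <- function() {
  rbind(
    c(0.0, 0.0, 0.0), c(1.5, 0.0, 0.0), c(2.2, 1.3, 0.0),
    c(1.6, 2.4, 0.0), c(2.0, -1.2, 1.0),
    c(3.5, 1.3, 0.0), c(4.3, 2.5, 0.0), c(5.8, 2.3, 0.0),
    c(6.4, 1.2, 0.0), c(3.9, 3.4, 1.2), c(4.5, 3.6, 2.6),
    c(5.7, 3.3, 2.9), c(3.8, 4.2, 3.4))
}

toy_ensemble <- function(n = 2L, shift = c(0, 0, 0)) {
  crd <- toy_protein_coords()
  xyz <- do.call(rbind, lapply(seq_len(n), function(i) {
    as.vector(t(sweep(crd, 2, (i - 1) * shift, `+`)))
  }))
  ph4_ensemble(xyz, toy_protein_atoms())
}

# phenylalanine side-chain ring (ideal hexagon, 1.39 A bond length)
phe_ring <- function(center = c(0, 0, 0)) {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  r <- 1.39
  coords <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang),
                  center[3])
  atoms <- data.frame(
    elety = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    resid = "PHE", resno = 1L, chain = "A", elesy = "C")
  list(coords = coords, atoms = atoms)
}

# ethanol with explicit hydrogens: C1-C2-O, H on O and on carbons
ethanol_conformer <- function() {
  coords <- rbind(
    c(0.0, 0.0, 0.0),    # C1 (CH3)
    c(1.5, 0.0, 0.0),    # C2
    c(2.2, 1.2, 0.0),    # O
    c(3.1, 1.1, 0.3),    # H(O)
    c(-0.5, 0.9, 0.3), c(-0.4, -0.9, 0.3), c(0.1, 0.1, -1.1),  # H(C1)
    c(1.9, -0.5, 0.9), c(1.8, -0.6, -0.8))                      # H(C2)
  list(coords = coords,
       elem = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
       bonds = data.frame(a = c(1, 2, 3, 1, 1, 1, 2, 2),
                          b = c(2, 3, 4, 5, 6, 7, 8, 9),
                          order = 1L),
       classes = NULL)
}

# benzene, no explicit hydrogens
benzene_conformer <- function() {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  coords <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  list(coords = coords, elem = rep("C", 6),
       bonds = data.frame(a = 1:6, b = c(2:6, 1),
                          order = rep(c(2L, 1L), 3)),
       classes = NULL)
}

# per-frame feature lists with a feature planted in a chosen frame subset
planted_frames_features <- function(n_frames, present, class = "Don",
                                    pos = c(0, 0, 0), radius = 1.2) {
  lapply(seq_len(n_frames), function(i) {
    if (i %in% present)
      data.frame(class = class, x = pos[1], y = pos[2], z = pos[3],
                 radius = radius)
    else
      data.frame(class = character(), x = numeric(), y = numeric(),
                 z = numeric(), radius = numeric())
  })
}
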