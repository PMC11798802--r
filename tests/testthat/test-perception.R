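test_that("template typing places the expected annotation points", {
  pts <- perceive_annotations(toy_protein_coords(), toy_protein_atoms())
  crd <- toy_protein_coords()
  # backbone amide N -> Don at the nitrogen
  don <- pts[pts$class == "Don", ]
  expect_true(any(don$x == crd[1, 1] & don$y == crd[1, 2]))
  # backbone carbonyl O -> Acc
  acc <- pts[pts$class == "Acc", ]
  expect_true(any(acc$x == crd[4, 1]))
  # aspartate: Ani at the carboxylate centroid, Acc on both oxygens
  ani <- pts[pts$class == "Ani", ]
  expect_equal(nrow(ani), 1)
  expect_equal(c(ani$x, ani$y, ani$z),
               unname(colMeans(crd[11:13, ])), tolerance = 1e-12)
  expect_true(all(c(crd[12, 1], crd[13, 1]) %in% acc$x))
})

test_that("an aromatic ring yields one Aro point at its centroid", {
  ring <- phe_ring(center = c(2, -1, 3))
  pts <- perceive_annotations(ring$coords, ring$atoms)
  aro <- pts[pts$class == "Aro", ]
  expect_equal(nrow(aro), 1)
  expect_equal(c(aro$x, aro$y, aro$z), c(2, -1, 3), tolerance = 1e-9)
})

test_that("untypable atoms produce an empty annotation table", {
  atoms <- data.frame(elety = "C", resid = "PKT", resno = 1L,
                      chain = "A", elesy = "C")
  pts <- perceive_annotations(matrix(0, 1, 3), atoms)
  expect_equal(nrow(pts), 0)
})

test_that("feature radii follow the class defaults", {
  pts <- data.frame(class = c("Acc", "Don", "Aro", "Hyd", "Cat", "Ani"),
                    x = c(0, 10, 20, 30, 40, 50), y = 0, z = 0,
                    source = "atom", source_atoms = "1")
  f <- build_features(pts)
  expect_equal(f$radius[f$class == "Acc"], 1.2)
  expect_equal(f$radius[f$class == "Don"], 1.2)
  expect_equal(f$radius[f$class == "Aro"], 1.4)
  expect_equal(f$radius[f$class == "Hyd"], 1.6)
  expect_equal(f$radius[f$class == "Cat"], 1.2)
  expect_equal(f$radius[f$class == "Ani"], 1.2)
})

test_that("hydrophobic merging groups points within 1 A, capped at 3 A", {
  two_hyd <- function(d) data.frame(
    class = "Hyd", x = c(0, d), y = 0, z = 0,
    source = "atom", source_atoms = c("1", "2"))
  near <- build_features(two_hyd(0.8))
  expect_equal(nrow(near), 1)
  expect_equal(near$radius, 0.4 + 1.6)   # half-separation + class radius
  expect_lte(near$radius, 3.0)
  far <- build_features(two_hyd(1.5))
  expect_equal(nrow(far), 2)
  expect_equal(far$radius, c(1.6, 1.6))
  # transitive chain: 0-0.9-1.8 merges all three though ends are 1.8 apart
  chain <- build_features(data.frame(
    class = "Hyd", x = c(0, 0.9, 1.8), y = 0, z = 0,
    source = "atom", source_atoms = c("1", "2", "3")))
  expect_equal(nrow(chain), 1)
  # a long chain's radius is capped at 3.0
  long <- build_features(data.frame(
    class = "Hyd", x = seq(0, 4.5, by = 0.9), y = 0, z = 0,
    source = "atom", source_atoms = as.character(1:6)))
  expect_equal(nrow(long), 1)
  expect_equal(long$radius, 3.0)
})

test_that("hydrophobic merging is independent of point order", {
  set.seed(5)
  pts <- data.frame(class = "Hyd",
                    x = c(0, 0.9, 1.8, 6, 6.9, 10), y = 0, z = 0,
                    source = "atom", source_atoms = as.character(1:6))
  f1 <- build_features(pts)
  f2 <- build_features(pts[sample(nrow(pts)), ])
  expect_equal(f1, f2)
})

test_that("co-located donor/acceptor and donor/cation points merge", {
  pts <- data.frame(class = c("Don", "Acc"), x = c(0, 0.3), y = 0, z = 0,
                    source = "atom", source_atoms = c("1", "1"))
  f <- build_features(pts)
  expect_equal(nrow(f), 1)
  expect_equal(f$class, "Don|Acc")
  expect_equal(f$x, 0.15)
  pts2 <- data.frame(class = c("Don", "Cat"), x = 0, y = 0, z = 0,
                     source = "atom", source_atoms = c("1", "1"))
  expect_equal(build_features(pts2)$class, "Don|Cat")
  # beyond the overlap tolerance they stay separate
  pts3 <- data.frame(class = c("Don", "Acc"), x = c(0, 0.8), y = 0, z = 0,
                     source = "atom", source_atoms = c("1", "2"))
  expect_setequal(build_features(pts3)$class, c("Acc", "Don"))
})

test_that("features are equivariant under rigid motion and deterministic", {
  crd <- toy_protein_coords()
  atoms <- toy_protein_atoms()
  f1 <- build_features(perceive_annotations(crd, atoms))
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  crd2 <- sweep(crd %*% t(R), 2, c(3, -2, 1), `+`)
  f2 <- build_features(perceive_annotations(crd2, atoms))
  expect_equal(f2$radius[order(f2$class)], f1$radius[order(f1$class)])
  expect_equal(sort(f2$class), sort(f1$class))
  c1 <- sweep(as.matrix(f1[order(f1$class, f1$x), c("x", "y", "z")]) %*%
                t(R), 2, c(3, -2, 1), `+`)
  c2 <- as.matrix(f2[order(f2$class, f2$x), c("x", "y", "z")])
  # same multiset of centers after applying the same motion
  d <- as.matrix(stats::dist(rbind(c1, c2)))[seq_len(nrow(c1)),
                                             nrow(c1) + seq_len(nrow(c2))]
  expect_lt(max(apply(d, 1, min)), 1e-9)
  # determinism: identical input gives byte-identical output
  expect_identical(f1, build_features(perceive_annotations(crd, atoms)))
})

test_that("per-frame site perception is constant on a rigid ensemble", {
  ens <- toy_ensemble(n = 10, shift = c(0, 0, 0))
  sf <- perceive_site(ens, site_residues(c(10, 12)))
  expect_length(sf, 10)
  for (i in 2:10) expect_identical(sf[[i]], sf[[1]])
})

test_that("a feature leaving the site drops from that frame only", {
  gen <- make_ensemble(ensemble_spec(n_frames = 6, jitter_sigma = 0,
                                     binding_fraction = 0.34, seed = 2))
  sf <- perceive_site(gen$ensemble, gen$site)
  occ <- gen$truth$occupancy
  planted <- which(gen$truth$features$role == "planted")
  for (j in planted) {
    cls <- gen$truth$features$class[j]
    pos <- unlist(gen$truth$features[j, c("x", "y", "z")])
    got <- vapply(seq_len(6), function(i) {
      f <- sf[[i]]
      any(f$class == cls &
            sqrt((f$x - pos[1])^2 + (f$y - pos[2])^2 +
                   (f$z - pos[3])^2) < 0.5)
    }, logical(1))
    expect_equal(as.integer(got), occ[, j])
  }
})

test_that("ligand graph perception types ethanol and benzene sensibly", {
  eth <- annotate_conformer(ethanol_conformer())
  # hydroxyl O is both donor and acceptor -> combined class
  expect_true("Don|Acc" %in% eth$class)
  # terminal CH3 carbon is hydrophobic; C2 borders O so it is not
  expect_equal(sum(eth$class == "Hyd"), 1)
  bz <- annotate_conformer(benzene_conformer())
  aro <- bz[bz$class == "Aro", ]
  expect_equal(nrow(aro), 1)
  expect_equal(c(aro$x, aro$y, aro$z), c(0, 0, 0), tolerance = 1e-9)
  # six hydrophobic ring atoms plus the contiguous-group centroid
  expect_equal(sum(bz$class == "Hyd"), 7)
})

test_that("explicit per-atom classes override graph perception", {
  cf <- list(coords = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
             elem = c("C", "C", "C"),
             bonds = data.frame(a = 1:2, b = 2:3, order = 1L),
             classes = c("Don", "-", "Aro"))
  pts <- annotate_conformer(cf)
  expect_equal(pts$class, c("Don", "Aro"))
  expect_equal(pts$x, c(0, 2))
})
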