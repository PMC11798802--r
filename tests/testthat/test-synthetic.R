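test_that("the generator is bit-reproducible under a fixed seed", {
  a <- make_ensemble(ensemble_spec(n_frames = 30, seed = 5))
  b <- make_ensemble(ensemble_spec(n_frames = 30, seed = 5))
  expect_identical(a$ensemble$xyz, b$ensemble$xyz)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth$occupancy, b$truth$occupancy)
  c <- make_ensemble(ensemble_spec(n_frames = 30, seed = 6))
  expect_false(identical(a$ensemble$xyz, c$ensemble$xyz))
})

test_that("zero jitter leaves only feature on/off variation", {
  gen <- make_ensemble(ensemble_spec(n_frames = 10, jitter_sigma = 0,
                                     seed = 3))
  npk <- gen$spec$n_site_atoms
  pocket_cols <- seq_len(3 * npk)
  for (i in 2:10)
    expect_equal(gen$ensemble$xyz[i, pocket_cols],
                 gen$ensemble$xyz[1, pocket_cols])
})

test_that("realized occupancy frequencies sit in the binomial 99% CI", {
  gen <- make_ensemble(ensemble_spec(n_frames = 200, seed = 42))
  occ <- gen$truth$occupancy
  feats <- gen$truth$features
  nb <- sum(gen$labels == 1)
  for (j in which(feats$role == "planted")) {
    hits_b <- sum(occ[gen$labels == 1, j])
    ci <- qbinom(c(0.005, 0.995), nb, feats$freq_binding[j])
    expect_gte(hits_b, ci[1]); expect_lte(hits_b, ci[2])
    hits_nb <- sum(occ[gen$labels == 0, j])
    ci2 <- qbinom(c(0.005, 0.995), 200 - nb, feats$freq_nonbinding[j])
    expect_gte(hits_nb, ci2[1]); expect_lte(hits_nb, ci2[2])
  }
})

test_that("generator bookkeeping and the encoder agree bit-exactly", {
  gen <- make_ensemble(ensemble_spec(n_frames = 50, seed = 9))
  ens <- superpose_ensemble(gen$ensemble, gen$superpose_site)
  occ <- encode_binary(build_consensus(perceive_site(ens, gen$site)),
                       gen$labels)
  feats <- gen$truth$features
  for (j in seq_len(nrow(feats))) {
    # find the consensus column at the planted position/class
    cand <- occ$features
    d <- sqrt((cand$x - feats$x[j])^2 + (cand$y - feats$y[j])^2 +
                (cand$z - feats$z[j])^2)
    hit <- which(d < 1.0 &
                   classes_compatible(cand$class,
                                      rep(feats$class[j], nrow(cand))))
    expect_length(hit, 1)
    expect_equal(unname(occ$matrix[, cand$id[hit]]),
                 gen$truth$occupancy[, j])
  }
})

test_that("infeasible generator frequencies are refused", {
  expect_error(ensemble_spec(planted = data.frame(
    class = "Don", x = 0, y = 0, z = 0,
    freq_binding = 1.2, freq_nonbinding = 0.05)), "frequencies")
  expect_error(ensemble_spec(binding_fraction = 0), "binding_fraction")
  expect_error(ensemble_spec(n_frames = 5, binding_fraction = 0.1),
               "binding_fraction")
})

test_that("zero active jitter makes every active match exactly", {
  q <- structure(list(
    features = data.frame(id = c("F1_Don", "F2_Acc", "F3_Hyd"),
                          class = c("Don", "Acc", "Hyd"),
                          x = c(0, 4, 2), y = c(0, 0, 3), z = 0,
                          radius = c(1.2, 1.2, 1.6)),
    match_mode = "all", m = 3L), class = "ph4_query")
  gen <- make_library(library_spec(q, n_actives = 10, n_decoys = 0,
                                   conformers_per_molecule = 2,
                                   active_jitter = 0, seed = 11))
  out <- search_library(q, gen$library, tolerance = 0)
  expect_true(all(out$results$matched))
  expect_lt(max(out$results$rmsd), 1e-6)
})

test_that("drop-one decoys never match an all-features query", {
  q <- structure(list(
    features = data.frame(id = c("F1_Don", "F2_Acc", "F3_Hyd", "F4_Aro"),
                          class = c("Don", "Acc", "Hyd", "Aro"),
                          x = c(0, 4, 2, -2), y = c(0, 0, 3, 2), z = 0,
                          radius = c(1.2, 1.2, 1.6, 1.4)),
    match_mode = "all", m = 4L), class = "ph4_query")
  gen <- make_library(library_spec(q, n_actives = 5, n_decoys = 40,
                                   conformers_per_molecule = 3,
                                   active_jitter = 0.2, seed = 13))
  out <- search_library(q, gen$library, tolerance = 0.2)
  decoys <- out$results$activity == "decoy"
  expect_false(any(out$results$matched[decoys]))
  expect_true(all(out$results$matched[!decoys]))
})

test_that("an over-large active jitter warns", {
  q <- structure(list(
    features = data.frame(id = c("F1_Don", "F2_Acc", "F3_Hyd"),
                          class = c("Don", "Acc", "Hyd"),
                          x = c(0, 4, 2), y = c(0, 0, 3), z = 0,
                          radius = c(1.2, 1.2, 1.6)),
    match_mode = "all", m = 3L), class = "ph4_query")
  expect_warning(library_spec(q, active_jitter = 1.3), "jitter")
})

test_that("SDF round trip preserves the library through the parser", {
  q <- structure(list(
    features = data.frame(id = c("F1_Don", "F2_Acc", "F3_Hyd"),
                          class = c("Don", "Acc", "Hyd"),
                          x = c(0, 4, 2), y = c(0, 0, 3), z = 0,
                          radius = c(1.2, 1.2, 1.6)),
    match_mode = "all", m = 3L), class = "ph4_query")
  gen <- make_library(library_spec(q, n_actives = 3, n_decoys = 4,
                                   conformers_per_molecule = 2,
                                   seed = 17))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_library(gen$library, path)
  back <- read_ligand_library(path)
  expect_length(back$molecules, 7)
  ids <- vapply(back$molecules, `[[`, "", "id")
  expect_setequal(ids, vapply(gen$library$molecules, `[[`, "", "id"))
  m0 <- gen$library$molecules[[1]]
  m1 <- back$molecules[[which(ids == m0$id)]]
  expect_equal(m1$activity, m0$activity)
  expect_length(m1$conformers, length(m0$conformers))
  expect_equal(m1$conformers[[1]]$coords, m0$conformers[[1]]$coords,
               tolerance = 1e-4)
  expect_equal(m1$conformers[[1]]$classes, m0$conformers[[1]]$classes)
  # screening the reloaded library gives the same hit set
  out0 <- search_library(q, gen$library, tolerance = 0.3)
  out1 <- search_library(q, back, tolerance = 0.3)
  expect_equal(out1$results$matched[match(out0$results$molecule_id,
                                          out1$results$molecule_id)],
               out0$results$matched)
})

test_that("a band excluding the planted frequency kills recovery", {
  r <- end_to_end_recovery(ensemble_spec(n_frames = 100, seed = 19),
                           band = c(0.40, 0.55), k = 1)
  expect_equal(r$recall, 0)
  expect_equal(r$ef_flag, "NA")
})

test_that("a decoy-free library yields the +Inf EF sentinel", {
  ens_spec <- ensemble_spec(n_frames = 100, seed = 23)
  gen <- make_ensemble(ens_spec)
  planted <- gen$truth$features[gen$truth$features$role == "planted", ]
  q <- structure(list(
    features = data.frame(
      id = paste0("T", seq_len(nrow(planted)), "_", planted$class),
      class = planted$class, x = planted$x, y = planted$y, z = planted$z,
      radius = 1.2),
    match_mode = "all", m = nrow(planted)), class = "ph4_query")
  nuis <- gen$truth$features[gen$truth$features$role == "nuisance", ]
  lib <- library_spec(q, n_actives = 10, n_decoys = 0,
                      conformers_per_molecule = 2,
                      extra_points = nuis[, c("class", "x", "y", "z")],
                      seed = 23)
  r <- end_to_end_recovery(ens_spec, lib_spec = lib)
  expect_identical(r$ef, Inf)
  expect_equal(r$ef_flag, "no-decoy-hits")
})
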