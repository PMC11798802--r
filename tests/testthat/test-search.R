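toy_query <- function() {
  structure(list(
    features = data.frame(
      id = c("F1_Don", "F2_Acc", "F3_Aro", "F4_Hyd"),
      class = c("Don", "Acc", "Aro", "Hyd"),
      x = c(0, 4, 0, 2), y = c(0, 0, 4, 2), z = c(0, 0, 0, 3),
      radius = c(1.2, 1.2, 1.4, 1.6)),
    match_mode = "all", m = 4L), class = "ph4_query")
}

points_at_query <- function(q) {
  data.frame(class = q$features$class, x = q$features$x,
             y = q$features$y, z = q$features$z)
}

test_that("query assembly validates feature ids and size", {
  sf <- lapply(1:5, function(i)
    data.frame(class = c("Don", "Acc", "Aro"), x = c(0, 5, -5),
               y = 0, z = 0, radius = c(1.2, 1.2, 1.4)))
  occ <- encode_binary(build_consensus(sf), labels = c(1, 1, 0, 0, 0))
  q <- build_query(occ, feature_ids = occ$features$id)
  expect_s3_class(q, "ph4_query")
  expect_equal(nrow(q$features), 3)
  expect_error(build_query(occ, feature_ids = occ$features$id[1:2]),
               ">= 3 features")
  expect_error(build_query(occ, feature_ids = c("F1_Don", "nope", "x")),
               "unknown feature ids")
  # manual override wins over votes
  votes <- data.frame(feature_id = occ$features$id,
                      selected = c(TRUE, TRUE, FALSE))
  q2 <- build_query(occ, votes = votes, feature_ids = occ$features$id)
  expect_equal(nrow(q2$features), 3)
})

test_that("exact placement matches with zero RMSD", {
  q <- toy_query()
  r <- match_conformer(q, points_at_query(q))
  expect_true(r$matched)
  expect_lt(r$rmsd, 1e-10)
  expect_equal(r$correspondence$point_index, 1:4)
})

test_that("a conformer missing a required class cannot match", {
  q <- toy_query()
  pts <- points_at_query(q)[-1, ]           # drop the donor point
  r <- match_conformer(q, pts)
  expect_false(r$matched)
  expect_true(is.na(r$rmsd))
  # duplicated class elsewhere does not compensate
  pts2 <- rbind(pts, data.frame(class = "Acc", x = 9, y = 9, z = 9))
  expect_false(match_conformer(q, pts2)$matched)
})

test_that("combined classes satisfy either member class", {
  q <- toy_query()
  pts <- points_at_query(q)
  pts$class[1] <- "Don|Acc"                 # point side
  expect_true(match_conformer(q, pts)$matched)
  q2 <- toy_query()
  q2$features$class[2] <- "Don|Acc"         # query side
  pts2 <- points_at_query(toy_query())
  pts2$class[2] <- "Don"
  expect_true(match_conformer(q2, pts2)$matched)
  expect_false(any(classes_compatible("Aro|PiR", "Hyd")))
})

test_that("matching agrees with the exhaustive oracle on jittered actives", {
  set.seed(33)
  for (i in 1:25) {
    case <- random_match_case(nf = sample(3:5, 1), extra = sample(0:3, 1),
                              jitter = 0.3)
    fast <- match_conformer(case$query, case$points, tolerance = 0.5)
    slow <- oracle_match(case$query, case$points, tolerance = 0.5)
    expect_equal(fast$matched, slow$matched)
    if (fast$matched) expect_equal(fast$rmsd, slow$rmsd, tolerance = 1e-6)
  }
})

test_that("matching is invariant under proper rigid motions", {
  set.seed(37)
  q <- toy_query()
  pts <- points_at_query(q)
  pts[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] +
    matrix(rnorm(12, 0, 0.2), ncol = 3)
  base <- match_conformer(q, pts, tolerance = 0.5)
  expect_true(base$matched)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0),
                c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])),
                c(0, sin(th[2]), cos(th[2])))
    moved <- as.matrix(pts[, c("x", "y", "z")]) %*% t(Rz %*% Rx)
    moved <- sweep(moved, 2, runif(3, -15, 15), `+`)
    pts2 <- pts; pts2[, c("x", "y", "z")] <- moved
    r <- match_conformer(q, pts2, tolerance = 0.5)
    expect_true(r$matched)
    expect_equal(r$rmsd, base$rmsd, tolerance = 1e-6)
    expect_equal(det(r$rotation), 1, tolerance = 1e-9)
  }
})

test_that("mirror-image conformers are rejected (no improper fits)", {
  q <- toy_query()
  pts <- points_at_query(q)
  pts$x <- -pts$x                           # reflection
  r <- match_conformer(q, pts)
  expect_false(r$matched)
})

test_that("accepted-match RMSD is bounded by the largest feature radius", {
  set.seed(41)
  q <- toy_query()
  for (i in 1:10) {
    pts <- points_at_query(q)
    pts[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] +
      matrix(rnorm(12, 0, 0.6), ncol = 3)
    r <- match_conformer(q, pts, tolerance = 0.2)
    if (r$matched)
      expect_lte(r$rmsd, max(q$features$radius) + 0.2 + 1e-9)
  }
})

test_that("relaxing all-features to (n-1)-of-n never shrinks the hit set", {
  set.seed(43)
  q_all <- toy_query()
  q_rel <- toy_query(); q_rel$match_mode <- "m-of-n"; q_rel$m <- 3L
  for (i in 1:15) {
    pts <- points_at_query(q_all)
    pts[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] +
      matrix(rnorm(12, 0, 0.8), ncol = 3)
    a <- match_conformer(q_all, pts, tolerance = 0.3)
    b <- match_conformer(q_rel, pts, tolerance = 0.3)
    if (a$matched) expect_true(b$matched)
    if (a$matched && b$matched) expect_lte(b$rmsd, a$rmsd + 1e-9)
  }
})

test_that("library search keeps the best conformer per molecule", {
  q <- toy_query()
  good <- points_at_query(q)
  near <- good; near$x <- near$x + 0.1      # small distortion
  far <- good; far$x <- far$x + 0.6         # larger distortion
  as_conf <- function(p) list(coords = as.matrix(p[, c("x", "y", "z")]),
                              elem = rep("C", nrow(p)),
                              bonds = data.frame(a = integer(),
                                                 b = integer(),
                                                 order = integer()),
                              classes = p$class)
  lib <- ph4_library(list(
    list(id = "M1", activity = "active",
         conformers = list(as_conf(far), as_conf(near)))))
  out <- search_library(q, lib, tolerance = 0.8)
  expect_true(out$results$matched)
  expect_equal(out$results$conformer, 2L)   # the 0.1-shift conformer wins
  expect_error(search_library(q, ph4_library(list())), "empty")
})

test_that("synthetic library screening recovers the ground-truth hit set", {
  q <- toy_query()
  gen <- make_library(library_spec(q, n_actives = 20, n_decoys = 60,
                                   conformers_per_molecule = 3,
                                   active_jitter = 0.2, seed = 7))
  out <- search_library(q, gen$library, tolerance = 0.2)
  hits <- out$results$molecule_id[out$results$matched]
  expect_setequal(hits, gen$truth$molecule_id[gen$truth$must_match])
})

test_that("query JSON round trips", {
  q <- toy_query()
  path <- withr::local_tempfile(fileext = ".json")
  write_query(q, path)
  back <- read_query(path)
  expect_equal(back$features, q$features)
  expect_equal(back$match_mode, q$match_mode)
})
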