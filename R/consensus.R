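#' Cluster per-frame features into consensus features
#'
#' Greedy leader clustering within each feature class: features are
#' visited in frame order (canonical order within a frame); a feature
#' joins the first-founded cluster of its class whose running centroid
#' lies within `cluster_radius`, otherwise it founds a new cluster. The
#' centroid is updated incrementally. A cluster's frequency is the
#' fraction of distinct frames contributing at least one member — a frame
#' with two members of one cluster counts once, which is what makes the
#' binary occurrence-matrix column means equal the frequencies.
#'
#' Consensus ids are assigned in descending frequency order, `F1_<class>`
#' first.
#'
#' @param site_features list of per-frame feature tables
#'   ([perceive_site()] output); list order is frame (time) order.
#' @param cluster_radius joining distance in Angstrom (default 1.5).
#' @return An object of class `ph4_consensus`: `features` (data.frame
#'   `id`, `class`, `x`, `y`, `z`, `radius`, `frequency`, `member_count`),
#'   `members` (data.frame `frame`, `id`), `n_frames`.
#' @export
build_consensus <- function(site_features, cluster_radius = 1.5) {
  if (!is.finite(cluster_radius) || cluster_radius <= 0)
    stop("cluster_radius must be > 0")
  nfr <- length(site_features)
  if (nfr == 0L) stop("no frames")
  # cluster state, per class
  cl_class <- character(); cl_sum <- NULL; cl_n <- integer()
  cl_radsum <- numeric()
  memb_frame <- integer(); memb_cluster <- integer()
  for (fi in seq_len(nfr)) {
    f <- site_features[[fi]]
    if (is.null(f) || nrow(f) == 0L) next
    for (r in seq_len(nrow(f))) {
      p <- c(f$x[r], f$y[r], f$z[r])
      same <- which(cl_class == f$class[r])
      hit <- 0L
      if (length(same) > 0L) {
        ctr <- cl_sum[same, , drop = FALSE] / cl_n[same]
        d2 <- rowSums(sweep(ctr, 2, p)^2)
        ok <- which(d2 <= cluster_radius^2)
        if (length(ok) > 0L) hit <- same[ok[1]]   # first-founded wins ties
      }
      if (hit == 0L) {
        cl_class <- c(cl_class, f$class[r])
        cl_sum <- rbind(cl_sum, p)
        cl_n <- c(cl_n, 1L)
        cl_radsum <- c(cl_radsum, f$radius[r])
        hit <- length(cl_class)
      } else {
        cl_sum[hit, ] <- cl_sum[hit, ] + p
        cl_n[hit] <- cl_n[hit] + 1L
        cl_radsum[hit] <- cl_radsum[hit] + f$radius[r]
      }
      memb_frame <- c(memb_frame, fi)
      memb_cluster <- c(memb_cluster, hit)
    }
  }
  k <- length(cl_class)
  if (k == 0L) stop("no features to cluster")
  freq <- vapply(seq_len(k), function(j)
    length(unique(memb_frame[memb_cluster == j])) / nfr, numeric(1))
  ctr <- cl_sum / cl_n
  feats <- data.frame(class = cl_class, x = ctr[, 1], y = ctr[, 2],
                      z = ctr[, 3], radius = cl_radsum / cl_n,
                      frequency = freq, member_count = cl_n)
  # id assignment: descending frequency, ties by class then center
  ord <- order(-feats$frequency, feats$class, feats$x, feats$y, feats$z)
  feats <- feats[ord, , drop = FALSE]
  feats$id <- paste0("F", seq_len(k), "_", feats$class)
  feats <- feats[, c("id", "class", "x", "y", "z", "radius",
                     "frequency", "member_count")]
  rownames(feats) <- NULL
  remap <- match(seq_len(k), ord)   # old cluster index -> new row
  members <- data.frame(frame = memb_frame,
                        id = feats$id[remap[memb_cluster]])
  structure(list(features = feats, members = members, n_frames = nfr),
            class = "ph4_consensus")
}

#' @export
print.ph4_consensus <- function(x, ...) {
  cat("ph4_consensus:", nrow(x$features), "consensus features from",
      x$n_frames, "frames\n")
  invisible(x)
}

#' Binary conformation x feature occurrence matrix
#'
#' Entry (i, k) is 1 iff frame i contributed at least one member to
#' consensus feature k; the per-frame binding label rides along. Column
#' means equal the consensus frequencies exactly.
#'
#' @param consensus a `ph4_consensus`.
#' @param labels binary vector (1 = binding-selected frame), one per frame.
#' @return An object of class `ph4_occurrence`: `matrix` (frames x
#'   features, 0/1, feature ids as colnames), `labels`, `frequency`
#'   (named), `features` (the consensus feature table, for query building).
#' @export
encode_binary <- function(consensus, labels) {
  stopifnot(inherits(consensus, "ph4_consensus"))
  nfr <- consensus$n_frames
  if (length(labels) != nfr)
    stop("label vector length (", length(labels),
         ") does not match frame count (", nfr, ")")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  ids <- consensus$features$id
  m <- matrix(0L, nrow = nfr, ncol = length(ids),
              dimnames = list(NULL, ids))
  mm <- unique(consensus$members)
  m[cbind(mm$frame, match(mm$id, ids))] <- 1L
  structure(list(matrix = m, labels = as.integer(labels),
                 frequency = stats::setNames(consensus$features$frequency, ids),
                 features = consensus$features),
            class = "ph4_occurrence")
}

#' @export
print.ph4_occurrence <- function(x, ...) {
  cat("ph4_occurrence:", nrow(x$matrix), "frames x", ncol(x$matrix),
      "features;", sum(x$labels), "binding-labelled frames\n")
  invisible(x)
}

#' Retain features inside a frequency band
#'
#' Keeps the occurrence-matrix columns whose consensus frequency f
#' satisfies `low <= f <= high`. `high = NULL` means no upper bound; the
#' no-threshold run is `threshold_by_frequency(occ, low = 0)`, which keeps
#' everything. Banded runs conventionally start at `low = 0.01`.
#'
#' @param occ a `ph4_occurrence`.
#' @param low lower frequency bound (fraction, default 0.01).
#' @param high upper frequency bound (fraction) or `NULL` for none.
#' @return The filtered `ph4_occurrence`.
#' @export
threshold_by_frequency <- function(occ, low = 0.01, high = NULL) {
  stopifnot(inherits(occ, "ph4_occurrence"))
  if (!is.null(high) && low > high) stop("low bound exceeds high bound")
  f <- occ$frequency
  keep <- f >= low
  if (!is.null(high)) keep <- keep & f <= high
  occ$matrix <- occ$matrix[, keep, drop = FALSE]
  occ$frequency <- f[keep]
  occ$features <- occ$features[keep, , drop = FALSE]
  occ
}

#' Write an occurrence matrix as CSV
#'
#' Rows are frames, columns the consensus feature ids, plus a trailing
#' `label` column.
#'
#' @param occ a `ph4_occurrence`.
#' @param path output path.
#' @export
write_occurrence_csv <- function(occ, path) {
  df <- as.data.frame(occ$matrix)
  df$label <- occ$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence matrix from CSV
#'
#' Inverse of [write_occurrence_csv()]. Frequencies are recomputed as
#' column means (they are equal by construction).
#'
#' @param path CSV path.
#' @return A `ph4_occurrence` (without the consensus feature geometry).
#' @export
read_occurrence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lab <- df$label
  df$label <- NULL
  m <- as.matrix(df)
  structure(list(matrix = m, labels = as.integer(lab),
                 frequency = colMeans(m), features = NULL),
            class = "ph4_occurrence")
}
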