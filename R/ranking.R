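#' One-way ANOVA F statistic of a feature column against the frame label
#'
#' Textbook decomposition: `F = MS_between / MS_within` for the two label
#' groups. Zero within-group variance with nonzero between-group variance
#' returns `+Inf` — a perfect separator, deliberately ranked above every
#' finite value rather than treated as an error.
#'
#' @param x numeric (here binary) feature column.
#' @param labels binary group labels, same length.
#' @return The F value (possibly `Inf`; 0 when group means are equal).
#' @export
anova_f <- function(x, labels) {
  check_two_class(x, labels)
  g1 <- x[labels == 1]; g0 <- x[labels == 0]
  n1 <- length(g1); n0 <- length(g0); n <- n1 + n0
  gm <- mean(x)
  ss_between <- n1 * (mean(g1) - gm)^2 + n0 * (mean(g0) - gm)^2
  ss_within <- sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)
  ms_between <- ss_between / 1
  ms_within <- ss_within / (n - 2)
  if (ms_within == 0) {
    if (ms_between == 0) return(0)
    return(Inf)
  }
  ms_between / ms_within
}

#' Mutual information of a binary feature column and the frame label
#'
#' Plug-in estimate from the empirical 2x2 joint table,
#' `sum p(x,y) log2( p(x,y) / (p(x) p(y)) )`, with `0 log 0 = 0`.
#' In bits, a balanced column identical to the label scores exactly 1.
#'
#' @inheritParams anova_f
#' @param unit `"bits"` (default) or `"nats"`.
#' @param normalized divide by `min(H(x), H(y))` (off by default; offered
#'   because some usages quote MI on a 0-1 scale).
#' @return Mutual information (>= 0).
#' @export
mutual_information <- function(x, labels, unit = c("bits", "nats"),
                               normalized = FALSE) {
  unit <- match.arg(unit)
  check_two_class(x, labels)
  n <- length(x)
  logf <- if (unit == "bits") log2 else log
  mi <- 0
  for (a in unique(x)) for (b in 0:1) {
    pxy <- sum(x == a & labels == b) / n
    if (pxy == 0) next
    px <- sum(x == a) / n; py <- sum(labels == b) / n
    mi <- mi + pxy * logf(pxy / (px * py))
  }
  mi <- max(mi, 0)   # clamp -0 rounding
  if (normalized) {
    hx <- entropy_vec(x, logf); hy <- entropy_vec(labels, logf)
    denom <- min(hx, hy)
    mi <- if (denom == 0) 0 else mi / denom
  }
  mi
}

entropy_vec <- function(v, logf) {
  p <- table(v) / length(v)
  -sum(ifelse(p > 0, p * logf(p), 0))
}

#' Diagonal-line entropy (ENTR) of a binary presence series
#'
#' Recurrence-plot diagonal-line entropy for the per-feature occupancy
#' time series, in frame order. The recurrence matrix is
#' `R(i,j) = 1 iff x_i == x_j` (exact match; equivalent to any threshold
#' below 1 on the absolute difference of a binary series). Maximal
#' diagonal line segments of length `>= l_min` are collected from all
#' off-main diagonals (the line of identity is excluded), and ENTR is the
#' Shannon entropy of the line-length histogram, in nats. A line spanning
#' its entire diagonal is border-censored — the plot cannot reveal its
#' true length — so all such lines share one "maximal" histogram bin. A
#' degenerate histogram gives 0; in particular the constant series, whose
#' off-diagonals are each one full-diagonal line, collapses to that single
#' bin and scores exactly 0.
#'
#' @param x binary series in frame (time) order.
#' @param l_min minimal line length counted (default 2).
#' @return Entropy in nats (>= 0).
#' @export
rqa_entropy <- function(x, l_min = 2L) {
  n <- length(x)
  if (n < l_min + 1L) stop("series too short for RQA (need length >= l_min + 1)")
  lengths <- numeric(0)
  # upper-triangle diagonals; the symmetric lower triangle duplicates every
  # line and cannot change the normalized length distribution
  for (d in seq_len(n - 1L)) {
    eq <- x[seq_len(n - d)] == x[seq_len(n - d) + d]
    r <- rle(eq)
    runs <- r$lengths[r$values & r$lengths >= l_min]
    # border-censored: a run filling the whole diagonal joins the shared
    # "maximal" bin (coded Inf) instead of its numeric length
    runs[runs == n - d] <- Inf
    if (length(runs) > 0L) lengths <- c(lengths, runs)
  }
  if (length(lengths) == 0L) return(0)
  p <- table(lengths) / length(lengths)
  -sum(p * log(p))
}

#' Absolute Spearman rank correlation of a feature column and the label
#'
#' `|rho|` with average ranks for ties (the standard tie correction). A
#' constant column cannot be ranked against anything: it scores 0 and the
#' result carries attribute `degenerate = TRUE` instead of erroring, so a
#' sweep over many columns never aborts.
#'
#' @inheritParams anova_f
#' @return `|rho|` in `[0, 1]`.
#' @export
spearman_score <- function(x, labels) {
  if (length(x) != length(labels)) stop("length mismatch")
  if (length(unique(x)) < 2L || length(unique(labels)) < 2L)
    return(structure(0, degenerate = TRUE))
  abs(stats::cor(x, labels, method = "spearman"))
}

check_two_class <- function(x, labels) {
  if (length(x) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2L)
    stop("both label classes must be present")
  invisible(TRUE)
}

#' Rank occurrence-matrix columns by four methods and vote
#'
#' Scores every column with ANOVA F, mutual information, RQA diagonal
#' entropy, and absolute Spearman correlation; ranks each method's
#' statistic in descending order (ties broken by ascending feature id, so
#' the pipeline is bit-reproducible); takes the per-method top-`k` sets;
#' and retains the features appearing in all four — a voting score of 4.
#' Columns with zero variance are dropped before ranking and can never be
#' selected.
#'
#' @param occ a `ph4_occurrence` (after any frequency banding).
#' @param k per-method cut (top-k).
#' @param l_min minimal RQA line length.
#' @return data.frame with one row per surviving feature: the four
#'   statistics, the four ranks, `score` (0-4) and `selected`
#'   (`score == 4`).
#' @export
rank_and_vote <- function(occ, k, l_min = 2L) {
  stopifnot(inherits(occ, "ph4_occurrence"))
  if (k < 1L) stop("k must be >= 1")
  m <- occ$matrix
  keep <- apply(m, 2, function(col) length(unique(col)) > 1L)
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < k)
    stop("k (", k, ") exceeds the ", ncol(m),
         " non-constant columns available")
  ids <- colnames(m)
  labels <- occ$labels
  stat <- data.frame(
    feature_id = ids,
    f_value = apply(m, 2, anova_f, labels = labels),
    mi = apply(m, 2, mutual_information, labels = labels),
    rqa_entr = apply(m, 2, rqa_entropy, l_min = l_min),
    spearman_abs = apply(m, 2, function(col)
      as.numeric(spearman_score(col, labels))))
  rank_desc <- function(v) {
    ord <- order(-v, ids)       # ties by ascending feature id
    r <- integer(length(v)); r[ord] <- seq_along(v); r
  }
  stat$rank_f <- rank_desc(stat$f_value)
  stat$rank_mi <- rank_desc(stat$mi)
  stat$rank_rqa <- rank_desc(stat$rqa_entr)
  stat$rank_sp <- rank_desc(stat$spearman_abs)
  stat$score <- (stat$rank_f <= k) + (stat$rank_mi <= k) +
    (stat$rank_rqa <= k) + (stat$rank_sp <= k)
  stat$selected <- stat$score == 4L
  rownames(stat) <- NULL
  stat
}
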