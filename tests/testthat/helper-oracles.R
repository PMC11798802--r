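# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition by a different route than the package
# (aov model fits, full recurrence matrices, exhaustive assignment
# enumeration) so agreement is informative.

# one-way ANOVA F via stats::aov model fit
oracle_anova_f <- function(x, labels) {
  fit <- summary(stats::aov(x ~ factor(labels)))[[1]]
  ssb <- fit[["Sum Sq"]][1]
  ssw <- fit[["Sum Sq"]][2]
  # zero within-group variance (up to model-fit rounding): sentinel cases
  if (ssw < 1e-10) {
    if (ssb < 1e-10) return(0)
    return(Inf)
  }
  fit[["F value"]][1]
}

# plug-in MI from the contingency table of counts
oracle_mi_bits <- function(x, labels) {
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(labels, levels = sort(unique(labels))))
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij == 0) next
    mi <- mi + (nij / n) * log2((nij * n) / (sum(tab[i, ]) * sum(tab[, j])))
  }
  max(mi, 0)
}

# diagonal-line entropy from the explicit full recurrence matrix,
# scanning every off-identity diagonal of both triangles; a run filling
# its whole diagonal is border-censored into one shared "maximal" bin
oracle_rqa_entropy <- function(x, l_min = 2L) {
  n <- length(x)
  R <- outer(x, x, `==`)
  lens <- numeric(0)
  for (d in c(-(n - 1):-1, 1:(n - 1))) {
    idx <- if (d > 0) cbind(seq_len(n - d), seq_len(n - d) + d)
           else cbind(seq_len(n + d) - d, seq_len(n + d))
    diag_vals <- R[idx]
    dlen <- length(diag_vals)
    run <- 0L
    for (v in c(diag_vals, FALSE)) {
      if (v) run <- run + 1L
      else {
        if (run >= l_min) lens <- c(lens, if (run == dlen) Inf else run)
        run <- 0L
      }
    }
  }
  if (length(lens) == 0L) return(0)
  p <- table(lens) / length(lens)
  -sum(p * log(p))
}

# Spearman |rho| from average ranks plugged into the Pearson formula
oracle_spearman_abs <- function(x, labels) {
  rx <- rank(x); ry <- rank(labels)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  abs(num / den)
}

# exhaustive correspondence matcher: enumerate every injective
# class-compatible assignment (no pruning), Kabsch each, keep the
# minimum-RMSD assignment passing the radius check
oracle_match <- function(query, points, tolerance = 0) {
  qf <- query$features
  nq <- nrow(qf)
  np <- nrow(points)
  qxyz <- as.matrix(qf[, c("x", "y", "z")])
  pxyz <- as.matrix(points[, c("x", "y", "z")])
  compat <- matrix(FALSE, nq, np)
  members <- function(s) strsplit(s, "|", fixed = TRUE)[[1]]
  for (i in seq_len(nq)) for (j in seq_len(np))
    compat[i, j] <- length(intersect(members(qf$class[i]),
                                     members(points$class[j]))) > 0
  best <- list(matched = FALSE, rmsd = NA_real_)
  assign <- integer(nq)
  recurse <- function(i) {
    if (i > nq) {
      fit <- ph4ensemble::kabsch(pxyz[assign, , drop = FALSE], qxyz)
      moved <- fit$transform(pxyz[assign, , drop = FALSE])
      resid <- sqrt(rowSums((moved - qxyz)^2))
      if (all(resid <= qf$radius + tolerance) &&
          (!best$matched || fit$rmsd < best$rmsd))
        best <<- list(matched = TRUE, rmsd = fit$rmsd, assign = assign)
      return(NULL)
    }
    for (j in which(compat[i, ])) {
      if (j %in% assign[seq_len(i - 1L)]) next
      assign[i] <<- j
      recurse(i + 1L)
    }
    NULL
  }
  recurse(1L)
  best
}

# random query/conformer pair for matcher comparisons: a query of nf
# features and a conformer carrying a rigidly-moved jittered copy of the
# query points plus distractor points
random_match_case <- function(nf = 4L, extra = 3L, jitter = 0.2,
                              classes = c("Don", "Acc", "Aro", "Hyd", "Cat")) {
  cls <- sample(classes, nf, replace = TRUE)
  centers <- matrix(stats::runif(nf * 3, -5, 5), ncol = 3)
  while (min(stats::dist(centers)) < 2) {
    centers <- matrix(stats::runif(nf * 3, -5, 5), ncol = 3)
  }
  rad <- c(Don = 1.2, Acc = 1.2, Cat = 1.2, Ani = 1.2,
           Aro = 1.4, Hyd = 1.6)[cls]
  query <- structure(list(
    features = data.frame(id = paste0("F", seq_len(nf), "_", cls),
                          class = cls, x = centers[, 1], y = centers[, 2],
                          z = centers[, 3], radius = unname(rad)),
    match_mode = "all", m = nf), class = "ph4_query")
  pts <- centers + matrix(stats::rnorm(nf * 3, 0, jitter), ncol = 3)
  pcls <- cls
  if (extra > 0L) {
    pts <- rbind(pts, matrix(stats::runif(extra * 3, -8, 8), ncol = 3))
    pcls <- c(pcls, sample(classes, extra, replace = TRUE))
  }
  th <- stats::runif(1, 0, 2 * pi)
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pts <- sweep(pts %*% t(R), 2, stats::runif(3, -10, 10), `+`)
  list(query = query,
       points = data.frame(class = pcls, x = pts[, 1], y = pts[, 2],
                           z = pts[, 3]))
}
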