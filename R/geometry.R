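#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum ||R p_i + t - q_i||^2` over paired points, the closed-form
#' SVD solution. Reflections are rejected: the returned rotation always
#' has determinant +1, so chirality is preserved.
#'
#' @param P n x 3 matrix of moving points.
#' @param Q n x 3 matrix of reference points (same row pairing as `P`).
#' @return A list with `rotation` (3 x 3), `translation` (length 3),
#'   `rmsd` (post-fit RMSD in the units of the input), and `transform`,
#'   a function mapping an m x 3 matrix through the fitted motion.
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' th <- pi / 5
#' R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' fit <- kabsch(P, P %*% t(R) + 2)
#' fit$rmsd   # ~0
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3L, ncol(Q) == 3L, nrow(P) == nrow(Q), nrow(P) >= 3L)
  if (!all(is.finite(P)) || !all(is.finite(Q)))
    stop("kabsch: non-finite coordinates")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))              # H = Pc' Qc ; R = V D U'
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1                        # degenerate (collinear) input
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  moved <- Pc %*% t(R)                      # rows rotated
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = t, rmsd = rmsd,
       transform = function(X) sweep(as.matrix(X) %*% t(R), 2, t, `+`))
}

#' RMSD between two paired point sets
#' @param A,B n x 3 matrices.
#' @return Root-mean-square deviation.
#' @export
rmsd_points <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  sqrt(mean(rowSums((A - B)^2)))
}

# random proper rotation matrix (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
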