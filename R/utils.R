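# Small numeric helpers shared across modules.

#' Signed cube root
#' @noRd
cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' TM-score distance scale d0
#'
#' Length-dependent distance expected between structurally unrelated positions,
#' \eqn{d_0 = 1.24 (L - 15)^{1/3} - 1.8} angstrom, clamped from below at
#' `floor` because the printed formula turns non-positive for short alignments.
#'
#' @param L number of positions used for normalization (integer >= 1).
#' @param floor minimum d0 in angstrom (default 0.5).
#' @return d0 in angstrom.
#' @export
#' @examples
#' tm_d0(100) # about 3.65
tm_d0 <- function(L, floor = 0.5) {
  stopifnot(L >= 1)
  max(1.24 * cbrt(L - 15) - 1.8, floor)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds rotation R (det +1) and translation t minimizing the RMSD of
#' `x %*% t(R) + t` onto `y`.
#'
#' @param x,y n x 3 coordinate matrices, n >= 3.
#' @param w optional non-negative weights of length n.
#' @return list with `rotation` (3x3), `translation` (length 3).
#' @noRd
kabsch <- function(x, y, w = NULL) {
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 3)
  if (is.null(w)) w <- rep(1, nrow(x))
  w <- w / sum(w)
  cx <- colSums(x * w)
  cy <- colSums(y * w)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  h <- t(xc * w) %*% yc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = r, translation = as.numeric(cy - r %*% cx))
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, `+`)
}

#' Rotation matrix from a rotation vector (axis-angle exponential map)
#' @noRd
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
}

#' Random rotation matrix (uniform via QR of Gaussian matrix)
#' @noRd
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Row-wise Euclidean distances between matched coordinate rows
#' @noRd
row_dist <- function(a, b) sqrt(rowSums((a - b)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
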