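# Rigid-body geometry: Kabsch superposition, RMSD, random rotations.
# Coordinates are N x 3 matrices in Angstrom throughout.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimising the
#' least-squares deviation of \code{moving \%*\% t(R) + t} from \code{fixed}.
#' Reflections are excluded (det(R) = +1).
#'
#' @param moving N x 3 coordinate matrix to be transformed.
#' @param fixed N x 3 reference coordinates, same row order.
#' @param weights optional per-point non-negative weights.
#' @return A list with \code{rotation} (3 x 3), \code{translation}
#'   (length 3), \code{fitted} (transformed \code{moving}) and \code{rmsd}.
#' @export
kabsch_fit <- function(moving, fixed, weights = NULL) {
  P <- as.matrix(moving); Q <- as.matrix(fixed)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stopf("kabsch_fit: coordinate sets must be equal-sized N x 3 matrices")
  w <- weights %||% rep(1, nrow(P))
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc * w) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pc %*% t(R)
  fitted <- sweep(fitted, 2, cq, "+")
  list(rotation = R,
       translation = as.numeric(cq - as.numeric(R %*% cp)),
       fitted = fitted,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' RMSD between two coordinate sets in place (no superposition)
#'
#' @param a,b N x 3 coordinate matrices, same row order.
#' @return Root-mean-square deviation in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stopf("coord_rmsd: dimension mismatch (%d x %d vs %d x %d)",
          nrow(a), ncol(a), nrow(b), ncol(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# apply rotation R and translation t to row-coordinates
apply_rigid <- function(X, R, t) {
  sweep(as.matrix(X) %*% t(R), 2, t, "+")
}

# uniform-ish random proper rotation (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# unit vector
unit <- function(v) v / sqrt(sum(v^2))

# some vector perpendicular to v
perp_vector <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(ref - sum(ref * v) * v)
}

# angle at vertex b of the path a-b-c, degrees
angle_deg <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# least-squares plane normal of a ring (unit vector)
plane_normal <- function(coords) {
  X <- sweep(as.matrix(coords), 2, colMeans(coords))
  s <- svd(X)
  unit(s$v[, 3])
}
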