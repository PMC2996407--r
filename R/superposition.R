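#' Optimal rigid-body superposition of corresponded point sets
#'
#' Computes the proper rigid motion (rotation + translation) that minimizes
#' the root-mean-square deviation of `P` mapped onto `Q`, together with the
#' minimal RMSD itself.  The minimal RMSD is obtained from the largest root
#' of the quartic characteristic polynomial of the 4x4 quaternion key matrix
#' (the QCP formulation), found by Newton iteration -- no eigen decomposition
#' of the covariance matrix is performed on the fast path.  The rotation is
#' recovered from the quaternion eigenvector via the adjugate of
#' `K - lambda I`; degenerate configurations (collinear points, k < 3) fall
#' back to an SVD-based solution, which still attains the minimal RMSD but
#' the rotation is then just one valid minimizer.
#'
#' @param P,Q numeric k x 3 matrices of corresponding coordinates (Angstrom).
#' @return an object of class `rigid_alignment`: a list with elements
#'   `rotation` (proper 3x3 orthogonal matrix, det = +1), `translation`
#'   (length-3 vector) and `rmsd` (Angstrom).  The alignment maps `P` onto
#'   `Q`: `apply_alignment(a, P)` superposes `P` on `Q` at RMSD `a$rmsd`.
#' @seealso [apply_alignment()], [invert_alignment()]
#' @export
optimal_superposition <- function(P, Q) {
  P <- as_coord_matrix(P)
  Q <- as_coord_matrix(Q)
  if (nrow(P) != nrow(Q))
    stop("point sets have different lengths: ", nrow(P), " vs ", nrow(Q))
  k <- nrow(P)
  if (k == 0L) stop("empty point sets")
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- P; Pc[, 1L] <- P[, 1L] - cp[1L]
  Pc[, 2L] <- P[, 2L] - cp[2L]; Pc[, 3L] <- P[, 3L] - cp[3L]
  Qc <- Q; Qc[, 1L] <- Q[, 1L] - cq[1L]
  Qc[, 2L] <- Q[, 2L] - cq[2L]; Qc[, 3L] <- Q[, 3L] - cq[3L]
  GA <- sum(Pc * Pc)
  GB <- sum(Qc * Qc)
  M <- crossprod(Pc, Qc)  # M[i, j] = sum_a Pc[a, i] * Qc[a, j]

  K <- quaternion_key_matrix(M)
  lam <- qcp_largest_root(K, upper = (GA + GB) / 2)

  rot <- NULL
  if (!is.na(lam)) {
    rot <- rotation_from_quaternion_matrix(K, lam)
  }
  if (is.na(lam) || is.null(rot)) {
    # SVD fallback: guaranteed-correct minimizer
    sol <- kabsch_svd(Pc, Qc)
    rot <- sol$rotation
    lam <- sol$lambda
  }
  # report the deviation the returned transform attains (equals the minimum
  # to second order in any rotation error; avoids the cancellation in
  # sqrt((GA+GB-2*lambda)/k) near zero)
  attained <- function(R) {
    d <- Pc %*% t(R) - Qc
    sqrt(sum(d * d) / k)
  }
  rmsd <- attained(rot)
  poly_rmsd <- sqrt(max(0, (GA + GB - 2 * lam) / k))
  if (rmsd > poly_rmsd + 1e-6 * (1 + poly_rmsd)) {
    # quaternion eigenvector was inaccurate (near-degenerate top eigenvalue)
    rot <- kabsch_svd(Pc, Qc)$rotation
    rmsd <- attained(rot)
  }
  structure(
    list(rotation = rot,
         translation = as.numeric(cq - rot %*% cp),
         rmsd = rmsd),
    class = "rigid_alignment")
}

# 4x4 symmetric key matrix of the quaternion formulation (Horn convention):
# its largest eigenvalue equals max_R sum_i q_i . R p_i.
quaternion_key_matrix <- function(M) {
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    nrow = 4L, byrow = TRUE)
}

# Largest real root of det(K - lambda I) by Newton iteration seeded at the
# upper bound (GA+GB)/2.  The characteristic polynomial is computed from the
# traces of K powers (Newton's identities); tr(K) = 0 so the cubic term
# vanishes.  Returns NA on non-convergence.
qcp_largest_root <- function(K, upper, tol = 1e-11, max_iter = 50L) {
  K2 <- K %*% K
  p2 <- sum(diag(K2))
  p3 <- sum(diag(K2 %*% K))
  p4 <- sum(K2 * K2)  # tr(K2 %*% K2) for symmetric K2
  e2 <- -p2 / 2
  e3 <- p3 / 3
  e4 <- -(e2 * p2 + p4) / 4
  # P(x) = x^4 + e2 x^2 - e3 x + e4
  x <- upper
  scale <- max(abs(upper), 1)
  for (it in seq_len(max_iter)) {
    x2 <- x * x
    f  <- x2 * x2 + e2 * x2 - e3 * x + e4
    df <- 4 * x2 * x + 2 * e2 * x - e3
    if (!is.finite(f) || !is.finite(df) || abs(df) < 1e-30) return(NA_real_)
    xn <- x - f / df
    if (!is.finite(xn)) return(NA_real_)
    if (abs(xn - x) < tol * scale) return(xn)
    x <- xn
  }
  NA_real_
}

# Rotation matrix from the eigenvector of K for eigenvalue lam, computed as
# the largest-norm column of adj(K - lam I).  Returns NULL when the adjugate
# is numerically zero (degenerate eigenvalue).
rotation_from_quaternion_matrix <- function(K, lam) {
  A <- K - diag(lam, 4L)
  adj <- matrix(0, 4L, 4L)
  sel <- list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  for (j in 1:4) {
    for (i in 1:4) {
      minor <- A[sel[[i]], sel[[j]]]
      adj[j, i] <- (-1)^(i + j) * det3(minor)
    }
  }
  norms <- colSums(adj^2)
  best <- which.max(norms)
  if (norms[best] < 1e-22) return(NULL)
  q <- adj[, best] / sqrt(norms[best])
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3L, byrow = TRUE)
  R
}

det3 <- function(m) {
  m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
  m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
  m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
}

# SVD (Kabsch) solution on centered coordinates; reflection-corrected.
# Returns the rotation and the attained value of max_R sum q . R p.
kabsch_svd <- function(Pc, Qc) {
  C <- crossprod(Qc, Pc)  # C[a, b] = sum_i Qc[i, a] * Pc[i, b]
  sv <- svd(C)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  lambda <- sum(sv$d * c(1, 1, s))
  list(rotation = R, lambda = lambda)
}

#' Apply a rigid alignment to points
#'
#' @param alignment a `rigid_alignment` (from [optimal_superposition()]).
#' @param points numeric k x 3 matrix (or length-3 vector).
#' @return transformed points, same shape as the input.
#' @export
apply_alignment <- function(alignment, points) {
  vec <- is.null(dim(points))
  X <- as_coord_matrix(points)
  Y <- X %*% t(alignment$rotation)
  Y <- sweep(Y, 2L, alignment$translation, `+`)
  if (vec) as.numeric(Y) else Y
}

#' Invert a rigid alignment
#'
#' @param alignment a `rigid_alignment`.
#' @return the inverse `rigid_alignment` (rmsd carried over unchanged).
#' @export
invert_alignment <- function(alignment) {
  Rt <- t(alignment$rotation)
  structure(
    list(rotation = Rt,
         translation = as.numeric(-Rt %*% alignment$translation),
         rmsd = alignment$rmsd),
    class = "rigid_alignment")
}

#' @export
print.rigid_alignment <- function(x, ...) {
  cat("Rigid alignment: rmsd =", format(x$rmsd, digits = 6), "A\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

as_coord_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("coordinates must be a k x 3 matrix or 3-vector")
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns")
  storage.mode(x) <- "double"
  x
}

# Plain RMSD between corresponded point sets under an already-chosen
# alignment (used to cross-check reported rmsds and for centroid RMSD).
rmsd_under_alignment <- function(alignment, P, Q) {
  P2 <- apply_alignment(alignment, as_coord_matrix(P))
  d <- P2 - as_coord_matrix(Q)
  sqrt(sum(d * d) / nrow(P2))
}
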