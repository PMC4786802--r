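#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` over the
#' atoms in `fit_idx`, by singular value decomposition of the covariance
#' matrix with the determinant correction that guarantees a proper
#' rotation (no reflection). This is the rotation/translation correction
#' applied before any RMSD or contact analysis of a trajectory.
#'
#' @param mobile,reference Congruent n x 3 coordinate matrices.
#' @param fit_idx Atom indices used for the fit (default: all).
#' @return List with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (post-fit RMSD over `fit_idx`, Angstrom) and `xyz` (the whole
#'   mobile matrix after the transform). The transform maps mobile
#'   coordinates as `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, fit_idx = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    stop("fit error: coordinate matrices must be congruent n x 3")
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(mobile))
  if (length(fit_idx) < 3) stop("fit error: need at least 3 fit atoms")
  A <- mobile[fit_idx, , drop = FALSE]
  B <- reference[fit_idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(A0, B0))
  if (s$d[2] < 1e-10)
    stop("fit error: degenerate (collinear) fit geometry")
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  tr <- cb - as.numeric(ca %*% R)
  fitted <- sweep(mobile %*% R, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted[fit_idx, , drop = FALSE] - B)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, xyz = fitted)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b Congruent n x 3 matrices.
#' @param idx Optional atom indices to measure over.
#' @param fit Superpose `a` onto `b` (over `idx`) before measuring?
#'   Default FALSE (positions compared as given).
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b, idx = NULL, fit = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(idx)) idx <- seq_len(nrow(a))
  if (fit) {
    a <- kabsch_superpose(a, b, idx)$xyz
  }
  sqrt(mean(rowSums((a[idx, , drop = FALSE] - b[idx, , drop = FALSE])^2)))
}
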