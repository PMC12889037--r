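#' Kabsch rigid-body superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between two paired coordinate sets, via SVD of the
#' cross-covariance matrix with the reflection branch corrected so that the
#' returned rotation always has determinant +1.
#'
#' The returned transform maps `mobile` onto `target` as
#' `mobile %*% rotation + translation` (rotation acting on row vectors); use
#' [apply_superposition()] to apply it.
#'
#' @param mobile,target Numeric N x 3 matrices (N >= 3) of paired coordinates.
#' @param weights Optional non-negative per-atom weights, not all zero.
#'
#' @return A list of class `superposition` with elements `rotation` (3 x 3,
#'   det +1), `translation` (length-3, Angstrom), `rmsd` (Angstrom, weighted
#'   if weights given) and `n_atoms`.
#' @export
#' @examples
#' a <- matrix(rnorm(18), 6)
#' th <- pi / 3
#' rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
#' b <- a %*% rz + matrix(c(5, 0, 0), 6, 3, byrow = TRUE)
#' kabsch_superpose(a, b)$rmsd # ~0
kabsch_superpose <- function(mobile, target, weights = NULL) {
  check_coord_matrix(mobile, "mobile", min_rows = 3L)
  check_coord_matrix(target, "target", min_rows = 3L)
  n <- nrow(mobile)
  if (nrow(target) != n) abort("`mobile` and `target` must have equal shapes.")
  if (is.null(weights)) {
    w <- rep(1, n)
  } else {
    w <- as.numeric(weights)
    if (length(w) != n) abort("`weights` must have one entry per atom.")
    if (any(w < 0) || all(w == 0)) abort("`weights` must be non-negative and not all zero.")
  }
  w <- w / sum(w)

  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  mc <- sweep(mobile, 2, cm)
  tc <- sweep(target, 2, ct)

  # collinear / degenerate input has no unique rotation
  sv_m <- svd(mc * sqrt(w))$d
  if (sv_m[2] <= 1e-8 * max(sv_m[1], 1e-12)) {
    abort("degenerate (collinear) coordinates: superposition is not unique.")
  }

  h <- t(mc * w) %*% tc
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  rotation <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  translation <- as.numeric(ct - cm %*% rotation)

  fitted <- mc %*% rotation
  msd <- sum(w * rowSums((fitted - tc)^2))
  structure(
    list(
      rotation = rotation,
      translation = translation,
      rmsd = sqrt(max(msd, 0)),
      n_atoms = n
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms, rmsd = %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param sp A `superposition` from [kabsch_superpose()].
#' @param coords Numeric N x 3 matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  stopifnot(inherits(sp, "superposition"))
  check_coord_matrix(coords, "coords")
  sweep(coords %*% sp$rotation, 2, -sp$translation)
}

#' Root-mean-square deviation between paired coordinates
#'
#' No superposition is performed; compose with [kabsch_superpose()] when a
#' best-fit RMSD is wanted.
#'
#' @param a,b Numeric N x 3 matrices of paired coordinates (Angstrom).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) {
  check_coord_matrix(a, "a")
  check_coord_matrix(b, "b")
  if (!all(dim(a) == dim(b))) abort("`a` and `b` must have equal shapes.")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Radius of gyration of a coordinate set
#'
#' Unweighted by default: `sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))`, with the
#' result converted from Angstrom to nanometres.
#'
#' @param coords Numeric N x 3 matrix (Angstrom).
#' @param weights Optional non-negative weights.
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(coords, weights = NULL) {
  check_coord_matrix(coords, "coords")
  n <- nrow(coords)
  if (is.null(weights)) {
    w <- rep(1, n)
  } else {
    w <- as.numeric(weights)
    if (length(w) != n) abort("`weights` must have one entry per atom.")
    if (any(w < 0) || all(w == 0)) abort("`weights` must be non-negative and not all zero.")
  }
  w <- w / sum(w)
  centre <- colSums(coords * w)
  sqrt(sum(w * rowSums(sweep(coords, 2, centre)^2))) / 10
}
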