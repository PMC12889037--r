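#' Superpose every frame of an ensemble onto a reference
#'
#' Rigidly fits each frame (using only the stated residue positions as the
#' fit set, all coordinates transformed) either onto a supplied representative
#' conformation or onto the iteratively refined ensemble mean
#' (`reference = "mean"`: fit-to-mean iterated until the mean shifts by less
#' than `tol` Angstrom).
#'
#' @param ens An [ensemble()].
#' @param reference A [structure3d()] sharing the ensemble's residue set, or
#'   the string `"mean"`.
#' @param positions Optional integer vector of residue numbers used for the
#'   fit (default: all residues); at least 3.
#' @param tol Convergence tolerance (Angstrom) for the mean-reference mode.
#' @param max_iter Iteration cap for the mean-reference mode.
#' @return The superposed [ensemble()].
#' @export
superpose_ensemble <- function(ens, reference = "mean", positions = NULL,
                               tol = 1e-6, max_iter = 20L) {
  stopifnot(inherits(ens, "ensemble"))
  resno <- ens$frames[[1]]$residue_numbers
  if (is.null(positions)) {
    fit_idx <- seq_along(resno)
  } else {
    fit_idx <- match(positions, resno)
    if (anyNA(fit_idx)) abort("`positions` must be a subset of the ensemble's residues.")
    if (length(fit_idx) < 3L) abort("need at least 3 fit positions.")
  }
  coords <- lapply(ens$frames, `[[`, "coords")

  fit_all_to <- function(target_sub) {
    lapply(coords, function(xy) {
      sp <- kabsch_superpose(xy[fit_idx, , drop = FALSE], target_sub)
      apply_superposition(sp, xy)
    })
  }

  if (inherits(reference, "structure3d")) {
    if (!identical(reference$residue_numbers, resno)) {
      abort("`reference` does not share the ensemble's residue set.")
    }
    coords <- fit_all_to(reference$coords[fit_idx, , drop = FALSE])
  } else if (identical(reference, "mean")) {
    mean_sub <- Reduce(`+`, coords) / length(coords)
    mean_sub <- mean_sub[fit_idx, , drop = FALSE]
    for (it in seq_len(max_iter)) {
      coords <- fit_all_to(mean_sub)
      new_mean <- Reduce(`+`, coords) / length(coords)
      new_mean <- new_mean[fit_idx, , drop = FALSE]
      shift <- sqrt(mean(rowSums((new_mean - mean_sub)^2)))
      mean_sub <- new_mean
      if (shift < tol) break
    }
  } else {
    abort("`reference` must be a structure3d or the string \"mean\".")
  }

  frames <- purrr::map2(ens$frames, coords, function(f, xy) {
    structure3d(f$id, f$residue_numbers, f$residue_codes, xy)
  })
  ensemble(ens$homolog_id, frames, ens$times_ns)
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' For a superposed ensemble, computes the isotropic (scalar-product)
#' residue-residue cross-correlation
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`, where `dr_i` is the
#' displacement of residue i from its ensemble-average position. Entries
#' involving a residue with zero fluctuation are set to 0 and flagged with a
#' warning.
#'
#' @param ens A superposed [ensemble()] with at least two frames.
#' @return An object of class `dccm_matrix`: list with `matrix` (N x N,
#'   symmetric, unit diagonal) and `residue_numbers`.
#' @export
dccm <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  f <- n_frames(ens)
  if (f < 2L) abort("DCCM requires at least two frames.")
  xyz <- ensemble_xyz(ens)                      # F x 3N
  n <- ncol(xyz) / 3L
  centred <- sweep(xyz, 2, colMeans(xyz))
  dx <- centred[, seq(1, 3 * n, by = 3), drop = FALSE]
  dy <- centred[, seq(2, 3 * n, by = 3), drop = FALSE]
  dz <- centred[, seq(3, 3 * n, by = 3), drop = FALSE]
  cov_ij <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / f
  var_i <- diag(cov_ij)
  zero <- var_i <= .Machine$double.eps
  denom <- sqrt(outer(var_i, var_i))
  cc <- cov_ij / denom
  if (any(zero)) {
    warn(sprintf(
      "%d residue(s) with zero fluctuation; their correlations set to 0.",
      sum(zero)
    ))
    cc[zero, ] <- 0
    cc[, zero] <- 0
  }
  diag(cc) <- 1
  cc <- pmin(pmax((cc + t(cc)) / 2, -1), 1)
  structure(
    list(matrix = cc, residue_numbers = ens$frames[[1]]$residue_numbers),
    class = "dccm_matrix"
  )
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat(sprintf("<dccm_matrix> %d x %d residues\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Mean cross-correlation between two residue sets
#'
#' Averages the DCCM entries `C_ij` over `i` in `set_a`, `j` in `set_b`
#' (off-diagonal block). Negative values indicate anti-correlated, hinge-like
#' motion of the two sets.
#'
#' @param dc A `dccm_matrix` from [dccm()].
#' @param set_a,set_b Disjoint, non-empty vectors of residue numbers.
#' @return Mean correlation (scalar in `[-1, 1]`).
#' @export
inter_set_correlation <- function(dc, set_a, set_b) {
  stopifnot(inherits(dc, "dccm_matrix"))
  if (length(set_a) < 1L || length(set_b) < 1L) abort("both sets must be non-empty.")
  if (length(intersect(set_a, set_b)) > 0L) abort("`set_a` and `set_b` must be disjoint.")
  ia <- match(set_a, dc$residue_numbers)
  ib <- match(set_b, dc$residue_numbers)
  if (anyNA(ia) || anyNA(ib)) abort("sets must be subsets of the DCCM residues.")
  mean(dc$matrix[ia, ib, drop = FALSE])
}

# shared constructor for PCA results (single-trajectory and joint)
new_traj_pca <- function(mean_coords, eigenvalues, eigenvectors, projections,
                         frame_info, residue_numbers, residue_codes,
                         core_positions = NULL) {
  total <- sum(eigenvalues)
  fractions <- if (total > 0) eigenvalues / total else rep(0, length(eigenvalues))
  structure(
    list(
      mean_coords = mean_coords,
      eigenvalues = eigenvalues,
      eigenvectors = eigenvectors,
      variance_fractions = fractions,
      projections = projections,
      frame_info = frame_info,
      residue_numbers = residue_numbers,
      residue_codes = residue_codes,
      core_positions = core_positions
    ),
    class = "traj_pca"
  )
}

#' @export
print.traj_pca <- function(x, ...) {
  k <- min(3L, length(x$variance_fractions))
  cat(sprintf(
    "<traj_pca> %d frames x %d residues; PC1-%d variance: %s\n",
    nrow(x$projections), length(x$residue_numbers), k,
    paste(sprintf("%.1f%%", 100 * x$variance_fractions[seq_len(k)]), collapse = ", ")
  ))
  invisible(x)
}

# core PCA of an F x 3N coordinate matrix; eigenvector signs fixed so the
# largest-magnitude loading of each component is positive
pca_xyz_matrix <- function(xyz) {
  f <- nrow(xyz)
  mean_vec <- colMeans(xyz)
  centred <- sweep(xyz, 2, mean_vec)
  sv <- svd(centred)
  eigenvalues <- sv$d^2 / (f - 1)
  keep <- seq_len(min(f - 1L, length(eigenvalues)))
  eigenvalues <- eigenvalues[keep]
  vectors <- sv$v[, keep, drop = FALSE]
  projections <- centred %*% vectors
  for (j in seq_along(keep)) {
    pivot <- which.max(abs(vectors[, j]))
    if (vectors[pivot, j] < 0) {
      vectors[, j] <- -vectors[, j]
      projections[, j] <- -projections[, j]
    }
  }
  list(
    mean_vec = mean_vec, eigenvalues = eigenvalues,
    vectors = vectors, projections = projections
  )
}

#' Cartesian principal component analysis of a trajectory
#'
#' Eigen-decomposition of the 3N x 3N covariance (1/(F-1) normalisation) of
#' the superposed frame coordinates, computed via SVD of the centred frame
#' matrix. Projections are centred; eigenvector signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param ens A superposed [ensemble()] with at least three frames.
#' @return A `traj_pca` object: `mean_coords` (N x 3), `eigenvalues`
#'   (non-increasing), `eigenvectors` (3N x k), `variance_fractions`,
#'   `projections` (F x k matrix) and a `frame_info` tibble.
#' @export
trajectory_pca <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  if (n_frames(ens) < 3L) abort("trajectory PCA requires at least three frames.")
  res <- pca_xyz_matrix(ensemble_xyz(ens))
  new_traj_pca(
    mean_coords = xyz_to_coords(res$mean_vec),
    eigenvalues = res$eigenvalues,
    eigenvectors = res$vectors,
    projections = res$projections,
    frame_info = tibble(
      homolog_id = ens$homolog_id,
      frame = seq_len(n_frames(ens)),
      time_ns = ens$times_ns
    ),
    residue_numbers = ens$frames[[1]]$residue_numbers,
    residue_codes = ens$frames[[1]]$residue_codes
  )
}

#' Interpolate structures along a principal component
#'
#' Generates conformations `mean + t * sigma * PC` for `t` evenly spaced in
#' `[-t_range, +t_range]`, where `sigma` is the standard deviation captured by
#' the component. Useful for visualising the extent of a principal motion.
#'
#' @param pca A `traj_pca`.
#' @param pc_index Component to interpolate (1-based).
#' @param n_steps Number of interpolated structures (default 11).
#' @param t_range Half-range in standard deviations (default 3).
#' @return An [ensemble()] of interpolated conformations (pseudo-times are the
#'   interpolation parameter t).
#' @export
pc_interpolate <- function(pca, pc_index = 1L, n_steps = 11L, t_range = 3) {
  stopifnot(inherits(pca, "traj_pca"))
  if (pc_index > length(pca$eigenvalues)) abort("`pc_index` exceeds available components.")
  lambda <- pca$eigenvalues[pc_index]
  if (lambda <= .Machine$double.eps) abort("cannot interpolate a zero-eigenvalue component.")
  sigma <- sqrt(lambda)
  vec <- pca$eigenvectors[, pc_index]
  ts <- seq(-t_range, t_range, length.out = n_steps)
  mean_vec <- as.numeric(t(pca$mean_coords))
  frames <- lapply(ts, function(t) {
    structure3d(
      sprintf("pc%d_t%+.2f", pc_index, t),
      pca$residue_numbers, pca$residue_codes,
      xyz_to_coords(mean_vec + t * sigma * vec)
    )
  })
  ensemble(sprintf("pc%d_interpolation", pc_index), frames, ts)
}
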