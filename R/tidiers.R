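#' Tidy a trajectory PCA into per-frame projections
#'
#' @param x A `traj_pca`.
#' @param n_pcs Number of leading components to return (default 3).
#' @param ... Unused.
#' @return A tibble: the frame metadata joined with `PC1..PCk` projections.
#' @export
tidy.traj_pca <- function(x, n_pcs = 3L, ...) {
  k <- min(n_pcs, ncol(x$projections))
  proj <- as_tibble(x$projections[, seq_len(k), drop = FALSE],
                    .name_repair = ~ paste0("PC", seq_len(k)))
  dplyr::bind_cols(x$frame_info, proj)
}

#' One-row PCA summary
#'
#' @param x A `traj_pca`.
#' @param ... Unused.
#' @return A tibble with `n_frames`, `n_residues`, `n_components`,
#'   `pc1_fraction`, `pc2_fraction`, `pc3_fraction`.
#' @export
glance.traj_pca <- function(x, ...) {
  fr <- function(i) if (length(x$variance_fractions) >= i) x$variance_fractions[i] else NA_real_
  tibble(
    n_frames = nrow(x$projections),
    n_residues = length(x$residue_numbers),
    n_components = length(x$eigenvalues),
    pc1_fraction = fr(1), pc2_fraction = fr(2), pc3_fraction = fr(3)
  )
}

#' Tidy a DCCM into long form
#'
#' @param x A `dccm_matrix`.
#' @param ... Unused.
#' @return A tibble `residue_i`, `residue_j`, `correlation` (all pairs).
#' @export
tidy.dccm_matrix <- function(x, ...) {
  n <- length(x$residue_numbers)
  tibble(
    residue_i = rep(x$residue_numbers, times = n),
    residue_j = rep(x$residue_numbers, each = n),
    correlation = as.numeric(x$matrix)
  )
}

#' Tidy a TM-score result
#'
#' @param x A `tm_score`.
#' @param ... Unused.
#' @return One row per corresponded pair with the distance at the reported
#'   superposition and its score contribution.
#' @export
tidy.tm_score <- function(x, ...) {
  tibble(
    pos_a = x$correspondence[, 1],
    pos_b = x$correspondence[, 2],
    distance = x$distances,
    contribution = 1 / (1 + (x$distances / x$d0)^2) / x$normalization_length
  )
}

#' One-row TM-score summary
#'
#' @param x A `tm_score`.
#' @param ... Unused.
#' @return A tibble with `score`, `d0`, `n_pairs`, `normalization_length`.
#' @export
glance.tm_score <- function(x, ...) {
  tibble(
    score = x$score, d0 = x$d0, n_pairs = x$n_pairs,
    normalization_length = x$normalization_length
  )
}

#' Tidy a core-finding result
#'
#' @param x A `core_find`.
#' @param ... Unused.
#' @return The removal trace tibble with a `in_core` flag appended for the
#'   removed positions.
#' @export
tidy.core_find <- function(x, ...) {
  dplyr::mutate(x$trace, in_core = .data$removed_position %in% x$core_positions)
}
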