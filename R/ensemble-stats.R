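#' Drop the equilibration phase of a trajectory
#'
#' Removes all frames with time strictly below `offset_ns`; frames at exactly
#' the offset are retained.
#'
#' @param ens An [ensemble()].
#' @param offset_ns Equilibration offset in ns (default 20).
#' @return An [ensemble()] restricted to frames with `time >= offset_ns`.
#' @export
apply_equilibration_offset <- function(ens, offset_ns = 20) {
  stopifnot(inherits(ens, "ensemble"))
  keep <- ens$times_ns >= offset_ns
  if (!any(keep)) {
    abort(sprintf(
      "equilibration offset %g ns removes all %d frames of '%s'.",
      offset_ns, n_frames(ens), ens$homolog_id
    ))
  }
  ensemble(ens$homolog_id, ens$frames[keep], ens$times_ns[keep])
}

#' Sample evenly spaced frames from a trajectory
#'
#' Picks one frame per requested time on the grid `start_ns, start_ns +
#' step_ns, ..., stop_ns`, taking the nearest available frame within
#' `step_ns / 2`. The defaults yield the eight-conformation sample used for
#' cross-homolog comparisons.
#'
#' @param ens An [ensemble()].
#' @param start_ns,stop_ns,step_ns Sampling grid in ns (defaults 25, 95, 10).
#' @return An [ensemble()] with one frame per grid time, in time order.
#' @export
sample_frames <- function(ens, start_ns = 25, stop_ns = 95, step_ns = 10) {
  stopifnot(inherits(ens, "ensemble"))
  if (stop_ns < start_ns) abort("`stop_ns` must be >= `start_ns`.")
  wanted <- seq(start_ns, stop_ns, by = if (stop_ns > start_ns) step_ns else 1)
  tol <- step_ns / 2
  picked <- integer(length(wanted))
  missing <- numeric(0)
  for (i in seq_along(wanted)) {
    dists <- abs(ens$times_ns - wanted[i])
    j <- which.min(dists)
    if (dists[j] > tol) {
      missing <- c(missing, wanted[i])
    } else {
      picked[i] <- j
    }
  }
  if (length(missing) > 0) {
    abort(sprintf(
      "no frame of '%s' within %g ns of requested times: %s",
      ens$homolog_id, tol, paste(missing, collapse = ", ")
    ))
  }
  picked <- unique(picked)
  ensemble(ens$homolog_id, ens$frames[picked], ens$times_ns[picked])
}

#' Per-frame descriptor series for an ensemble
#'
#' For `metric = "rmsd_vs_reference"` every frame is first rigidly superposed
#' onto the reference (so only internal deformation is measured); for
#' `metric = "rg"` the radius of gyration (nm) of each frame is returned.
#'
#' @param ens An [ensemble()].
#' @param metric `"rmsd_vs_reference"` (Angstrom) or `"rg"` (nm).
#' @param reference A [structure3d()] sharing the residue set; required for
#'   the RMSD metric.
#' @return A tibble with columns `time_ns` and `value`.
#' @export
descriptor_series <- function(ens, metric = c("rmsd_vs_reference", "rg"),
                              reference = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  metric <- match.arg(metric)
  if (metric == "rg") {
    vals <- vapply(ens$frames, function(f) radius_of_gyration(f$coords), numeric(1))
  } else {
    if (is.null(reference)) abort("`reference` is required for metric 'rmsd_vs_reference'.")
    stopifnot(inherits(reference, "structure3d"))
    if (!identical(reference$residue_numbers, ens$frames[[1]]$residue_numbers)) {
      abort("`reference` does not share the ensemble's residue set.")
    }
    vals <- vapply(ens$frames, function(f) {
      sp <- kabsch_superpose(f$coords, reference$coords)
      rmsd(apply_superposition(sp, f$coords), reference$coords)
    }, numeric(1))
  }
  tibble(time_ns = ens$times_ns, value = vals)
}

#' Median and (unscaled) median absolute deviation
#'
#' The even-length median is the mean of the two central order statistics;
#' the MAD is `median(|x - median(x)|)` without the 1.4826 consistency factor.
#'
#' @param values Non-empty numeric vector.
#' @return A tibble with columns `median` and `mad`.
#' @export
summarize_median_mad <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values))) {
    abort("`values` must be a non-empty finite numeric vector.")
  }
  med <- median(values)
  tibble(median = med, mad = median(abs(values - med)))
}

#' Robust per-homolog descriptor summaries
#'
#' Computes a descriptor series per homolog ensemble (after an equilibration
#' offset) and reduces it to median and unscaled MAD. The RMSD reference for
#' each homolog is its own first frame (the pre-equilibration starting model).
#'
#' @param hset A [homolog_set()] whose records carry ensembles.
#' @param metric `"rg"` or `"rmsd_vs_reference"`.
#' @param offset_ns Equilibration offset in ns (default 20).
#' @return A tibble with columns `homolog_id`, `group`, `metric`, `n`,
#'   `median`, `mad`. Homologs without ensembles are skipped with a warning.
#' @export
ensemble_summary <- function(hset, metric = c("rg", "rmsd_vs_reference"),
                             offset_ns = 20) {
  stopifnot(inherits(hset, "homolog_set"))
  metric <- match.arg(metric)
  recs <- hset$records
  out <- purrr::pmap(
    list(recs$id, recs$group, recs$ensemble),
    function(id, group, ens) {
      if (is.null(ens)) {
        warn(sprintf("homolog '%s' has no ensemble; skipped.", id))
        return(NULL)
      }
      ref <- ens$frames[[1]]
      eq <- apply_equilibration_offset(ens, offset_ns)
      series <- descriptor_series(eq, metric, reference = ref)
      mm <- summarize_median_mad(series$value)
      tibble(
        homolog_id = id, group = group, metric = metric,
        n = nrow(series), median = mm$median, mad = mm$mad
      )
    }
  )
  dplyr::bind_rows(out)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two_sided"`, `"less"`, or `"greater"`.
#' @return The p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) abort("both samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 12L) && !ties
  alt <- switch(alternative, two_sided = "two.sided", less = "less", greater = "greater")
  suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Pairwise Wilcoxon tests across labelled groups
#'
#' Tests every unordered pair of groups with [wilcoxon_rank_sum()] and adjusts
#' the p-values for multiple testing.
#'
#' @param data A data frame.
#' @param value,group Columns of `data` holding the values and the group
#'   labels (tidy-eval; defaults `value` and `group`).
#' @param adjust Adjustment method: `"holm"` (default), `"bonferroni"`,
#'   `"BH"`, or `"none"`.
#' @param alternative Passed to [wilcoxon_rank_sum()].
#' @return A tibble with columns `group_a`, `group_b`, `n_a`, `n_b`,
#'   `p_value`, `p_adjusted`. Groups with fewer than two values are dropped
#'   with a warning.
#' @export
pairwise_wilcoxon <- function(data, value = value, group = group,
                              adjust = c("holm", "bonferroni", "BH", "none"),
                              alternative = "two_sided") {
  adjust <- match.arg(adjust)
  vals <- dplyr::pull(data, {{ value }})
  grps <- as.character(dplyr::pull(data, {{ group }}))
  split_vals <- split(vals, grps)
  sizes <- vapply(split_vals, length, integer(1))
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0) {
    warn(sprintf("groups with <2 values skipped: %s", paste(small, collapse = ", ")))
    split_vals <- split_vals[sizes >= 2L]
  }
  ids <- sort(names(split_vals))
  if (length(ids) < 2L) abort("need at least two groups with >=2 values.")
  pairs <- combn(ids, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tibble(
      group_a = a, group_b = b,
      n_a = length(split_vals[[a]]), n_b = length(split_vals[[b]]),
      p_value = wilcoxon_rank_sum(split_vals[[a]], split_vals[[b]], alternative)
    )
  })
  res$p_adjusted <- p.adjust(res$p_value, method = if (adjust == "none") "none" else adjust)
  res
}
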