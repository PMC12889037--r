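tm_d0 <- function(l, d0_min = 0.5) {
  max(1.24 * (max(l - 15, 0))^(1 / 3) - 1.8, d0_min)
}

coords_of <- function(x, arg = "structure") {
  if (inherits(x, "structure3d")) return(x$coords)
  check_coord_matrix(x, arg)
  x
}

#' TM-score under a fixed residue correspondence
#'
#' Evaluates the length-normalised structural similarity
#' `score = (1/L) * sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = max(1.24 (L-15)^(1/3) - 1.8, 0.5)`, maximised over rigid-body
#' superpositions of the fixed corresponded pairs. The maximisation is a
#' deterministic iterative scheme: fragment seeds (full run, central half,
#' central quarter of the correspondence; for 10 or fewer pairs additionally
#' every 3-pair subset), each followed by up to 20 rounds of iteratively
#' reweighted fitting (weights `1/(1 + (d_i/d0)^2)^2`, the score term's
#' derivative); the best score over all visited superpositions is kept.
#'
#' The correspondence is supplied (e.g. from an MSA), not searched, so
#' absolute values are not comparable to tools that optimise the alignment.
#'
#' @param a,b [structure3d()] objects or N x 3 coordinate matrices.
#' @param correspondence Two-column integer matrix of paired positions
#'   (1-based indices into `a` and `b` respectively).
#' @param normalization_length Length L used for normalisation and d0;
#'   defaults to the shorter chain.
#' @return An object of class `tm_score`: `score`, `d0`, `n_pairs`,
#'   `correspondence`, `normalization_length`, `superposition` (maps `b` onto
#'   `a`) and per-pair `distances` at the reported superposition.
#' @export
tm_score_fixed <- function(a, b, correspondence, normalization_length = NULL) {
  ca <- coords_of(a, "a")
  cb <- coords_of(b, "b")
  correspondence <- as.matrix(correspondence)
  if (ncol(correspondence) != 2L || nrow(correspondence) < 1L) {
    abort("`correspondence` must be a non-empty two-column matrix of (posA, posB) pairs.")
  }
  if (max(correspondence[, 1]) > nrow(ca) || max(correspondence[, 2]) > nrow(cb) ||
      min(correspondence) < 1L) {
    abort("`correspondence` indices out of range.")
  }
  np <- nrow(correspondence)
  l <- normalization_length %||% min(nrow(ca), nrow(cb))
  if (l < 1L) abort("`normalization_length` must be >= 1.")
  if (np < 3L) abort("need at least 3 corresponded pairs.")
  d0 <- tm_d0(l)

  p <- ca[correspondence[, 1], , drop = FALSE]
  q <- cb[correspondence[, 2], , drop = FALSE]

  score_of <- function(di) sum(1 / (1 + (di / d0)^2)) / l

  central_run <- function(len) {
    len <- max(3L, min(np, len))
    start <- max(1L, floor((np - len) / 2) + 1L)
    start:(start + len - 1L)
  }
  seeds <- unique(list(
    seq_len(np),
    central_run(ceiling(np / 2)),
    central_run(ceiling(np / 4))
  ))
  # short correspondences have a rugged score surface (d0 at its floor):
  # seed from every 3-pair subset so the deterministic search is exhaustive
  if (np <= 10L) {
    triples <- combn(np, 3L)
    seeds <- unique(c(seeds, lapply(seq_len(ncol(triples)), function(k) triples[, k])))
  }

  best <- list(score = -Inf)
  for (seed in seeds) {
    # start from an unweighted fit of the seed fragment, then ascend the
    # score by iteratively reweighted fitting; the weights are the score
    # term's derivative, w_i = 1 / (1 + (d_i/d0)^2)^2, so each re-fit is an
    # exact majorize-minimize ascent step on the TM objective
    w <- rep(1e-9, np)
    w[seed] <- 1
    for (iter in seq_len(20L)) {
      sp <- tryCatch(
        kabsch_superpose(q, p, weights = w),
        error = function(e) NULL
      )
      if (is.null(sp)) break
      qt <- apply_superposition(sp, q)
      di <- sqrt(rowSums((qt - p)^2))
      sc <- score_of(di)
      if (sc > best$score) {
        best <- list(score = sc, superposition = sp, distances = di)
      }
      w_new <- 1 / (1 + (di / d0)^2)^2
      if (max(abs(w_new - w)) < 1e-12) break
      w <- w_new
    }
  }
  if (!is.finite(best$score)) abort("TM-score optimisation failed on degenerate input.")

  structure(
    list(
      score = min(best$score, 1),
      d0 = d0,
      n_pairs = np,
      correspondence = correspondence,
      normalization_length = l,
      superposition = best$superposition,
      distances = best$distances
    ),
    class = "tm_score"
  )
}

#' @export
print.tm_score <- function(x, ...) {
  cat(sprintf(
    "<tm_score> %.4f (L = %d, d0 = %.2f A, %d pairs)\n",
    x$score, x$normalization_length, x$d0, x$n_pairs
  ))
  invisible(x)
}

#' MSA-guided TM-score between two conformations
#'
#' Derives the residue correspondence from the MSA columns where neither
#' sequence is gapped, then calls [tm_score_fixed()].
#'
#' @param a,b [structure3d()] objects whose `id`s appear in `m` and whose
#'   lengths match their ungapped MSA rows.
#' @param m An [msa()].
#' @param normalize Chain whose length normalises the score: `"shorter"`
#'   (default), `"longer"`, `"a"`, or `"b"`.
#' @return A `tm_score` object.
#' @export
tm_score_msa <- function(a, b, m, normalize = c("shorter", "longer", "a", "b")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(a, "structure3d"), inherits(b, "structure3d"), inherits(m, "msa"))
  map_a <- msa_column_map(m, a$id)
  map_b <- msa_column_map(m, b$id)
  la <- length(a$residue_numbers)
  lb <- length(b$residue_numbers)
  if (sum(!is.na(map_a)) != la) {
    abort(sprintf("structure '%s' length does not match its MSA row.", a$id))
  }
  if (sum(!is.na(map_b)) != lb) {
    abort(sprintf("structure '%s' length does not match its MSA row.", b$id))
  }
  shared <- which(!is.na(map_a) & !is.na(map_b))
  if (length(shared) < 3L) abort("fewer than 3 shared ungapped MSA columns.")
  corr <- cbind(map_a[shared], map_b[shared])
  l <- switch(normalize,
    shorter = min(la, lb),
    longer = max(la, lb),
    a = la,
    b = lb
  )
  tm_score_fixed(a, b, corr, normalization_length = l)
}

#' Exhaustive pairwise TM-score table across a homolog family
#'
#' Compares sampled conformations either within each homolog (all unordered
#' frame pairs) or between homologs (all frame pairs of every unordered
#' homolog pair), with MSA-guided correspondences. Group labels are attached;
#' the reference homolog counts as type-I for the comparison class.
#'
#' @param hset A [homolog_set()] with an MSA and sampled ensembles of equal
#'   frame counts. Homologs without an ensemble are skipped with a warning.
#' @param mode `"within_homolog"` or `"between_homolog"`.
#' @param normalize Passed to [tm_score_msa()].
#' @return A tibble with columns `id_a`, `conf_a`, `id_b`, `conf_b`, `score`,
#'   `comparison_class` (`within_homolog`, `within_group`, `between_group`).
#' @export
pairwise_matrix <- function(hset, mode = c("within_homolog", "between_homolog"),
                            normalize = "shorter") {
  mode <- match.arg(mode)
  stopifnot(inherits(hset, "homolog_set"))
  if (is.null(hset$msa)) abort("`hset` must carry an MSA.")
  recs <- hset$records
  has_ens <- !vapply(recs$ensemble, is.null, logical(1))
  if (any(!has_ens)) {
    warn(sprintf(
      "homologs without ensembles skipped: %s",
      paste(recs$id[!has_ens], collapse = ", ")
    ))
  }
  recs <- recs[has_ens, , drop = FALSE]
  if (nrow(recs) < 1L) abort("no homologs with ensembles.")
  counts <- vapply(recs$ensemble, n_frames, integer(1))
  if (length(unique(counts)) != 1L) {
    abort("ensembles must be sampled to equal frame counts before comparison.")
  }
  eff_group <- ifelse(recs$group == "reference", "type-I", recs$group)

  rows <- list()
  if (mode == "within_homolog") {
    for (i in seq_len(nrow(recs))) {
      ens <- recs$ensemble[[i]]
      prs <- combn(n_frames(ens), 2L)
      for (k in seq_len(ncol(prs))) {
        f1 <- prs[1, k]; f2 <- prs[2, k]
        ts <- tm_score_msa(ens$frames[[f1]], ens$frames[[f2]], hset$msa, normalize)
        rows[[length(rows) + 1L]] <- tibble(
          id_a = recs$id[i], conf_a = f1, id_b = recs$id[i], conf_b = f2,
          score = ts$score, comparison_class = "within_homolog"
        )
      }
    }
  } else {
    if (nrow(recs) < 2L) abort("between-homolog mode needs at least two homologs.")
    hp <- combn(nrow(recs), 2L)
    for (k in seq_len(ncol(hp))) {
      i <- hp[1, k]; j <- hp[2, k]
      cls <- if (eff_group[i] == eff_group[j]) "within_group" else "between_group"
      ea <- recs$ensemble[[i]]; eb <- recs$ensemble[[j]]
      for (f1 in seq_len(n_frames(ea))) {
        for (f2 in seq_len(n_frames(eb))) {
          ts <- tm_score_msa(ea$frames[[f1]], eb$frames[[f2]], hset$msa, normalize)
          rows[[length(rows) + 1L]] <- tibble(
            id_a = recs$id[i], conf_a = f1, id_b = recs$id[j], conf_b = f2,
            score = ts$score, comparison_class = cls
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-class summary of a pairwise score table
#'
#' @param pair_table A tibble from [pairwise_matrix()] (columns `score`,
#'   `comparison_class`).
#' @return A tibble with `comparison_class`, `n`, `median`, `min`, `max`.
#' @export
group_summary <- function(pair_table) {
  if (nrow(pair_table) < 1L) abort("`pair_table` is empty.")
  expected <- c("within_homolog", "within_group", "between_group")
  absent <- setdiff(expected, unique(pair_table$comparison_class))
  if (length(absent) > 0) {
    inform(sprintf("classes absent from table: %s", paste(absent, collapse = ", ")))
  }
  pair_table |>
    dplyr::group_by(.data$comparison_class) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$score),
      min = min(.data$score),
      max = max(.data$score),
      .groups = "drop"
    )
}

# gather all conformations of a homolog set on the shared ungapped MSA
# columns; returns coordinates per conformation plus column bookkeeping in
# reference-sequence numbering
gather_shared_conformations <- function(hset) {
  stopifnot(inherits(hset, "homolog_set"))
  if (is.null(hset$msa)) abort("`hset` must carry an MSA.")
  recs <- hset$records
  has_ens <- !vapply(recs$ensemble, is.null, logical(1))
  recs <- recs[has_ens, , drop = FALSE]
  if (nrow(recs) < 1L) abort("no homologs with ensembles.")
  maps <- lapply(recs$id, function(id) msa_column_map(hset$msa, id))
  shared_cols <- which(Reduce(`&`, lapply(maps, function(mp) !is.na(mp))))
  ref_map <- msa_column_map(hset$msa, hset$reference_id)
  if (anyNA(ref_map[shared_cols])) {
    abort("shared columns must be ungapped in the reference row.")
  }
  ref_positions <- ref_map[shared_cols]
  ref_codes <- seq_chars(msa_sequence(hset$msa, hset$reference_id))[ref_positions]

  confs <- list()
  info <- list()
  for (i in seq_len(nrow(recs))) {
    ens <- recs$ensemble[[i]]
    idx <- maps[[match(recs$id[i], recs$id)]][shared_cols]
    for (f in seq_len(n_frames(ens))) {
      confs[[length(confs) + 1L]] <- ens$frames[[f]]$coords[idx, , drop = FALSE]
      info[[length(info) + 1L]] <- tibble(
        homolog_id = recs$id[i], group = recs$group[i], frame = f,
        time_ns = ens$times_ns[f]
      )
    }
  }
  list(
    coords = confs,
    frame_info = dplyr::bind_rows(info),
    ref_positions = ref_positions,
    ref_codes = ref_codes
  )
}

# superposition-free rigidity score: for each position, the lower-quartile
# variance (across conformations) of its distances to all other positions.
# Positions inside a rigid, conserved block keep fixed distances to at least
# a quarter of the structure, so this ranks core candidates without any fit
# and without being biased toward the larger of two rigid blocks.
distance_rigidity <- function(coords) {
  m <- length(coords)
  p <- nrow(coords[[1]])
  s1 <- matrix(0, p, p)
  s2 <- matrix(0, p, p)
  for (xy in coords) {
    d <- as.matrix(stats::dist(xy))
    s1 <- s1 + d
    s2 <- s2 + d^2
  }
  varmat <- pmax(s2 / m - (s1 / m)^2, 0)
  diag(varmat) <- NA
  apply(varmat, 1, stats::quantile, probs = 0.25, na.rm = TRUE, names = FALSE)
}

# fit every conformation to the iteratively refined mean over the rows given
# by `fit_rows`, optionally with per-position fit weights
superpose_conformations <- function(coords, fit_rows, weights = NULL,
                                    tol = 1e-5, max_iter = 10L) {
  mean_sub <- Reduce(`+`, coords)[fit_rows, , drop = FALSE] / length(coords)
  for (it in seq_len(max_iter)) {
    coords <- lapply(coords, function(xy) {
      sp <- kabsch_superpose(xy[fit_rows, , drop = FALSE], mean_sub,
                             weights = weights)
      apply_superposition(sp, xy)
    })
    new_mean <- Reduce(`+`, coords)[fit_rows, , drop = FALSE] / length(coords)
    shift <- sqrt(mean(rowSums((new_mean - mean_sub)^2)))
    mean_sub <- new_mean
    if (shift < tol) break
  }
  coords
}

#' Iterative core-residue finding across homolog conformations
#'
#' Starting from all MSA columns shared (ungapped) across homologs with
#' ensembles, repeatedly: superpose every conformation on the current
#' candidate set (fit-to-mean, weighted towards the currently quietest
#' positions; the first round is anchored by a superposition-free internal
#' distance-rigidity ranking), compute the per-position variance (mean
#' squared deviation from the across-conformation mean position), and remove
#' the most variable position. The removal trace is the core-residue
#' identification graph; the default stopping rule cuts it at the knee of the
#' trace (the largest second difference of the lightly smoothed
#' log-max-variance curve, i.e. where the trace settles onto its noise
#' floor); `target_count` keeps a fixed number of positions instead.
#'
#' @param hset A [homolog_set()] with MSA and ensembles.
#' @param stop `"knee"` (default) or `"count"`.
#' @param target_count Required core size when `stop = "count"`.
#' @param min_core Smallest candidate set explored (default 4).
#' @return A list of class `core_find`: `core_positions`
#'   (reference-sequence numbering, sorted), `trace` (tibble with
#'   `iteration`, `removed_position`, `max_variance`, `n_remaining`), and
#'   `stop`.
#' @export
core_find <- function(hset, stop = c("knee", "count"), target_count = NULL,
                      min_core = 4L) {
  stop <- match.arg(stop)
  g <- gather_shared_conformations(hset)
  if (length(g$coords) < 2L) abort("core finding requires at least two conformations.")
  p <- length(g$ref_positions)
  if (p < 4L) abort("fewer than 4 shared ungapped columns.")
  if (stop == "count") {
    if (is.null(target_count)) abort("`target_count` required for stop = 'count'.")
    if (target_count < 3L || target_count >= p) {
      abort("`target_count` must be in [3, number of shared positions).")
    }
  }

  active <- seq_len(p)        # row indices into the shared-column coordinates
  trace <- list()
  # initial fit weights come from the superposition-free rigidity ranking;
  # afterwards each round reuses its own measured variances, so the
  # superposition anchors on the quietest positions of the current set
  # instead of being dragged toward large mobile blocks
  v <- distance_rigidity(g$coords)
  repeat {
    if (length(active) <= min_core) break
    w <- 1 / (v + 1e-6)
    coords <- superpose_conformations(g$coords, active, weights = w)
    sub <- lapply(coords, function(xy) xy[active, , drop = FALSE])
    mean_sub <- Reduce(`+`, sub) / length(sub)
    v <- Reduce(`+`, lapply(sub, function(xy) rowSums((xy - mean_sub)^2))) / length(sub)
    if (length(trace) == 0L && max(v) < 1e-12) break  # identical structures
    worst <- which.max(v)
    trace[[length(trace) + 1L]] <- tibble(
      iteration = length(trace) + 1L,
      removed_position = g$ref_positions[active[worst]],
      max_variance = v[worst],
      n_remaining = length(active) - 1L
    )
    active <- active[-worst]
    v <- v[-worst]
    if (stop == "count" && length(active) <= target_count) break
  }
  trace <- dplyr::bind_rows(trace)

  if (stop == "knee" && nrow(trace) >= 3L) {
    # knee of the removal trace: largest second difference, taken on the log
    # scale (variances span orders of magnitude between mobile positions and
    # the noise floor) after light median smoothing
    v <- log10(pmax(trace$max_variance, 1e-12))
    if (length(v) >= 5L) v <- stats::runmed(v, 3L)
    k <- 2:(length(v) - 1L)
    d2 <- v[k - 1L] - 2 * v[k] + v[k + 1L]
    knee <- k[which.max(d2)]
    removed <- trace$removed_position[seq_len(knee - 1L)]
    core <- sort(setdiff(g$ref_positions, removed))
  } else if (stop == "knee") {
    core <- sort(g$ref_positions)
  } else {
    core <- sort(g$ref_positions[active])
  }
  structure(
    list(core_positions = core, trace = trace, stop = stop),
    class = "core_find"
  )
}

#' @export
print.core_find <- function(x, ...) {
  cat(sprintf(
    "<core_find> %d core positions (stop: %s, %d removals traced)\n",
    length(x$core_positions), x$stop, nrow(x$trace)
  ))
  invisible(x)
}

#' Joint PCA of conformations across homologs
#'
#' Superposes every conformation on the core positions (fit-to-mean), then
#' runs Cartesian PCA over all shared ungapped columns. Projections carry
#' homolog and group labels in `frame_info`.
#'
#' @param hset A [homolog_set()] with MSA and ensembles.
#' @param core_positions Reference-sequence positions used as the
#'   superposition anchor (subset of the shared columns), e.g. from
#'   [core_find()].
#' @return A `traj_pca` whose `frame_info` has one row per conformation
#'   (`homolog_id`, `group`, `frame`, `time_ns`).
#' @export
joint_pca <- function(hset, core_positions) {
  g <- gather_shared_conformations(hset)
  if (length(g$coords) < 3L) abort("joint PCA requires at least three conformations.")
  fit_rows <- match(core_positions, g$ref_positions)
  if (anyNA(fit_rows)) abort("`core_positions` must be shared ungapped columns.")
  if (length(fit_rows) < 3L) abort("need at least 3 core positions.")
  coords <- superpose_conformations(g$coords, fit_rows)
  xyz <- t(vapply(coords, function(xy) as.numeric(t(xy)),
                  numeric(3L * length(g$ref_positions))))
  res <- pca_xyz_matrix(xyz)
  new_traj_pca(
    mean_coords = xyz_to_coords(res$mean_vec),
    eigenvalues = res$eigenvalues,
    eigenvectors = res$vectors,
    projections = res$projections,
    frame_info = g$frame_info,
    residue_numbers = g$ref_positions,
    residue_codes = g$ref_codes,
    core_positions = sort(core_positions)
  )
}

#' Rank homologs by conformational outlierness in PC space
#'
#' In the first `n_pcs` principal components, computes each homolog's centroid
#' distance from the global medoid homolog (the centroid minimising the total
#' distance to all other centroids) and its within-homolog spread (mean
#' pairwise distance between its own projections), then ranks descending by
#' centroid distance with spread as tie-break.
#'
#' @param pca A `traj_pca` from [joint_pca()] with homolog-labelled frames.
#' @param n_pcs Number of leading components used (default 3).
#' @return A tibble `homolog_id`, `group`, `centroid_distance`, `spread`,
#'   `rank`, sorted by rank.
#' @export
outlier_rank <- function(pca, n_pcs = 3L) {
  stopifnot(inherits(pca, "traj_pca"))
  info <- pca$frame_info
  ids <- unique(info$homolog_id)
  if (length(ids) < 3L) abort("outlier ranking requires at least three homologs.")
  k <- min(n_pcs, ncol(pca$projections))
  proj <- pca$projections[, seq_len(k), drop = FALSE]

  centroids <- t(vapply(ids, function(id) {
    colMeans(proj[info$homolog_id == id, , drop = FALSE])
  }, numeric(k)))
  dmat <- as.matrix(stats::dist(centroids))
  medoid <- which.min(rowSums(dmat))
  centroid_distance <- dmat[, medoid]

  spread <- vapply(ids, function(id) {
    pr <- proj[info$homolog_id == id, , drop = FALSE]
    if (nrow(pr) < 2L) return(0)
    mean(stats::dist(pr))
  }, numeric(1))

  group_of <- vapply(ids, function(id) info$group[info$homolog_id == id][1], character(1))
  out <- tibble(
    homolog_id = ids, group = unname(group_of),
    centroid_distance = unname(centroid_distance), spread = unname(spread)
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$centroid_distance),
                        dplyr::desc(.data$spread), .data$homolog_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' Progressive greedy removal of structurally divergent homologs
#'
#' At each step removes the homolog whose removal maximises the median score
#' among the remaining between-homolog pairs (ties broken by lexicographic
#' id), recording the median after every removal.
#'
#' @param pair_table A between-homolog score table (columns `id_a`, `id_b`,
#'   `score`).
#' @param k Number of homologs to remove; must leave at least two.
#' @return A tibble `step` (0..k), `removed_id` (`NA` for step 0),
#'   `median_score`, `n_pairs`.
#' @export
progressive_removal <- function(pair_table, k) {
  pt <- dplyr::filter(pair_table, .data$id_a != .data$id_b)
  if (nrow(pt) < 1L) abort("`pair_table` has no between-homolog rows.")
  ids <- sort(unique(c(pt$id_a, pt$id_b)))
  if (k >= length(ids) - 1L) abort("`k` must leave at least two homologs.")

  median_for <- function(keep) {
    rows <- pt$id_a %in% keep & pt$id_b %in% keep
    if (!any(rows)) return(c(NA_real_, 0))
    c(median(pt$score[rows]), sum(rows))
  }

  keep <- ids
  m0 <- median_for(keep)
  out <- list(tibble(
    step = 0L, removed_id = NA_character_, median_score = m0[1], n_pairs = as.integer(m0[2])
  ))
  for (step in seq_len(k)) {
    cand <- vapply(keep, function(id) median_for(setdiff(keep, id))[1], numeric(1))
    best <- keep[which(cand == max(cand))]
    removed <- sort(best)[1]                    # lexicographic tie-break
    keep <- setdiff(keep, removed)
    m <- median_for(keep)
    out[[length(out) + 1L]] <- tibble(
      step = step, removed_id = removed,
      median_score = m[1], n_pairs = as.integer(m[2])
    )
  }
  dplyr::bind_rows(out)
}
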