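#' Global-alignment pairwise sequence identity
#'
#' Aligns two amino-acid sequences globally (Needleman-Wunsch, BLOSUM62,
#' affine gaps: opening 11, extension 1) and reports the fraction of
#' alignment columns with identical residues; the denominator is the number
#' of alignment columns (a pairwise alignment has no double-gap columns).
#'
#' @param seq_a,seq_b Non-empty amino-acid sequences (standard 20 letters).
#' @param gap_opening,gap_extension Affine gap penalties (defaults 11, 1).
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACDE", "ACDF") # 0.75
pairwise_identity <- function(seq_a, seq_b, gap_opening = 11, gap_extension = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty.")
  check_amino_acids(seq_chars(seq_a), "seq_a")
  check_amino_acids(seq_chars(seq_b), "seq_b")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global"
  )
  pa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  pb <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  sum(pa == pb & pa != "-") / length(pa)
}

#' Classify homologs into type-I / distant / unassigned groups
#'
#' A homolog is type-I when its identity to the reference is at least
#' `type1_min` (default 0.72); otherwise it is distant when its best identity
#' to any seed distant homolog is at least `distant_min` (default 0.35);
#' otherwise unassigned.
#'
#' @param data A data frame with one row per homolog.
#' @param identity_to_reference Column of identities to the reference
#'   (tidy-eval; default `identity_to_reference`).
#' @param identity_to_distant Column with the maximum identity to the seed
#'   distant homologs (default `identity_to_distant`); `NA` treated as 0.
#' @param type1_min,distant_min Classification thresholds.
#' @return `data` with a `group` column added.
#' @export
classify_homologs <- function(data,
                              identity_to_reference = identity_to_reference,
                              identity_to_distant = identity_to_distant,
                              type1_min = 0.72, distant_min = 0.35) {
  ref_id <- dplyr::pull(data, {{ identity_to_reference }})
  dist_id <- dplyr::pull(data, {{ identity_to_distant }})
  dist_id[is.na(dist_id)] <- 0
  if (any(ref_id < 0 | ref_id > 1, na.rm = TRUE)) abort("identities must be in [0, 1].")
  data$group <- dplyr::case_when(
    ref_id >= type1_min ~ "type-I",
    dist_id >= distant_min ~ "distant",
    TRUE ~ "unassigned"
  )
  data
}

# Shannon-entropy conservation score of one MSA column (characters)
column_conservation <- function(chars) {
  res <- chars[chars != "-"]
  if (length(res) == 0L) return(NA_real_)
  p <- table(res) / length(res)
  h <- -sum(p * log2(p))
  1 - h / log2(20)
}

#' Per-column Shannon-entropy conservation profile
#'
#' For each MSA column computes `1 - H / log2(20)` where `H` is the Shannon
#' entropy of the non-gap residue frequencies (gaps are excluded from the
#' frequencies, not treated as a 21st symbol). Columns with gap fraction
#' above 0.5 are flagged; all-gap columns score `NA`.
#'
#' @param m An [msa()].
#' @return A tibble with `column`, `score`, `gap_fraction`, `flagged`.
#' @export
conservation_profile <- function(m) {
  stopifnot(inherits(m, "msa"))
  mat <- do.call(rbind, lapply(unname(m$rows), seq_chars))
  ncol_aln <- ncol(mat)
  scores <- apply(mat, 2, column_conservation)
  gap_frac <- colMeans(mat == "-")
  tibble(
    column = seq_len(ncol_aln),
    score = as.numeric(scores),
    gap_fraction = gap_frac,
    flagged = gap_frac > 0.5 | is.na(scores)
  )
}

#' Conservation differential between two alignments
#'
#' Computes per-column conservation for a full alignment and for an
#' alignment of a sequence subset, maps both tracks onto the ungapped
#' positions of a common reference sequence, and reports the per-position
#' difference `delta = score_subset - score_all` within a reference-numbering
#' window. Positive deltas mark positions whose conservation rises when the
#' designated (e.g. divergent) sequences are removed.
#'
#' @param msa_all [msa()] over all sequences.
#' @param msa_subset [msa()] over the retained subset (same reference
#'   sequence present).
#' @param reference_id Reference sequence id, present in both alignments.
#' @param window Integer pair `(start, end)` in reference numbering
#'   (default `c(10, 268)`), intersected with the reference length.
#' @return A tibble `position`, `score_all`, `score_subset`, `delta`.
#' @export
conservation_differential <- function(msa_all, msa_subset, reference_id,
                                      window = c(10, 268)) {
  stopifnot(inherits(msa_all, "msa"), inherits(msa_subset, "msa"))
  for (m in list(msa_all, msa_subset)) {
    if (!reference_id %in% m$ids) {
      abort(sprintf("reference '%s' missing from an alignment.", reference_id))
    }
  }
  if (msa_sequence(msa_all, reference_id) != msa_sequence(msa_subset, reference_id)) {
    abort("reference sequence differs between the two alignments.")
  }

  map_track <- function(m) {
    prof <- conservation_profile(m)
    cmap <- msa_column_map(m, reference_id)
    keep <- !is.na(cmap)
    tibble(position = cmap[keep], score = prof$score[keep])
  }
  all_track <- map_track(msa_all)
  sub_track <- map_track(msa_subset)
  ref_len <- nchar(msa_sequence(msa_all, reference_id))
  lo <- max(window[1], 1L)
  hi <- min(window[2], ref_len)
  dplyr::inner_join(
    dplyr::rename(all_track, score_all = "score"),
    dplyr::rename(sub_track, score_subset = "score"),
    by = "position"
  ) |>
    dplyr::filter(.data$position >= lo, .data$position <= hi) |>
    dplyr::mutate(delta = .data$score_subset - .data$score_all)
}

#' Indel blocks of a query relative to a reference in an MSA
#'
#' Deletions are maximal column runs where the query is gapped but the
#' reference is not (positioned at the first reference position of the run);
#' insertions are maximal runs where the reference is gapped but the query is
#' not (anchored to the preceding reference position, 0 at the start). Runs
#' shorter than `min_length` are dropped.
#'
#' @param m An [msa()].
#' @param reference_id,query_id Row ids.
#' @param min_length Minimum block length reported (default 3).
#' @return A tibble `kind` (`deletion`/`insertion`), `reference_position`,
#'   `length`.
#' @export
indel_blocks <- function(m, reference_id, query_id, min_length = 3L) {
  stopifnot(inherits(m, "msa"))
  ref <- seq_chars(msa_row(m, reference_id))
  qry <- seq_chars(msa_row(m, query_id))
  ref_map <- msa_column_map(m, reference_id)
  # last reference position at or before each column (0 before the first)
  last_ref <- cummax(ifelse(is.na(ref_map), 0L, ref_map))

  state <- dplyr::case_when(
    ref != "-" & qry == "-" ~ "deletion",
    ref == "-" & qry != "-" ~ "insertion",
    TRUE ~ "none"
  )
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] == "none" || r$lengths[k] < min_length) next
    pos <- if (r$values[k] == "deletion") {
      ref_map[starts[k]]
    } else {
      if (starts[k] == 1L) 0L else last_ref[starts[k] - 1L]
    }
    out[[length(out) + 1L]] <- tibble(
      kind = r$values[k], reference_position = as.integer(pos),
      length = as.integer(r$lengths[k])
    )
  }
  if (length(out) == 0L) {
    return(tibble(
      kind = character(), reference_position = integer(), length = integer()
    ))
  }
  dplyr::bind_rows(out)
}

#' Default residue classes for HTH motif patterns
#'
#' Small \{G, A, S, C, T\}; hydrophobic \{A, V, L, I, M, F, W, Y, C\};
#' polar \{S, T, N, Q, H, K, R, D, E, Y, W\}. Observed natural motifs deviate
#' from strict class membership, hence motif scans allow violations.
#'
#' @return Named list of character vectors `small`, `hydrophobic`, `polar`.
#' @export
default_residue_classes <- function() {
  list(
    small = c("G", "A", "S", "C", "T"),
    hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y", "C"),
    polar = c("S", "T", "N", "Q", "H", "K", "R", "D", "E", "Y", "W")
  )
}

#' Scan a sequence for HTH-associated residue-class triplets
#'
#' Slides a 3-residue window over a region and classifies each triplet
#' against a class pattern: `"shs"` (small-hydrophobic-small) or `"phs"`
#' (polar-hydrophobic-small). Triplets violating the pattern at no more than
#' `max_violations` positions are reported, sorted by (violations, position).
#'
#' @param sequence Amino-acid sequence.
#' @param pattern `"shs"` or `"phs"`.
#' @param region Optional integer pair `(start, end)` limiting the scan
#'   (1-based inclusive, positions of the triplet's first residue lie within
#'   `start` to `end - 2`).
#' @param max_violations Maximum tolerated class violations (default 1).
#' @param classes Residue classes, see [default_residue_classes()].
#' @return A tibble `position`, `triplet`, `violations`.
#' @export
#' @examples
#' motif_scan("AGISA", "shs") # GIS with 0 violations
motif_scan <- function(sequence, pattern = c("shs", "phs"), region = NULL,
                       max_violations = 1L,
                       classes = default_residue_classes()) {
  pattern <- match.arg(pattern)
  chars <- seq_chars(sequence)
  check_amino_acids(chars, "sequence")
  n <- length(chars)
  region <- region %||% c(1L, n)
  if (region[1] < 1L || region[2] > n || region[1] > region[2]) {
    abort("`region` must lie within the sequence.")
  }
  class_seq <- switch(pattern,
    shs = list(classes$small, classes$hydrophobic, classes$small),
    phs = list(classes$polar, classes$hydrophobic, classes$small)
  )
  starts <- seq.int(region[1], max(region[1], region[2] - 2L))
  starts <- starts[starts + 2L <= region[2]]
  if (length(starts) == 0L) {
    return(tibble(position = integer(), triplet = character(), violations = integer()))
  }
  rows <- purrr::map(starts, function(s) {
    trip <- chars[s:(s + 2L)]
    viol <- sum(!purrr::map2_lgl(trip, class_seq, ~ .x %in% .y))
    tibble(position = s, triplet = paste(trip, collapse = ""), violations = viol)
  })
  dplyr::bind_rows(rows) |>
    dplyr::filter(.data$violations <= max_violations) |>
    dplyr::arrange(.data$violations, .data$position)
}

#' Sliding-window net formal charge profile
#'
#' Sequence-level proxy for local electrostatics: K and R count +1, D and E
#' count -1, all other residues (including histidine) 0; the profile is the
#' sliding-window sum.
#'
#' @param sequence Amino-acid sequence.
#' @param window Window width (default 10), at most the sequence length.
#' @return A tibble `start`, `end`, `charge` (one row per window).
#' @export
charge_profile <- function(sequence, window = 10L) {
  chars <- seq_chars(sequence)
  check_amino_acids(chars, "sequence")
  n <- length(chars)
  if (window < 1L || window > n) abort("`window` must be in [1, sequence length].")
  q <- ifelse(chars %in% c("K", "R"), 1L, ifelse(chars %in% c("D", "E"), -1L, 0L))
  cs <- cumsum(c(0L, q))
  starts <- seq_len(n - window + 1L)
  tibble(
    start = starts,
    end = starts + window - 1L,
    charge = cs[starts + window] - cs[starts]
  )
}

#' Domain length and inter-domain gap arithmetic
#'
#' Lengths are `end - start + 1` (1-based inclusive numbering); the gap
#' between consecutive domains is `next_start - prev_end - 1`.
#'
#' @param annotations A data frame with columns `name`, `start`, `end` (and
#'   optionally `role`); domains must not overlap.
#' @return A list with tibbles `domains` (`name`, `start`, `end`, `length`)
#'   and `gaps` (`from`, `to`, `gap_length`).
#' @export
#' @examples
#' ann <- tibble::tibble(
#'   name = c("N-HTH", "C-HTH"), start = c(21, 138), end = c(75, 192)
#' )
#' domain_arithmetic(ann)
domain_arithmetic <- function(annotations) {
  ann <- as_tibble(annotations)
  if (!all(c("name", "start", "end") %in% names(ann))) {
    abort("`annotations` needs columns name, start, end.")
  }
  if (any(ann$start > ann$end)) abort("each annotation must have start <= end.")
  ann <- dplyr::arrange(ann, .data$start)
  if (nrow(ann) > 1L && any(ann$start[-1] <= ann$end[-nrow(ann)])) {
    abort("annotations must not overlap.")
  }
  domains <- dplyr::mutate(
    ann[, c("name", "start", "end")],
    length = .data$end - .data$start + 1L
  )
  gaps <- if (nrow(ann) > 1L) {
    tibble(
      from = ann$name[-nrow(ann)],
      to = ann$name[-1],
      gap_length = ann$start[-1] - ann$end[-nrow(ann)] - 1L
    )
  } else {
    tibble(from = character(), to = character(), gap_length = integer())
  }
  list(domains = domains, gaps = gaps)
}
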