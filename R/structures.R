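#' Single conformation as an ordered C-alpha trace
#'
#' A `structure3d` holds one conformation of a protein chain reduced to its
#' C-alpha atoms: residue numbers, one-letter residue codes, and an N x 3
#' coordinate matrix in Angstrom.
#'
#' @param id Character identifier of the conformation (usually the homolog id).
#' @param residue_numbers Integer vector, strictly increasing.
#' @param residue_codes Character vector of one-letter amino-acid codes.
#' @param coords Numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#'
#' @return An object of class `structure3d`.
#' @export
#' @examples
#' s <- structure3d("toy", 1:3, c("A", "G", "S"), matrix(rnorm(9), 3))
#' s
structure3d <- function(id, residue_numbers, residue_codes, coords) {
  if (!is.character(id) || length(id) != 1L) abort("`id` must be a single string.")
  residue_numbers <- as.integer(residue_numbers)
  check_coord_matrix(coords, "coords")
  n <- nrow(coords)
  if (length(residue_numbers) != n || length(residue_codes) != n) {
    abort("`residue_numbers`, `residue_codes` and `coords` must have equal lengths.")
  }
  if (n > 1 && any(diff(residue_numbers) <= 0)) {
    abort("`residue_numbers` must be strictly increasing.")
  }
  check_amino_acids(residue_codes, "residue_codes")
  dimnames(coords) <- NULL
  structure(
    list(
      id = id,
      residue_numbers = residue_numbers,
      residue_codes = as.character(residue_codes),
      coords = coords
    ),
    class = "structure3d"
  )
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf(
    "<structure3d> %s: %d residues (%d-%d)\n",
    x$id, length(x$residue_numbers),
    min(x$residue_numbers), max(x$residue_numbers)
  ))
  invisible(x)
}

#' Time-stamped conformational ensemble of one homolog
#'
#' An `ensemble` is a sequence of [structure3d()] frames sharing the same
#' residue numbering and codes, each frame stamped with a simulation time in
#' nanoseconds.
#'
#' @param homolog_id Character identifier of the homolog.
#' @param frames List of [structure3d()] objects sharing residue numbering.
#' @param times_ns Numeric vector of frame times (ns), strictly increasing.
#'
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(homolog_id, frames, times_ns) {
  if (!is.character(homolog_id) || length(homolog_id) != 1L) {
    abort("`homolog_id` must be a single string.")
  }
  if (!is.list(frames) || length(frames) < 1L ||
      !all(vapply(frames, inherits, logical(1), "structure3d"))) {
    abort("`frames` must be a non-empty list of structure3d objects.")
  }
  times_ns <- as.numeric(times_ns)
  if (length(times_ns) != length(frames)) {
    abort("`times_ns` must have one entry per frame.")
  }
  if (length(times_ns) > 1 && any(diff(times_ns) <= 0)) {
    abort("`times_ns` must be strictly increasing.")
  }
  ref <- frames[[1]]
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!identical(f$residue_numbers, ref$residue_numbers) ||
        !identical(f$residue_codes, ref$residue_codes)) {
      abort(sprintf("frame %d does not share residue numbering/codes with frame 1.", i))
    }
  }
  structure(
    list(homolog_id = homolog_id, frames = frames, times_ns = times_ns),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf(
    "<ensemble> %s: %d frames x %d residues, t = %g..%g ns\n",
    x$homolog_id, length(x$frames), length(x$frames[[1]]$residue_numbers),
    min(x$times_ns), max(x$times_ns)
  ))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x An [ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  length(x$frames)
}

# frames as an F x 3N matrix (x1, y1, z1, x2, ...), the layout used by
# trajectory PCA and the bio3d cross-checks
ensemble_xyz <- function(ens) {
  stopifnot(inherits(ens, "ensemble"))
  t(vapply(
    ens$frames,
    function(f) as.numeric(t(f$coords)),
    numeric(3L * nrow(ens$frames[[1]]$coords))
  ))
}

xyz_to_coords <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' Multiple sequence alignment container
#'
#' Holds aligned amino-acid rows (20 one-letter codes plus `-` gap) with
#' unique sequence identifiers.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param rows Character vector of aligned sequences, all the same length.
#'
#' @return An object of class `msa`.
#' @export
msa <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- as.character(rows)
  if (length(ids) != length(rows) || length(ids) < 1L) {
    abort("`ids` and `rows` must be non-empty and of equal length.")
  }
  if (anyDuplicated(ids)) abort("`ids` must be unique.")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    abort("all MSA rows must have equal length.")
  }
  for (i in seq_along(rows)) {
    check_amino_acids(seq_chars(rows[i]), sprintf("row '%s'", ids[i]), allow_gap = TRUE)
  }
  structure(list(ids = ids, rows = setNames(rows, ids)), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf(
    "<msa> %d sequences x %d columns\n", length(x$ids), nchar(x$rows[[1]])
  ))
  invisible(x)
}

msa_row <- function(m, id) {
  stopifnot(inherits(m, "msa"))
  if (!id %in% m$ids) abort(sprintf("sequence '%s' not found in MSA.", id))
  m$rows[[id]]
}

# ungapped sequence of a row
msa_sequence <- function(m, id) gsub("-", "", msa_row(m, id), fixed = TRUE)

# for one row: vector over columns, giving the residue index (1-based within the
# ungapped sequence) at each column, NA at gaps
msa_column_map <- function(m, id) {
  ch <- seq_chars(msa_row(m, id))
  idx <- rep(NA_integer_, length(ch))
  idx[ch != "-"] <- seq_len(sum(ch != "-"))
  idx
}

#' Homolog family container
#'
#' Bundles per-homolog records (id, sequence, group label, optional
#' conformational ensemble) with a shared multiple sequence alignment and a
#' designated reference homolog.
#'
#' @param records A data frame / tibble with columns `id`, `sequence`, `group`
#'   (one of `"reference"`, `"type-I"`, `"distant"`, `"unassigned"`), and an
#'   optional `ensemble` list-column of [ensemble()] objects (or `NULL`).
#' @param msa An [msa()] covering at least all record ids, or `NULL`.
#' @param reference_id Identifier of the reference homolog; must appear in
#'   `records`.
#'
#' @return An object of class `homolog_set`.
#' @export
homolog_set <- function(records, msa = NULL, reference_id) {
  records <- as_tibble(records)
  needed <- c("id", "sequence", "group")
  if (!all(needed %in% names(records))) {
    abort("`records` must have columns id, sequence, group.")
  }
  if (!"ensemble" %in% names(records)) {
    records$ensemble <- vector("list", nrow(records))
  }
  if (anyDuplicated(records$id)) abort("record ids must be unique.")
  ok_groups <- c("reference", "type-I", "distant", "unassigned")
  bad <- setdiff(unique(records$group), ok_groups)
  if (length(bad)) abort(sprintf("unknown group labels: %s", paste(bad, collapse = ", ")))
  if (!reference_id %in% records$id) {
    abort(sprintf("reference_id '%s' not present in records.", reference_id))
  }
  for (i in seq_len(nrow(records))) {
    check_amino_acids(seq_chars(records$sequence[i]), sprintf("sequence of '%s'", records$id[i]))
    e <- records$ensemble[[i]]
    if (!is.null(e)) {
      if (!inherits(e, "ensemble")) abort("`ensemble` column must hold ensemble objects or NULL.")
      if (paste(e$frames[[1]]$residue_codes, collapse = "") != records$sequence[i]) {
        abort(sprintf("ensemble residue codes of '%s' do not match its sequence.", records$id[i]))
      }
    }
  }
  if (!is.null(msa)) {
    stopifnot(inherits(msa, "msa"))
    for (i in seq_len(nrow(records))) {
      if (records$id[i] %in% msa$ids &&
          msa_sequence(msa, records$id[i]) != records$sequence[i]) {
        abort(sprintf("MSA row of '%s' does not match its sequence when ungapped.", records$id[i]))
      }
    }
  }
  structure(
    list(records = records, msa = msa, reference_id = reference_id),
    class = "homolog_set"
  )
}

#' @export
print.homolog_set <- function(x, ...) {
  n_ens <- sum(!vapply(x$records$ensemble, is.null, logical(1)))
  cat(sprintf(
    "<homolog_set> %d homologs (reference: %s), %d with ensembles\n",
    nrow(x$records), x$reference_id, n_ens
  ))
  print(dplyr::count(x$records, .data$group))
  invisible(x)
}
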