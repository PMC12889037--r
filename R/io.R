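#' Read a multi-model PDB file into an ensemble
#'
#' Parses a single-chain, multi-model PDB file (MODEL/ENDMDL blocks) and keeps
#' the C-alpha trace of every model. Every residue present in the file must
#' carry a CA atom and all models must describe the same residue set; both
#' conditions are validated before coordinates are read (coordinate parsing is
#' delegated to \pkg{bio3d}).
#'
#' @param path Path to the PDB file.
#' @param frame_times Optional numeric vector of frame times in ns (one per
#'   MODEL, strictly increasing). Defaults to `0, 1, 2, ...` because the PDB
#'   format has no standard field for simulation time.
#' @param homolog_id Identifier for the resulting ensemble; defaults to the
#'   file name without extension.
#'
#' @return An [ensemble()] with one frame per MODEL, file residue numbering
#'   preserved.
#' @export
read_multi_model_pdb <- function(path, frame_times = NULL, homolog_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  homolog_id <- homolog_id %||% sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  validate_multi_model_lines(lines, path)

  pdb <- bio3d::read.pdb(path, multi = TRUE, ATOM.only = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (length(sel$atom) < 1L) abort(sprintf("no CA atoms found in %s", path))
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  if (length(unique(atoms$chain)) > 1L) {
    abort(sprintf("%s contains more than one chain; expected a single chain.", path))
  }
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  n_models <- nrow(xyz)
  resno <- atoms$resno
  codes <- bio3d::aa321(atoms$resid)
  check_amino_acids(codes, "residue codes")

  frame_times <- frame_times %||% as.numeric(seq_len(n_models) - 1L)
  if (length(frame_times) != n_models) {
    abort(sprintf(
      "frame_times has %d entries but %s contains %d models.",
      length(frame_times), path, n_models
    ))
  }
  frames <- lapply(seq_len(n_models), function(i) {
    structure3d(homolog_id, resno, codes, xyz_to_coords(xyz[i, ]))
  })
  ensemble(homolog_id, frames, frame_times)
}

# light structural scan of the raw PDB lines: per-model residue sets from ATOM
# records, CA presence per residue, consistency across models. bio3d silently
# recycles coordinates for ragged models, so these contracts are checked here.
validate_multi_model_lines <- function(lines, path) {
  model_starts <- grep("^MODEL", lines)
  atom_idx <- grep("^ATOM  ", lines)
  if (length(atom_idx) == 0L) abort(sprintf("no ATOM records in %s", path))
  if (length(model_starts) == 0L) {
    model_of <- rep(1L, length(atom_idx))
  } else {
    model_of <- findInterval(atom_idx, model_starts)
    if (any(model_of == 0L)) abort(sprintf("ATOM records before first MODEL in %s", path))
  }
  atom_lines <- lines[atom_idx]
  atom_name <- trimws(substr(atom_lines, 13, 16))
  resno <- suppressWarnings(as.integer(substr(atom_lines, 23, 26)))
  if (any(is.na(resno))) abort(sprintf("unparseable residue numbers in %s", path))

  per_model <- split(data.frame(atom_name, resno), model_of)
  residue_sets <- lapply(per_model, function(df) {
    has_ca <- tapply(df$atom_name == "CA", df$resno, any)
    missing <- names(has_ca)[!has_ca]
    if (length(missing) > 0L) {
      abort(sprintf(
        "residue %s has no CA atom in %s", paste(missing, collapse = ", "), path
      ))
    }
    sort(unique(df$resno[df$atom_name == "CA"]))
  })
  ref_set <- residue_sets[[1]]
  for (m in seq_along(residue_sets)) {
    if (!identical(residue_sets[[m]], ref_set)) {
      diff_res <- c(
        setdiff(ref_set, residue_sets[[m]]),
        setdiff(residue_sets[[m]], ref_set)
      )
      abort(sprintf(
        "model %d has an inconsistent residue set in %s (differs at residue %s)",
        m, path, paste(diff_res, collapse = ", ")
      ))
    }
  }
  invisible(TRUE)
}

#' Write a structure or ensemble as a (multi-model) PDB file
#'
#' @param x A [structure3d()] or [ensemble()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "structure3d")) {
    xyz <- matrix(as.numeric(t(x$coords)), nrow = 1L)
    template <- x
  } else if (inherits(x, "ensemble")) {
    xyz <- ensemble_xyz(x)
    template <- x$frames[[1]]
  } else {
    abort("`x` must be a structure3d or an ensemble.")
  }
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = template$residue_numbers,
    resid = bio3d::aa123(template$residue_codes),
    elety = rep("CA", length(template$residue_numbers)),
    chain = rep("A", length(template$residue_numbers))
  )
  invisible(path)
}

#' Read a FASTA file of amino-acid sequences
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) abort(sprintf("no sequences in %s", path))
  tibble(
    id = vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L),
    sequence = unname(as.character(set))
  )
}

#' Write amino-acid sequences as FASTA
#'
#' @param seqs Tibble with columns `id` and `sequence`, or a named character
#'   vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs) && !is.null(names(seqs))) {
    seqs <- tibble(id = names(seqs), sequence = unname(seqs))
  }
  writeLines(
    as.character(rbind(paste0(">", seqs$id), seqs$sequence)),
    path
  )
  invisible(path)
}

#' Read a multiple sequence alignment (aligned FASTA or Clustal)
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (detect a CLUSTAL header), `"fasta"`, or
#'   `"clustal"`.
#' @return An [msa()].
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  m <- as.character(aln)
  ids <- vapply(strsplit(names(m), "\\s+"), `[[`, character(1), 1L)
  msa(ids, toupper(unname(m)))
}

#' Write an MSA as aligned FASTA
#'
#' @param m An [msa()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa <- function(m, path) {
  stopifnot(inherits(m, "msa"))
  write_fasta(tibble(id = m$ids, sequence = unname(m$rows)), path)
}

#' Write a records table to TSV or JSON
#'
#' Column order is preserved; TSV uses tab separation with a header row, JSON
#' is an array of row objects.
#'
#' @param records A data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_table <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as_tibble(records)
  if (format == "tsv") {
    readr::write_tsv(records, path)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"`.
#' @return A tibble.
#' @export
read_table_file <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}
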