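# one-letter amino-acid alphabet used throughout
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# evaluate `expr` under a fixed RNG state, restoring the caller's state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

check_coord_matrix <- function(x, arg = "coords", min_rows = 1L) {
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 3L) {
    abort(sprintf("`%s` must be a numeric N x 3 matrix.", arg))
  }
  if (nrow(x) < min_rows) {
    abort(sprintf("`%s` must have at least %d rows.", arg, min_rows))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite coordinates.", arg))
  }
  invisible(x)
}

check_amino_acids <- function(chars, arg = "sequence", allow_gap = FALSE) {
  allowed <- if (allow_gap) c(AA_ALPHABET, "-") else AA_ALPHABET
  bad <- setdiff(unique(chars), allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` contains non-standard symbols: %s", arg,
      paste(bad, collapse = ", ")
    ))
  }
  invisible(chars)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
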