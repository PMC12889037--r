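# Shared fixtures, built once per test run and cached (the family and its
# derived tables are the expensive objects).

.fixture_env <- new.env(parent = emptyenv())

withr_local_tempfile <- function(ext = ".tmp", env = parent.frame()) {
  withr::local_tempfile(fileext = ext, .local_envir = env)
}

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

FAMILY_SEED <- 11L

get_family <- function() memo("family", function() make_family(seed = FAMILY_SEED))

get_sampled <- function() memo("sampled", function() {
  fam <- get_family()
  hs <- fam$homolog_set
  hs$records$ensemble <- lapply(hs$records$ensemble, sample_frames)
  hs
})

get_core <- function() memo("core", function() core_find(get_sampled()))

get_tm_within <- function() memo("tm_within", function() {
  pairwise_matrix(get_sampled(), "within_homolog")
})

get_tm_between <- function() memo("tm_between", function() {
  pairwise_matrix(get_sampled(), "between_homolog")
})

get_ref_dynamics <- function() memo("ref_dyn", function() {
  fam <- get_family()
  ens <- fam$homolog_set$records$ensemble[[1]]
  eq <- apply_equilibration_offset(ens, 20)
  sup <- superpose_ensemble(eq, "mean")
  list(sup = sup, dccm = dccm(sup), pca = trajectory_pca(sup),
       truth = attr(ens, "hinge_truth"))
})

get_joint_pca <- function() memo("joint_pca", function() {
  joint_pca(get_sampled(), get_core()$core_positions)
})

# classification table of the family from computed identities
get_family_classification <- function() memo("classification", function() {
  recs <- get_family()$homolog_set$records
  ref_seq <- recs$sequence[recs$id == "ref"]
  distant_ids <- recs$id[recs$group == "distant"]
  idt <- purrr::map_dfr(seq_len(nrow(recs)), function(i) {
    others <- setdiff(distant_ids, recs$id[i])
    tibble::tibble(
      id = recs$id[i],
      identity_to_reference = pairwise_identity(recs$sequence[i], ref_seq),
      identity_to_distant = if (length(others) > 0) {
        max(vapply(others, function(d) {
          pairwise_identity(recs$sequence[i], recs$sequence[recs$id == d])
        }, numeric(1)))
      } else {
        NA_real_
      }
    )
  })
  classify_homologs(idt)
})

# a small random globular structure
tiny_structure <- function(n = 8L, seed = 1L, id = "toy") {
  set.seed(seed)
  codes <- sample(c("A", "G", "S", "L", "V", "K", "E"), n, replace = TRUE)
  structure3d(id, seq_len(n), codes, matrix(rnorm(n * 3, sd = 4), n, 3))
}

rigid_copy <- function(coords, angle_deg = 30, axis = c(0, 0, 1),
                       shift = c(1, -2, 3)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, byrow = TRUE)
  r <- diag(3) * cos(th) + sin(th) * k + (1 - cos(th)) * (a %o% a)
  sweep(coords %*% t(r), 2, -shift)
}

# minimal two-homolog set with identical-length sequences and tiny ensembles
tiny_homolog_set <- function(n_res = 12L, n_frames = 8L, seed = 2L) {
  set.seed(seed)
  codes <- sample(c("A", "G", "S", "L", "V", "K", "E", "D", "R", "T", "N", "I"),
                  n_res, replace = TRUE)
  base <- matrix(rnorm(n_res * 3, sd = 5), n_res, 3)
  mk_ens <- function(id, offset) {
    frames <- lapply(seq_len(n_frames), function(f) {
      structure3d(id, seq_len(n_res), codes,
                  base + offset + matrix(rnorm(n_res * 3, sd = 0.3), n_res, 3))
    })
    ensemble(id, frames, seq_len(n_frames) - 1)
  }
  seq_str <- paste(codes, collapse = "")
  records <- tibble::tibble(
    id = c("h1", "h2"),
    sequence = c(seq_str, seq_str),
    group = c("reference", "type-I"),
    ensemble = list(mk_ens("h1", 0), mk_ens("h2", 2))
  )
  homolog_set(records, msa = msa(c("h1", "h2"), c(seq_str, seq_str)),
              reference_id = "h1")
}

write_mm_pdb_fixture <- function(path, n_models = 2L, n_res = 3L,
                                 drop_res_in_model = NULL,
                                 ca_less_residue = NULL) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (r in seq_len(n_res)) {
      if (!is.null(drop_res_in_model) && m == drop_res_in_model[1] &&
          r == drop_res_in_model[2]) next
      atom <- if (!is.null(ca_less_residue) && r == ca_less_residue) " N  " else " CA "
      lines <- c(lines, sprintf(
        "ATOM  %5d %s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        r, atom, r, r * 1.1 + m * 0.05, r * 2.0, m * 1.0
      ))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
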