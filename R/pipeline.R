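#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable parameter at its
#' default: equilibration offset 20 ns, sampling grid 25-95 ns every 10 ns,
#' conservation window 10-268, type-I identity threshold 0.72, distant seed
#' threshold 0.35, shorter-chain TM normalisation, knee-stopped core finding.
#'
#' @param input_dir Directory holding `sequences.fasta`, `alignment.fasta`,
#'   `<id>.pdb` ensembles and a `times.yaml` sidecar (the layout written by
#'   [write_family()]).
#' @param output_dir Directory for the stage outputs.
#' @param ... Named overrides of any default.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir, ...) {
  cfg <- list(
    input_dir = input_dir,
    output_dir = output_dir,
    reference_id = NULL,          # default: from times.yaml
    offset_ns = 20,
    sample_start_ns = 25,
    sample_stop_ns = 95,
    sample_step_ns = 10,
    conservation_window = c(10, 268),
    type1_min = 0.72,
    distant_min = 0.35,
    normalize = "shorter",
    core_stop = "knee",
    core_target_count = NULL,
    outlier_k = 2L,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

read_family_inputs <- function(cfg) {
  need <- file.path(cfg$input_dir, c("sequences.fasta", "alignment.fasta", "times.yaml"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    abort(sprintf("missing input files: %s", paste(missing, collapse = ", ")))
  }
  seqs <- read_fasta(need[1])
  m <- read_msa(need[2])
  side <- yaml::read_yaml(need[3])
  reference_id <- cfg$reference_id %||% side$reference_id
  if (is.null(reference_id)) abort("no reference_id in config or times.yaml.")
  times <- as.numeric(side$times_ns)
  groups <- side$groups

  ensembles <- lapply(seqs$id, function(id) {
    p <- file.path(cfg$input_dir, paste0(id, ".pdb"))
    if (!file.exists(p)) return(NULL)
    read_multi_model_pdb(p, frame_times = times, homolog_id = id)
  })
  records <- tibble(
    id = seqs$id,
    sequence = seqs$sequence,
    group = vapply(seqs$id, function(id) {
      g <- groups[[id]] %||% "unassigned"
      as.character(g)
    }, character(1)),
    ensemble = ensembles
  )
  homolog_set(records, msa = m, reference_id = reference_id)
}

run_stage <- function(name, expr) {
  inform(sprintf("[pipeline] stage: %s", name))
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full homolog-divergence pipeline
#'
#' Executes, in order: homolog classification, conservation differential,
#' indel and motif scans, ensemble descriptor summaries, reference-homolog
#' DCCM and single-trajectory PCA, core-residue finding, joint PCA with
#' outlier ranking and progressive removal, and the pairwise TM-score
#' tables. Each stage writes a TSV/JSON artifact whose file name carries a
#' short hash of the configuration, plus a run manifest.
#'
#' Homologs without ensembles pass through the sequence-only stages and are
#' skipped (with a warning) by the structural stages.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the homolog set, the stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- substr(rlang::hash(unclass(cfg)), 1, 8)
  out_file <- function(stem, ext = "tsv") {
    file.path(cfg$output_dir, sprintf("%s-%s.%s", stem, cfg_hash, ext))
  }
  outputs <- character(0)
  emit <- function(tbl, stem, format = "tsv") {
    path <- out_file(stem, if (format == "tsv") "tsv" else "json")
    write_table(tbl, path, format)
    outputs <<- c(outputs, path)
    path
  }

  hset <- run_stage("load-inputs", read_family_inputs(cfg))
  recs <- hset$records
  ref_seq <- recs$sequence[recs$id == hset$reference_id]

  ## 1. classification by identity
  classified <- run_stage("classify", {
    distant_seed_ids <- recs$id[recs$group == "distant"]
    idt <- purrr::map_dfr(seq_len(nrow(recs)), function(i) {
      to_ref <- pairwise_identity(recs$sequence[i], ref_seq)
      to_dist <- if (length(setdiff(distant_seed_ids, recs$id[i])) > 0) {
        max(vapply(setdiff(distant_seed_ids, recs$id[i]), function(d) {
          pairwise_identity(recs$sequence[i], recs$sequence[recs$id == d])
        }, numeric(1)))
      } else {
        NA_real_
      }
      tibble(id = recs$id[i], identity_to_reference = to_ref,
             identity_to_distant = to_dist)
    })
    idt <- classify_homologs(idt, type1_min = cfg$type1_min,
                             distant_min = cfg$distant_min)
    # the reference and the declared distant seeds define their classes
    idt$group[idt$id == hset$reference_id] <- "reference"
    idt$group[idt$id %in% distant_seed_ids] <- "distant"
    emit(idt, "classify")
    idt
  })

  ## 2. conservation differential (all vs without-distant subset)
  conservation <- run_stage("conservation-differential", {
    distant_ids <- classified$id[classified$group == "distant"]
    keep <- setdiff(hset$msa$ids, distant_ids)
    sub <- msa(keep, unname(hset$msa$rows[keep]))
    cd <- conservation_differential(hset$msa, sub, hset$reference_id,
                                    window = cfg$conservation_window)
    emit(cd, "conservation-differential")
    cd
  })

  ## 3. indel blocks + motif scan
  indels <- run_stage("indels-motifs", {
    others <- setdiff(recs$id, hset$reference_id)
    ind <- purrr::map_dfr(others, function(id) {
      dplyr::mutate(indel_blocks(hset$msa, hset$reference_id, id), id = id,
                    .before = 1)
    })
    emit(ind, "indels")
    motifs <- purrr::map_dfr(c("shs", "phs"), function(p) {
      dplyr::mutate(motif_scan(ref_seq, p), pattern = p, .before = 1)
    })
    emit(motifs, "motifs")
    list(indels = ind, motifs = motifs)
  })

  ## 4. ensemble summaries (median/MAD of Rg and RMSD)
  summaries <- run_stage("ensemble-summary", {
    s <- dplyr::bind_rows(
      ensemble_summary(hset, "rg", offset_ns = cfg$offset_ns),
      ensemble_summary(hset, "rmsd_vs_reference", offset_ns = cfg$offset_ns)
    )
    emit(s, "ensemble-summary")
    s
  })

  has_ens <- !vapply(recs$ensemble, is.null, logical(1))
  structural <- NULL
  if (sum(has_ens) >= 2L) {
    ## 5. reference-homolog DCCM + PCA
    ref_dyn <- run_stage("reference-dynamics", {
      ens <- recs$ensemble[[match(hset$reference_id, recs$id)]]
      if (is.null(ens)) ens <- recs$ensemble[has_ens][[1]]
      eq <- apply_equilibration_offset(ens, cfg$offset_ns)
      sup <- superpose_ensemble(eq, reference = "mean")
      dc <- dccm(sup)
      emit(tidy(dc), "dccm")
      pc <- trajectory_pca(sup)
      emit(tidy(pc), "pca-single")
      list(dccm = dc, pca = pc)
    })

    ## 6. sampled set, core finding, joint PCA, TM tables
    structural <- run_stage("structural-comparison", {
      sampled <- hset
      sampled$records$ensemble <- lapply(sampled$records$ensemble, function(e) {
        if (is.null(e)) NULL else sample_frames(
          e, cfg$sample_start_ns, cfg$sample_stop_ns, cfg$sample_step_ns
        )
      })
      core <- core_find(sampled, stop = cfg$core_stop,
                        target_count = cfg$core_target_count)
      emit(core$trace, "core-trace")
      jp <- joint_pca(sampled, core$core_positions)
      emit(tidy(jp), "pca-joint")
      tm_within <- pairwise_matrix(sampled, "within_homolog", cfg$normalize)
      tm_between <- pairwise_matrix(sampled, "between_homolog", cfg$normalize)
      emit(dplyr::bind_rows(tm_within, tm_between), "tmscore")
      ranks <- outlier_rank(jp)
      removal <- progressive_removal(tm_between, cfg$outlier_k)
      emit(dplyr::bind_rows(
        dplyr::mutate(ranks, table = "outlier_rank"),
        dplyr::mutate(removal, table = "progressive_removal")
      ) |> dplyr::select("table", dplyr::everything()), "outliers")
      list(core = core, joint_pca = jp, tm_within = tm_within,
           tm_between = tm_between, ranks = ranks, removal = removal,
           dynamics = ref_dyn)
    })
  } else {
    warn("fewer than two homologs with ensembles; structural stages skipped.")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("confdiv")),
    config = unclass(cfg),
    config_hash = cfg_hash,
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, out_file("manifest", "json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    homolog_set = hset, classified = classified, conservation = conservation,
    indels = indels, summaries = summaries, structural = structural,
    manifest = manifest
  ))
}
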