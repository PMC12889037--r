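# --- geometric primitives -----------------------------------------------

#' Ideal alpha-helix C-alpha trace
#'
#' Places n points on a helix with the given rise per residue, twist per
#' residue and radius (defaults approximate an ideal alpha helix and give a
#' consecutive C-alpha spacing of ~3.8 Angstrom). The helix axis is z, the
#' first atom sits at `(radius, 0, 0)`.
#'
#' @param n Number of residues (>= 1).
#' @param rise Rise per residue (Angstrom, default 1.5).
#' @param twist Twist per residue (degrees, default 100).
#' @param radius Helix radius (Angstrom, default 2.3).
#' @return An n x 3 coordinate matrix.
#' @export
make_helix <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  if (n < 1L) abort("`n` must be >= 1.")
  i <- seq_len(n) - 1L
  theta <- i * twist * pi / 180
  cbind(radius * cos(theta), radius * sin(theta), i * rise)
}

# rotation matrix (for row vectors: x %*% rot) turning the z axis onto `dir`
rotation_to_direction <- function(dir) {
  dir <- dir / sqrt(sum(dir^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * dir[3] - z[3] * dir[2],
         z[3] * dir[1] - z[1] * dir[3],
         z[1] * dir[2] - z[2] * dir[1])
  c_ <- sum(z * dir)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))    # antiparallel: flip about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, byrow = TRUE)
  rot <- diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  t(rot)
}

# axis-angle rotation matrix for row vectors
rotation_about_axis <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle_rad); s <- sin(angle_rad)
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, byrow = TRUE)
  t(diag(3) * c_ + s * k + (1 - c_) * (a %o% a))
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# lay consecutive helical segments along the given directions; each segment's
# first atom is placed 3.8 A from the previous atom along its direction, so
# the chain stays connected (~3.8 A steps) everywhere
build_segments <- function(seg_lengths, directions) {
  coords <- NULL
  for (k in seq_along(seg_lengths)) {
    h <- make_helix(seg_lengths[k]) %*% rotation_to_direction(directions[[k]])
    anchor <- if (is.null(coords)) {
      c(0, 0, 0)
    } else {
      coords[nrow(coords), ] + 3.8 * directions[[k]] / sqrt(sum(directions[[k]]^2))
    }
    h <- sweep(h, 2, h[1, ] - anchor)
    coords <- rbind(coords, h)
  }
  coords
}

# partition n residues into m roughly equal helical segments
split_lengths <- function(n, m) {
  base <- rep(n %/% m, m)
  extra <- n %% m
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base[base > 0]
}

# alternating up/down bundle directions with seeded jitter -> compact domain
bundle_directions <- function(m, jitter = 0.35) {
  base <- random_unit_vector()
  lapply(seq_len(m), function(k) {
    d <- base * (-1)^(k - 1) + jitter * rnorm(3)
    d / sqrt(sum(d^2))
  })
}

# a fold is assembled from named blocks; each block is a list of helical
# segment lengths plus one direction per segment, so individual blocks (e.g.
# the linker) can be swapped while the others keep their exact geometry
new_block <- function(name, role, n, m, jitter) {
  lens <- split_lengths(n, m)
  list(name = name, role = role, lens = lens,
       dirs = bundle_directions(length(lens), jitter))
}

fold_from_blocks <- function(blocks) {
  coords <- build_segments(
    unlist(lapply(blocks, `[[`, "lens")),
    do.call(c, lapply(blocks, `[[`, "dirs"))
  )
  pos <- 1L
  ann <- lapply(blocks, function(b) {
    n <- sum(b$lens)
    row <- tibble(name = b$name, start = pos, end = pos + n - 1L, role = b$role)
    pos <<- pos + n
    row
  })
  list(coords = coords, annotations = dplyr::bind_rows(ann))
}

#' Synthetic two-domain fold with linker and terminal extensions
#'
#' Builds a connected C-alpha chain with two multi-helix (four-bundle)
#' domains joined by a multi-helix linker, plus optional terminal
#' extensions; consecutive C-alpha distances stay within [3.6, 4.0]
#' Angstrom by construction. The amino-acid sequence is drawn uniformly at
#' random.
#'
#' @param n_domain_a,n_domain_b Domain sizes (>= 4 residues each).
#' @param n_linker Linker size (>= 4).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param n_term,c_term Terminal extension lengths (default 0).
#' @param n_linker_helices Number of helical segments in the linker
#'   (default 2).
#' @return A list of class `synthetic_fold` with `structure`
#'   ([structure3d()]), `annotations` (tibble `name`, `start`, `end`,
#'   `role`, tiling the chain) and the internal block layout.
#' @export
make_two_domain_fold <- function(n_domain_a, n_linker, n_domain_b, seed,
                                 n_term = 0L, c_term = 0L,
                                 n_linker_helices = 2L) {
  if (min(n_domain_a, n_linker, n_domain_b) < 4L) {
    abort("domains and linker must have at least 4 residues.")
  }
  with_seed(seed, {
    blocks <- list()
    if (n_term > 0L) {
      blocks <- c(blocks, list(new_block("N-ext", "extension", n_term,
                                         max(1L, n_term %/% 10L), 0.6)))
    }
    blocks <- c(blocks, list(new_block("domain-A", "HTH", n_domain_a, 4L, 0.35)))
    blocks <- c(blocks, list(new_block("linker", "IDL", n_linker,
                                       n_linker_helices, 0.6)))
    blocks <- c(blocks, list(new_block("domain-B", "HTH", n_domain_b, 4L, 0.35)))
    if (c_term > 0L) {
      blocks <- c(blocks, list(new_block("C-ext", "extension", c_term,
                                         max(1L, c_term %/% 25L), 0.6)))
    }
    built <- fold_from_blocks(blocks)
    n <- nrow(built$coords)
    sequence <- sample(AA_ALPHABET, n, replace = TRUE)
    structure(
      list(
        structure = structure3d("fold", seq_len(n), sequence, built$coords),
        annotations = built$annotations,
        blocks = blocks
      ),
      class = "synthetic_fold"
    )
  })
}

#' Synthetic hinge-motion ensemble
#'
#' Generates frames in which all residues beyond the hinge are rigidly
#' rotated about an axis through the hinge C-alpha by
#' `angle(t) = amplitude_deg * sin(2 * pi * t / period_ns)`, with optional
#' per-atom Gaussian jitter. The rotation axis is a fixed unit vector
#' perpendicular to the hinge-to-mobile-centroid direction, so the motion is
#' a clean open/close swing. True per-frame hinge angles are recorded in the
#' `hinge_truth` attribute.
#'
#' @param struct A [structure3d()].
#' @param hinge_position Residue number of the hinge (inside the linker);
#'   residues with larger numbers move.
#' @param amplitude_deg Hinge amplitude in degrees.
#' @param times_ns Frame times (default 0 to 100 ns every 5 ns).
#' @param jitter_sigma Per-coordinate Gaussian noise sd in Angstrom
#'   (default 0.3).
#' @param mobile_jitter_scale Noise multiplier for the mobile block (default
#'   3): residues swung about a hinge fluctuate more than the anchored
#'   domain, as in the elevated RMSF of lever-arm motion, so only the
#'   stationary side of the hinge is a genuine low-variability core.
#' @param period_ns Hinge oscillation period (default 400 ns: a slow opening
#'   over a 100 ns trajectory, so every frame has a distinct true angle).
#' @param seed Integer RNG seed.
#' @return An [ensemble()] with attribute `hinge_truth`: tibble `frame`,
#'   `time_ns`, `angle_deg`.
#' @export
make_hinge_ensemble <- function(struct, hinge_position, amplitude_deg,
                                times_ns = seq(0, 100, by = 5),
                                jitter_sigma = 0.3, mobile_jitter_scale = 3,
                                period_ns = 400, seed = 1L) {
  stopifnot(inherits(struct, "structure3d"))
  hi <- match(hinge_position, struct$residue_numbers)
  if (is.na(hi)) abort("`hinge_position` not found in the structure.")
  mobile <- struct$residue_numbers > hinge_position
  if (!any(mobile) || all(mobile)) abort("hinge must split the chain in two.")
  pivot <- struct$coords[hi, ]
  v <- colMeans(struct$coords[mobile, , drop = FALSE]) - pivot
  e <- diag(3)[, which.min(abs(v))]
  axis <- c(v[2] * e[3] - v[3] * e[2], v[3] * e[1] - v[1] * e[3], v[1] * e[2] - v[2] * e[1])
  axis <- axis / sqrt(sum(axis^2))

  with_seed(seed, {
    angles <- amplitude_deg * sin(2 * pi * times_ns / period_ns)
    frames <- lapply(seq_along(times_ns), function(f) {
      xy <- struct$coords
      rot <- rotation_about_axis(axis, angles[f] * pi / 180)
      xy[mobile, ] <- sweep(sweep(xy[mobile, , drop = FALSE], 2, pivot) %*% rot, 2, -pivot)
      if (jitter_sigma > 0) {
        sds <- jitter_sigma * ifelse(mobile, mobile_jitter_scale, 1)
        xy <- xy + matrix(rnorm(length(xy), sd = rep(sds, 3)), nrow(xy), 3)
      }
      structure3d(struct$id, struct$residue_numbers, struct$residue_codes, xy)
    })
    ens <- ensemble(struct$id, frames, times_ns)
    attr(ens, "hinge_truth") <- tibble(
      frame = seq_along(times_ns), time_ns = times_ns, angle_deg = angles
    )
    ens
  })
}

# --- sequence mutation machinery ----------------------------------------

blosum_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum_env$m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  blosum_env$m
}

# substitution-matrix-similar replacements: prefer residues scoring >= 0
# against the original (keeps folds plausible), fall back to any other residue
similar_replacement <- function(res, exclude = character(0)) {
  b <- blosum62()
  cand <- setdiff(AA_ALPHABET[b[res, ] >= 0], c(res, exclude))
  if (length(cand) == 0L) cand <- setdiff(AA_ALPHABET, c(res, exclude))
  cand[sample.int(length(cand), 1L)]
}

mutate_positions <- function(chars, positions, replacements = NULL) {
  for (k in seq_along(positions)) {
    p <- positions[k]
    chars[p] <- if (is.null(replacements)) similar_replacement(chars[p]) else replacements[k]
  }
  chars
}

# --- family generator ----------------------------------------------------

#' Seeded synthetic homolog family with known ground truth
#'
#' Generates a reference homolog plus type-I (high identity, same fold) and
#' distant (low identity, linker deletion + post-domain insertion) homologs,
#' each with a hinge-motion conformational ensemble, a ground-truth MSA
#' built by construction, and a `truth` record (planted indels,
#' target/achieved identities, hinge angles, stable positions). The two
#' helix-turn-helix domains and the terminal extensions keep the reference
#' geometry in every homolog (conserved folds); distant homologs share a
#' rebuilt two-helix linker (the reference linker carries four helices) and
#' an inserted loop immediately downstream of domain B.
#'
#' The default architecture mirrors a two-HTH regulator: 20-residue N
#' extension, 55-residue domain A (positions 21-75), 62-residue linker
#' (76-137), 55-residue domain B (138-192), 67-residue C extension (total
#' 259). Distant homologs delete a band-sized block at the linker end
#' (adjacent to domain B) and insert a short block immediately after domain
#' B. Achieved identities are verified with [pairwise_identity()] to within
#' 0.03 of their targets.
#'
#' @param reference Optional `synthetic_fold` from [make_two_domain_fold()];
#'   default builds the architecture above.
#' @param n_type1,n_distant Number of non-reference type-I and distant
#'   homologs (defaults 5 and 2).
#' @param identity_band_type1,identity_band_distant Target identity bands to
#'   the reference (defaults (0.72, 1.0) and (0.26, 0.50)).
#' @param linker_deletion,post_domain_insertion Planted indel length ranges
#'   (defaults (32, 36) and (7, 9)).
#' @param times_ns Frame times per ensemble (default 0-100 ns every 5 ns, so
#'   a 20 ns offset and a 25-95/10 sampling grid both apply cleanly).
#' @param amplitude_range Per-homolog hinge amplitude range in degrees
#'   (default (15, 30)).
#' @param jitter_sigma Per-atom coordinate noise (Angstrom, default 0.3).
#' @param fold_noise Per-homolog static fold perturbation (Angstrom,
#'   default 0.25).
#' @param hinge_position Hinge residue in reference numbering (default 100,
#'   inside the linker, upstream of the planted deletions).
#' @param seed Integer RNG seed (mandatory).
#' @return A list of class `synthetic_family` with elements `homolog_set`
#'   ([homolog_set()]) and `truth`.
#' @export
make_family <- function(reference = NULL,
                        n_type1 = 5L, n_distant = 2L,
                        identity_band_type1 = c(0.72, 1.0),
                        identity_band_distant = c(0.26, 0.50),
                        linker_deletion = c(32L, 36L),
                        post_domain_insertion = c(7L, 9L),
                        times_ns = seq(0, 100, by = 5),
                        amplitude_range = c(15, 30),
                        jitter_sigma = 0.3,
                        fold_noise = 0.25,
                        hinge_position = 100L,
                        seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  stopifnot(
    identity_band_type1[1] > 0, identity_band_type1[2] <= 1,
    identity_band_distant[1] > 0, identity_band_distant[2] <= 1
  )
  with_seed(seed, {
    fold <- reference %||% make_two_domain_fold(
      n_domain_a = 55L, n_linker = 62L, n_domain_b = 55L,
      seed = sample.int(.Machine$integer.max, 1L),
      n_term = 20L, c_term = 67L,
      n_linker_helices = 4L        # type-I linkers carry four helices
    )
    stopifnot(inherits(fold, "synthetic_fold"))
    ref_struct <- fold$structure
    ann <- fold$annotations
    ref_chars <- ref_struct$residue_codes
    l_ref <- length(ref_chars)
    dom_b <- ann[ann$name == "domain-B", ]
    linker <- ann[ann$name == "linker", ]
    if (nrow(dom_b) != 1L || nrow(linker) != 1L) abort("fold must have domain-B and linker.")
    if (hinge_position <= linker$start || hinge_position >= linker$end) {
      abort("`hinge_position` must lie strictly inside the linker.")
    }

    ids <- c(
      "ref",
      if (n_type1 > 0) sprintf("type1_%02d", seq_len(n_type1)),
      if (n_distant > 0) sprintf("distant_%02d", seq_len(n_distant))
    )

    # --- type-I sequences: gapless mutation to a target identity ---
    type1_seqs <- list()
    identity_rows <- list()
    for (j in seq_len(n_type1)) {
      target <- runif(
        1,
        min(identity_band_type1[1] + 0.005, identity_band_type1[2]),
        identity_band_type1[2]
      )
      n_mut <- round((1 - target) * l_ref)
      perm <- sample.int(l_ref)
      chars <- mutate_positions(ref_chars, perm[seq_len(n_mut)])
      achieved <- pairwise_identity(
        paste(chars, collapse = ""), paste(ref_chars, collapse = "")
      )
      if (abs(achieved - target) > 0.03 || achieved < identity_band_type1[1]) {
        abort(sprintf("type-I identity calibration failed (target %.3f, got %.3f).", target, achieved))
      }
      type1_seqs[[j]] <- chars
      identity_rows[[length(identity_rows) + 1L]] <- tibble(
        id = sprintf("type1_%02d", j), target = target, achieved = achieved
      )
    }

    # --- distant homologs: indels + heavy mutation, calibrated ---
    linker_end <- linker$end
    del_lens <- if (n_distant > 0) {
      sample(seq(linker_deletion[1], linker_deletion[2]), n_distant, replace = TRUE)
    } else integer(0)
    ins_lens <- if (n_distant > 0) {
      sample(seq(post_domain_insertion[1], post_domain_insertion[2]), n_distant, replace = TRUE)
    } else integer(0)
    max_ins <- if (n_distant > 0) max(ins_lens) else 0L

    distant <- list()   # per homolog: list(kept, chars_at_kept, ins_chars, del_len, ins_len)
    perm1 <- NULL; n1 <- NULL; repl1 <- NULL
    for (j in seq_len(n_distant)) {
      del_len <- del_lens[j]
      ins_len <- ins_lens[j]
      kept <- setdiff(seq_len(l_ref), (linker_end - del_len + 1L):linker_end)
      ins_chars <- sample(AA_ALPHABET, ins_len, replace = TRUE)

      if (j == 1L) {
        target <- runif(1, identity_band_distant[1] + 0.04, identity_band_distant[2] - 0.04)
        perm1 <- sample.int(l_ref)
        n_mut <- round((1 - target) * l_ref)
        chars <- NULL; achieved <- NA_real_
        for (it in seq_len(40L)) {
          mut_pos <- perm1[seq_len(min(n_mut, l_ref))]
          repl1 <- vapply(mut_pos, function(p) similar_replacement(ref_chars[p]), character(1))
          chars <- mutate_positions(ref_chars, mut_pos, repl1)
          seq_j <- paste(c(chars[kept[kept <= dom_b$end]], ins_chars,
                           chars[kept[kept > dom_b$end]]), collapse = "")
          achieved <- pairwise_identity(seq_j, paste(ref_chars, collapse = ""))
          if (abs(achieved - target) <= 0.025 &&
              achieved > identity_band_distant[1] &&
              achieved < identity_band_distant[2]) break
          n_mut <- n_mut + round((achieved - target) * l_ref)
          n_mut <- max(1L, min(l_ref, n_mut))
        }
        if (abs(achieved - target) > 0.03) {
          abort(sprintf("distant identity calibration failed (target %.3f, got %.3f).", target, achieved))
        }
        n1 <- n_mut
        distant[[j]] <- list(
          kept = kept, chars = chars, ins_chars = ins_chars,
          del_len = del_len, ins_len = ins_len,
          target = target, achieved = achieved
        )
      } else {
        # derive from the first distant homolog: same mutated positions, a
        # fraction keeps the first homolog's replacements -> moderate mutual
        # identity, reference identity stays in band
        target_cross <- runif(1, 0.44, 0.50)
        mut_pos <- perm1[seq_len(n1)]
        share <- 0.2
        chars <- NULL; ach_ref <- NA_real_; ach_cross <- NA_real_
        d1 <- distant[[1]]
        seq_1 <- paste(c(d1$chars[d1$kept[d1$kept <= dom_b$end]], d1$ins_chars,
                         d1$chars[d1$kept[d1$kept > dom_b$end]]), collapse = "")
        for (it in seq_len(40L)) {
          keep_mask <- runif(n1) < share
          repl <- vapply(seq_len(n1), function(k) {
            if (keep_mask[k]) {
              repl1[k]
            } else {
              similar_replacement(ref_chars[mut_pos[k]], exclude = repl1[k])
            }
          }, character(1))
          chars <- mutate_positions(ref_chars, mut_pos, repl)
          seq_j <- paste(c(chars[kept[kept <= dom_b$end]], ins_chars,
                           chars[kept[kept > dom_b$end]]), collapse = "")
          ach_ref <- pairwise_identity(seq_j, paste(ref_chars, collapse = ""))
          ach_cross <- pairwise_identity(seq_j, seq_1)
          ok_ref <- ach_ref > identity_band_distant[1] && ach_ref < identity_band_distant[2]
          if (abs(ach_cross - target_cross) <= 0.03 && ok_ref) break
          share <- min(0.95, max(0.02, share + (target_cross - ach_cross) * 1.2))
        }
        distant[[j]] <- list(
          kept = kept, chars = chars, ins_chars = ins_chars,
          del_len = del_len, ins_len = ins_len,
          target = target_cross, achieved = ach_ref, cross = ach_cross
        )
      }
      identity_rows[[length(identity_rows) + 1L]] <- tibble(
        id = sprintf("distant_%02d", j),
        target = distant[[j]]$target, achieved = distant[[j]]$achieved
      )
    }

    # --- ground-truth MSA: reference columns + insertion block ----------
    ins_anchor <- dom_b$end
    build_row <- function(chars_at_ref, kept, ins_chars, ins_len) {
      row <- rep("-", l_ref + max_ins)
      before <- seq_len(ins_anchor)
      after <- if (ins_anchor < l_ref) (ins_anchor + 1L):l_ref else integer(0)
      row[before] <- ifelse(before %in% kept, chars_at_ref[before], "-")
      if (max_ins > 0L && ins_len > 0L) {
        row[ins_anchor + seq_len(ins_len)] <- ins_chars
      }
      row[after + max_ins] <- ifelse(after %in% kept, chars_at_ref[after], "-")
      paste(row, collapse = "")
    }
    msa_rows <- c(
      build_row(ref_chars, seq_len(l_ref), character(0), 0L),
      vapply(seq_len(n_type1), function(j) {
        build_row(type1_seqs[[j]], seq_len(l_ref), character(0), 0L)
      }, character(1)),
      vapply(seq_len(n_distant), function(j) {
        d <- distant[[j]]
        build_row(d$chars, d$kept, d$ins_chars, d$ins_len)
      }, character(1))
    )
    family_msa <- msa(ids, msa_rows)

    # --- structures and hinge ensembles ---------------------------------
    # domains and extensions keep the reference geometry in every homolog
    # (the conserved tetra-helical folds); only the contracted linker and
    # the inserted loop are rebuilt, with directions shared by all distant
    # homologs (their common divergent fold)
    distant_fold_seed <- sample.int(.Machine$integer.max %/% 2L, 1L)
    distant_geometry <- with_seed(distant_fold_seed, list(
      linker_dirs = bundle_directions(2L, 0.6),
      insertion_dir = random_unit_vector()
    ))
    # per-homolog static fold heterogeneity, larger on the mobile side of the
    # hinge: across homologs the regions around the C-terminal domain (the
    # contracting linker, the inserted loop, the packing of the extension)
    # diverge structurally, so only the N-side block is conserved family-wide
    perturb <- function(coords) {
      sds <- fold_noise * ifelse(seq_len(nrow(coords)) > hinge_position, 3, 1)
      coords + matrix(rnorm(length(coords), sd = rep(sds, 3)), nrow(coords), 3)
    }
    build_homolog <- function(id, chars) {
      xy <- perturb(ref_struct$coords)
      structure3d(id, seq_along(chars), chars, xy)
    }
    build_distant_homolog <- function(id, d) {
      blocks <- fold$blocks
      names(blocks) <- vapply(blocks, `[[`, character(1), "name")
      n_linker_d <- linker$end - linker$start + 1L - d$del_len
      blocks[["linker"]] <- list(
        name = "linker", role = "IDL",
        lens = split_lengths(n_linker_d, 2L),
        dirs = distant_geometry$linker_dirs
      )
      insertion <- list(
        name = "insertion", role = "extension",
        lens = d$ins_len, dirs = list(distant_geometry$insertion_dir)
      )
      i_b <- which(names(blocks) == "domain-B")
      blocks <- append(unname(blocks), list(insertion), after = i_b)
      built <- fold_from_blocks(blocks)
      chars <- c(d$chars[d$kept[d$kept <= ins_anchor]], d$ins_chars,
                 d$chars[d$kept[d$kept > ins_anchor]])
      n <- length(chars)
      if (nrow(built$coords) != n) {
        abort("internal error: distant fold length mismatch.")
      }
      structure3d(id, seq_len(n), chars, perturb(built$coords))
    }

    amplitudes <- runif(length(ids), amplitude_range[1], amplitude_range[2])
    hinge_rows <- list()
    records <- list()
    for (i in seq_along(ids)) {
      id <- ids[i]
      st <- if (id == "ref") {
        structure3d(id, seq_len(l_ref), ref_chars, ref_struct$coords)
      } else if (startsWith(id, "type1")) {
        build_homolog(id, type1_seqs[[as.integer(sub("type1_", "", id))]])
      } else {
        build_distant_homolog(id, distant[[as.integer(sub("distant_", "", id))]])
      }
      ens <- make_hinge_ensemble(
        st, hinge_position = hinge_position, amplitude_deg = amplitudes[i],
        times_ns = times_ns, jitter_sigma = jitter_sigma,
        seed = sample.int(.Machine$integer.max, 1L)
      )
      ht <- attr(ens, "hinge_truth")
      ht$homolog_id <- id
      hinge_rows[[i]] <- ht
      records[[i]] <- tibble(
        id = id,
        sequence = paste(st$residue_codes, collapse = ""),
        group = if (id == "ref") "reference" else if (startsWith(id, "type1")) "type-I" else "distant",
        ensemble = list(ens)
      )
    }
    records <- dplyr::bind_rows(records)

    planted <- if (n_distant > 0) {
      dplyr::bind_rows(lapply(seq_len(n_distant), function(j) {
        d <- distant[[j]]
        tibble(
          id = sprintf("distant_%02d", j),
          kind = c("deletion", "insertion"),
          reference_position = c(linker_end - d$del_len + 1L, ins_anchor),
          length = c(d$del_len, d$ins_len)
        )
      }))
    } else {
      tibble(id = character(), kind = character(),
             reference_position = integer(), length = integer())
    }

    hset <- homolog_set(records, msa = family_msa, reference_id = "ref")
    truth <- list(
      seed = seed,
      annotations = ann,
      hinge_position = hinge_position,
      stable_positions = seq_len(hinge_position),
      planted_indels = planted,
      identities = dplyr::bind_rows(identity_rows),
      amplitudes = tibble(id = ids, amplitude_deg = amplitudes),
      hinge_angles = dplyr::bind_rows(hinge_rows)
    )
    structure(list(homolog_set = hset, truth = truth), class = "synthetic_family")
  })
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("<synthetic_family>\n")
  print(x$homolog_set)
  invisible(x)
}

#' Write a synthetic family to disk
#'
#' Emits `sequences.fasta`, `alignment.fasta`, one multi-model PDB per
#' homolog ensemble, a `times.yaml` sidecar with the frame times, and
#' `truth.json` with the ground-truth record. Output bytes are a
#' deterministic function of the family object.
#'
#' @param fam A `synthetic_family` from [make_family()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_family <- function(fam, dir) {
  stopifnot(inherits(fam, "synthetic_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hs <- fam$homolog_set
  write_fasta(hs$records[, c("id", "sequence")], file.path(dir, "sequences.fasta"))
  write_msa(hs$msa, file.path(dir, "alignment.fasta"))
  for (i in seq_len(nrow(hs$records))) {
    ens <- hs$records$ensemble[[i]]
    if (!is.null(ens)) {
      write_pdb(ens, file.path(dir, paste0(hs$records$id[i], ".pdb")))
    }
  }
  yaml::write_yaml(
    list(times_ns = as.numeric(hs$records$ensemble[[1]]$times_ns),
         reference_id = hs$reference_id,
         groups = setNames(as.list(hs$records$group), hs$records$id)),
    file.path(dir, "times.yaml")
  )
  truth <- fam$truth
  jsonlite::write_json(
    list(
      seed = truth$seed,
      hinge_position = truth$hinge_position,
      stable_positions = truth$stable_positions,
      annotations = truth$annotations,
      planted_indels = truth$planted_indels,
      identities = truth$identities,
      amplitudes = truth$amplitudes
    ),
    file.path(dir, "truth.json"),
    dataframe = "rows", digits = NA, pretty = TRUE
  )
  invisible(dir)
}
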