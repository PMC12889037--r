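test_that("ideal helices have alpha-helical C-alpha spacing", {
  h <- make_helix(20)
  d <- sqrt(rowSums(diff(h)^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  expect_equal(make_helix(1), cbind(2.3, 0, 0))
  # rigidity: internal distances survive arbitrary rigid moves
  moved <- rigid_copy(h, 72, c(1, 0, 2), c(5, 5, -5))
  expect_equal(as.matrix(dist(moved)), as.matrix(dist(h)), tolerance = 1e-9)
})

test_that("two-domain folds are connected chains with tiling annotations", {
  f <- make_two_domain_fold(55, 62, 55, seed = 3, n_term = 20, c_term = 67)
  st <- f$structure
  expect_equal(nrow(st$coords), 259L)
  ann <- f$annotations
  # annotations tile 1..N without overlap
  ann <- ann[order(ann$start), ]
  expect_equal(ann$start[1], 1L)
  expect_equal(ann$end[nrow(ann)], 259L)
  expect_true(all(ann$start[-1] == ann$end[-nrow(ann)] + 1))

  # connectivity bound holds across many seeds
  for (s in 1:100) {
    g <- make_two_domain_fold(12, 8, 12, seed = s)
    d <- sqrt(rowSums(diff(g$structure$coords)^2))
    expect_true(all(d >= 3.6 & d <= 4.0))
  }

  # distinct seeds give distinct coordinates; same seed reproduces exactly
  f2 <- make_two_domain_fold(55, 62, 55, seed = 4, n_term = 20, c_term = 67)
  expect_false(isTRUE(all.equal(f$structure$coords, f2$structure$coords)))
  f3 <- make_two_domain_fold(55, 62, 55, seed = 3, n_term = 20, c_term = 67)
  expect_identical(f$structure$coords, f3$structure$coords)
})

test_that("hinge ensembles rotate only the mobile block and record true angles", {
  fold <- make_two_domain_fold(16, 10, 16, seed = 6)
  st <- fold$structure

  # amplitude 0, jitter 0: all frames identical
  flat <- make_hinge_ensemble(st, 21, 0, jitter_sigma = 0, seed = 1)
  for (f in flat$frames) expect_equal(f$coords, st$coords, tolerance = 1e-12)

  # jitter 0: the stable block never moves
  ens <- make_hinge_ensemble(st, 21, 30, jitter_sigma = 0, seed = 1)
  stable <- st$residue_numbers <= 21
  for (f in ens$frames) {
    expect_equal(f$coords[stable, ], st$coords[stable, ], tolerance = 1e-12)
  }

  # rotation-extraction oracle recovers the planted angles within 1 degree
  truth <- attr(ens, "hinge_truth")
  mobile <- st$residue_numbers > 21
  rec <- vapply(seq_along(ens$frames), function(i) {
    oracle_rotation_angle(st$coords[mobile, ], ens$frames[[i]]$coords[mobile, ])
  }, numeric(1))
  expect_true(all(abs(rec - abs(truth$angle_deg)) < 1))
})

test_that("family generation is deterministic down to the written bytes", {
  fam1 <- make_family(n_type1 = 1, n_distant = 1, seed = 99)
  fam2 <- make_family(n_type1 = 1, n_distant = 1, seed = 99)
  expect_identical(fam1$homolog_set$records$sequence,
                   fam2$homolog_set$records$sequence)
  expect_identical(fam1$homolog_set$records$ensemble[[2]]$frames[[3]]$coords,
                   fam2$homolog_set$records$ensemble[[2]]$frames[[3]]$coords)

  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_family(fam1, d1)
  write_family(fam2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the data
  fam3 <- make_family(n_type1 = 1, n_distant = 1, seed = 100)
  expect_false(identical(fam1$homolog_set$records$sequence,
                         fam3$homolog_set$records$sequence))
})

test_that("degenerate bands reproduce the reference exactly", {
  fam <- make_family(n_type1 = 2, n_distant = 0,
                     identity_band_type1 = c(1, 1), seed = 5)
  seqs <- fam$homolog_set$records$sequence
  expect_equal(seqs[2], seqs[1])
  expect_equal(seqs[3], seqs[1])
})

test_that("achieved identities stay within 0.03 of their targets across seeds", {
  for (s in c(101, 202, 303)) {
    fam <- make_family(n_type1 = 2, n_distant = 2, seed = s)
    idt <- fam$truth$identities
    type1 <- idt[grepl("^type1", idt$id), ]
    expect_true(all(abs(type1$achieved - type1$target) <= 0.03))
    d1 <- idt[idt$id == "distant_01", ]
    expect_true(abs(d1$achieved - d1$target) <= 0.03)
    # all distant homologs end up inside the distant band
    dd <- idt[grepl("^distant", idt$id), ]
    expect_true(all(dd$achieved > 0.26 & dd$achieved < 0.50))
  }
})

test_that("the default family reproduces its planted ground truth end to end", {
  fam <- get_family()
  hs <- fam$homolog_set

  # (a) classification recovers the planted labels
  cl <- get_family_classification()
  truth_groups <- ifelse(hs$records$group == "reference", "type-I",
                         hs$records$group)
  expect_equal(cl$group, truth_groups)

  # (b) planted indel blocks are recovered exactly
  for (id in hs$records$id[hs$records$group == "distant"]) {
    got <- indel_blocks(hs$msa, "ref", id)
    want <- fam$truth$planted_indels[fam$truth$planted_indels$id == id, ]
    expect_equal(got[order(got$kind), c("kind", "reference_position", "length")],
                 want[order(want$kind), c("kind", "reference_position", "length")],
                 ignore_attr = TRUE)
  }
  # type-I homologs carry no indels
  expect_equal(nrow(indel_blocks(hs$msa, "ref", "type1_01")), 0L)

  # (c) anti-correlated domains in the reference homolog's DCCM
  dyn <- get_ref_dynamics()
  dom <- fam$truth$annotations
  dom_a <- seq(dom$start[dom$name == "domain-A"], dom$end[dom$name == "domain-A"])
  dom_b <- seq(dom$start[dom$name == "domain-B"], dom$end[dom$name == "domain-B"])
  expect_lt(inter_set_correlation(dyn$dccm, dom_a, dom_b), 0)

  # (d) conformational spread < fold divergence: within-homolog medians beat
  # between-group medians
  med_within <- median(get_tm_within()$score)
  med_between <- median(
    get_tm_between()$score[get_tm_between()$comparison_class == "between_group"]
  )
  expect_gt(med_within, med_between)
})
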