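test_that("pairwise identity follows the alignment-column definition", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  expect_equal(pairwise_identity("ACDE", "ACE"), 0.75)     # one gap column
  expect_equal(pairwise_identity("ACDE", "ACE"),
               pairwise_identity("ACE", "ACDE"))           # symmetry
  expect_error(pairwise_identity("ACXE", "ACDE"), "non-standard")
  expect_error(pairwise_identity("", "ACDE"), "non-empty")
})

test_that("pairwise identity agrees with exhaustive alignment enumeration", {
  set.seed(17)
  pool <- c("A", "C", "D", "E", "G", "K", "L", "S")
  for (rep in 1:4) {
    a <- paste(sample(pool, 5, replace = TRUE), collapse = "")
    b <- paste(sample(pool, sample(4:6, 1), replace = TRUE), collapse = "")
    idents <- oracle_identity_set(a, b)
    ours <- pairwise_identity(a, b)
    expect_true(any(abs(idents - ours) < 1e-9),
                info = sprintf("%s vs %s: ours %.4f, oracle {%s}", a, b, ours,
                               paste(round(idents, 4), collapse = ", ")))
  }
})

test_that("homologs classify into type-I / distant / unassigned by threshold", {
  df <- tibble::tibble(
    id = c("close", "zbi_like", "orphan", "edge"),
    identity_to_reference = c(0.99, 0.33, 0.46, 0.72),
    identity_to_distant = c(NA, 0.48, 0.34, NA)
  )
  out <- classify_homologs(df)
  expect_equal(out$group, c("type-I", "distant", "unassigned", "type-I"))
  expect_error(classify_homologs(tibble::tibble(
    identity_to_reference = 1.2, identity_to_distant = NA
  )), "\\[0, 1\\]")
})

test_that("conservation scores span the entropy range and ignore row order", {
  m <- msa(c("a", "b", "c", "d"),
           c("AAWA", "AVWA", "AAWC", "AVWG"))
  prof <- conservation_profile(m)
  expect_equal(prof$score[1], 1)                      # identical column
  expect_equal(prof$score[2], 1 - 1 / log2(20), tolerance = 1e-9) # half A half V
  expect_equal(prof$score[3], 1)
  # uniform over all 20 residues scores 0
  m20 <- msa(sprintf("s%02d", 1:20),
             c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  expect_equal(conservation_profile(m20)$score, 0, tolerance = 1e-12)
  # reordering rows leaves the profile unchanged
  m_perm <- msa(c("d", "b", "a", "c"),
                c("AVWG", "AVWA", "AAWA", "AAWC"))
  expect_equal(conservation_profile(m_perm)$score, prof$score)
  # all-gap column flagged NA
  mg <- msa(c("a", "b"), c("A-A", "C-C"))
  pg <- conservation_profile(mg)
  expect_true(is.na(pg$score[2]) && pg$flagged[2])
})

test_that("conservation differential localises subset-specific divergence", {
  # 5 sequences; the two removed ones carry the only substitutions at column 3
  rows_all <- c(ref = "AKWDE", s2 = "AKWDE", s3 = "AKWDE",
                d1 = "AKADE", d2 = "AKVDE")
  m_all <- msa(names(rows_all), unname(rows_all))
  m_sub <- msa(names(rows_all)[1:3], unname(rows_all)[1:3])
  cd <- conservation_differential(m_all, m_sub, "ref", window = c(1, 5))
  expect_equal(nrow(cd), 5L)
  base <- conservation_profile(m_all)$score
  expect_equal(cd$delta[cd$position == 3], 1 - base[3], tolerance = 1e-12)
  expect_equal(cd$delta[cd$position != 3], rep(0, 4))

  # identical alignments give zero delta; windows clip the output
  cd0 <- conservation_differential(m_all, m_all, "ref", window = c(2, 4))
  expect_equal(cd0$delta, rep(0, 3))
  expect_equal(range(cd0$position), c(2, 4))
  expect_error(conservation_differential(m_all, m_sub, "nope"), "missing")
})

test_that("indel blocks are recovered in reference numbering and mirror", {
  # identical rows: no blocks
  m0 <- msa(c("r", "q"), c("ACDEF", "ACDEF"))
  expect_equal(nrow(indel_blocks(m0, "r", "q")), 0L)

  # 36-column deletion mapping to reference 100-135
  set.seed(2)
  ref_chars <- sample(c("A", "L", "K", "S", "T", "E"), 150, replace = TRUE)
  qry <- ref_chars
  qry[100:135] <- "-"
  m1 <- msa(c("r", "q"), c(paste(ref_chars, collapse = ""),
                           paste(qry, collapse = "")))
  b1 <- indel_blocks(m1, "r", "q")
  expect_equal(b1, tibble::tibble(kind = "deletion", reference_position = 100L,
                                  length = 36L))

  # 8-column insertion anchored after reference position 192
  ref2 <- c(sample(c("A", "L", "K"), 192, replace = TRUE), rep("-", 8),
            sample(c("A", "L", "K"), 10, replace = TRUE))
  qry2 <- ref2
  qry2[193:200] <- sample(c("G", "S"), 8, replace = TRUE)
  m2 <- msa(c("r", "q"), c(paste(ref2, collapse = ""), paste(qry2, collapse = "")))
  b2 <- indel_blocks(m2, "r", "q")
  expect_equal(b2, tibble::tibble(kind = "insertion", reference_position = 192L,
                                  length = 8L))

  # swapping reference and query mirrors kinds (positions move to the other
  # sequence's numbering)
  b2m <- indel_blocks(m2, "q", "r")
  expect_equal(b2m$kind, "deletion")
  expect_equal(b2m$length, 8L)

  # min_length filters short runs
  m3 <- msa(c("r", "q"), c("ACDEFG", "AC--FG"))
  expect_equal(nrow(indel_blocks(m3, "r", "q")), 0L)
  expect_equal(nrow(indel_blocks(m3, "r", "q", min_length = 2)), 1L)
})

test_that("motif scans reproduce the canonical HTH triplets", {
  hits <- motif_scan("AGISA", "shs")
  expect_true(any(hits$triplet == "GIS" & hits$violations == 0))
  els <- motif_scan("AELSA", "shs")
  expect_equal(els$violations[els$triplet == "ELS"], 1L)   # E is not small
  expect_false("KKK" %in% motif_scan("AKKKA", "shs")$triplet)
  qae <- motif_scan("AQAEA", "phs")
  expect_equal(qae$violations[qae$triplet == "QAE"], 1L)   # E is not small
  # region restriction and sorting
  hits2 <- motif_scan("GISAGIS", "shs", region = c(4, 7))
  expect_true(all(hits2$position >= 4))
  expect_true(!is.unsorted(hits2$violations))
})

test_that("charge profiles sum K/R as +1 and D/E as -1", {
  expect_equal(charge_profile("KKKKK", 5)$charge, 5L)
  expect_equal(charge_profile("KDKDK", 5)$charge, 1L)
  expect_equal(charge_profile("AGSTL", 5)$charge, 0L)
  expect_equal(charge_profile("HHHHH", 5)$charge, 0L)      # His neutral
  p <- charge_profile("KKDDAK", 3)
  expect_equal(p$charge, c(1L, -1L, -2L, 0L))
  expect_error(charge_profile("KK", 5), "window")
})

test_that("domain arithmetic reproduces lengths and linker gaps", {
  ann <- tibble::tibble(name = c("N-HTH", "C-HTH"),
                        start = c(21, 138), end = c(75, 192))
  da <- domain_arithmetic(ann)
  expect_equal(da$domains$length, c(55L, 55L))
  expect_equal(da$gaps$gap_length, 62L)
  adj <- domain_arithmetic(tibble::tibble(
    name = c("a", "b"), start = c(1, 11), end = c(10, 20)
  ))
  expect_equal(adj$gaps$gap_length, 0L)
  expect_error(domain_arithmetic(tibble::tibble(
    name = c("a", "b"), start = c(1, 5), end = c(10, 20)
  )), "overlap")
})
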