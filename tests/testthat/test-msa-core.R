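test_that("aligned FASTA round-trips and rejects malformed input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seqA", "LKQAVNNLAMKWR-QEYLVLNESF",
               ">seqB", "lkqsvnnlamkwreqeylvlnesf"), fa)
  msa <- read_aligned_fasta(fa, family_side = "Dpr", subgroup_id = "blue")
  expect_s3_class(msa, "AlignedSubfamily")
  expect_equal(msa$sequence_ids, c("seqA", "seqB"))
  expect_equal(ncol_msa(msa), 24)
  expect_equal(substr(msa$rows[2], 1, 4), "LKQS")  # uppercased

  out <- withr::local_tempfile(fileext = ".fasta")
  write_aligned_fasta(msa, out)
  expect_equal(read_aligned_fasta(out, "Dpr", "blue")$rows, msa$rows)

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "LKQA", ">b", "LKQ"), ragged)
  expect_error(read_aligned_fasta(ragged, "Dpr"), "record 2.*'b'")

  badchar <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "LKXA"), badchar)
  expect_error(read_aligned_fasta(badchar, "Dpr"), "'X'.*column 3")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_aligned_fasta(empty, "Dpr"), "empty")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "LK", ">a", "LK"), dup)
  expect_error(read_aligned_fasta(dup, "Dpr"), "duplicate")
})

test_that("interfacial positions are residues with strictly positive dASA", {
  asa <- data.frame(protein_id = c("p", "p", "p", "q"),
                    residue_number = c(5L, 6L, 7L, 3L),
                    delta_asa = c(12.3, 0, 0.001, 0))
  got <- assign_interfacial_positions(asa)
  expect_equal(got$p, c(5L, 7L))
  expect_equal(got$q, integer(0))

  expect_error(assign_interfacial_positions(
    data.frame(protein_id = "p", residue_number = c(5L, 5L),
               delta_asa = c(1, 2))), "duplicate")
  expect_error(assign_interfacial_positions(
    data.frame(protein_id = "p", residue_number = 5L, delta_asa = -1)),
    "non-negative")

  # monotone: adding a positive record never removes a position
  for (i in 1:20) {
    base <- data.frame(protein_id = "p",
                       residue_number = sample(100, 8),
                       delta_asa = round(stats::runif(8, 0, 5), 2))
    extra <- rbind(base, data.frame(protein_id = "p",
                                    residue_number = 101L + i,
                                    delta_asa = stats::runif(1, 0.1, 5)))
    expect_true(all(assign_interfacial_positions(base)$p %in%
                      assign_interfacial_positions(extra)$p))
  }
})

test_that("column extraction follows family-position order", {
  # alignment columns hold distinct letters so provenance is visible
  msa <- aligned_subfamily(rep("ACDEFGHIKL", 3),
                           sequence_ids = c("r", "s", "t"),
                           family_side = "DIP", subgroup_id = "g",
                           reference_id = "r")
  # family positions 1,2,3 live at alignment columns 2,4,9
  map <- data.frame(family_position = c(2L, 1L, 3L),
                    protein_id = "r",
                    residue_number = c(12L, 11L, 13L),
                    alignment_column = c(4L, 2L, 9L))
  out <- extract_interfacial_columns(msa, map)
  expect_equal(out$rows[1], "CEK")  # source columns 2, 4, 9 in that order
  expect_equal(nrow_msa(out), 3)

  expect_error(extract_interfacial_columns(
    msa, transform(map, protein_id = "other")), "absent from position map")
  expect_error(extract_interfacial_columns(
    msa, transform(map, alignment_column = c(4L, 2L, 99L))), "beyond")
  expect_error(extract_interfacial_columns(msa, map[0, ]),
               "absent|contiguous|positions")
})

test_that("column frequency profiles are exact counts over 21 symbols", {
  msa <- aligned_subfamily(c(a = "K", b = "K", c = "R", d = "-"),
                           family_side = "Dpr")
  pr <- column_frequency_profile(msa, 1)
  expect_equal(pr[["K"]], 0.5)
  expect_equal(pr[["R"]], 0.25)
  expect_equal(pr[["-"]], 0.25)
  expect_equal(sum(pr), 1)
  expect_error(column_frequency_profile(msa, 2), "out of range")

  all_k <- aligned_subfamily(rep("K", 4), paste0("s", 1:4), "Dpr")
  expect_equal(column_frequency_profile(all_k, 1)[["K"]], 1)

  # property: sums to 1 and all in [0,1] for random alignments
  withr::local_seed(42)
  for (i in 1:25) {
    m <- random_msa(sample(2:12, 1), sample(1:20, 1))
    p <- column_frequency_profile(m, sample(ncol_msa(m), 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("extraction commutes with frequency profiling", {
  withr::local_seed(7)
  msa <- random_msa(8, 40)
  msa$reference_id <- "s1"
  cols <- sort(sample(40, 12))
  map <- data.frame(family_position = seq_along(cols), protein_id = "s1",
                    residue_number = seq_along(cols),
                    alignment_column = cols)
  sub <- extract_interfacial_columns(msa, map)
  for (fp in c(1L, 5L, 12L)) {
    expect_equal(c(unclass(column_frequency_profile(sub, fp))),
                 c(unclass(column_frequency_profile(msa, cols[fp]))))
  }
})

test_that("mean pairwise identity handles gaps as specified", {
  two <- aligned_subfamily(c(a = strrep("A", 33), b = strrep("A", 33)),
                           family_side = "Dpr")
  expect_equal(mean_pairwise_identity(two), 100)

  onediff <- aligned_subfamily(
    c(a = strrep("A", 33), b = paste0(strrep("A", 32), "S")),
    family_side = "Dpr")
  expect_equal(mean_pairwise_identity(onediff), 32 / 33 * 100,
               tolerance = 1e-12)

  # gap-vs-residue mismatches; gap-gap columns drop out of the comparison
  gappy <- aligned_subfamily(c(a = "AAAA", b = "AA--", c = "AAAA"),
                             family_side = "Dpr")
  expect_equal(mean_pairwise_identity(gappy), (50 + 50 + 100) / 3,
               tolerance = 1e-12)

  expect_error(mean_pairwise_identity(
    aligned_subfamily(c(a = "AAAA"), family_side = "Dpr")), "at least 2")
  expect_error(mean_pairwise_identity(
    aligned_subfamily(c(a = "-", b = "-"), family_side = "Dpr")),
    "no comparable")

  # invariant under row permutation
  withr::local_seed(11)
  for (i in 1:10) {
    m <- random_msa(5, 12)
    perm <- sample(5)
    mp <- aligned_subfamily(m$rows[perm], m$sequence_ids[perm],
                            family_side = "Dpr")
    expect_equal(mean_pairwise_identity(mp), mean_pairwise_identity(m))
  }
})

test_that("position map validation catches structural defects", {
  ok <- data.frame(family_position = 1:3, protein_id = "p",
                   residue_number = 11:13, alignment_column = c(2L, 4L, 9L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_position_map(ok, path)
  expect_equal(read_position_map(path), ok)
  dup <- rbind(ok, ok[1, ])
  expect_error(negcon:::validate_position_map(dup), "duplicate")
  gap <- ok; gap$family_position <- c(1L, 2L, 4L)
  expect_error(negcon:::validate_position_map(gap), "contiguous")
})
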