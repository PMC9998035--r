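test_that("profile merge: trivial cases", {
  a <- c(x = "MKV")
  expect_identical(unname(profile_merge_align(a, a[0])[1]), "MKV")
  m <- profile_merge_align(c(x = "MKV"), c(y = "MKV"))
  expect_equal(nchar(m[[1]]), 3L)
  expect_false(any(grepl("-", m)))
  expect_error(profile_merge_align(character(0), character(0)), "empty")
})

test_that("sub-MSA preservation holds on random merges", {
  set.seed(131)
  for (i in 1:300) {
    a <- random_alignment(sample(1:4, 1), sample(3:10, 1), prefix = "a")
    b <- random_alignment(sample(1:4, 1), sample(3:10, 1), prefix = "b")
    merged <- profile_merge_align(a, b)
    expect_identical(recover_submsa(merged, names(a)), a,
                     info = paste("trial", i, "side a"))
    expect_identical(recover_submsa(merged, names(b)), b,
                     info = paste("trial", i, "side b"))
    # every merged column uses at most one column of each input, in order
    cm <- attr(merged, "column_map")
    expect_identical(cm$a_col[!is.na(cm$a_col)],
                     seq_len(nchar(a[[1]])))
    expect_identical(cm$b_col[!is.na(cm$b_col)],
                     seq_len(nchar(b[[1]])))
  }
})

test_that("merge DP attains the exhaustive-enumeration optimum", {
  set.seed(132)
  lens <- list(c(2, 3), c(4, 4), c(5, 3), c(6, 6), c(5, 7), c(8, 4),
               c(7, 7), c(8, 8), c(3, 8), c(6, 5))
  for (ln in lens) {
    a <- random_alignment(sample(1:3, 1), ln[1], prefix = "a")
    b <- random_alignment(sample(1:3, 1), ln[2], prefix = "b")
    merged <- profile_merge_align(a, b)
    sc <- naive_pair_scores(a, b)
    best <- enum_align_oracle(sc, gap_open = 10, gap_extend = 0.5)
    mine <- pairing_score(attr(merged, "column_map"), sc, 10, 0.5)
    expect_equal(mine, best, tolerance = 1e-9)
    expect_equal(attr(merged, "score"), best, tolerance = 1e-6)
  }
})

test_that("gap-threshold trimming matches the vendored reference output", {
  msa <- read_fasta(test_path("fixtures", "trim_input.fasta"))
  trimmed <- trim_columns(msa, keep_fraction = 0.05)
  # kept columns: residue fractions 1.0, 2/30, 15/30, 1.0, 2/30
  expect_identical(trimmed$kept, c(1L, 3L, 5L, 7L, 8L))
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(trimmed$msa, out)
  expect_identical(readBin(out, "raw", file.size(out)),
                   readBin(test_path("fixtures", "trim_expected_gt05.fasta"),
                           "raw",
                           file.size(test_path("fixtures",
                                               "trim_expected_gt05.fasta"))))
  # boundary: 1/30 = 3.3% removed, 2/30 = 6.7% kept at gt = 0.05
  mat <- do.call(rbind, strsplit(msa, ""))
  expect_lt(mean(mat[, 2] != "-"), 0.05)
  expect_gt(mean(mat[, 3] != "-"), 0.05)
})

test_that("trimming edge cases and idempotence", {
  set.seed(133)
  msa <- random_alignment(6, 20, gap_prob = 0.4)
  t_all <- trim_columns(msa, 1e-9)
  expect_identical(t_all$msa, msa)
  t_full <- trim_columns(msa, 1)
  mat <- do.call(rbind, strsplit(msa, ""))
  expect_identical(t_full$kept, which(colSums(mat == "-") == 0))
  t1 <- trim_columns(msa, 0.4)
  t2 <- trim_columns(t1$msa, 0.4)
  expect_identical(t2$msa, t1$msa)
  allgap <- c(a = "---", b = "-A-")
  expect_error(trim_columns(allgap, 0.9), "columns removed")
})

test_that("arm-coverage species selection equals brute force", {
  pmap <- default_paralog_map()
  genes <- c(pmap$pairs$subunit, pmap$excluded)
  set.seed(134)
  for (i in 1:30) {
    states <- matrix(sample(c("present", "absent"), 10 * length(genes),
                            TRUE),
                     10, length(genes),
                     dimnames = list(paste0("sp", 1:10), genes))
    pm <- presence_matrix(states,
                          complexes = list(Cx = genes), conditioning = NA)
    got <- select_species_by_arm_coverage(pm, pmap, min_per_arm = 2)
    arm1 <- pmap$pairs$subunit[pmap$pairs$arm == "arm1"]
    arm2 <- pmap$pairs$subunit[pmap$pairs$arm == "arm2"]
    want <- rownames(states)[
      rowSums(states[, arm1] == "present") >= 2 &
        rowSums(states[, arm2] == "present") >= 2]
    expect_identical(got, want)
  }
  # boundary: exactly 2 per arm is included; 4 all in one arm is not
  states <- matrix("absent", 2, length(genes),
                   dimnames = list(c("edge", "lopsided"), genes))
  states["edge", c("Ask1", "Dad2", "Dad3", "Duo1")] <- "present"
  states["lopsided", c("Ask1", "Dad2", "Dad4", "Hsk3")] <- "present"
  pm <- presence_matrix(states, complexes = list(Cx = genes),
                        conditioning = NA)
  expect_identical(select_species_by_arm_coverage(pm, pmap, 2), "edge")
})

test_that("arm supermatrix: layout, partitions, gap padding", {
  pmap <- paralog_map(data.frame(
    subunit = c("U1", "V1", "U2", "V2"),
    partner = c("U2", "V2", "U1", "V1"),
    arm = c("arm1", "arm1", "arm2", "arm2"),
    pair = c("U", "V", "U", "V")))
  aln <- list(U1 = c(spA = "MKVA", spB = "MKVC"),
              U2 = c(spA = "MKIA", spB = "MKIC"),
              V1 = c(spA = "DDE", spB = "DDE"),
              V2 = c(spA = "DQE", spB = "DQE"))
  sm <- build_arm_supermatrix(aln, pmap, species = c("spA", "spB"),
                              trim_keep_fraction = NULL, premerged = TRUE)
  expect_equal(length(sm$alignment), 4L)
  expect_equal(nrow(sm$partition), 2L)
  widths <- nchar(sm$alignment)
  expect_true(all(widths == sm$partition$end[2]))
  expect_equal(sm$partition$end[2] - sm$partition$start[1] + 1L,
               sum(4L, 3L))
  expect_identical(unname(sm$alignment[["spA__arm1"]]), "MKVADDE")
  expect_identical(unname(sm$alignment[["spA__arm2"]]), "MKIADQE")

  # dropping a subunit from one species pads that block with gaps
  aln2 <- aln; aln2$V1 <- aln2$V1["spA"]
  sm2 <- build_arm_supermatrix(aln2, pmap, species = c("spA", "spB"),
                               trim_keep_fraction = NULL, premerged = TRUE)
  expect_identical(unname(sm2$alignment[["spB__arm1"]]), "MKVC---")
  expect_equal(nchar(sm2$alignment[["spB__arm1"]]),
               nchar(sm2$alignment[["spA__arm1"]]))

  # a species with an entirely missing arm triggers the contract error
  aln3 <- aln
  aln3$U1 <- aln3$U1["spA"]; aln3$V1 <- aln3$V1["spA"]
  expect_error(build_arm_supermatrix(aln3, pmap,
                                     species = c("spA", "spB"),
                                     trim_keep_fraction = NULL,
                                     premerged = TRUE),
               "all-gap")

  expect_error(build_arm_supermatrix(aln, pmap, species = "bad__name",
                                     premerged = TRUE),
               "reserved")
})

test_that("full concatenation equals manual pasting", {
  aln <- list(g1 = c(A = "MK", B = "MR", C = "MQ"),
              g2 = c(A = "DDE", C = "DNE"))
  cc <- build_full_concatenation(aln, species = c("A", "B", "C"))
  expect_identical(unname(cc$alignment[["A"]]), "MKDDE")
  expect_identical(unname(cc$alignment[["B"]]), "MR---")
  expect_identical(unname(cc$alignment[["C"]]), "MQDNE")
  expect_equal(cc$partition$start, c(1L, 3L))
  expect_equal(cc$partition$end, c(2L, 5L))
  # single subunit: identity
  cc1 <- build_full_concatenation(aln["g1"], species = c("A", "B", "C"))
  expect_identical(unname(cc1$alignment), unname(aln$g1))
})
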