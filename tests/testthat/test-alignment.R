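test_that("trivial alignments: single member and identical sequences", {
  fam1 <- family_from_seqs(c(A = "MTEYKLVV"))
  aln1 <- alignFamily(fam1)
  expect_equal(alignmentLength(aln1), 8L)
  expect_false(grepl("-", alignmentRows(aln1)[["A"]]))

  fam2 <- family_from_seqs(c(A = "MTEYKLVV", B = "MTEYKLVV"))
  aln2 <- alignFamily(fam2)
  expect_equal(unname(alignmentRows(aln2)), rep("MTEYKLVV", 2))
})

test_that("builtin aligner places the expected single gap (pairwise oracle)", {
  ## optimal global BLOSUM62 alignment of ACDEFG vs ACEFG deletes the D
  fam <- family_from_seqs(c(X = "ACDEFG", Y = "ACEFG"))
  aln <- alignFamily(fam)
  expect_equal(alignmentLength(aln), 6L)
  expect_equal(unname(alignmentRows(aln)[["X"]]), "ACDEFG")
  expect_equal(unname(alignmentRows(aln)[["Y"]]), "AC-EFG")
  prof <- buildConsensus(aln)
  expect_equal(columnCoverage(prof)[3], 1L)   # the D column
})

test_that("degapping any builtin-aligned row reproduces the input exactly", {
  fam <- generateFamily(nMembers = 8, length = 60, substitutionRate = 0.15,
                        indelRate = 0.05, seed = 21)$family
  aln <- alignFamily(fam)
  degapped <- gsub("-", "", alignmentRows(aln), fixed = TRUE)
  expect_identical(degapped[names(familySequences(fam))],
                   setNames(as.character(familySequences(fam)),
                            names(familySequences(fam))))
})

test_that("prealigned backend validates rows against the family", {
  fam <- family_from_seqs(c(X = "ACDEFG", Y = "ACEFG"))
  pre <- tempfile(fileext = ".fasta")
  writeLines(c(">X", "ACDEFG", ">Y", "AC-EFG"), pre)
  aln <- alignFamily(fam, backend = "prealigned", prealignedPath = pre)
  expect_equal(alignmentLength(aln), 6L)
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">X", "ACDEFG", ">Y", "AC-EFD"), bad)
  expect_error(alignFamily(fam, backend = "prealigned", prealignedPath = bad),
               "Y")
})

test_that("a missing external aligner gives an actionable error", {
  fam <- family_from_seqs(c(X = "ACDEFG", Y = "ACEFG"))
  expect_error(alignFamily(fam, backend = "external",
                           exe = "no-such-aligner-exists"),
               "prealigned")
})

test_that("consensus takes the modal residue with alphabetical tie-break", {
  aln <- alignment_from_rows(c(A = "AAC", B = "A-C", C = "C-C"))
  prof <- buildConsensus(aln)
  expect_equal(consensusSequence(prof), c("A", "A", "C"))
  expect_equal(columnCoverage(prof), c(3L, 1L, 3L))
  ## two-way tie A vs C in column 1 resolves alphabetically
  aln2 <- alignment_from_rows(c(A = "A", B = "C"))
  expect_equal(consensusSequence(buildConsensus(aln2)), "A")
  ## all-gap column gets "-" and zero coverage
  aln3 <- alignment_from_rows(c(A = "A-C", B = "A-C"))
  prof3 <- buildConsensus(aln3)
  expect_equal(consensusSequence(prof3)[2], "-")
  expect_equal(columnCoverage(prof3)[2], 0L)
})

test_that("coordinate maps invert each other on random alignments", {
  aln <- alignment_from_rows(c(A = "A-CD", B = "ABCD"))
  expect_equal(mapToConsensus(aln, "A", 2L), 3L)     # gap offset
  expect_error(mapToConsensus(aln, "A", 9L), "A")
  expect_error(reverseMap(aln, 99L), "out of range")
  rm3 <- reverseMap(aln, 2L)
  expect_equal(rm3$gene_symbol, "B")                 # only B is non-gap

  for (s in 1:5) {
    truth <- generateFamily(nMembers = 5, length = 30,
                            substitutionRate = 0.2, indelRate = 0.1,
                            seed = 100 + s)
    aln <- truth$alignment
    for (m in memberIds(aln)) {
      len <- nchar(gsub("-", "", alignmentRows(aln)[[m]], fixed = TRUE))
      for (p in seq_len(len)) {
        col <- mapToConsensus(aln, m, p)
        rm <- reverseMap(aln, col)
        expect_true(any(rm$gene_symbol == m & rm$position == p))
      }
    }
  }
})

test_that("reverse mapping honours domain offsets", {
  aln <- alignment_from_rows(c(A = "A-CD", B = "ABCD"),
                             offsets = c(A = 10L, B = 1L))
  rm <- reverseMap(aln, 3L)
  expect_equal(rm$position[rm$gene_symbol == "A"], 11L)  # fragment pos 2
})

test_that("pooling counts, translates offsets and tracks exclusions", {
  aln <- alignment_from_rows(c(A = "MTEYK", B = "MTEYK"))
  muts <- mut_records(c("A", "B", "A", "Z"), c(5L, 5L, 2L, 1L))
  prof <- poolMutations(aln, muts)
  expect_equal(mutationCounts(prof)[5], 2L)
  expect_equal(mutationCounts(prof)[2], 1L)
  expect_equal(totalMutations(prof), 3L)
  expect_equal(unname(diagnostics(prof)["unknown_gene"]), 1L)
  ## a domain starting at offset 10: residue 3 of the protein is upstream
  aln2 <- alignment_from_rows(c(A = "MTEYK"), offsets = c(A = 10L))
  prof2 <- poolMutations(aln2, mut_records("A", c(3L, 12L)))
  expect_equal(totalMutations(prof2), 1L)
  expect_equal(unname(diagnostics(prof2)["out_of_fragment"]), 1L)
  expect_equal(mutationProvenance(prof2)$column, 3L)    # 12 - 10 + 1
})

test_that("subsetting keeps the column frame and commutes with pooling", {
  truth <- generateFamily(nMembers = 6, length = 40, substitutionRate = 0.1,
                          indelRate = 0.05, seed = 33)
  aln <- truth$alignment
  keep <- memberIds(aln)[1:3]
  sub <- subsetMembers(aln, keep)
  expect_equal(alignmentLength(sub), alignmentLength(aln))
  expect_identical(alignmentRows(sub), alignmentRows(aln)[keep])
  expect_error(subsetMembers(aln, "NOPE"), "unknown")

  coh <- generateCohort(truth$family, aln, nSamples = 20,
                        backgroundRate = 2, seed = 34)
  muts <- coh$mutations
  p1 <- poolMutations(sub, muts[muts$gene_symbol %in% keep, , drop = FALSE])
  p2 <- poolMutations(sub, muts)   # pooling itself drops foreign genes
  expect_equal(mutationCounts(p1), mutationCounts(p2))
})
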