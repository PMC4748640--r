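test_that("hypothesis workflow finds a planted hotspot end to end", {
  truth <- generateFamily(nMembers = 8, length = 60, substitutionRate = 0.05,
                          indelRate = 0.02, seed = 71)
  coh <- generateCohort(truth$family, truth$alignment, nSamples = 40,
                        backgroundRate = 1,
                        hotspots = data.frame(column = 20, fraction = 0.35),
                        seed = 72)
  res <- runHypothesis(truth$family, coh$mutations, seed = 73)
  expect_s4_class(res$hotspots, "HotspotTable")
  sig <- significantHotspots(res$hotspots)
  ## the planted consensus column (or the builtin aligner's image of it)
  ## is in the significant set; with deletion-only evolution the builtin
  ## aligner reproduces the frame, so the column index matches
  expect_true(20L %in% sig$column)
  expect_lt(globalP(res$hotspots), 0.05)
})

test_that("same config and seed give byte-identical outputs", {
  truth <- generateFamily(nMembers = 6, length = 40, substitutionRate = 0.05,
                          indelRate = 0.02, seed = 74)
  coh <- generateCohort(truth$family, truth$alignment, nSamples = 20,
                        backgroundRate = 1,
                        hotspots = data.frame(column = 15, fraction = 0.3),
                        seed = 75)
  d1 <- tempfile(); d2 <- tempfile()
  runHypothesis(truth$family, coh$mutations, seed = 76, outDir = d1)
  runHypothesis(truth$family, coh$mutations, seed = 76, outDir = d2)
  for (f in c("alignment.fasta", "consensus.tsv", "hotspots.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  ## the sidecar records config, seed and checksums
  info <- readLines(file.path(d1, "run.info"))
  expect_true(any(grepl("seed: 76", info)))
  expect_true(any(grepl("md5 hotspots.tsv", info)))
})

test_that("single-gene analysis runs without any alignment effect", {
  fam <- generateFamily(nMembers = 1, length = 80, substitutionRate = 0,
                        indelRate = 0, seed = 77)
  muts <- mut_records("GENE01", rep(40L, 6),
                      ref = substr(as.character(familySequences(fam$family)),
                                   40, 40))
  res <- runHypothesis(fam$family, muts, seed = 78)
  expect_equal(alignmentLength(res$alignment), 80L)
  tab <- hotspotTable(res$hotspots)
  expect_equal(tab$count[40], 6L)
  expect_true(all(tab$trident == 1))   # one sequence: conservation is trivial
})

test_that("empty profiles are a clean nothing-to-test result", {
  fam <- generateFamily(nMembers = 3, length = 30, substitutionRate = 0,
                        indelRate = 0, seed = 79)
  silent_only <- mut_records("GENE01", 5L, ref = "X", class = "silent")
  silent_only$ref_aa <- substr(as.character(familySequences(fam$family))[1],
                               5, 5)
  expect_message(res <- runHypothesis(fam$family, silent_only, seed = 80),
                 "nothing to test")
  expect_null(res$hotspots)
})

test_that("data-driven sweep: per-family + per-gene reports, unified table", {
  truth1 <- generateFamily(nMembers = 5, length = 50, substitutionRate = 0.05,
                           indelRate = 0, seed = 81)
  truth2 <- generateFamily(nMembers = 4, length = 40, substitutionRate = 0.05,
                           indelRate = 0, seed = 82)
  seqs1 <- as.character(familySequences(truth1$family))
  names(seqs1) <- paste0("FAM1_", names(seqs1))
  seqs2 <- as.character(familySequences(truth2$family))
  names(seqs2) <- paste0("FAM2_", names(seqs2))
  fasta <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(c(seqs1, seqs2)), fasta)
  domains <- make_domain_table(data.frame(
    gene_symbol = c(names(seqs1), names(seqs2)),
    family_id = rep(c("PFA", "PFB"), c(length(seqs1), length(seqs2))),
    start = 1L,
    end = c(nchar(seqs1), nchar(seqs2))))

  coh1 <- generateCohort(truth1$family, truth1$alignment, nSamples = 30,
                         backgroundRate = 0.5,
                         hotspots = data.frame(column = 25, fraction = 0.5),
                         seed = 83)
  coh2 <- generateCohort(truth2$family, truth2$alignment, nSamples = 30,
                         backgroundRate = 0.5, seed = 84)
  muts <- rbind(
    transform(coh1$mutations, gene_symbol = paste0("FAM1_", gene_symbol)),
    transform(coh2$mutations, gene_symbol = paste0("FAM2_", gene_symbol)))

  res <- runDataDriven(muts, fasta, domains, seed = 85)
  expect_setequal(names(res$families), c("PFA", "PFB"))
  expect_true(length(res$singles) >= 1L)
  expect_true(is.data.frame(res$unified))
  ## unified rows = union of significant rows, deduplicated by support key
  n_family <- sum(vapply(res$families, function(r)
    nrow(significantHotspots(r$hotspots)), 0L))
  n_single_rows <- lapply(names(res$singles), function(g) {
    s <- significantHotspots(res$singles[[g]]$hotspots)
    if (nrow(s)) paste(g, s$column) else character(0)
  })
  n_single <- length(unique(unlist(n_single_rows)))
  expect_equal(nrow(res$unified), n_family + n_single)
  ## the planted family hotspot is in the unified table with family support
  expect_true(any(res$unified$support == "family" &
                  res$unified$family == "PFA" & res$unified$column == 25L))
})

test_that("data-driven sweep on one family matches the hypothesis run", {
  truth <- generateFamily(nMembers = 5, length = 50, substitutionRate = 0.05,
                          indelRate = 0, seed = 86)
  coh <- generateCohort(truth$family, truth$alignment, nSamples = 30,
                        backgroundRate = 0.5,
                        hotspots = data.frame(column = 10, fraction = 0.4),
                        seed = 87)
  seqs <- as.character(familySequences(truth$family))
  fasta <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta)
  domains <- make_domain_table(data.frame(
    gene_symbol = names(seqs), family_id = "PFX", start = 1L,
    end = nchar(seqs)))
  dd <- runDataDriven(coh$mutations, fasta, domains, seed = 88)
  hyp <- runHypothesis(truth$family, coh$mutations, seed = 88)
  expect_equal(hotspotTable(dd$families$PFX$hotspots),
               hotspotTable(hyp$hotspots))
})

test_that("simulate workflow writes inputs the readers accept unchanged", {
  d <- tempfile()
  paths <- runSimulate(d, seed = 90,
                       familyArgs = list(nMembers = 5, length = 40,
                                         substitutionRate = 0.05,
                                         indelRate = 0.02),
                       cohortArgs = list(nSamples = 20, backgroundRate = 1,
                                         hotspots = data.frame(column = 12,
                                                               fraction = 0.4)))
  expect_true(all(file.exists(paths)))
  fam <- readFamily(paths[["family"]])
  muts <- readMutations(paths[["mutations"]])
  expect_equal(length(familySequences(fam)), 5L)
  res <- runHypothesis(fam, muts, seed = 91, backend = "prealigned",
                       prealignedPath = paths[["alignment"]])
  expect_s4_class(res$hotspots, "HotspotTable")
  ## truth table matches the cohort construction on disk
  truth <- read.delim(paths[["truth"]])
  expect_equal(nrow(truth), nrow(muts))
  ## seed stability of the writer
  d2 <- tempfile()
  paths2 <- runSimulate(d2, seed = 90,
                        familyArgs = list(nMembers = 5, length = 40,
                                          substitutionRate = 0.05,
                                          indelRate = 0.02),
                        cohortArgs = list(nSamples = 20, backgroundRate = 1,
                                          hotspots = data.frame(column = 12,
                                                                fraction = 0.4)))
  expect_identical(readLines(paths[["mutations"]]),
                   readLines(paths2[["mutations"]]))
})
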