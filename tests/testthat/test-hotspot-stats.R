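test_that("shannon entropy matches the closed form", {
  expect_equal(shannonEntropy(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannonEntropy(c(5, 0, 0, 0)), 0)
  expect_equal(shannonEntropy(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_error(shannonEntropy(c(0, 0)), "N = 0")
  ## bounds: 0 <= H <= log(#nonzero) <= log K
  set.seed(4)
  for (i in 1:25) {
    counts <- rpois(sample(3:30, 1), 2)
    if (sum(counts) == 0) counts[1] <- 1
    H <- shannonEntropy(counts)
    expect_gte(H, 0)
    expect_lte(H, log(sum(counts > 0)) + 1e-12)
  }
})

test_that("sampling weights are coverage-proportional and normalised", {
  expect_equal(samplingWeights(c(2, 0, 2)), c(0.5, 0, 0.5))
  expect_equal(samplingWeights(rep(3L, 10)), rep(0.1, 10))
  set.seed(5)
  cov <- rpois(50, 4)
  cov[1] <- 1   # guard non-zero
  w <- samplingWeights(cov)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, cov / sum(cov))
  expect_error(samplingWeights(rep(0, 4)), "all-zero")
})

test_that("bootstrap replicates conserve N and respect degenerate weights", {
  null <- simulateNull(c(0, 1, 0), N = 7L, nBoot = 50L, seed = 2)
  expect_true(all(null@bootCounts[, 2] == 7L))
  expect_true(all(null@bootCounts[, c(1, 3)] == 0L))
  null2 <- simulateNull(rep(0.25, 4), N = 9L, nBoot = 200L, seed = 3)
  expect_true(all(rowSums(null2@bootCounts) == 9L))
  ## reproducible under the seed, and the RNG state outside is untouched
  null3 <- simulateNull(rep(0.25, 4), N = 9L, nBoot = 200L, seed = 3)
  expect_identical(null2@bootCounts, null3@bootCounts)
})

test_that("gamma fit recovers parameters and flags degeneracy", {
  set.seed(11)
  x <- rgamma(5000, shape = 2, scale = 3)
  fit <- fitGamma(x)
  expect_equal(fit$shape, 2, tolerance = 0.1)
  expect_equal(fit$scale, 3, tolerance = 0.15)
  expect_null(fitGamma(rep(2.5, 100)))        # zero variance
  expect_null(fitGamma(c(1)))                 # too few values
  ## zeros are outside the support and ignored by the fit
  fit2 <- fitGamma(c(x[1:500], rep(0, 10)))
  expect_false(is.null(fit2))
  ## agreement with an independent ML fitter
  fit_ind <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  expect_equal(fit$shape, unname(fit_ind$estimate["shape"]), tolerance = 1e-3)
  expect_equal(1 / fit$scale, unname(fit_ind$estimate["rate"]),
               tolerance = 1e-3)
})

test_that("global p-value uses the lower tail of the entropy null", {
  null <- simulateNull(rep(0.02, 50), N = 40L, nBoot = 1000L, seed = 6)
  expect_false(is.null(null@entropyNull))
  expect_lt(globalPvalue(0, null), 1e-6)       # maximal clustering
  med <- qgamma(0.5, shape = null@entropyNull$shape,
                scale = null@entropyNull$scale)
  expect_equal(globalPvalue(med, null), 0.5, tolerance = 1e-9)
  ## monotone in the observed entropy
  expect_lt(globalPvalue(1.0, null), globalPvalue(2.0, null))
})

test_that("per-position p-values: trivial columns, monotonicity, determinism", {
  null <- simulateNull(c(0.5, 0.5, 0), N = 20L, nBoot = 500L, seed = 7)
  p <- positionPvalues(c(0L, 12L, 5L), null)
  expect_equal(p[1], 1)            # n_i = 0 carries no evidence
  expect_equal(p[3], 1)            # zero-weight column
  expect_lt(p[2], 0.5)
  ## increasing n_i at a fixed null never increases p
  pseq <- vapply(0:20, function(n) positionPvalues(c(n, 0L, 0L), null)[1], 0)
  expect_true(all(diff(pseq) <= 1e-12))
  ## bit-identical results under identical seed + inputs
  null_b <- simulateNull(c(0.5, 0.5, 0), N = 20L, nBoot = 500L, seed = 7)
  expect_identical(positionPvalues(c(0L, 12L, 5L), null_b), p)
})

test_that("a planted hotspot gets a tiny p and the rest stay calibrated", {
  K <- 100L; N <- 50L
  w <- rep(1 / K, K)
  set.seed(8)
  counts <- as.integer(rmultinom(1, N - 15L, w))
  counts[40] <- counts[40] + 15L   # ~30% of N on one column
  null <- simulateNull(w, N = N, nBoot = 1000L, seed = 9)
  p <- positionPvalues(counts, null)
  expect_lt(p[40], 1e-4)
  expect_equal(which.min(p), 40L)
  expect_gt(min(p[-40]), 1e-4)
})

test_that("BH correction is trident-gated and matches the oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  q <- correctQvalues(p, trident = rep(1, 4))
  expect_equal(q, rep(0.04, 4))
  ## single gated-in column: q == p
  q1 <- correctQvalues(c(0.2, 0.01), trident = c(0.05, 0.9))
  expect_true(is.na(q1[1]))
  expect_equal(q1[2], 0.01)
  ## identical p is a BH fixed point
  expect_equal(correctQvalues(rep(0.07, 5), rep(1, 5)), rep(0.07, 5))
  ## no gated-in column warns and yields all-NA
  expect_warning(qe <- correctQvalues(p, trident = rep(0, 4)), "gate")
  expect_true(all(is.na(qe)))
  ## gate is strict: trident exactly 0.1 is out
  q2 <- correctQvalues(c(0.5, 0.5), trident = c(0.1, 0.100001))
  expect_true(is.na(q2[1]) && !is.na(q2[2]))
})

test_that("hotspot calling reverse-maps contributors and reports global p", {
  truth <- generateFamily(nMembers = 8, length = 60, substitutionRate = 0.05,
                          indelRate = 0.02, seed = 41)
  coh <- generateCohort(truth$family, truth$alignment, nSamples = 40,
                        backgroundRate = 0.5,
                        hotspots = data.frame(column = 30, fraction = 0.4),
                        seed = 42)
  aln <- truth$alignment
  consensus <- buildConsensus(aln)
  prof <- poolMutations(aln, coh$mutations)
  null <- simulateNull(samplingWeights(consensus), totalMutations(prof),
                       nBoot = 1000L, seed = 43)
  ht <- callHotspots(prof, consensus, null, aln)
  tab <- hotspotTable(ht)
  expect_equal(nrow(tab), alignmentLength(aln))
  expect_true(tab$significant[30])
  expect_lt(globalP(ht), 0.05)
  ## contributors at the planted column name real provenance
  contrib <- strsplit(tab$contributors[30], ";")[[1]]
  expect_equal(length(contrib), tab$count[30])
  expect_true(all(grepl("^GENE[0-9]+:[0-9]+:S[0-9]+$", contrib)))
  ## q >= p wherever both exist
  ok <- !is.na(tab$q)
  expect_true(all(tab$q[ok] >= tab$p[ok] - 1e-12))
  ## export round-trip of the TSV report
  out <- tempfile(fileext = ".tsv")
  writeHotspotTable(ht, out)
  back <- read.delim(out)
  expect_equal(nrow(back), nrow(tab))
  expect_true(file.exists(paste0(out, ".meta.txt")))
})
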