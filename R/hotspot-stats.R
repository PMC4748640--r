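## The statistical model: Shannon entropy of the pooled profile, a
## coverage-weighted multinomial bootstrap null, Gamma fits (global entropy
## null and per-column count nulls), Trident-gated BH correction, hotspot
## calling with reverse-mapped contributors.

#' Shannon entropy of a pooled mutational profile
#'
#' `H = -sum_i p_i log(p_i)` with `p_i = n_i / N`, natural logarithm;
#' zero-count positions contribute nothing. Low entropy means the mutations
#' cluster on few consensus positions; the maximum, `log(K)`, is reached by a
#' perfectly uniform profile.
#'
#' @param x A \linkS4class{MutationProfile} or a non-negative count vector.
#' @return Non-negative entropy in nats.
#' @export
#' @examples
#' shannonEntropy(c(1, 1, 1, 1))  # log(4)
#' shannonEntropy(c(5, 0, 0, 0))  # 0
shannonEntropy <- function(x) {
  counts <- if (is(x, "MutationProfile")) mutationCounts(x) else x
  if (any(counts < 0)) .stop_data("negative mutation counts")
  N <- sum(counts)
  if (N == 0) .stop_data("entropy is undefined for an empty profile (N = 0)")
  p <- counts[counts > 0] / N
  -sum(p * log(p))
}

#' Coverage-proportional sampling weights of the bootstrap null
#'
#' The probability that a random mutation falls on consensus column `i` is
#' proportional to the number of member residues aligned there (the column
#' coverage): the more gaps a column has, the less likely a random mutation
#' lands on it. This corrects the bias of finding more mutations in
#' well-covered regions of the consensus.
#'
#' @param profile A \linkS4class{ConsensusProfile} or a coverage vector.
#' @return Probability vector summing to 1.
#' @export
samplingWeights <- function(profile) {
  cov <- if (is(profile, "ConsensusProfile")) columnCoverage(profile)
         else profile
  tot <- sum(cov)
  if (tot <= 0) .stop_data("all-zero coverage: nothing can be sampled")
  cov / tot
}

#' Simulate the bootstrap null of random mutational profiles
#'
#' Each replicate redistributes the `N` observed mutations over the `K`
#' consensus columns by one multinomial draw with the coverage-proportional
#' weights: same profile length, same total mutation count, coverage-biased
#' placement. Reproducible under the given seed.
#'
#' @param weights Probability vector (see [samplingWeights()]).
#' @param N Total mutation count (>= 1).
#' @param nBoot Number of replicates (default 1000).
#' @param seed Integer seed (required; recorded in the model).
#' @return A \linkS4class{NullModel} with the replicate count matrix, the
#'   replicate entropies and the fitted Gamma entropy null.
#' @export
simulateNull <- function(weights, N, nBoot = 1000L, seed) {
  if (missing(seed)) .stop_config("simulateNull() requires an explicit seed")
  if (N < 1L) .stop_data("the null needs at least one mutation (N >= 1)")
  if (abs(sum(weights) - 1) > 1e-8)
    .stop_data("weights must sum to 1")
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  boot <- t(rmultinom(nBoot, size = N, prob = weights))   # nBoot x K
  storage.mode(boot) <- "integer"
  P <- boot / N
  logP <- ifelse(boot > 0L, log(P), 0)
  ent <- -rowSums(P * logP)
  ## Gamma null of the entropies; all-in-one-column replicates have entropy 0,
  ## outside the Gamma support.  If few (<= 10%), exclude them from the fit;
  ## if many, fall back to the empirical tail.
  zero <- ent <= .Machine$double.eps
  entropyNull <- NULL
  if (mean(zero) <= 0.10) {
    fit <- fitGamma(ent[!zero])
    if (!is.null(fit)) entropyNull <- fit
  }
  new("NullModel", bootCounts = boot, bootEntropies = ent,
      entropyNull = entropyNull, weights = as.numeric(weights), seed = seed)
}

#' Maximum-likelihood Gamma fit
#'
#' Fits shape and scale by maximum likelihood (moment-matching
#' initialisation, Newton refinement of the shape on the profile likelihood).
#' Returns `NULL` as a degenerate marker when fewer than 2 distinct positive
#' values remain or the sample variance is essentially zero; callers then use
#' an empirical tail instead. Zeros are outside the Gamma support: for
#' entropy samples they are excluded upstream ([simulateNull()]), for count
#' samples a continuity offset is added upstream ([positionPvalues()]).
#'
#' @param samples Numeric vector of positive values.
#' @return `list(shape=, scale=)`, or `NULL` (degenerate).
#' @export
fitGamma <- function(samples) {
  samples <- samples[is.finite(samples) & samples > 0]
  if (length(samples) < 2L || length(unique(samples)) < 2L) return(NULL)
  m <- mean(samples)
  v <- stats::var(samples)
  if (v < 1e-12 * m^2) return(NULL)
  fit <- .gamma_mle(mean_x = m, mean_log = mean(log(samples)))
  if (is.null(fit$shape) || !is.finite(fit$shape)) return(NULL)
  list(shape = fit$shape, scale = fit$scale)
}

## vectorised Gamma MLE from sufficient statistics: solves
##   log(shape) - digamma(shape) = log(mean) - mean(log)
## Newton iterations on log-shape; works column-wise for thousands of fits.
.gamma_mle <- function(mean_x, mean_log) {
  s <- log(mean_x) - mean_log
  s <- pmax(s, 1e-12)
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)   # moment-style init
  for (it in 1:25) {
    f <- log(shape) - digamma(shape) - s
    fp <- 1 / shape - trigamma(shape)
    step <- f / (fp * shape)                               # Newton in log-space
    shape <- shape * exp(-pmax(pmin(step, 5), -5))
  }
  list(shape = shape, scale = mean_x / shape)
}

#' Global randomness p-value of the mutational profile
#'
#' Compares the observed entropy with the fitted Gamma null of the bootstrap
#' entropies. Clustering of mutations strictly lowers the entropy, so the
#' lower tail `P(H_null <= H_obs)` is reported: a small p-value means the
#' profile is far more concentrated than coverage-weighted chance allows.
#' When the Gamma fit was degenerate, the add-one empirical lower tail of the
#' bootstrap entropies is used.
#'
#' @param hObs Observed entropy ([shannonEntropy()]).
#' @param null A \linkS4class{NullModel}.
#' @return P-value in (0, 1].
#' @export
globalPvalue <- function(hObs, null) {
  g <- null@entropyNull
  if (is.null(g)) {
    b <- null@bootEntropies
    return((sum(b <= hObs) + 1) / (length(b) + 1))
  }
  pgamma(hObs, shape = g$shape, scale = g$scale)
}

#' Per-position hotspot p-values
#'
#' For every consensus column the null distribution of its mutation count is
#' taken from the bootstrap replicates: a Gamma distribution is fitted to the
#' replicate counts of that column (with a +0.5 continuity offset, since the
#' counts are discrete and the Gamma support is positive) and the upper tail
#' `P(X >= n_i)` is evaluated at `n_i - 0.5`. Columns whose replicate counts
#' are almost all zero (> 90%) are too sparse for a Gamma shape: they fall
#' back to the add-one empirical exceedance
#' `(#\{boot >= n_i\} + 1) / (n_boot + 1)`. Zero-weight columns (all-gap;
#' unmappable for a mutation) get p = 1.
#'
#' @param profile A \linkS4class{MutationProfile}, or a bare count vector of
#'   length `K` (convenient in calibration experiments).
#' @param null A \linkS4class{NullModel} simulated for the same `K` and `N`.
#' @return Numeric vector of `K` p-values in (0, 1].
#' @export
positionPvalues <- function(profile, null) {
  counts <- if (is(profile, "MutationProfile")) mutationCounts(profile)
            else profile
  boot <- null@bootCounts
  K <- ncol(boot)
  if (length(counts) != K)
    .stop_data("profile has %d columns but the null has %d", length(counts), K)
  nBoot <- nrow(boot)
  zero_frac <- colMeans(boot == 0L)
  p <- rep(1, K)
  gamma_cols <- which(null@weights > 0 & zero_frac <= 0.9)
  emp_cols <- which(null@weights > 0 & zero_frac > 0.9)
  if (length(gamma_cols)) {
    x <- boot[, gamma_cols, drop = FALSE] + 0.5
    fit <- .gamma_mle(mean_x = colMeans(x), mean_log = colMeans(log(x)))
    pv <- pgamma(counts[gamma_cols] - 0.5, shape = fit$shape,
                 scale = fit$scale, lower.tail = FALSE)
    ## degenerate columns (zero variance) -> empirical fallback
    degen <- !is.finite(pv) | apply(x, 2L, function(v) length(unique(v)) == 1L)
    p[gamma_cols] <- pv
    if (any(degen)) emp_cols <- c(emp_cols, gamma_cols[degen])
  }
  for (j in emp_cols)
    p[j] <- (sum(boot[, j] >= counts[j]) + 1) / (nBoot + 1)
  p[counts == 0L & null@weights > 0] <-
    pmax(p[counts == 0L & null@weights > 0], 1)
  pmin(p, 1)
}

#' Trident-gated Benjamini-Hochberg q-values
#'
#' The hotspot search targets conserved positions: only columns whose Trident
#' score exceeds the gate (default 0.1, strict) enter the BH correction; the
#' number of gated-in columns is the BH family size `m`. Gated-out columns
#' keep their p-value but receive no q-value (`NA`), so nothing disappears
#' silently from the report.
#'
#' @param pvals Per-column p-values.
#' @param trident Per-column Trident scores (same length).
#' @param gate Conservation gate (default 0.1; strict `>`).
#' @return Numeric vector of q-values, `NA` where gated out.
#' @export
correctQvalues <- function(pvals, trident, gate = 0.1) {
  if (length(pvals) != length(trident))
    .stop_data("pvals and trident must have equal length")
  gated <- trident > gate
  q <- rep(NA_real_, length(pvals))
  if (!any(gated)) {
    warning("no column passes the conservation gate; no q-values computed")
    return(q)
  }
  q[gated] <- p.adjust(pvals[gated], method = "BH")
  q
}

#' Call mutation hotspots on the consensus
#'
#' Assembles the full per-column report: observed pooled count, per-position
#' p-value ([positionPvalues()]), Trident-gated q-value ([correctQvalues()]),
#' significance at the q cutoff, and the contributing mutations reverse-mapped
#' to their original gene/position/sample/tumor-type via the pooled
#' provenance. The global entropy randomness p-value is attached.
#'
#' @param profile A \linkS4class{MutationProfile}.
#' @param consensus A \linkS4class{ConsensusProfile}.
#' @param null A \linkS4class{NullModel}.
#' @param aln The \linkS4class{ConsensusAlignment} the profile was pooled on.
#' @param alpha Q-value cutoff for the significant set (default 0.05).
#' @param gate Trident gate passed to [correctQvalues()].
#' @return A \linkS4class{HotspotTable}.
#' @export
callHotspots <- function(profile, consensus, null, aln,
                         alpha = 0.05, gate = 0.1) {
  counts <- mutationCounts(profile)
  K <- length(counts)
  p <- positionPvalues(profile, null)
  tr <- tridentScores(consensus)
  q <- correctQvalues(p, tr, gate = gate)
  prov <- mutationProvenance(profile)
  contributors <- vapply(seq_len(K), function(i) {
    rows <- prov[prov$column == i, , drop = FALSE]
    if (!nrow(rows)) return("")
    paste(sprintf("%s:%d:%s", rows$gene_symbol, rows$original_position,
                  rows$sample_id), collapse = ";")
  }, "")
  tab <- data.frame(
    column = seq_len(K),
    consensus_aa = consensusSequence(consensus),
    coverage = columnCoverage(consensus),
    trident = tr,
    count = counts,
    p = p,
    q = q,
    significant = !is.na(q) & q < alpha,
    contributors = contributors,
    stringsAsFactors = FALSE)
  new("HotspotTable", table = tab,
      globalP = globalPvalue(shannonEntropy(profile), null),
      meta = list(seed = null@seed, n_boot = nrow(null@bootCounts),
                  q_alpha = alpha, trident_gate = gate,
                  N = sum(counts), K = K))
}

#' Export a hotspot table as TSV with a run-metadata sidecar
#'
#' @param x A \linkS4class{HotspotTable}.
#' @param path Output TSV path; the metadata sidecar is written next to it as
#'   `<path>.meta.txt`.
#' @return Invisibly, `path`.
#' @export
writeHotspotTable <- function(x, path) {
  write.table(hotspotTable(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- x@meta
  lines <- c(sprintf("global_p: %.8g", globalP(x)),
             vapply(names(meta),
                    function(k) sprintf("%s: %s", k,
                                        paste(meta[[k]], collapse = ",")), ""))
  writeLines(lines, paste0(path, ".meta.txt"))
  invisible(path)
}
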