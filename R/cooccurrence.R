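## Mutual exclusivity / co-occurrence of mutated features across samples,
## stratified by tumor type: the probabilistic (hypergeometric) species
## co-occurrence model, plus a 2x2 Fisher exact test for domain-level
## exclusivity.

#' Binary sample-by-feature mutation presence matrix
#'
#' Builds the presence/absence matrix for one tumor-type stratum. At
#' `level = "gene"` the features are gene symbols; at `level = "position"`
#' they are significant consensus columns of a \linkS4class{HotspotTable}
#' (labelled `"column_<i>"`), and a sample is marked for a column if any of
#' its mutations maps there through the alignment. A sample mutated at
#' several hotspot columns contributes to each corresponding feature
#' (presence, not counts).
#'
#' @param muts Mutation `data.frame` (class-filtered).
#' @param level `"gene"` or `"position"`.
#' @param stratum Tumor-type label selecting the samples; `NULL` keeps all.
#' @param hotspots A \linkS4class{HotspotTable} (required for
#'   `level = "position"`).
#' @param aln The \linkS4class{ConsensusAlignment} (required for
#'   `level = "position"`).
#' @return Binary integer matrix, samples in rows, features in columns, with
#'   attribute `stratum`.
#' @export
buildPresenceMatrix <- function(muts, level = c("gene", "position"),
                                stratum = NULL, hotspots = NULL, aln = NULL) {
  level <- match.arg(level)
  if (!is.null(stratum)) {
    muts <- muts[muts$tumor_type == stratum, , drop = FALSE]
    if (nrow(muts) == 0L)
      warning("stratum '", stratum, "' contains no mutations")
  }
  if (level == "gene") {
    samples <- sort(unique(muts$sample_id))
    features <- sort(unique(muts$gene_symbol))
    M <- matrix(0L, length(samples), length(features),
                dimnames = list(samples, features))
    if (nrow(muts))
      M[cbind(match(muts$sample_id, samples),
              match(muts$gene_symbol, features))] <- 1L
  } else {
    if (is.null(hotspots) || is.null(aln))
      .stop_config("level = 'position' requires hotspots and aln")
    sig <- significantHotspots(hotspots,
                               alpha = hotspots@meta$q_alpha %||% 0.05)
    cols <- sig$column
    samples <- sort(unique(muts$sample_id))
    features <- paste0("column_", cols)
    M <- matrix(0L, length(samples), length(features),
                dimnames = list(samples, features))
    if (nrow(muts) && length(cols)) {
      rows <- alignmentRows(aln)
      offs <- memberOffsets(aln)
      for (i in seq_len(nrow(muts))) {
        g <- muts$gene_symbol[i]
        if (!(g %in% names(rows))) next
        frag_pos <- muts$position[i] - offs[[g]] + 1L
        rc <- .residue_columns(.chars(rows[[g]]))
        if (frag_pos < 1L || frag_pos > length(rc)) next
        hit <- match(rc[frag_pos], cols)
        if (!is.na(hit)) M[match(muts$sample_id[i], samples), hit] <- 1L
      }
    }
  }
  attr(M, "stratum") <- stratum %||% "all"
  M
}

#' Exact co-occurrence probabilities for one feature pair
#'
#' Probabilistic model of random placement: given `n_sites` samples of which
#' `n_a` carry feature A and `n_b` carry feature B, the number `J` of samples
#' carrying both is hypergeometric,
#' `P(J = j) = C(n_a, j) C(n_sites - n_a, n_b - j) / C(n_sites, n_b)`.
#' Both reported tails include the observed point mass:
#' `p_lt = P(J <= j_obs)` supports a mutual-exclusivity call (fewer co-mutated
#' samples than chance), `p_gt = P(J >= j_obs)` a co-occurrence call.
#'
#' @param nSites Number of samples in the stratum.
#' @param nA,nB Number of samples mutated in features A and B.
#' @param jObs Observed number of co-mutated samples.
#' @return Named list `p_lt`, `p_gt`, `expected` (= `nA * nB / nSites`).
#' @export
#' @examples
#' pairProbabilities(4, 2, 2, 0)  # p_lt = 1/6
pairProbabilities <- function(nSites, nA, nB, jObs) {
  if (nA < 0 || nB < 0 || nA > nSites || nB > nSites)
    .stop_data("infeasible marginals: nA=%d nB=%d nSites=%d", nA, nB, nSites)
  lo <- max(0L, nA + nB - nSites)
  hi <- min(nA, nB)
  if (jObs < lo || jObs > hi)
    .stop_data("infeasible co-occurrence count jObs=%d (support [%d, %d])",
               jObs, lo, hi)
  list(p_lt = phyper(jObs, nA, nSites - nA, nB),
       p_gt = phyper(jObs - 1, nA, nSites - nA, nB, lower.tail = FALSE),
       expected = nA * nB / nSites)
}

#' Pairwise mutual-exclusivity / co-occurrence analysis
#'
#' Scores every feature pair of a presence matrix with
#' [pairProbabilities()], corrects the two tails across pairs (default BH,
#' within the stratum), and calls each pair `mutually_exclusive` when the
#' adjusted lower tail is below `alpha`, `co_occurring` when the adjusted
#' upper tail is, and `neutral` otherwise. Pairs whose expected co-occurrence
#' is below 1 are flagged low-power (too rare to ever reach significance).
#'
#' @param M Presence matrix from [buildPresenceMatrix()].
#' @param alpha Significance cutoff on the corrected p-values (default 0.05).
#' @param correction `"BH"` (default), `"bonferroni"` or `"none"`.
#' @return `data.frame` of \code{PairResult} rows: `feature_a`, `feature_b`,
#'   `stratum`, `n_sites`, `n_a`, `n_b`, `j_obs`, `expected`, `p_lt`, `p_gt`,
#'   `p_lt_adj`, `p_gt_adj`, `low_power`, `call`.
#' @export
cooccurAnalysis <- function(M, alpha = 0.05,
                            correction = c("BH", "bonferroni", "none")) {
  correction <- match.arg(correction)
  if (ncol(M) < 2L)
    .stop_data("pairwise analysis needs at least 2 features")
  nSites <- nrow(M)
  pairs <- combn(colnames(M), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    nA <- sum(M[, a]); nB <- sum(M[, b]); j <- sum(M[, a] & M[, b])
    pp <- pairProbabilities(nSites, nA, nB, j)
    data.frame(feature_a = a, feature_b = b,
               stratum = attr(M, "stratum") %||% "all",
               n_sites = nSites, n_a = nA, n_b = nB, j_obs = j,
               expected = pp$expected, p_lt = pp$p_lt, p_gt = pp$p_gt,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  adj <- if (correction == "none") "none" else correction
  res$p_lt_adj <- p.adjust(res$p_lt, method = adj)
  res$p_gt_adj <- p.adjust(res$p_gt, method = adj)
  res$low_power <- res$expected < 1
  res$call <- ifelse(res$p_lt_adj < alpha, "mutually_exclusive",
              ifelse(res$p_gt_adj < alpha, "co_occurring", "neutral"))
  res
}

#' Fisher exact test on a 2x2 contingency table
#'
#' Conditional exact test on fixed margins, used for domain-level exclusivity
#' (e.g. samples mutated in one kinase domain class versus another). The
#' reported odds ratio is the sample odds ratio `(a d) / (b c)`; when `b c`
#' is 0 and `a d` positive it is `Inf`, and `NaN` when both products vanish.
#'
#' @param a,b,c,d Non-negative cell counts (row-wise).
#' @return Named list `odds_ratio`, `p` (two-sided).
#' @export
fisher2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) .stop_data("negative cell count")
  if (sum(cells) == 0) .stop_data("all-zero contingency table")
  ft <- fisher.test(matrix(cells, nrow = 2L, byrow = TRUE))
  or <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c)
  list(odds_ratio = or, p = ft$p.value)
}
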