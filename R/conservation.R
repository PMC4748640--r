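## Per-column Trident conservation and pairwise k-tuple sequence homogeneity.

## normalized BLOSUM62 distance between residue pairs:
##   s(a,b) = B(a,b) / sqrt(B(a,a) * B(b,b))   (identical residues -> 1)
##   d(a,b) = (1 - s(a,b)) / (1 - min s)       (most dissimilar pair -> 1)
.blosum_distance <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      B <- .blosum62()[AA_LETTERS, AA_LETTERS]
      s <- B / sqrt(outer(diag(B), diag(B)))
      d <- (1 - s) / (1 - min(s))
      diag(d) <- 0
      cache <<- d
    }
    cache
  }
})

#' Trident conservation score of one alignment column
#'
#' A composite per-column conservation measure combining three aspects of the
#' column:
#' \describe{
#'   \item{`t_entropy`}{residue diversity: Shannon entropy of the non-gap
#'     residues, normalised by `log(min(n, 20))` so it lies in `[0, 1]` (the
#'     more distinct residues, the less conserved);}
#'   \item{`r_chemical`}{chemical diversity: mean pairwise distance of the
#'     non-gap residues under a BLOSUM62-derived metric, rescaled so identical
#'     pairs score 0 and the most dissimilar BLOSUM62 pair scores 1;}
#'   \item{`g_gap`}{relative gap frequency in the column.}
#' }
#' The combined score is
#' `(1 - t_entropy)^alpha * (1 - r_chemical)^beta * (1 - g_gap)^gamma`,
#' defaulting to exponents `(1, 0.5, 3)`, the weights recommended for this
#' family of scores. An all-gap column scores 0 (fully unconserved by
#' convention). Entropy and chemical diversity are computed on the non-gap
#' residues only; the gap term uses the full column height.
#'
#' @param column Character vector of residues and `"-"` gaps (one alignment
#'   column, any order).
#' @param exponents Numeric triple `(alpha, beta, gamma)`.
#' @return Named list with `t_entropy`, `r_chemical`, `g_gap`, `score`, all in
#'   `[0, 1]`.
#' @export
#' @examples
#' columnTrident(c("G", "G", "G", "G", "A"))
columnTrident <- function(column, exponents = c(1, 0.5, 3)) {
  stopifnot(length(column) >= 1L, length(exponents) == 3L)
  gaps <- column == "-"
  g_gap <- mean(gaps)
  res <- column[!gaps]
  if (!length(res))
    return(list(t_entropy = 1, r_chemical = 1, g_gap = 1, score = 0))
  n <- length(res)
  tab <- table(res)
  p <- as.numeric(tab) / n
  H <- -sum(p * log(p))
  denom <- log(min(n, 20L))
  t_entropy <- if (denom > 0) min(H / denom, 1) else 0
  if (n == 1L) {
    r_chemical <- 0
  } else {
    D <- .blosum_distance()
    idx <- match(res, AA_LETTERS)
    if (anyNA(idx)) {              # non-canonical letters (X): max distance
      r_chemical <- 1
    } else {
      pairs <- combn(idx, 2L)
      r_chemical <- mean(D[cbind(pairs[1L, ], pairs[2L, ])])
    }
  }
  score <- (1 - t_entropy)^exponents[1L] *
           (1 - r_chemical)^exponents[2L] *
           (1 - g_gap)^exponents[3L]
  list(t_entropy = t_entropy, r_chemical = r_chemical, g_gap = g_gap,
       score = score)
}

#' Per-column Trident scores of an alignment
#'
#' @param aln A \linkS4class{ConsensusAlignment}.
#' @param exponents See [columnTrident()].
#' @return Numeric vector of length `K` in `[0, 1]`.
#' @export
tridentProfile <- function(aln, exponents = c(1, 0.5, 3)) {
  M <- .aln_matrix(aln)
  vapply(seq_len(ncol(M)),
         function(i) columnTrident(M[, i], exponents)$score, 0)
}

#' k-tuple similarity of two amino-acid sequences
#'
#' The number of distinct length-`k` subsequences shared by the two sequences,
#' divided by the number of distinct `k`-tuples of the shorter sequence; a
#' fast alignment-free similarity in `[0, 1]`. If either sequence is shorter
#' than `k` the measure degenerates to an exact-match indicator.
#'
#' @param seqA,seqB Amino-acid strings.
#' @param k Tuple length (default 3, tripeptides).
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' ktupleSimilarity("ACDEF", "ACDGG", k = 3)  # 1/3
ktupleSimilarity <- function(seqA, seqB, k = 3L) {
  seqA <- as.character(seqA); seqB <- as.character(seqB)
  if (nchar(seqA) < k || nchar(seqB) < k)
    return(as.numeric(seqA == seqB))
  tuples <- function(s)
    unique(substring(s, seq_len(nchar(s) - k + 1L),
                     seq_len(nchar(s) - k + 1L) + k - 1L))
  ta <- tuples(seqA); tb <- tuples(seqB)
  shorter <- if (nchar(seqA) <= nchar(seqB)) ta else tb
  length(intersect(ta, tb)) / length(shorter)
}

#' Warn about members too dissimilar from the rest of the family
#'
#' Including a sequence that differs too much from the others can invalidate
#' the consensus analysis: its residues align poorly and drag the column frame
#' around. As a safety net, each member's mean k-tuple similarity to all other
#' members is computed, and members below the threshold (default 0.2) produce
#' a named warning. The analysis proceeds regardless.
#'
#' @param family A \linkS4class{ProteinFamily} (at least 2 members).
#' @param threshold Similarity floor below which a member is flagged.
#' @param k Tuple length for [ktupleSimilarity()].
#' @return Invisibly, a `data.frame` with `gene_symbol`, `mean_similarity`,
#'   `flagged`; flagged members also raise R warnings.
#' @export
checkHomogeneity <- function(family, threshold = 0.2, k = 3L) {
  seqs <- as.character(familySequences(family))
  n <- length(seqs)
  if (n < 2L) .stop_data("homogeneity check needs at least 2 members")
  sim <- matrix(1, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      sim[i, j] <- sim[j, i] <- ktupleSimilarity(seqs[i], seqs[j], k = k)
  mean_sim <- (rowSums(sim) - 1) / (n - 1)
  flagged <- mean_sim < threshold
  for (i in which(flagged))
    warning(sprintf(
      "member '%s' differs too much from the rest of the family (mean k-tuple similarity %.3f < %.3f)",
      names(seqs)[i], mean_sim[i], threshold), call. = FALSE)
  invisible(data.frame(gene_symbol = names(seqs), mean_similarity = mean_sim,
                       flagged = flagged, stringsAsFactors = FALSE))
}
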