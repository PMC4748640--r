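#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern alignedSubject
#' @importFrom stats rmultinom pgamma qgamma phyper fisher.test p.adjust
#'   rpois runif setNames
#' @importFrom utils read.delim write.table combn packageVersion
NULL

AA_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")

#' ProteinFamily: a set of family members to be aligned together
#'
#' Holds the amino-acid sequences of the members of one protein family
#' (typically the human members of a Pfam domain family), optional domain
#' annotations, and the 1-based offset of each stored fragment on its
#' full-length protein (1 when the whole protein is stored, the domain start
#' when sequences were trimmed to a domain).
#'
#' @slot sequences An [Biostrings::AAStringSet] named by gene symbol; gap-free.
#' @slot domains A `data.frame` with columns `gene_symbol`, `family_id`,
#'   `start`, `end` (1-based inclusive residue coordinates on the full
#'   protein). May have zero rows.
#' @slot offsets Named integer vector, one entry per member: 1-based position
#'   of the first stored residue on the full-length protein.
#'
#' @seealso [readFamily()], [alignFamily()], [generateFamily()]
#' @export
setClass("ProteinFamily",
  representation(sequences = "AAStringSet",
                 domains   = "data.frame",
                 offsets   = "integer"))

setValidity("ProteinFamily", function(object) {
  msg <- character()
  nm <- names(object@sequences)
  if (is.null(nm) || any(nm == "") || anyNA(nm))
    msg <- c(msg, "all sequences must be named by gene symbol")
  else if (anyDuplicated(nm))
    msg <- c(msg, sprintf("duplicate gene symbol: %s",
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  seqs <- as.character(object@sequences)
  if (any(grepl("-", seqs, fixed = TRUE)))
    msg <- c(msg, "sequences must not contain gap characters")
  if (length(object@offsets) != length(object@sequences) ||
      !identical(names(object@offsets), nm))
    msg <- c(msg, "offsets must be named one-to-one with sequences")
  if (length(object@offsets) && any(object@offsets < 1L))
    msg <- c(msg, "offsets must be >= 1")
  d <- object@domains
  need <- c("gene_symbol", "family_id", "start", "end")
  if (!all(need %in% names(d)))
    msg <- c(msg, "domains must have columns gene_symbol, family_id, start, end")
  else if (nrow(d)) {
    if (any(d$start < 1L | d$start > d$end))
      msg <- c(msg, "domain spans must satisfy 1 <= start <= end")
    known <- d$gene_symbol %in% nm
    if (any(known)) {
      lens <- setNames(Biostrings::width(object@sequences), nm)
      full_len <- lens[d$gene_symbol[known]] + object@offsets[d$gene_symbol[known]] - 1L
      if (any(d$end[known] > full_len))
        msg <- c(msg, "domain spans must fall within the protein length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusAlignment: a multiple alignment in a fixed column frame
#'
#' A multiple alignment of family members whose columns define the shared
#' consensus coordinate system that mutations are pooled onto. Rows are
#' equal-length gapped amino-acid strings; degapping a row reproduces the
#' member's input fragment exactly. The column frame (alignment length `K`) is
#' stable under member subsetting so that hotspot positions remain comparable
#' between full-family and subfamily analyses.
#'
#' @slot rows Named character vector of equal-length gapped rows (gap `"-"`).
#' @slot offsets Named integer vector: 1-based start of each member's aligned
#'   fragment on the full-length protein (see [ProteinFamily]).
#'
#' @seealso [alignFamily()], [subsetMembers()], [mapToConsensus()],
#'   [reverseMap()]
#' @export
setClass("ConsensusAlignment",
  representation(rows = "character", offsets = "integer"))

setValidity("ConsensusAlignment", function(object) {
  msg <- character()
  nm <- names(object@rows)
  if (length(object@rows) == 0L) msg <- c(msg, "alignment has no rows")
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    msg <- c(msg, "rows must be uniquely named by gene symbol")
  if (length(unique(nchar(object@rows))) > 1L)
    msg <- c(msg, "all rows must have equal length")
  if (!identical(names(object@offsets), nm))
    msg <- c(msg, "offsets must be named one-to-one with rows")
  if (length(msg)) msg else TRUE
})

#' ConsensusProfile: per-column consensus residue, coverage and conservation
#'
#' @slot consensus Character vector of length `K`: modal non-gap residue per
#'   column (`"-"` only for all-gap columns).
#' @slot coverage Integer vector of length `K`: number of non-gap residues per
#'   column; these are the sampling weights of the bootstrap null.
#' @slot trident Numeric vector of length `K` in `[0, 1]`: per-column Trident
#'   conservation score.
#'
#' @seealso [buildConsensus()], [tridentProfile()], [samplingWeights()]
#' @export
setClass("ConsensusProfile",
  representation(consensus = "character",
                 coverage  = "integer",
                 trident   = "numeric"))

setValidity("ConsensusProfile", function(object) {
  msg <- character()
  K <- length(object@consensus)
  if (length(object@coverage) != K || length(object@trident) != K)
    msg <- c(msg, "consensus, coverage and trident must have equal length")
  if (any(object@coverage < 0L))
    msg <- c(msg, "coverage must be non-negative")
  if (any((object@coverage == 0L) != (object@consensus == "-")))
    msg <- c(msg, "consensus must be '-' exactly on zero-coverage columns")
  tr <- object@trident[!is.na(object@trident)]
  if (any(tr < 0 | tr > 1))
    msg <- c(msg, "trident scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MutationProfile: pooled per-column mutation counts with provenance
#'
#' @slot counts Integer vector of length `K`: pooled mutation count per
#'   consensus column.
#' @slot provenance `data.frame` with one row per pooled mutation: `column`,
#'   `gene_symbol`, `original_position` (1-based on the full protein),
#'   `sample_id`, `tumor_type`.
#' @slot diagnostics Named integer vector counting excluded records by reason
#'   (`unknown_gene`, `out_of_fragment`, `gap_position`).
#'
#' @seealso [poolMutations()], [shannonEntropy()]
#' @export
setClass("MutationProfile",
  representation(counts = "integer",
                 provenance = "data.frame",
                 diagnostics = "integer"))

setValidity("MutationProfile", function(object) {
  msg <- character()
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (sum(object@counts) != nrow(object@provenance))
    msg <- c(msg, "sum(counts) must equal the number of provenance rows")
  if (nrow(object@provenance) &&
      !all(object@provenance$column >= 1L &
           object@provenance$column <= length(object@counts)))
    msg <- c(msg, "provenance columns must lie within [1, K]")
  if (length(msg)) msg else TRUE
})

#' NullModel: the coverage-weighted bootstrap null of the mutational profile
#'
#' Bootstrap replicates redistribute the observed `N` mutations over the `K`
#' consensus columns by a multinomial draw with coverage-proportional
#' probabilities; a Gamma distribution fitted to the replicate entropies is the
#' null for the global randomness test, and per-column Gamma fits to the
#' replicate counts are the nulls for the per-position hotspot test.
#'
#' @slot bootCounts Integer matrix, `n_boot` rows by `K` columns; every row
#'   sums to `N`.
#' @slot bootEntropies Numeric vector of length `n_boot`.
#' @slot entropyNull Named list `list(shape=, scale=)`, or `NULL` when the
#'   Gamma fit was degenerate and the empirical tail is used instead.
#' @slot weights Numeric sampling-probability vector of length `K`.
#' @slot seed Integer seed the replicates were drawn under.
#'
#' @seealso [simulateNull()], [globalPvalue()], [positionPvalues()]
#' @export
setClass("NullModel",
  representation(bootCounts = "matrix",
                 bootEntropies = "numeric",
                 entropyNull = "ANY",
                 weights = "numeric",
                 seed = "integer"))

setValidity("NullModel", function(object) {
  msg <- character()
  if (ncol(object@bootCounts) != length(object@weights))
    msg <- c(msg, "bootCounts must have one column per weight")
  rs <- rowSums(object@bootCounts)
  if (length(unique(rs)) > 1L)
    msg <- c(msg, "every bootstrap replicate must conserve N")
  if (any(object@bootCounts[, object@weights == 0, drop = FALSE] != 0L))
    msg <- c(msg, "zero-weight columns must have all-zero bootstrap counts")
  if (length(msg)) msg else TRUE
})

#' HotspotTable: per-column hotspot test results
#'
#' The full per-column report of a family analysis: observed pooled count,
#' per-position p-value, Trident-gated Benjamini-Hochberg q-value (`NA` where
#' the column is gated out by conservation), and the contributing mutations
#' reverse-mapped to their original protein coordinates. Access the table with
#' [hotspotTable()], the global randomness p-value with [globalP()] and the
#' significant subset with [significantHotspots()].
#'
#' @slot table `data.frame` with columns `column`, `consensus_aa`, `coverage`,
#'   `trident`, `count`, `p`, `q`, `significant`, `contributors`.
#' @slot globalP Numeric: p-value of the global entropy randomness test.
#' @slot meta Named list of run metadata (seed, n_boot, thresholds, filters).
#'
#' @export
setClass("HotspotTable",
  representation(table = "data.frame", globalP = "numeric", meta = "list"))

setValidity("HotspotTable", function(object) {
  msg <- character()
  need <- c("column", "consensus_aa", "coverage", "trident", "count",
            "p", "q", "significant", "contributors")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
  else {
    ok <- !is.na(object@table$q)
    if (any(object@table$q[ok] < object@table$p[ok] - 1e-12))
      msg <- c(msg, "q-values must be >= their p-values")
  }
  if (length(msg)) msg else TRUE
})
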