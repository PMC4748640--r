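#' @rdname ProteinFamily-class
#' @param object,x A \linkS4class{ProteinFamily}.
#' @export
setGeneric("familySequences", function(x) standardGeneric("familySequences"))

#' @rdname ProteinFamily-class
#' @export
setGeneric("familyDomains", function(x) standardGeneric("familyDomains"))

#' @rdname ProteinFamily-class
#' @export
setGeneric("memberOffsets", function(x) standardGeneric("memberOffsets"))

#' @rdname ConsensusAlignment-class
#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))

#' @rdname ConsensusAlignment-class
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' @rdname ConsensusAlignment-class
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @rdname ConsensusProfile-class
#' @export
setGeneric("consensusSequence", function(x) standardGeneric("consensusSequence"))

#' @rdname ConsensusProfile-class
#' @export
setGeneric("columnCoverage", function(x) standardGeneric("columnCoverage"))

#' @rdname ConsensusProfile-class
#' @export
setGeneric("tridentScores", function(x) standardGeneric("tridentScores"))

#' @rdname MutationProfile-class
#' @export
setGeneric("mutationCounts", function(x) standardGeneric("mutationCounts"))

#' @rdname MutationProfile-class
#' @export
setGeneric("mutationProvenance",
           function(x) standardGeneric("mutationProvenance"))

#' @rdname MutationProfile-class
#' @export
setGeneric("totalMutations", function(x) standardGeneric("totalMutations"))

#' Diagnostics attached to a parsed or pooled object
#'
#' Readers and pooling operations never fail silently: every skipped or
#' excluded record is tallied by reason. `diagnostics()` returns that tally.
#'
#' @param x An object carrying a diagnostics tally (a mutation table returned
#'   by [readMutations()]/[validateMutations()], or a
#'   \linkS4class{MutationProfile}).
#' @return Named integer vector of exclusion counts by reason.
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname HotspotTable-class
#' @export
setGeneric("hotspotTable", function(x) standardGeneric("hotspotTable"))

#' @rdname HotspotTable-class
#' @export
setGeneric("globalP", function(x) standardGeneric("globalP"))

#' @rdname HotspotTable-class
#' @param alpha Q-value cutoff used by `significantHotspots`.
#' @export
setGeneric("significantHotspots",
           function(x, alpha = 0.05) standardGeneric("significantHotspots"))

## ---- accessors -------------------------------------------------------------

#' @rdname ProteinFamily-class
#' @export
setMethod("familySequences", "ProteinFamily", function(x) x@sequences)

#' @rdname ProteinFamily-class
#' @export
setMethod("familyDomains", "ProteinFamily", function(x) x@domains)

#' @rdname ProteinFamily-class
#' @export
setMethod("memberOffsets", "ProteinFamily", function(x) x@offsets)

#' @rdname ConsensusAlignment-class
#' @export
setMethod("alignmentRows", "ConsensusAlignment", function(x) x@rows)

#' @rdname ConsensusAlignment-class
#' @export
setMethod("memberIds", "ConsensusAlignment", function(x) names(x@rows))

#' @rdname ConsensusAlignment-class
#' @export
setMethod("alignmentLength", "ConsensusAlignment",
          function(x) nchar(x@rows[[1L]]))

#' @rdname ConsensusAlignment-class
#' @export
setMethod("memberOffsets", "ConsensusAlignment", function(x) x@offsets)

#' @rdname ConsensusProfile-class
#' @export
setMethod("consensusSequence", "ConsensusProfile", function(x) x@consensus)

#' @rdname ConsensusProfile-class
#' @export
setMethod("columnCoverage", "ConsensusProfile", function(x) x@coverage)

#' @rdname ConsensusProfile-class
#' @export
setMethod("tridentScores", "ConsensusProfile", function(x) x@trident)

#' @rdname MutationProfile-class
#' @export
setMethod("mutationCounts", "MutationProfile", function(x) x@counts)

#' @rdname MutationProfile-class
#' @export
setMethod("mutationProvenance", "MutationProfile", function(x) x@provenance)

#' @rdname MutationProfile-class
#' @export
setMethod("totalMutations", "MutationProfile", function(x) sum(x@counts))

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "MutationProfile", function(x) x@diagnostics)

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "data.frame", function(x) {
  d <- attr(x, "diagnostics")
  if (is.null(d)) integer(0) else d
})

#' @rdname HotspotTable-class
#' @export
setMethod("hotspotTable", "HotspotTable", function(x) x@table)

#' @rdname HotspotTable-class
#' @export
setMethod("globalP", "HotspotTable", function(x) x@globalP)

#' @rdname HotspotTable-class
#' @export
setMethod("significantHotspots", "HotspotTable", function(x, alpha = 0.05) {
  tab <- x@table
  tab[!is.na(tab$q) & tab$q < alpha, , drop = FALSE]
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "ProteinFamily", function(object) {
  n <- length(object@sequences)
  cat(sprintf("ProteinFamily with %d member%s\n", n, if (n == 1) "" else "s"))
  w <- Biostrings::width(object@sequences)
  cat(sprintf("  sequence length: %d..%d\n", min(w), max(w)))
  if (nrow(object@domains))
    cat(sprintf("  domain annotations: %d span%s (%s)\n",
                nrow(object@domains),
                if (nrow(object@domains) == 1) "" else "s",
                paste(unique(object@domains$family_id), collapse = ", ")))
  if (any(object@offsets != 1L))
    cat("  sequences are domain-trimmed fragments (offsets recorded)\n")
})

setMethod("show", "ConsensusAlignment", function(object) {
  cat(sprintf("ConsensusAlignment: %d members, %d columns\n",
              length(object@rows), alignmentLength(object)))
  gaps <- sum(vapply(object@rows,
                     function(r) sum(strsplit(r, "")[[1]] == "-"), 0L))
  cat(sprintf("  gap characters: %d\n", gaps))
})

setMethod("show", "ConsensusProfile", function(object) {
  cat(sprintf("ConsensusProfile over %d columns\n", length(object@consensus)))
  cat(sprintf("  mean coverage %.2f, mean Trident %.3f\n",
              mean(object@coverage), mean(object@trident, na.rm = TRUE)))
})

setMethod("show", "MutationProfile", function(object) {
  cat(sprintf("MutationProfile: N = %d mutations over %d columns (%d mutated)\n",
              sum(object@counts), length(object@counts),
              sum(object@counts > 0L)))
  if (sum(object@diagnostics) > 0L)
    cat("  excluded:",
        paste(sprintf("%s=%d", names(object@diagnostics), object@diagnostics),
              collapse = ", "), "\n")
})

setMethod("show", "NullModel", function(object) {
  cat(sprintf("NullModel: %d bootstrap replicates, K = %d, N = %d (seed %d)\n",
              nrow(object@bootCounts), ncol(object@bootCounts),
              if (nrow(object@bootCounts)) sum(object@bootCounts[1L, ]) else 0L,
              object@seed))
  if (is.null(object@entropyNull))
    cat("  global null: empirical tail (degenerate Gamma fit)\n")
  else
    cat(sprintf("  global null: Gamma(shape = %.3f, scale = %.4f)\n",
                object@entropyNull$shape, object@entropyNull$scale))
})

setMethod("show", "HotspotTable", function(object) {
  sig <- significantHotspots(object,
                             alpha = object@meta$q_alpha %||% 0.05)
  cat(sprintf("HotspotTable over %d columns; global p = %.4g\n",
              nrow(object@table), object@globalP))
  cat(sprintf("  significant hotspots (q < %.2g): %d\n",
              object@meta$q_alpha %||% 0.05, nrow(sig)))
  if (nrow(sig))
    cat("  columns:", paste(utils::head(sig$column, 10), collapse = ", "),
        if (nrow(sig) > 10) "..." else "", "\n")
})
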