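## Multiple alignment of family members, consensus construction, and the
## bidirectional residue <-> consensus-column coordinate maps.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

## center-star progressive alignment: align every member to the center with
## global affine-gap pairwise alignment, then merge under "once a gap, always
## a gap".  Deterministic: the center is the member with the highest summed
## pairwise score (ties -> first in input order).
.center_star <- function(seqs) {
  n <- length(seqs)
  if (n == 1L) return(setNames(as.character(seqs), names(seqs)))
  mat <- .blosum62()
  chr <- as.character(seqs)
  if (length(unique(chr)) == 1L)
    return(setNames(chr, names(seqs)))
  ## pairwise scores of every member against every other
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    sc <- pairwiseAlignment(AAStringSet(chr[(i + 1L):n]),
                            Biostrings::AAString(chr[i]), type = "global",
                            substitutionMatrix = mat,
                            gapOpening = 10, gapExtension = 0.5,
                            scoreOnly = TRUE)
    score[i, (i + 1L):n] <- sc
    score[(i + 1L):n, i] <- sc
  }
  center <- which.max(rowSums(score))
  others <- setdiff(seq_len(n), center)
  c_len <- nchar(chr[center])
  ## per pairwise alignment: gaps inserted into the center row before center
  ## residue k (slot k in 1..c_len) or after the last residue (slot c_len+1)
  ins <- matrix(0L, nrow = length(others), ncol = c_len + 1L)
  aligned_pat <- character(length(others))
  for (j in seq_along(others)) {
    pa <- pairwiseAlignment(Biostrings::AAString(chr[others[j]]),
                            Biostrings::AAString(chr[center]),
                            type = "global", substitutionMatrix = mat,
                            gapOpening = 10, gapExtension = 0.5)
    csub <- .chars(as.character(alignedSubject(pa)))  # center, gapped
    aligned_pat[j] <- as.character(alignedPattern(pa))
    slot <- 1L; run <- 0L
    for (ch in csub) {
      if (ch == "-") run <- run + 1L
      else { ins[j, slot] <- run; run <- 0L; slot <- slot + 1L }
    }
    ins[j, c_len + 1L] <- run
  }
  merged <- apply(ins, 2L, max)
  pad <- function(gapped_row, row_ins) {
    out <- character(0); pos <- 1L; rc <- .chars(gapped_row); ri <- 1L
    for (slot in seq_len(c_len + 1L)) {
      take <- row_ins[slot]
      if (take > 0L) { out <- c(out, rc[ri:(ri + take - 1L)]); ri <- ri + take }
      out <- c(out, rep("-", merged[slot] - take))
      if (slot <= c_len) { out <- c(out, rc[ri]); ri <- ri + 1L }
    }
    paste(out, collapse = "")
  }
  rows <- character(n)
  rows[center] <- pad(chr[center], rep(0L, c_len + 1L))
  for (j in seq_along(others))
    rows[others[j]] <- pad(aligned_pat[j], ins[j, ])
  setNames(rows, names(seqs))
}

#' Align a protein family into a consensus coordinate frame
#'
#' Produces a \linkS4class{ConsensusAlignment} from family member sequences.
#' Three backends are supported:
#' \describe{
#'   \item{`builtin`}{A deterministic center-star progressive alignment whose
#'     pairwise steps are global BLOSUM62 affine-gap alignments
#'     ([Biostrings::pairwiseAlignment]). It is adequate for small-to-medium
#'     families and for fully reproducible test runs; it is not a Clustal
#'     Omega reimplementation, and its use is recorded in the run metadata.}
#'   \item{`external`}{Shells out to a Clustal-Omega-compatible executable
#'     (`exe -i <in.fasta> -o <out.fasta> --force`).}
#'   \item{`prealigned`}{Ingests an existing aligned FASTA whose degapped rows
#'     must reproduce the family sequences exactly.}
#' }
#'
#' @param family A \linkS4class{ProteinFamily}.
#' @param backend `"builtin"` (default), `"external"` or `"prealigned"`.
#' @param prealignedPath Aligned FASTA path (backend `"prealigned"`).
#' @param exe Executable name/path (backend `"external"`).
#' @return A \linkS4class{ConsensusAlignment}.
#' @export
alignFamily <- function(family,
                        backend = c("builtin", "external", "prealigned"),
                        prealignedPath = NULL, exe = "clustalo") {
  backend <- match.arg(backend)
  seqs <- familySequences(family)
  if (length(seqs) < 1L) .stop_data("cannot align an empty family")
  rows <- switch(backend,
    builtin = .center_star(seqs),
    external = {
      if (Sys.which(exe) == "")
        .stop_config(paste0(
          "external aligner '%s' not found on PATH; use backend = ",
          "'prealigned' with an existing aligned FASTA, or backend = ",
          "'builtin'"), exe)
      tin <- tempfile(fileext = ".fasta"); tout <- tempfile(fileext = ".fasta")
      writeXStringSet(seqs, tin)
      status <- system2(exe, c("-i", tin, "-o", tout, "--force"))
      if (status != 0L || !file.exists(tout))
        .stop_data("external aligner '%s' failed (exit %d)", exe, status)
      a <- readAAStringSet(tout)
      setNames(as.character(a),
               vapply(strsplit(names(a), "\\s+"), `[`, "", 1L))
    },
    prealigned = {
      if (is.null(prealignedPath))
        .stop_config("backend 'prealigned' requires prealignedPath")
      a <- readAAStringSet(prealignedPath)
      setNames(as.character(a),
               vapply(strsplit(names(a), "\\s+"), `[`, "", 1L))
    })
  want <- names(seqs)
  if (!all(want %in% names(rows)))
    .stop_data("alignment lacks member(s): %s",
               paste(setdiff(want, names(rows)), collapse = ", "))
  rows <- rows[want]
  degapped <- gsub("-", "", rows, fixed = TRUE)
  bad <- which(degapped != as.character(seqs))
  if (length(bad))
    .stop_data("aligned row inconsistent with input sequence for member: %s",
               paste(want[bad], collapse = ", "))
  new("ConsensusAlignment", rows = rows, offsets = memberOffsets(family))
}

#' Build the consensus profile of an alignment
#'
#' For every column: the consensus residue is the most frequent non-gap
#' residue (ties broken alphabetically; a gap becomes consensus only for
#' all-gap columns), the coverage is the number of non-gap residues (these are
#' the sampling weights of the bootstrap null), and the Trident conservation
#' score is computed with [tridentProfile()].
#'
#' @param aln A \linkS4class{ConsensusAlignment}.
#' @param exponents Trident exponents, see [columnTrident()].
#' @return A \linkS4class{ConsensusProfile}.
#' @export
buildConsensus <- function(aln, exponents = c(1, 0.5, 3)) {
  M <- .aln_matrix(aln)
  K <- ncol(M)
  consensus <- character(K)
  coverage <- integer(K)
  for (i in seq_len(K)) {
    col <- M[, i]
    res <- col[col != "-"]
    coverage[i] <- length(res)
    if (!length(res)) { consensus[i] <- "-"; next }
    tab <- table(res)
    top <- names(tab)[tab == max(tab)]
    consensus[i] <- sort(top)[1L]   # alphabetical tie-break
  }
  new("ConsensusProfile", consensus = consensus, coverage = coverage,
      trident = tridentProfile(aln, exponents = exponents))
}

.aln_matrix <- function(aln) {
  rows <- alignmentRows(aln)
  do.call(rbind, lapply(rows, .chars))
}

#' Map a member residue to its consensus column
#'
#' @param aln A \linkS4class{ConsensusAlignment}.
#' @param member Gene symbol of a member.
#' @param position 1-based residue index on the member's aligned fragment.
#' @return 1-based consensus column index (vectorised over `position`).
#' @seealso [reverseMap()]
#' @export
mapToConsensus <- function(aln, member, position) {
  rows <- alignmentRows(aln)
  if (!(member %in% names(rows)))
    .stop_data("member '%s' is not part of the alignment", member)
  cols <- .residue_columns(.chars(rows[[member]]))
  bad <- position < 1L | position > length(cols)
  if (any(bad))
    .stop_data("position %s out of range for member '%s' (fragment length %d)",
               paste(position[bad], collapse = ","), member, length(cols))
  cols[position]
}

#' List the members and original positions under a consensus column
#'
#' The reverse of [mapToConsensus()]: which member residues sit in a given
#' column, reported in full-protein coordinates (fragment position plus the
#' member's domain offset).
#'
#' @param aln A \linkS4class{ConsensusAlignment}.
#' @param column 1-based consensus column index.
#' @return `data.frame` with columns `gene_symbol`, `position` (1-based on the
#'   full protein); zero rows for an all-gap column.
#' @export
reverseMap <- function(aln, column) {
  K <- alignmentLength(aln)
  if (column < 1L || column > K)
    .stop_data("column %d out of range [1, %d]", column, K)
  rows <- alignmentRows(aln)
  offs <- memberOffsets(aln)
  gene <- character(0); pos <- integer(0)
  for (m in names(rows)) {
    rc <- .chars(rows[[m]])
    if (rc[column] == "-") next
    frag_pos <- sum(rc[seq_len(column)] != "-")
    gene <- c(gene, m)
    pos <- c(pos, frag_pos + offs[[m]] - 1L)
  }
  data.frame(gene_symbol = gene, position = pos, stringsAsFactors = FALSE)
}

#' Pool class-filtered mutations onto the consensus columns
#'
#' Translates every mutation from full-protein coordinates into its member's
#' aligned fragment (using the recorded domain offsets) and onto the consensus
#' column holding that residue, accumulating per-column counts with full
#' per-mutation provenance for later reverse mapping. Mutations on genes
#' absent from the alignment or falling outside the aligned fragment are
#' excluded and tallied.
#'
#' @param aln A \linkS4class{ConsensusAlignment}.
#' @param muts Mutation `data.frame` (already class-filtered).
#' @return A \linkS4class{MutationProfile}.
#' @export
poolMutations <- function(aln, muts) {
  rows <- alignmentRows(aln)
  offs <- memberOffsets(aln)
  K <- alignmentLength(aln)
  colmap <- lapply(rows, function(r) .residue_columns(.chars(r)))
  counts <- integer(K)
  diag <- c(unknown_gene = 0L, out_of_fragment = 0L)
  prov <- vector("list", nrow(muts))
  kept <- logical(nrow(muts))
  cols <- integer(nrow(muts))
  for (i in seq_len(nrow(muts))) {
    g <- muts$gene_symbol[i]
    if (!(g %in% names(rows))) { diag[["unknown_gene"]] <- diag[["unknown_gene"]] + 1L; next }
    frag_pos <- muts$position[i] - offs[[g]] + 1L
    if (frag_pos < 1L || frag_pos > length(colmap[[g]])) {
      diag[["out_of_fragment"]] <- diag[["out_of_fragment"]] + 1L; next
    }
    cols[i] <- colmap[[g]][frag_pos]
    kept[i] <- TRUE
  }
  if (any(kept)) {
    tab <- table(cols[kept])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  prov <- data.frame(column = cols[kept],
                     gene_symbol = muts$gene_symbol[kept],
                     original_position = muts$position[kept],
                     sample_id = muts$sample_id[kept],
                     tumor_type = muts$tumor_type[kept],
                     stringsAsFactors = FALSE)
  new("MutationProfile", counts = counts, provenance = prov,
      diagnostics = diag)
}

#' Subset an alignment to chosen members without re-compacting columns
#'
#' Drops all rows but `keep` while leaving the column frame untouched: the
#' alignment length `K` and all column indices are unchanged, so hotspot
#' positions found on the subset remain directly comparable with the
#' full-family analysis (columns may become all-gap).
#'
#' @param aln A \linkS4class{ConsensusAlignment}.
#' @param keep Character vector of member gene symbols to retain.
#' @return A \linkS4class{ConsensusAlignment} with the same `K`.
#' @export
subsetMembers <- function(aln, keep) {
  rows <- alignmentRows(aln)
  unknown <- setdiff(keep, names(rows))
  if (length(unknown))
    .stop_data("unknown member(s): %s", paste(unknown, collapse = ", "))
  new("ConsensusAlignment", rows = rows[keep],
      offsets = memberOffsets(aln)[keep])
}

#' Write an alignment as aligned FASTA
#'
#' @param aln A \linkS4class{ConsensusAlignment}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeAlignment <- function(aln, path) {
  writeXStringSet(AAStringSet(alignmentRows(aln)), path)
  invisible(path)
}

#' Export consensus, coverage and Trident as a TSV
#'
#' @param profile A \linkS4class{ConsensusProfile}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeConsensusProfile <- function(profile, path) {
  write.table(
    data.frame(column = seq_along(consensusSequence(profile)),
               consensus_aa = consensusSequence(profile),
               coverage = columnCoverage(profile),
               trident = tridentScores(profile)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
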