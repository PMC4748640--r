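## Reading and writing the MAF-derived mutation dialect, FASTA families and
## domain tables; parsing amino-acid-change strings; class filtering.

#' Default column-name mapping for the mutation dialect
#'
#' The mutation table is a tab-separated derivative of a MAF file. These are
#' the default header names for the five required fields; pass a modified copy
#' to [readMutations()] when your file uses different headers.
#'
#' @return Named character vector mapping logical field names
#'   (`gene_symbol`, `aa_change`, `sample_id`, `tumor_type`, `mutation_class`)
#'   to column headers.
#' @export
#' @examples
#' defaultDialect()
defaultDialect <- function() {
  c(gene_symbol    = "Hugo_Symbol",
    aa_change      = "Amino_Acid_Change",
    sample_id      = "Tumor_Sample_Barcode",
    tumor_type     = "Tumor_Type",
    mutation_class = "Mutation_Type")
}

#' Default mapping from raw mutation-class strings to the three-class scheme
#'
#' Substitutions that change the protein without altering the reading frame or
#' creating stop codons are grouped as `missense`; frame-shift indels,
#' nonsense and splice-site alterations as `truncating`; protein-neutral
#' substitutions as `silent`. Raw classes not in the map are left unclassified
#' and dropped by [filterMutations()].
#'
#' @return Named character vector: raw class string -> one of
#'   `"missense"`, `"truncating"`, `"silent"`.
#' @export
defaultClassMap <- function() {
  c(Missense_Mutation        = "missense",
    Missense                 = "missense",
    missense                 = "missense",
    In_Frame_Del             = "missense",
    In_Frame_Ins             = "missense",
    Nonsense_Mutation        = "truncating",
    Nonstop_Mutation         = "truncating",
    Frame_Shift_Del          = "truncating",
    Frame_Shift_Ins          = "truncating",
    Splice_Site              = "truncating",
    Splice_Site_SNP          = "truncating",
    Translation_Start_Site   = "truncating",
    truncating               = "truncating",
    Silent                   = "silent",
    silent                   = "silent")
}

#' Parse single-residue amino-acid-change strings
#'
#' Parses substitution notations such as `"G12D"`, `"Q61H"`, `"p.P29S"` or
#' positional shorthands like `"Q61"` (missing alternate residue is recorded
#' as `NA`). The stop symbol `*` is accepted as the alternate. Multi-residue
#' events (`"K601del"`, `"E545_Q546ins"`, ...) are not position-parseable into
#' a single residue and yield `NA` rows; hotspot counting only needs
#' single-residue substitutions.
#'
#' @param change Character vector of amino-acid-change strings.
#' @return `data.frame` with columns `ref_aa`, `position`, `alt_aa` and
#'   logical `ok`; failed parses have `ok = FALSE` and `NA` fields.
#' @export
#' @examples
#' parseAAChange(c("G12D", "p.P29S", "E542K", "K601del"))
parseAAChange <- function(change) {
  change <- as.character(change)
  stripped <- sub("^p\\.", "", trimws(change))
  m <- regmatches(stripped,
                  regexec("^([A-Z])([0-9]+)([A-Z*]?)$", stripped))
  ref <- vapply(m, function(g) if (length(g)) g[2L] else NA_character_, "")
  pos <- vapply(m, function(g) if (length(g)) g[3L] else NA_character_, "")
  alt <- vapply(m, function(g) if (length(g)) g[4L] else NA_character_, "")
  ok <- !is.na(ref) & ref %in% AA_LETTERS
  pos_i <- suppressWarnings(as.integer(pos))
  ok <- ok & !is.na(pos_i) & pos_i >= 1L
  alt[!is.na(alt) & alt == ""] <- NA_character_
  ok <- ok & (is.na(alt) | alt %in% c(AA_LETTERS, "*"))
  data.frame(ref_aa  = ifelse(ok, ref, NA_character_),
             position = ifelse(ok, pos_i, NA_integer_),
             alt_aa  = ifelse(ok, alt, NA_character_),
             ok = ok,
             stringsAsFactors = FALSE)
}

.new_mutation_frame <- function(n = 0L) {
  data.frame(gene_symbol = character(n), sample_id = character(n),
             tumor_type = character(n), mutation_class = character(n),
             ref_aa = character(n), position = integer(n),
             alt_aa = character(n), stringsAsFactors = FALSE)
}

#' Read somatic mutations from the tab-separated MAF-derived dialect
#'
#' Reads a tab-separated file whose header contains, under configurable names,
#' the gene symbol, amino-acid change, sample barcode, tumor type and mutation
#' class of each somatic mutation. Amino-acid changes are parsed with
#' [parseAAChange()]; rows that cannot be parsed into a single-residue
#' substitution are skipped and tallied in the `diagnostics` attribute
#' (retrieve it with [diagnostics()]).
#'
#' @param path Path to the tab-separated mutation file (with header).
#' @param dialect Column-name mapping as returned by [defaultDialect()].
#' @param classMap Raw-class mapping as returned by [defaultClassMap()].
#' @return `data.frame` with columns `gene_symbol`, `sample_id`, `tumor_type`,
#'   `mutation_class` (`missense`/`truncating`/`silent`/`NA`), `ref_aa`,
#'   `position`, `alt_aa`; attribute `diagnostics` counts skipped rows.
#' @seealso [filterMutations()], [writeMutations()]
#' @export
readMutations <- function(path, dialect = defaultDialect(),
                          classMap = defaultClassMap()) {
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "")
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols))
    .stop_config("mutation file '%s' lacks required column(s): %s",
                 path, paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) {
    warning("mutation file '", path, "' contains a header but no rows")
    out <- .new_mutation_frame()
    attr(out, "diagnostics") <- c(unparseable_change = 0L)
    return(out)
  }
  parsed <- parseAAChange(raw[[dialect[["aa_change"]]]])
  keep <- parsed$ok
  out <- data.frame(
    gene_symbol    = raw[[dialect[["gene_symbol"]]]][keep],
    sample_id      = raw[[dialect[["sample_id"]]]][keep],
    tumor_type     = raw[[dialect[["tumor_type"]]]][keep],
    mutation_class = unname(classMap[raw[[dialect[["mutation_class"]]]][keep]]),
    ref_aa         = parsed$ref_aa[keep],
    position       = parsed$position[keep],
    alt_aa         = parsed$alt_aa[keep],
    stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- c(unparseable_change = sum(!keep))
  out
}

#' Write mutations back out in the same tab-separated dialect
#'
#' Inverse of [readMutations()]: a written table read back yields the same
#' records (the amino-acid change is re-serialised as
#' `<ref><position><alt>`).
#'
#' @param muts Mutation `data.frame` as returned by [readMutations()].
#' @param path Output file path.
#' @param dialect Column-name mapping, see [defaultDialect()].
#' @return Invisibly, `path`.
#' @export
writeMutations <- function(muts, path, dialect = defaultDialect()) {
  change <- paste0(muts$ref_aa, muts$position,
                   ifelse(is.na(muts$alt_aa), "", muts$alt_aa))
  out <- data.frame(a = muts$gene_symbol, b = change, c = muts$sample_id,
                    d = muts$tumor_type, e = muts$mutation_class,
                    stringsAsFactors = FALSE)
  names(out) <- dialect[c("gene_symbol", "aa_change", "sample_id",
                          "tumor_type", "mutation_class")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter mutations by class
#'
#' The hotspot method looks for clustered gain-of-function substitutions, so
#' by default only missense-type mutations are retained. `include_truncating`
#' adds truncating alterations; `silent_only` keeps only silent mutations (the
#' negative-control workflow: silent mutations should show no clustering).
#'
#' @param muts Mutation `data.frame` (see [readMutations()]).
#' @param mode One of `"missense_only"` (default), `"include_truncating"`,
#'   `"silent_only"`.
#' @return The subset of `muts`, order preserved.
#' @export
filterMutations <- function(muts,
                            mode = c("missense_only", "include_truncating",
                                     "silent_only")) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) .stop_config(
                     "unknown mutation filter mode: %s",
                     paste(mode, collapse = "/")))
  keep <- switch(mode,
    missense_only      = muts$mutation_class %in% "missense",
    include_truncating = muts$mutation_class %in% c("missense", "truncating"),
    silent_only        = muts$mutation_class %in% "silent")
  muts[keep, , drop = FALSE]
}

#' Read a protein family from FASTA, with optional domain annotations
#'
#' Reads full-length protein sequences (one per gene, named by gene symbol in
#' the FASTA headers' first word) and, optionally, a tab-separated domain
#' table with columns `gene_symbol`, `family_id`, `start`, `end` (1-based
#' inclusive). When `familyFilter` names a domain family, sequences are
#' trimmed to their annotated span and the trim offset is recorded, so that
#' mutations given in full-protein coordinates can still be pooled.
#'
#' @param fastaPath FASTA file of amino-acid sequences.
#' @param domainTablePath Optional TSV of domain spans.
#' @param familyFilter Optional family accession (e.g. `"PF00071"`): restrict
#'   to annotated members and trim each sequence to its domain span.
#' @return A \linkS4class{ProteinFamily}.
#' @export
readFamily <- function(fastaPath, domainTablePath = NULL, familyFilter = NULL) {
  seqs <- readAAStringSet(fastaPath)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(names(seqs)))
    .stop_data("duplicate gene symbol in FASTA: %s",
               paste(unique(names(seqs)[duplicated(names(seqs))]),
                     collapse = ", "))
  domains <- data.frame(gene_symbol = character(), family_id = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  if (!is.null(domainTablePath)) {
    d <- read.delim(domainTablePath, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    need <- c("gene_symbol", "family_id", "start", "end")
    if (!all(need %in% names(d)))
      .stop_config("domain table lacks required column(s): %s",
                   paste(setdiff(need, names(d)), collapse = ", "))
    unknown <- !(d$gene_symbol %in% names(seqs))
    if (any(unknown)) {
      warning("domain table cites gene(s) absent from the FASTA, ignored: ",
              paste(unique(d$gene_symbol[unknown]), collapse = ", "))
      d <- d[!unknown, , drop = FALSE]
    }
    domains <- d[, need]
    domains$start <- as.integer(domains$start)
    domains$end <- as.integer(domains$end)
  }
  offsets <- setNames(rep(1L, length(seqs)), names(seqs))
  if (!is.null(familyFilter)) {
    sel <- domains[domains$family_id == familyFilter, , drop = FALSE]
    if (nrow(sel) == 0L)
      .stop_data("no member of the family carries a '%s' annotation",
                 familyFilter)
    sel <- sel[!duplicated(sel$gene_symbol), , drop = FALSE]
    seqs <- seqs[sel$gene_symbol]
    seqs <- AAStringSet(substr(as.character(seqs), sel$start, sel$end))
    names(seqs) <- sel$gene_symbol
    offsets <- setNames(sel$start, sel$gene_symbol)
    domains <- sel
  }
  new("ProteinFamily", sequences = seqs, domains = domains, offsets = offsets)
}

#' Drop mutations inconsistent with the family sequences
#'
#' Mutations whose position exceeds the protein length, or whose reference
#' residue disagrees with the stored sequence, are usually caused by
#' transcript-isoform mismatches; they are dropped here rather than allowed to
#' corrupt the pooled profile, with a per-gene tally in the `diagnostics`
#' attribute. Positions are interpreted on the full-length protein;
#' domain-trimmed families check the residue inside the stored fragment and
#' leave out-of-fragment mutations untouched (pooling excludes those itself).
#'
#' @param muts Mutation `data.frame`.
#' @param family A \linkS4class{ProteinFamily}.
#' @return Filtered mutation `data.frame`; attribute `diagnostics` is a named
#'   integer vector of dropped counts per gene.
#' @export
validateMutations <- function(muts, family) {
  seqs <- as.character(familySequences(family))
  offs <- memberOffsets(family)
  drop <- logical(nrow(muts))
  for (i in seq_len(nrow(muts))) {
    g <- muts$gene_symbol[i]
    if (!(g %in% names(seqs))) next
    frag_pos <- muts$position[i] - offs[[g]] + 1L
    if (frag_pos < 1L || frag_pos > nchar(seqs[[g]])) {
      if (offs[[g]] == 1L) drop[i] <- TRUE   # beyond full protein: isoform
      next                                    # outside a trimmed fragment: keep
    }
    if (substr(seqs[[g]], frag_pos, frag_pos) != muts$ref_aa[i]) drop[i] <- TRUE
  }
  out <- muts[!drop, , drop = FALSE]
  dropped <- muts$gene_symbol[drop]
  attr(out, "diagnostics") <-
    if (length(dropped)) c(table(dropped)) else integer(0)
  out
}
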