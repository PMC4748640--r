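## Fixtures are built in code at test time; nothing binary ships with the
## package.

## a tiny hand-written family with one annotated domain
make_tiny_family <- function() {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">RASA some description", "MTEYKLVVVGAGGVGKSALTIQ",
               ">RASB", "MTEYKLVVVGAGDVGKSALTIQ",
               ">RASC", "MTEYKLVVVGAGGVGKSLTIQ"), fa)
  fa
}

make_domain_table <- function(rows) {
  tsv <- tempfile(fileext = ".tsv")
  write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  tsv
}

## a mutation TSV in the default dialect
make_mutation_file <- function(df) {
  tsv <- tempfile(fileext = ".tsv")
  names(df) <- c("Hugo_Symbol", "Amino_Acid_Change", "Tumor_Sample_Barcode",
                 "Tumor_Type", "Mutation_Type")[seq_along(df)]
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  tsv
}

## build a ProteinFamily directly from named sequences
family_from_seqs <- function(seqs, offsets = NULL) {
  if (is.null(offsets)) offsets <- setNames(rep(1L, length(seqs)), names(seqs))
  new("ProteinFamily", sequences = Biostrings::AAStringSet(seqs),
      domains = data.frame(gene_symbol = character(), family_id = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE),
      offsets = offsets)
}

## build a ConsensusAlignment directly from named gapped rows
alignment_from_rows <- function(rows, offsets = NULL) {
  if (is.null(offsets)) offsets <- setNames(rep(1L, length(rows)), names(rows))
  new("ConsensusAlignment", rows = rows, offsets = offsets)
}

## mutation record data.frame shorthand
mut_records <- function(gene, position, ref = "A", alt = "V",
                        sample = NULL, tumor = "CANCER",
                        class = "missense") {
  n <- max(length(gene), length(position))
  data.frame(gene_symbol = rep_len(gene, n),
             sample_id = if (is.null(sample)) sprintf("S%03d", seq_len(n))
                         else rep_len(sample, n),
             tumor_type = rep_len(tumor, n),
             mutation_class = rep_len(class, n),
             ref_aa = rep_len(ref, n),
             position = rep_len(as.integer(position), n),
             alt_aa = rep_len(alt, n),
             stringsAsFactors = FALSE)
}

## independent brute-force BH oracle (sort, p*m/rank, backward cummin)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- (m / seq_len(m)) * p[o]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

## exhaustive co-occurrence oracle: fix the A-set, enumerate all B-sets
cooccur_oracle <- function(nSites, nA, nB, jObs) {
  aset <- seq_len(nA)
  if (nB == 0L) {
    overlaps <- 0L
  } else {
    bsets <- utils::combn(nSites, nB)
    overlaps <- apply(bsets, 2L, function(b) length(intersect(b, aset)))
  }
  list(p_lt = mean(overlaps <= jObs), p_gt = mean(overlaps >= jObs))
}
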