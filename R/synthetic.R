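## Synthetic protein families and mutation cohorts with planted ground truth:
## every statistical claim of the package is testable against a known answer
## without downloading anything.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Generate a synthetic protein family with known true alignment
#'
#' Emulates a domain family of homologous sequences: an ancestral random
#' amino-acid sequence is mutated independently per member, with per-site
#' substitutions (to a uniformly chosen different residue) and per-site
#' deletions. Because divergence is deletion-only (no insertions), every
#' member stays embedded in the ancestral coordinate frame, and the returned
#' ground-truth alignment is exact by construction -- aligner-independent
#' tests compare against it directly.
#'
#' @param nMembers Number of family members (default 20).
#' @param length Ancestral sequence length (default 200).
#' @param substitutionRate Per-site substitution probability per member
#'   (default 0.05).
#' @param indelRate Per-site deletion probability per member (default 0.02).
#' @param seed Integer seed (required; the generator is fully deterministic
#'   under it).
#' @return Named list: `family` (a \linkS4class{ProteinFamily}) and
#'   `alignment` (the true \linkS4class{ConsensusAlignment}, `K = length`).
#' @export
generateFamily <- function(nMembers = 20L, length = 200L,
                           substitutionRate = 0.05, indelRate = 0.02, seed) {
  if (missing(seed)) .stop_config("generateFamily() requires an explicit seed")
  stopifnot(nMembers >= 1L, length >= 1L,
            substitutionRate >= 0, substitutionRate <= 1,
            indelRate >= 0, indelRate <= 1)
  .with_seed(seed, {
    ancestor <- sample(AA_LETTERS, length, replace = TRUE)
    rows <- character(nMembers)
    for (m in seq_len(nMembers)) {
      row <- ancestor
      sub <- runif(length) < substitutionRate
      for (i in which(sub))
        row[i] <- sample(setdiff(AA_LETTERS, ancestor[i]), 1L)
      del <- runif(length) < indelRate
      ## never delete a whole member
      if (all(del)) del[sample.int(length, 1L)] <- FALSE
      row[del] <- "-"
      rows[m] <- paste(row, collapse = "")
    }
    names(rows) <- sprintf("GENE%02d", seq_len(nMembers))
    aln <- new("ConsensusAlignment", rows = rows,
               offsets = setNames(rep(1L, nMembers), names(rows)))
    fam <- new("ProteinFamily",
               sequences = AAStringSet(gsub("-", "", rows, fixed = TRUE)),
               domains = data.frame(gene_symbol = character(),
                                    family_id = character(),
                                    start = integer(), end = integer(),
                                    stringsAsFactors = FALSE),
               offsets = setNames(rep(1L, nMembers), names(rows)))
    list(family = fam, alignment = aln)
  })
}

#' Generate a synthetic mutation cohort with planted hotspots
#'
#' Distributes somatic mutation records over the members of a synthetic
#' family: a fraction `f_h` of all mutations is planted on the residues
#' mapping to each hotspot consensus column `h` (the carrying member is
#' drawn coverage-weighted, i.e. uniformly among the members with a residue
#' in that column), and the remainder falls uniformly over all
#' (member, residue) pairs. Hotspots are planted in consensus-column space on
#' purpose: the phenomenon of interest -- mutations rare in any single gene
#' but recurrent at a shared aligned position -- is then directly simulable.
#' Records carry sample and tumor-type labels; gene-level exclusivity pairs
#' are enforced by resampling the receiving sample. Reference residues always
#' agree with the member sequence, so generated records pass validation;
#' alternate residues are uniform over the 19 non-reference residues
#' (`mutationClass = "silent"` instead records a synonymous self-change).
#'
#' @param family A \linkS4class{ProteinFamily} from [generateFamily()].
#' @param trueAln Its ground-truth \linkS4class{ConsensusAlignment}.
#' @param nSamples Cohort size (default 50).
#' @param backgroundRate Expected background mutations per sample, Poisson
#'   (default 1).
#' @param hotspots `data.frame(column=, fraction=)` of planted hotspot columns
#'   and their fractions of the total mutation count (fractions sum to <= 1);
#'   `NULL` for a pure-background cohort.
#' @param exclusivityPairs Optional list of 2-element gene-symbol vectors
#'   forced never to co-occur in one sample.
#' @param tumorTypes Named probability vector of tumor-type labels (default a
#'   single `"CANCER"` stratum).
#' @param mutationClass `"missense"` (default) or `"silent"`.
#' @param nMutations Total mutation count anchor used only when the hotspot
#'   fractions sum to 1 (no background to scale from); default `nSamples`.
#' @param seed Integer seed (required).
#' @return Named list: `mutations` (record `data.frame` as from
#'   [readMutations()]) and `truth` (`data.frame` with `gene_symbol`,
#'   `position`, `column`, `sample_id`, `tumor_type`, `origin`).
#' @export
generateCohort <- function(family, trueAln, nSamples = 50L,
                           backgroundRate = 1, hotspots = NULL,
                           exclusivityPairs = NULL,
                           tumorTypes = c(CANCER = 1),
                           mutationClass = c("missense", "silent"),
                           nMutations = nSamples, seed) {
  if (missing(seed)) .stop_config("generateCohort() requires an explicit seed")
  mutationClass <- match.arg(mutationClass)
  fracs <- if (is.null(hotspots)) numeric(0) else hotspots$fraction
  if (sum(fracs) > 1 + 1e-9)
    .stop_config("hotspot fractions must sum to <= 1")
  rows <- alignmentRows(trueAln)
  members <- names(rows)
  row_chars <- lapply(rows, .chars)
  if (!is.null(hotspots))
    for (h in hotspots$column)
      if (sum(vapply(row_chars, function(rc) rc[h] != "-", TRUE)) == 0L)
        .stop_data("hotspot column %d has zero coverage", h)
  .with_seed(seed, {
    n_bg <- sum(rpois(nSamples, backgroundRate))
    total <- if (sum(fracs) >= 1 - 1e-9) nMutations
             else round(n_bg / (1 - sum(fracs)))
    n_hot <- if (length(fracs)) round(total * fracs) else integer(0)
    samples <- sprintf("S%03d", seq_len(nSamples))
    types <- names(tumorTypes)

    gene <- character(0); col <- integer(0); origin <- character(0)
    ## planted hotspot mutations: member uniform among non-gap carriers
    if (!is.null(hotspots)) {
      for (hidx in seq_along(n_hot)) {
        h <- hotspots$column[hidx]
        carriers <- members[vapply(row_chars, function(rc) rc[h] != "-", TRUE)]
        if (n_hot[hidx] > 0L) {
          gene <- c(gene, sample(carriers, n_hot[hidx], replace = TRUE))
          col <- c(col, rep.int(h, n_hot[hidx]))
          origin <- c(origin, rep.int("hotspot", n_hot[hidx]))
        }
      }
    }
    ## background: uniform over (member, residue) pairs
    if (n_bg > 0L) {
      pool_gene <- rep(members,
                       vapply(row_chars, function(rc) sum(rc != "-"), 0L))
      pool_col <- unlist(lapply(row_chars, function(rc) which(rc != "-")),
                         use.names = FALSE)
      pick <- sample.int(length(pool_gene), n_bg, replace = TRUE)
      gene <- c(gene, pool_gene[pick])
      col <- c(col, pool_col[pick])
      origin <- c(origin, rep.int("background", n_bg))
    }
    n <- length(gene)
    if (n == 0L) .stop_data("cohort specification yields zero mutations")

    ## residue coordinates on the member (deletion-only evolution: fragment
    ## position = number of non-gap sites up to the column; offsets are 1)
    pos <- integer(n); ref <- character(n)
    for (i in seq_len(n)) {
      rc <- row_chars[[gene[i]]]
      pos[i] <- sum(rc[seq_len(col[i])] != "-")
      ref[i] <- rc[col[i]]
    }
    alt <- if (mutationClass == "silent") ref
           else vapply(ref, function(r) sample(setdiff(AA_LETTERS, r), 1L), "")

    ## sample assignment with gene-level exclusivity enforcement
    samp <- sample(samples, n, replace = TRUE)
    if (!is.null(exclusivityPairs)) {
      partner <- function(g) unlist(lapply(exclusivityPairs, function(p)
        if (g == p[1L]) p[2L] else if (g == p[2L]) p[1L] else NULL))
      carried <- lapply(setNames(vector("list", nSamples), samples),
                        function(x) character(0))
      for (i in seq_len(n)) {
        forb <- partner(gene[i])
        tries <- 0L
        while (length(forb) && any(forb %in% carried[[samp[i]]])) {
          tries <- tries + 1L
          if (tries > 1000L)
            .stop_data("exclusivity constraints are infeasible")
          samp[i] <- sample(samples, 1L)
        }
        carried[[samp[i]]] <- union(carried[[samp[i]]], gene[i])
      }
    }
    tumor <- sample(types, n, replace = TRUE, prob = tumorTypes)

    muts <- data.frame(gene_symbol = gene, sample_id = samp,
                       tumor_type = tumor, mutation_class = mutationClass,
                       ref_aa = ref, position = pos, alt_aa = alt,
                       stringsAsFactors = FALSE)
    truth <- data.frame(gene_symbol = gene, position = pos, column = col,
                        sample_id = samp, tumor_type = tumor, origin = origin,
                        stringsAsFactors = FALSE)
    list(mutations = muts, truth = truth)
  })
}
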