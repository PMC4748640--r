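## End-to-end workflows: the hypothesis-driven single-family analysis, the
## data-driven sweep over all mutated families, and the simulation writer.

.sidecar <- function(path, config, files) {
  lines <- c(sprintf("package_version: %s",
                     as.character(packageVersion("famHotspot"))),
             sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             vapply(names(config), function(k)
               sprintf("%s: %s", k, paste(config[[k]], collapse = ",")), ""),
             vapply(files, function(f)
               sprintf("md5 %s: %s", basename(f), unname(tools::md5sum(f))),
               ""))
  writeLines(lines, path)
  invisible(path)
}

#' Hypothesis-driven analysis of one protein family
#'
#' Runs the full pipeline on a family the user has chosen: homogeneity safety
#' net, multiple alignment, consensus and Trident profile, class filtering,
#' pooling onto the consensus, bootstrap null, global and per-position tests,
#' hotspot calling with reverse-mapped contributors, and (optionally)
#' mutual-exclusivity analysis of the significant columns. A single-member
#' family is analysed on its own sequence (the alignment degenerates to the
#' identity map), matching the per-protein scan mode.
#'
#' If no mutation survives class filtering and pooling there is nothing to
#' test: the result carries `hotspots = NULL` and a message, rather than an
#' error.
#'
#' @param family A \linkS4class{ProteinFamily}.
#' @param mutations Mutation `data.frame` (see [readMutations()]).
#' @param seed Integer seed for the bootstrap (required).
#' @param nBoot Bootstrap replicates (default 1000).
#' @param mutationMode Class filter mode, see [filterMutations()].
#' @param tridentGate Conservation gate for q-values (default 0.1).
#' @param qAlpha Q-value significance cutoff (default 0.05).
#' @param homogeneityThreshold K-tuple similarity floor (default 0.2).
#' @param backend,prealignedPath,exe Alignment backend, see [alignFamily()].
#' @param cooccurLevel `NULL` (skip), `"gene"` or `"position"`: run
#'   [cooccurAnalysis()] per tumor-type stratum.
#' @param outDir Optional output directory: writes `alignment.fasta`,
#'   `consensus.tsv`, `hotspots.tsv` (+ metadata sidecar) and `run.info`.
#' @return Named list: `hotspots` (\linkS4class{HotspotTable} or `NULL`),
#'   `alignment`, `consensus`, `profile`, `null`, `homogeneity`,
#'   `cooccurrence` (list per stratum or `NULL`), `dropped` (validation
#'   diagnostics).
#' @export
runHypothesis <- function(family, mutations, seed, nBoot = 1000L,
                          mutationMode = "missense_only",
                          tridentGate = 0.1, qAlpha = 0.05,
                          homogeneityThreshold = 0.2,
                          backend = "builtin", prealignedPath = NULL,
                          exe = "clustalo", cooccurLevel = NULL,
                          outDir = NULL) {
  if (missing(seed)) .stop_config("runHypothesis() requires an explicit seed")
  homog <- NULL
  if (length(familySequences(family)) >= 2L)
    homog <- withCallingHandlers(
      checkHomogeneity(family, threshold = homogeneityThreshold),
      warning = function(w) { message("homogeneity: ", conditionMessage(w))
                              invokeRestart("muffleWarning") })
  aln <- alignFamily(family, backend = backend,
                     prealignedPath = prealignedPath, exe = exe)
  consensus <- buildConsensus(aln)
  muts <- validateMutations(mutations, family)
  dropped <- diagnostics(muts)
  muts <- filterMutations(muts, mode = mutationMode)
  profile <- poolMutations(aln, muts)
  result <- list(hotspots = NULL, alignment = aln, consensus = consensus,
                 profile = profile, null = NULL, homogeneity = homog,
                 cooccurrence = NULL, dropped = dropped)
  if (totalMutations(profile) == 0L) {
    message("no mutations left after filtering and pooling: nothing to test")
    return(result)
  }
  null <- simulateNull(samplingWeights(consensus),
                       N = totalMutations(profile), nBoot = nBoot,
                       seed = seed)
  hotspots <- callHotspots(profile, consensus, null, aln,
                           alpha = qAlpha, gate = tridentGate)
  result$null <- null
  result$hotspots <- hotspots
  if (!is.null(cooccurLevel)) {
    strata <- unique(muts$tumor_type)
    cooc <- list()
    for (s in strata) {
      M <- buildPresenceMatrix(muts, level = cooccurLevel, stratum = s,
                               hotspots = hotspots, aln = aln)
      if (ncol(M) >= 2L && nrow(M) >= 1L)
        cooc[[s]] <- cooccurAnalysis(M, alpha = qAlpha)
    }
    result$cooccurrence <- if (length(cooc)) cooc else NULL
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- c(writeAlignment(aln, file.path(outDir, "alignment.fasta")),
               writeConsensusProfile(consensus,
                                     file.path(outDir, "consensus.tsv")),
               writeHotspotTable(hotspots, file.path(outDir, "hotspots.tsv")))
    .sidecar(file.path(outDir, "run.info"),
             config = list(mode = "hypothesis", seed = seed, n_boot = nBoot,
                           mutation_mode = mutationMode,
                           trident_gate = tridentGate, q_alpha = qAlpha,
                           homogeneity_threshold = homogeneityThreshold,
                           backend = backend),
             files = files)
  }
  result
}

#' Data-driven sweep over every mutated family
#'
#' Given only a mutation table, a sequence FASTA and a domain-annotation
#' table, groups the mutated genes by domain family, runs the family
#' (consensus) analysis per family on the domain-trimmed sequences, runs the
#' single-sequence scan for every mutated gene, and merges all significant
#' hotspots into one unified table with their support type: `family` rows are
#' deduplicated by (family, column), `single` rows by (gene, position).
#'
#' @param mutations Mutation `data.frame`.
#' @param fastaPath FASTA of full-length protein sequences.
#' @param domainTablePath Domain-annotation TSV (see [readFamily()]).
#' @param seed Integer seed (required).
#' @param ... Further parameters passed to [runHypothesis()] (`nBoot`,
#'   `mutationMode`, `tridentGate`, `qAlpha`, `backend`, ...).
#' @param outDir Optional output directory; per-family subdirectories plus
#'   `unified.tsv`.
#' @return Named list: `families` (list of [runHypothesis()] results per
#'   family id), `singles` (per-gene results), `unified` (`data.frame` with
#'   `family`, `column`, `gene`, `position`, `p`, `q`, `support`).
#' @export
runDataDriven <- function(mutations, fastaPath, domainTablePath, seed, ...,
                          outDir = NULL) {
  if (missing(seed)) .stop_config("runDataDriven() requires an explicit seed")
  mutated_genes <- unique(mutations$gene_symbol)
  all_fam <- readFamily(fastaPath, domainTablePath)
  dom <- familyDomains(all_fam)
  fam_ids <- unique(dom$family_id[dom$gene_symbol %in% mutated_genes])
  families <- list()
  for (fid in fam_ids) {
    fam <- readFamily(fastaPath, domainTablePath, familyFilter = fid)
    res <- tryCatch(
      runHypothesis(fam, mutations, seed = seed, ...,
                    outDir = if (is.null(outDir)) NULL
                             else file.path(outDir, fid)),
      famHotspot_data_error = function(e) NULL)
    if (is.null(res) || is.null(res$hotspots)) {
      message("family ", fid, ": no mappable mutation, skipped")
      next
    }
    families[[fid]] <- res
  }
  singles <- list()
  present <- intersect(mutated_genes, names(familySequences(all_fam)))
  for (g in present) {
    fam1 <- new("ProteinFamily",
                sequences = familySequences(all_fam)[g],
                domains = dom[0, , drop = FALSE],
                offsets = memberOffsets(all_fam)[g])
    res <- runHypothesis(fam1, mutations[mutations$gene_symbol == g, ,
                                         drop = FALSE],
                         seed = seed, ...)
    if (!is.null(res$hotspots)) singles[[g]] <- res
  }
  unified <- .unify_hotspots(families, singles)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(unified, file.path(outDir, "unified.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(families = families, singles = singles, unified = unified)
}

.unify_hotspots <- function(families, singles) {
  rows <- list()
  for (fid in names(families)) {
    sig <- significantHotspots(families[[fid]]$hotspots)
    if (nrow(sig))
      rows[[length(rows) + 1L]] <- data.frame(
        family = fid, column = sig$column, gene = NA_character_,
        position = NA_integer_, p = sig$p, q = sig$q, support = "family",
        stringsAsFactors = FALSE)
  }
  for (g in names(singles)) {
    sig <- significantHotspots(singles[[g]]$hotspots)
    if (nrow(sig))
      rows[[length(rows) + 1L]] <- data.frame(
        family = NA_character_, column = NA_integer_, gene = g,
        position = sig$column, p = sig$p, q = sig$q, support = "single",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(family = character(), column = integer(),
                      gene = character(), position = integer(),
                      p = numeric(), q = numeric(), support = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  key <- ifelse(out$support == "family",
                paste("F", out$family, out$column),
                paste("S", out$gene, out$position))
  out <- out[!duplicated(key), , drop = FALSE]
  out[order(out$q, out$p), , drop = FALSE]
}

#' Write a synthetic family and cohort to disk
#'
#' Generates a family and cohort with [generateFamily()]/[generateCohort()]
#' and writes them in the exact formats the readers consume: `family.fasta`,
#' `alignment.fasta` (the ground-truth alignment), `mutations.tsv` (the
#' MAF-derived dialect) and `truth.tsv` (the planted assignments). The
#' written inputs feed [runHypothesis()] unchanged.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed (required).
#' @param familyArgs Named list of [generateFamily()] arguments.
#' @param cohortArgs Named list of [generateCohort()] arguments.
#' @return Invisibly, named character vector of the written paths.
#' @export
runSimulate <- function(outDir, seed, familyArgs = list(),
                        cohortArgs = list()) {
  if (missing(seed)) .stop_config("runSimulate() requires an explicit seed")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fam <- do.call(generateFamily, c(familyArgs, list(seed = seed)))
  coh <- do.call(generateCohort,
                 c(list(family = fam$family, trueAln = fam$alignment),
                   cohortArgs, list(seed = seed + 1L)))
  paths <- c(
    family    = file.path(outDir, "family.fasta"),
    alignment = file.path(outDir, "alignment.fasta"),
    mutations = file.path(outDir, "mutations.tsv"),
    truth     = file.path(outDir, "truth.tsv"))
  writeXStringSet(familySequences(fam$family), paths[["family"]])
  writeAlignment(fam$alignment, paths[["alignment"]])
  writeMutations(coh$mutations, paths[["mutations"]])
  write.table(coh$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  .sidecar(file.path(outDir, "run.info"),
           config = c(list(mode = "simulate", seed = seed),
                      familyArgs, cohortArgs),
           files = paths)
  invisible(paths)
}
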