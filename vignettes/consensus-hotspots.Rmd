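---
title: "Pooled hotspot detection on protein-family consensus alignments"
author: "famHotspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled hotspot detection on protein-family consensus alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famHotspot)
```

## The problem

Single-gene recurrence tests need many patients carrying mutations at the
same residue of the same gene. Genes mutated in well under 5% of a cohort
never get there. But somatic driver mutations concentrate on functional
residues, and functional residues are conserved across the members of a
protein family: the homologous positions of *KRAS*, *NRAS*, *RRAS2*,
*RAP1B*, ... occupy a single column of the family's multiple alignment.
famHotspot pools the mutations of all family members into that shared
coordinate system and tests the pooled profile, so a position mutated once
per gene in ten genes is a ten-mutation hotspot on the consensus.

## The procedure

1. **Family assembly** (`readFamily`): full-length sequences, one per gene,
   optionally trimmed to an annotated domain span. Trim offsets are kept so
   that mutation positions given on the full protein still map correctly.
2. **Homogeneity safety net** (`checkHomogeneity`): each member's mean
   k-tuple similarity (shared distinct k-mers over the shorter sequence's
   distinct k-mers; `k = 3`) to the rest of the family. Members under the
   floor (default 0.2) are flagged with a warning — a sufficiently alien
   sequence aligns poorly and can invalidate the whole column frame — but
   the analysis proceeds; the warning is a diagnostic, not a veto.
3. **Alignment** (`alignFamily`): an external Clustal-Omega-compatible
   binary, a pre-computed aligned FASTA, or the builtin deterministic
   center-star aligner (global BLOSUM62 affine-gap pairwise steps via
   `Biostrings::pairwiseAlignment`, merged under once-a-gap-always-a-gap).
   The builtin backend exists so no test or example depends on an external
   binary; it is a reasonable progressive aligner, not a Clustal Omega
   reimplementation, and the backend used is recorded in the run sidecar.
4. **Consensus and conservation** (`buildConsensus`): per column, the modal
   non-gap residue, the non-gap coverage, and the Trident conservation
   score.
5. **Pooling** (`poolMutations`): class-filtered mutations are translated
   through the offset and residue→column maps; each pooled mutation keeps
   its (gene, position, sample, tumor type) provenance for reverse mapping.
   Everything excluded (unknown gene, outside the aligned fragment) is
   tallied, never silently dropped.
6. **Statistics** (`simulateNull`, `globalPvalue`, `positionPvalues`,
   `correctQvalues`, `callHotspots`): described next.

## The statistical model

With `K` consensus columns, pooled counts `n_i`, and `N = Σ n_i`, the global
statistic is the Shannon entropy `H = −Σ (n_i/N) ln(n_i/N)`. The null is a
bootstrap of 1,000 random profiles, each a multinomial redistribution of
the `N` mutations over the `K` columns with probabilities proportional to
column coverage — the random model must not be penalised for gap-rich
columns that real mutations can rarely reach. A Gamma distribution is
fitted by maximum likelihood to the replicate entropies and the global
p-value is its **lower** tail at the observed `H`: clustering strictly
lowers entropy, so only the low tail is evidence of non-randomness. (The
direction is an interpretive choice; the alternative — treating both tails
as interesting — would also flag profiles *more uniform* than chance, which
is not a driver signature.)

Per position, the same bootstrap supplies the null counts of each column. A
Gamma is fitted to the column's replicate counts and the upper tail
evaluated at the observed count; q-values come from Benjamini–Hochberg
restricted to columns with Trident score strictly above 0.1 (the family
size `m` of the correction is the number of gated-in columns). Gated-out
columns keep their p-value with `q = NA`, so nothing disappears from the
report.

### Numerical choices

* **Gamma on discrete counts.** Bootstrap column counts are small integers
  with many zeros, while the Gamma lives on (0, ∞). We fit on
  `counts + 0.5` and evaluate the upper tail at `n_i − 0.5` (continuity
  correction). When more than 90% of a column's replicate counts are zero
  the shape is unidentifiable; the column falls back to the add-one
  empirical exceedance `(#{boot ≥ n_i} + 1)/(n_boot + 1)`, whose floor
  `1/(n_boot + 1)` is the honest resolution limit of a 1,000-replicate
  bootstrap. Zero-count and zero-weight columns get `p = 1` outright.
* **Gamma fitting.** Maximum likelihood with moment-style initialisation
  and Newton refinement of the shape on the profile likelihood, vectorised
  over columns from sufficient statistics (`mean`, `mean log`) — fitting
  thousands of columns costs two `colMeans`. Entropy replicates equal to
  zero (all `N` mutations in one column, possible at tiny `N`) are outside
  the support: excluded from the fit when ≤ 10% of replicates, otherwise
  the global test uses the empirical tail. A fit with essentially zero
  variance returns a degenerate marker and likewise falls back.
* **Consensus ties** are broken alphabetically (deterministic); a gap can
  be consensus only in an all-gap column. Column indices are 1-based
  everywhere in the public interface, as are residue positions ("G12").
* **Trident.** `score = (1−t)^α (1−r)^β (1−g)^γ` with `(α, β, γ) =
  (1, 0.5, 3)`, the weights recommended for this score family
  (configurable). `t` is the normalised residue entropy and `r` the mean
  pairwise BLOSUM62-derived distance (similarity normalised as
  `B(a,b)/√(B(a,a)B(b,b))`, then rescaled so identical pairs give distance
  0 and the most dissimilar pair 1), both computed on the non-gap residues;
  `g` is the gap fraction of the full column height. Computing `t`/`r` on
  non-gap residues and `g` on all rows is our convention; the gap penalty
  should not double-count through the entropy term.
* **Determinism.** Every stochastic step takes a mandatory seed, restores
  the caller's RNG state, and is recorded in the output sidecar together
  with parameter values and output checksums; identical config + seed gives
  byte-identical outputs.

## Mutual exclusivity

Two driver features on the same pathway tend not to co-occur in one tumor:
after the first hit there is no selective pressure for the second. For
features A and B mutated in `n_a` and `n_b` of `n` samples, the number of
co-mutated samples under random placement is hypergeometric;
`cooccurAnalysis` reports both tails (each including the observed point
mass), BH-corrected across the pairs of a tumor-type stratum, and calls
pairs mutually exclusive / co-occurring / neutral at adjusted p < 0.05.
Features can be genes or significant consensus columns — the latter extends
the classic gene-wise analysis to single aligned positions. Pairs with
expected co-occurrence below 1 are flagged low-power rather than
interpreted. `fisher2x2` provides the matching 2×2 exact test for
domain-level contrasts. The BH default for the pair correction is our
choice (consistent with the rest of the package); Bonferroni and no
correction are available.

## What the synthetic generator emulates — and what it does not

`generateFamily` evolves an ancestral random sequence into `n` members by
per-site substitutions and per-site **deletions only**. Deletion-only
divergence keeps every member inside the ancestral coordinate frame, so the
generator can return the exact true alignment alongside the sequences;
tests of the statistics can then be run against ground truth without
trusting any aligner. `generateCohort` plants hotspots **in consensus-column
space** — a fraction of all mutations lands on the residues of a chosen
column, the carrying member drawn uniformly among those with a residue
there — precisely because the phenomenon of interest is "rare per gene,
recurrent per column". The remainder is uniform background over all
(member, residue) pairs; reference residues always agree with the member
sequence; gene-level exclusivity pairs are enforced by resampling the
receiving sample.

Defaults (20 members, length 200, substitution rate 0.05, deletion rate
0.02, 50 samples, one background mutation per sample) are a desk-scale
stand-in for a mid-sized domain family with a moderately mutated cohort.

Real data differ in ways the generator does not model: insertion as well as
deletion history (so real column frames are aligner-dependent),
non-uniform mutational signatures along the sequence, transcript-isoform
coordinate mismatches, and families whose members differ vastly in length.
Passing the synthetic suite therefore demonstrates the statistics and the
coordinate bookkeeping, not alignment quality on hard families — that is
what the external-aligner backend and the homogeneity warning are for.

## Problem sizes used in the shipped experiments

The test-suite and acceptance-script experiments use `K = 100`, `N = 50`,
1,000 bootstrap replicates and 100–500 repetitions per experiment; the
rescue experiment uses 12 members of length 60 with exactly one mutation
per member on one conserved, fully covered column (the configuration the
method exists for), and the silent-mutation negative control uses 10
members of length 80 with ~50 uniform silent mutations per run. These sizes
make every experiment reproducible in seconds while keeping the binomial
standard errors of the measured rates a few percent.

## Known limitations

* The per-position Gamma null ignores the negative correlation between
  multinomial columns; at very small `K` the per-position p-values are
  mildly conservative.
* The empirical fallback cannot produce p below `1/(n_boot + 1)`; families
  whose signal rests on a single mutation per member need either enough
  members to engage the Gamma branch or a larger `nBoot`.
* The Gamma fit to the entropy null carries a small calibration bias in the
  extreme tails (the entropy of a multinomial is bounded and discrete, the
  Gamma is neither); global p-values near 0 or 1 are approximations.
* The builtin aligner is progressive and center-anchored: adequate for
  homogeneous families, not a substitute for a profile HMM aligner on
  divergent ones. Hotspot columns found under different aligners are
  comparable only via `subsetMembers`-style frame-preserving analyses, not
  across re-alignments.
* Multi-residue events (in-frame indels) are not single-position events and
  are excluded at parse time, with a diagnostic count.
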