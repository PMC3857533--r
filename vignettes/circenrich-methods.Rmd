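---
title: "circenrich: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circenrich: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circenrich)
```

## The enrichment model

circRNAs sequester miRNAs, so a circRNA whose interaction partners
concentrate in the miRNA set of a disease is a candidate regulator of that
disease. We model the partner set of a circRNA as a draw without replacement
from the miRNA universe: with `M_T` miRNAs overall, `M_d` associated with
disease *d*, and `m_c` partners of the circRNA, the number of
disease-associated partners `m_d` is hypergeometric under the null of no
association, and the evidence for enrichment is the upper tail

$$p = \sum_{i=m_d}^{\min(m_c, M_d)}
\frac{\binom{M_d}{i}\binom{M_T-M_d}{m_c-i}}{\binom{M_T}{m_c}}.$$

The model's assumptions are worth stating explicitly: partner sets are
treated as unordered draws with every miRNA equally likely a priori
(no preference by expression, conservation or seed-family size), and the
per-disease tests are treated as a family of `m` exchangeable hypotheses,
where `m` is the number of circRNAs interacting with at least one of the
disease's miRNAs. Family-wise error within a disease is controlled by
Bonferroni: a call is significant when `p < alpha / m` with `alpha = 0.05`
by default. The inequality is strict, `m` is computed per disease rather
than globally, and `m` is always recomputed after any filtering (such as
the optional curated-miRNA restriction), so the threshold refers to the
family actually tested.

Three degenerate situations are resolved by convention rather than left to
chance: circRNAs with no miRNA partner are never tested (their tail is
trivially 1); diseases whose miRNA set becomes empty after filtering are
skipped with a warning; and disease miRNAs absent from the universe are
dropped (with a reported count) before `M_d` is computed, since a draw from
the universe can never produce them. The universe itself is an explicit
input — it defaults to the miRNAs observed in the interaction table, but an
explicit universe file should be preferred, because the "total number of
miRNAs" is an annotation-release-dependent quantity that materially changes
every p-value.

### Numerical evaluation

The tail is evaluated in log space: each term via log-gamma binomial
coefficients, a max-shift before exponentiation, and Kahan-compensated
accumulation of the shifted terms. This is stable for universes of tens of
thousands of miRNAs and tails of any length. An independent exact-rational
evaluator (integer Pascal-triangle binomials, an exactly accumulated
integer numerator, extended-precision division) is shipped as
`hypergeom_tail_exact`; it is restricted to `M_T <= 62`, the range where
64-bit integers are exact, and exists for validation, not production. The
test suite compares the two on the full parameter grid up to `M_T = 60`
(about 1.1 million cases) at a relative tolerance of 1e-12, and also
cross-checks `stats::phyper` on random large-parameter draws; output ties in
the results table are broken lexicographically by circRNA id so reruns diff
cleanly.

## Coordinates and interval mapping

Externally the package speaks BED (0-based, half-open, `.` for unstranded)
and dbSNP/GWAS-style 1-based positions; internally everything is a
Bioconductor `GRanges` (1-based, closed), the native convention of the R
genomics stack. Each reader converts exactly once, each writer converts
back, and no other code touches coordinates, which confines the classic
off-by-one risk to two well-tested lines. The observable semantics are the
BED ones: a locus `[100, 200)` contains 0-based positions 100 and 199 but
not 99 or 200, and the suite asserts exactly this at locus boundaries.

Mapping conventions: a SNP hits a locus by position and chromosome alone
(strand-agnostic, as point features have no meaningful strand); an Ago site
hits a locus when they share at least one base — overlap, not containment —
and, by default, lie on the same strand, since PAR-CLIP clusters and
circRNAs are both stranded; a flag disables strand matching. A feature
contained in several overlapping loci contributes one mapping per locus
("multiplicity counting"), which is also how the mean trait-SNPs per mapped
circRNA figure is defined; unique-feature counts are reported alongside.
circRNA loci are treated as linear genomic spans between backsplice
coordinates — the junction itself is not modelled as sequence.

Because a "per-kb variant frequency" admits two readings, the density
summary reports both: the aggregate density (total mappings over total
locus length) and the mean of per-locus densities. They differ whenever
locus lengths vary; callers should state which they quote. Genome-build
agreement between the circRNA catalogue and the variant catalogues is the
caller's responsibility: the package performs no liftover and cannot detect
a mismatch beyond the chromosome-name check in the pipeline stage.

Overlap queries run through `GenomicRanges::findOverlaps`; the tests verify
every mapping operation against a hand-written naive all-pairs scan on
random instances up to 1,000 loci by 5,000 features.

## Networks

A disease's network has its (optionally curated) miRNAs plus all their
targets as nodes and the interaction rows restricted to those miRNAs as
edges. The graph is bipartite by construction and asserted to be so. Two
choices were genuinely open. First, disease miRNAs without any target are
kept as isolated nodes: dropping them would silently understate the
disease's miRNA complement in the export. Second, target node identity is
the pair (id, class) — the mRNA, lncRNA and circRNA catalogues have
independent namespaces, so a shared symbol must not merge nodes; SIF
carries the class in the relation (`targets_mRNA` etc.) and GraphML
disambiguates clashing vertex names as `id|class`. All exports are
lexicographically ordered, so re-export after any input shuffle is
byte-identical.

## The synthetic-data generator

The generator emulates the statistical shape of the real inputs — a circRNA
catalogue with genomic loci, a merged target-prediction table, a
disease–miRNA map, genome-wide and trait-labelled variant catalogues, and
CLIP-derived Ago sites — with a planted truth that makes recovery
measurable. Its default parameters are the package's reference study
conditions:

| parameter | default | rationale |
|---|---|---|
| miRNA universe `M_T` | 2000 | order of the annotated human miRNA complement |
| diseases × set size | 10 × 30 | typical curated disease–miRNA set sizes; sets may share miRNAs |
| circRNAs | 200 | keeps the full grid of tests fast while leaving per-disease families of ~50+ |
| locus length | lognormal, mean ≈ 9,043 bp (σ = 0.8 log-scale) | mean chosen so that the per-locus variant mean (~217) over the per-kb rate (24.01) reproduces the observed ratio; verified by the realized simulated mean |
| SNP rate | 24.01 per kb, per-locus Poisson | matches reported circRNA variant density |
| trait-SNP fraction | 0.002 | gives ~90 trait-labelled SNPs at default scale, the order of a GWAS-catalog overlap |
| Ago sites per circRNA | Poisson(2.658), 20–40 bp | matches reported mean site count; cluster widths typical of PAR-CLIP |
| background edge prob π0 | 0.01 | sparse prediction-table density; yields `m_c` ≈ 20 |
| planted edge prob π1 | 0.5, 5 planted pairs | a strong sponge: half the disease's miRNAs hit the planted circRNA |
| mRNA / lncRNA targets | 500 / 150 at edge prob 0.01 | populates the network classes without dominating runtime |

Planting works at the edge level: for a planted (circRNA, disease) pair,
each of the disease's miRNAs gains an edge to that circRNA with probability
π1 instead of π0, and the realized `m_d` per pair is recorded as the truth.
Setting π1 = π0 yields an exact null in which any significant call is a
family-wise false positive — this is how calibration is measured.

Randomness is organised as one root seed from which each stream (loci,
disease sets, edges, SNPs, Ago sites) derives a fixed sub-seed, so changing
or re-running one stage never perturbs another's draws, and identical
config plus seed gives byte-identical files. Loci are rejection-sampled to
be non-overlapping by default; an overlap-allowing mode exists specifically
to exercise multiplicity counting.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: sequence (no seed matches, no binding energetics;
interactions are sampled edges, not predictions), linkage disequilibrium or
any spatial clustering of variants, overlapping circRNA isoforms sharing
variants, expression or tissue specificity, and the curation biases of real
disease–miRNA databases (set sizes here are uniform and independent).
Results on synthetic data validate the machinery and its calibration, not
any biological claim.

## Problem sizes and runtime choices

The suite's statistical checks use: the exhaustive oracle grid to
`M_T = 60`; 500 null replicates and 100 planted replicates at the default
conditions for calibration and sensitivity; 100 random mapping instances
against the naive scan; and 200+ random records per round-trip property.
These sizes put the binomial standard errors well below the margins being
asserted (e.g. the null check allows 0.05 plus three standard errors over
5,000 disease replicates) while keeping the whole suite to a few minutes on
one core. The acceptance script uses 25 sensitivity and 100 null replicates
for the same reason.

## Known limitations

* Bonferroni is the only multiplicity correction offered; with hundreds of
  diseases a false-discovery-rate variant would often be preferred, but the
  per-disease family definition here is deliberately conservative.
* `M_d`, `m_c` and `m_d` treat all interactions as equally credible; there
  is no weighting by prediction confidence or number of supporting tools.
* The enrichment test conditions on the observed interaction table; it does
  not model uncertainty in the predictions themselves.
* No VCF input, no liftover, no LD expansion of GWAS SNPs, and no
  functional-consequence annotation of variants.
* The curated-miRNA filter is consumed as a user-supplied list; the package
  does not judge curation quality.
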