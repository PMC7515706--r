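---
title: "Methods: tiered CRISPR/Cas9 guide library design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered CRISPR/Cas9 guide library design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guideforge)
```

## The problem

A pooled CRISPR knockout screen is only as sensitive as its worst
guides. An effective guide must satisfy two partly independent demands:
the Cas9 ribonucleoprotein must cut efficiently and exclusively at the
intended site (guide-intrinsic properties), and the cut must actually
destroy the function of the target gene (target properties). Frameshifts
near the C terminus, in-frame repair at tolerant positions, and edits to
non-essential protein regions all produce phenotypically silent alleles
from perfectly good cuts. guideforge annotates both kinds of features
for every NGG guide in a genome, scores target-residue importance with a
deletion-based protein conservation statistic, and picks a small spaced
set of guides per gene by a transparent tier system.

## Guide extraction and anchoring

SpCas9 requires an NGG protospacer-adjacent motif. `extract_guides()`
enumerates every 23-nt window ending in GG on either strand and records
a 30-nt context (4 nt upstream, 20-nt protospacer, 3-nt PAM, 3 nt
downstream) for efficacy scoring. Guides whose context is clipped by a
contig edge are dropped, as are guides containing N (ambiguity codes are
normalized to N on input; Cas9 targeting of ambiguous sequence is
undefined). The blunt cut is placed between protospacer positions 17 and
18, 3 bp 5' of the PAM — the consensus SpCas9 cleavage position — and
`cut_position` stores the first base 3' of that bond on the reference
strand, so the two strands of one physical site agree. All genomic
coordinates in the package are 1-based inclusive, the Bioconductor
convention; spliced-CDS offsets are 0-based ("bases 5' of this
position"), which makes `pct_cds = offset / length` and
`aa = offset %/% 3 + 1` exact.

## Intrinsic features

**Homopolymers and Esp3I.** Runs are measured over the synthesized
construct — configurable vector flanks plus the protospacer — so a run
completed across a junction counts. The default window is
`construct_context("ACCG", "GT")`: the cloning overhang upstream and the
first two scaffold bases downstream. The window deliberately stops
before the scaffold's own internal T-run; that run is present in every
construct, so scanning it would flag all guides indiscriminately while
the polyT criterion exists to separate guides (runs of three or more
thymidines attenuate RNA Pol III transcription). Esp3I sites (CGTCTC)
are scanned on both strands by default because restriction of cloned
double-stranded DNA is strand-symmetric; a single-motif mode reproduces
the literal one-strand rule.

**Melting temperature.** Unified nearest-neighbor thermodynamics
(Allawi & SantaLucia 1997): stack enthalpies and entropies, terminal
initiation terms, entropic salt correction
`dS += 0.368 (n-1) ln[Na+]`, with defaults 0.25 uM strand concentration
and 50 mM Na+. Absolute Tm shifts by several degrees across tools and
assumed conditions; only the rank order across guides matters to the
design, and that is what the tests pin down.

**Cleavage efficacy.** Deliberately pluggable. Production databases join
scores from an external trained model through
`efficacy_scorer_table()`; the packaged
`efficacy_scorer_surrogate()` is a deterministic arithmetic hash of the
30-mer used by fixtures and examples. It carries no biological signal
and is documented as such — re-fitting a gradient-boosted efficacy model
is out of scope here.

## Specificity

Off-targets are enumerated with a seeded exact search: every NGG
site in the search space is indexed by its five non-overlapping 4-mer
chunks; by pigeonhole, any site within Hamming distance 4 of a query
shares at least one chunk, so seed lookup plus verification is complete
for up to four mismatches. No bulges are modeled. The search is
truncated at 5,000 sites and flagged; flagged guides are treated as
non-specific. Each off-target site is scored with the published
position-weight formula (product of `1 - W[p]` over mismatches, a mean
pairwise-distance factor, and `1/m^2`), and sites aggregate as
`1 / (1 + sum s_i)`.

Two conventions the formula leaves open are fixed here: a second
perfect-match site scores 1.0 (the `1/m^2` term is undefined at m = 0,
and a duplicate perfect site is maximally dangerous), and for fewer than
two mismatches the distance factor is defined as 1 (the formula's
limit). The guide's own genomic locus is excluded from the sum by
coordinates; when the search space is re-coordinatized (the
proteome-restricted score over spliced coding sequences) the first
perfect hit is taken as the origin instead. A guide whose site spans a
splice boundary has no perfect match in spliced-CDS space and sees a
near-match of itself; this is inherent to proteome-restricted scoring,
which is annotated but not used as a design criterion.

The hard filter used for tiering and for training-set inclusion is:
specificity strictly above 0.50 *and* zero off-targets within one
mismatch *and* no truncation.

## Target features

**%CDS and NMD.** The cut's fractional CDS position flags guides
landing past 95% of the coding sequence. NMD competence applies the
50-nt rule: for each frameshifting repair outcome (+1 and +2 nt
insertions at the cut), the shifted downstream frame of the mature mRNA
is scanned to its first stop codon; the frame counts as NMD-inducing
when that stop starts more than 55 nt (configurable; the conservative
end of the rule's 50-55 nt range) upstream of the last exon-exon
junction. The insertion model is a stated choice — real repair outcomes
are a spectrum — but it is deterministic, testable, and symmetric in the
two frames. Single-exon transcripts and last-exon cuts can never
qualify.

**Exon symmetry, splice sites, ESEs.** An internal exon whose coding
length is not a multiple of 3 is "asymmetric": skipping it frameshifts
the rest of the protein. Splice-site proximity is annotated as
donor/acceptor classes 0-2 nt into the intron but deliberately not used
for selection (splice edits produce unpredictable change-of-function
alleles). Exonic splicing enhancer motifs are exact-matched within the
targeted exon; by default the feature fires only when an occurrence
overlaps the cut (the mechanism is abrogation of the motif), with an
exon-presence mode for sensitivity analysis.

**Domains, sites, secondary structure, SNPs.** Protein-space intervals
(conserved-domain regions and sites, Pfam, Uniprot secondary structure)
are intersected with the residue under the cut. Polymorphisms at or
above 10% variant allele frequency overlapping the 23-nt guide+PAM
footprint (indels by reference footprint) disqualify a guide: the
target simply is not reliably present.

## Deletion-based conservation

The novel score: for every residue (or 2-3 residue window), delete it,
realign the variant protein to each ortholog, and record how much the
alignment score drops relative to wild type. Deltas are averaged within
ortholog clusters, then across clusters, and negated so larger positive
values mean more conserved. Alignment is semi-global (the query aligned
end to end, subject overhangs free) with BLOSUM62 and affine gaps
opening 10 / extending 1, a gap of length L costing `open + L*extend`.
An identity matrix (+5/-2) is shipped for sensitivity comparisons, as is
a substitution-mode score (mean over all 20 replacements). For
multi-residue deletions the window's value is attributed to every
residue in it and overlapping windows average — per-residue attribution
is not dictated by the per-deletion definition, so this choice is
stated rather than inherited. By default each ortholog is its own
cluster; `cluster_orthologs()` offers greedy 75%-identity clustering so
near-duplicate orthologs do not dominate the average. The design
threshold "conserved" is a track value strictly above 7.

## Tier assignment and picking

Guides are binarized against the design criteria (efficacy > 0.40,
conservation > 7, %CDS < 0.95, clean construct, no common SNP,
specificity band) and assigned to the lowest tier whose requirements
they meet. Tier 1 demands everything under full specificity; tiers 2-6
relax positive-selection features cumulatively in priority order —
domain, then conservation, then efficacy, then CDS position, then
construct/SNP cleanliness — holding full specificity fixed; tiers
7.1-7.6 repeat the ladder in the relaxed specificity band
(0.25 < score <= 0.50); tier 8 is everything else. Keeping specificity
for last reflects the strategic priority of avoiding off-target
activity. The exact order in which tiers 2-6 shed features is a genuine
design choice; it is shipped as a data file
(`inst/extdata/tier_table.tsv`), not code, and any nested ladder can be
substituted. Nesting guarantees monotonicity: improving any feature
never worsens a guide's tier.

Per gene, all tier-1 guides are included unconditionally with the
spacing constraint waived among them (their co-targeting redundancy is
judged worth it), truncated by efficacy if they exceed the quota.
Remaining slots are filled to maximize summed (tier, efficacy) rank
subject to cut sites at least 3 nt from every prior pick — waived picks
included. With at most 20 candidates the constrained subset problem is
solved exactly by enumeration; beyond that, greedily with local swap
improvement. Ties break toward lower genomic coordinate, making the
output deterministic. Both 6- and 12-guide-per-gene formats are a
parameter.

The binomial helper `genes_with_at_least_k_effective(n, k, p)` converts
per-guide effectiveness into gene-level coverage under random
assortment, quantifying why modest per-guide gains compound sharply at
the gene level.

## Training analysis

Screen fold changes are z-scored within (experiment, gene) using the
sample (n-1) standard deviation — the population/sample choice is not
dictated by the z-score definition, so it is fixed and stated; groups
of fewer than two guides, or zero spread, are dropped. Training records
are filtered to coding, specifically-targeting guides. The feature
model is ordinary least squares with categorical expansion, and
relative importance is the LMG decomposition (each predictor's
incremental R-squared averaged over orderings of model entry),
implemented directly: exact subset enumeration via precomputed cross
products up to 15 predictor groups, fixed-seed Monte Carlo over
orderings beyond. Exact shares sum to the model R-squared identically.
`median_diff_vs_prevalence()` provides the complementary triage view —
median activity difference of feature carriers against feature
prevalence in a reference guide universe — which surfaces rare, deadly
features a variance-decomposition dilutes.

Screen dropout metrics: reads per million per sample, every sample
rescaled so summed RPM over negative-control-gene guides is identical
across samples (Cas9 cutting depresses all targeting guides; controls
define the neutral axis), guide log2 fold changes against the averaged
reference samples with a 0.5-RPM pseudocount (configurable; tests use 0
for exact arithmetic), gene means, intra-gene CV reported as
`sd / |mean|` (the unsigned denominator keeps dropout CVs comparable),
and a hit call of gene LFC below -1 in at least one library.

## The synthetic-data generator

`make_fixture()` builds, from one seed, a single-contig genome
(defaults: six 4-exon genes on alternating strands, ~360-nt CDS each,
~6 kb total), ortholog sets with an invariant core (residues at 35-65%
of the protein) and heavily diverged tails, a planted perfect-match and
a planted two-mismatch off-target copy of one guide, polymorphisms at
VAF 0.20 and 0.05 straddling the 10% cutoff, domain/site/secondary
structure annotations anchored on the known core, an efficacy table,
and a small dropout screen with true fold changes of -2 (essential) and
0 (negative controls) plus lognormal count noise. Every planted truth is
recorded in a manifest so tests assert against construction, not
re-derivation. Sizes were chosen so brute-force oracles (full-scan
off-target search, exhaustive pick enumeration, DP alignment) run in
seconds; the test suite uses a 100-kb random genome for the off-target
equivalence property and n = 5,000 records for model recovery.

What the fixture does not emulate: realistic base composition, repeat
structure and segmental duplication (off-target landscapes in real
genomes are far denser), alternative isoforms, real codon usage,
indel-containing ortholog alignments, overdispersed screen counts, and
any real efficacy signal. Passing tests therefore demonstrate
correctness of the algorithms under their stated definitions, not
predictive performance on real genomes.

## Numerical choices and degenerate inputs

Strict inequalities at every printed threshold (0.40, 7, 0.95, 0.50,
0.25); boundary values fail. NA features fail their criterion rather
than erroring. Transcripts failing CDS invariants are rejected with a
logged reason, not fatally. Zero-guide genes return empty picks with a
message. Aliased model columns drop with a warning. The
rank-deficiency fallback for subset R-squared uses a QR solve. All
randomness in fixtures and simulations flows from explicit integer
seeds, and generator functions restore the caller's RNG state.

## Known limitations

Hamming-only off-target search (no DNA/RNA bulges); single-cut NMD
model without splice-isoform weighting; conservation requires
user-supplied ortholog sets (no homology search is run); the efficacy
surrogate is a placeholder; the tier-2-6 relaxation order is an
assumption recorded in the tier table; proteome-restricted specificity
penalizes splice-junction guides by construction.
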