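---
title: "Predicting polysaccharide utilization loci in marine Bacteroidetes metagenomes"
author: "pulseekR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting polysaccharide utilization loci in marine Bacteroidetes metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulseekR)
```

## The problem

Marine *Bacteroidetes* respond to phytoplankton blooms by degrading algal
polysaccharides (laminarin and other β-glucans, α-glucans, mannose-rich
polymers, sulfated xylans, alginate). The genomic unit of this capability
is the polysaccharide utilization locus (PUL): a co-located set of genes
encoding carbohydrate-active enzymes (CAZymes), often sulfatases, and the
SusC/SusD transporter tandem that captures oligosaccharides at the outer
membrane. In time-series metagenomes the analysis questions are: which
loci exist, what do they degrade, which approximate species carry them,
and when are those species abundant or their transporters expressed.

pulseekR implements that analysis chain for metagenome-assembled genomes
(MAGs) and their contigs: evidence filtering, locus calling, substrate
classification, MinHash (Mash) species clustering, SusC/D dereplication,
and RPKM/%NSAF quantitation — plus a synthetic-data module that generates
every input with planted ground truth, so the whole chain is testable
without external databases or sequencing data.

## Two-tier annotation

Genes receive roles from two evidence streams:

1. **Domain hits** (HMMER domtblout dialect) against CAZy family models,
   the sulfatase model PF00884, the four SusD models (PF07980, PF12741,
   PF14322, PF12771) and the SusC model TIGR04056. `filterDomainHits()`
   keeps a hit when it covers ≥ 30% of the model and its independent
   e-value passes a length-tiered ceiling (1e-5 for alignments longer
   than 80 aa, else 1e-3 — the dbCAN parser convention, applied uniformly
   to CAZy, Pfam and TIGRFAM models). When two hits on one gene overlap
   by more than half of the shorter aligned region, the lower e-value
   wins (ties: higher bitscore, then lexicographic model id) — a
   deterministic, idempotent resolution.
2. **Similarity confirmation**. A CAZyme annotation survives only if the
   gene also has a DIAMOND/BLAST-style hit to a protein of the *same*
   CAZy family at ≥ 30% identity, ≥ 40% query coverage and e-value
   ≤ 1e-20. Families compare at subfamily resolution only when both sides
   carry a subfamily suffix (GH5_46 vs plain GH5 counts as a match,
   GH5_46 vs GH5_12 does not), because similarity subjects are often
   listed at family level.

Only confirmed CAZyme families, plus the sulfatase/SusC/SusD roles, feed
locus calling. A gene whose confirmed families are all
glycosyltransferases and which has no other role is flagged GT-only.

## Locus calling

`callPuls()` chains marker genes (any role) along each contig: two
consecutive markers stay in one chain when strictly fewer than 10 genes
lie between them ("less than ten genes apart" is read literally; the gap
is configurable). Each maximal chain with ≥ 3 markers is a candidate
unless its markers are exclusively GT-only. A candidate is retained when
it has ≥ 1 susC- or susD-like gene and ≥ 2 genes with confirmed GH or PL
families (CE, GT and CBM are not degradative). Chaining is
strand-agnostic, and a chain touching a contig end is reported with a
truncation flag. One chain yields one locus even when it carries two or
three susC/D pairs; two loci are reported only when two disjoint chains
exist. Because chains are maximal, the order of chaining and filtering is
immaterial.

## Substrate classification

The five substrate classes are recognised from family composition by ten
prioritised rules (`defaultSubstrateRules()`), distilled from the
recurrent locus patterns: three β-glucan/laminarin variants
(GH16+GH3; GH16+GH30_1+GH17; GH5_46+GH16), simple and complex α-glucan
(GH65+GH13; ≥ 2×GH13), sulfated and sulfatase-free α-mannose-rich
(≥ 3×GH92 + ≥ 2 sulfatases; GH92+GH130+GH20+GH18 without sulfatases), two
sulfated-xylan patterns (GH10+GH3+2 sulfatases;
GH30+GH10+GH43_1+3 sulfatases) and alginate (any two of PL6/PL7/PL17).
More-constrained rules carry higher priority so "first match" is well
defined; when several rules match, the call is still the
highest-priority one and the locus is flagged `multi_match` for
inspection. The rules ship as editable YAML
(`writeSubstrateRules()`/`readSubstrateRules()`), not code constants,
because the source patterns are prose-level descriptions rather than
formal minima. Loci lacking a GH16 but carrying GH5_46+GH30_1 classify
as unknown unless the relaxed variant-C rule is switched on
(`relaxedLaminarinC`), mirroring the uncertainty about those loci.

## Approximate-species clustering

`sketchSequence()` builds a bottom-1000 MinHash sketch over canonical
21-mers (lexicographic minimum of a k-mer and its reverse complement;
ambiguous-base windows are skipped and counted). The hash is a seeded
splitmix64 finalizer over the 2-bit k-mer encoding, truncated to 53 bits
so hash values round-trip exactly through R doubles; the seed is recorded
in sketch JSON so sketches are reproducible and comparable.
`mashDistance()` uses the union-sketch Jaccard estimate (shared hashes
among the s smallest of the merged sketch) and
D = −(1/k)·ln(2j/(1+j)), capped at 1 when j = 0. At k = 21 this distance
tracks substitution divergence closely, so D ≤ 0.05 approximates ≥ 95%
average nucleotide identity — the usual same-species bound and the
default clustering threshold.

`clusterMags()` forms single-linkage connected components at that
threshold (matching the network depiction of approximate-species
clusters; complete linkage is available as a config alternative).
Quality gates: a multi-MAG cluster is kept when ≥ 2 members reach 70%
completeness; a singleton is dropped only when completeness ≤ 70% *and*
contamination ≥ 10% — the asymmetry follows the published gates. The two
most complete members represent a cluster (ties: lower contamination,
then id), and a cluster is flagged abundant when its representative-mean
RPKM strictly exceeds 5 in one sample or 38 summed over all samples.

## SusC/D dereplication and taxonomy votes

`clusterSusGenes()` replaces tree inspection with greedy centroid
clustering at ≥ 95% nucleotide identity: genes are processed in
descending length order (ties by id), each joining the first cluster
whose founder it matches, else founding its own — deterministic and
order-stable. Identity is Needleman–Wunsch matches divided by alignment
columns, so gaps (including end gaps) count against identity; a
shorter-sequence denominator is available via
`identityDenominator = "shorter"`. A cluster becomes a representative
when present in ≥ 4 metagenomes, or in 3 with expression support (a
proteome protein matching at ≥ 90% amino acid identity).

Taxonomy is voted from members' Mash-clusters: `assigned` when one
Mash-cluster holds at least half the votes and is the unique maximum;
`putative` for a strict plurality below half; `clade` when tied voters
all share one clade; otherwise `unassigned`. Members without an
assignment abstain (they are excluded from the denominator — the
published rule leaves that denominator open, and excluding abstentions
keeps the four outcomes exhaustive). At an exact 50/50 split there is no
unique majority cluster, so the vote falls through to the clade rule.

## Quantitation

RPKM follows the printed formula exactly:
RPKM = mapped_reads × 10⁶ / (assembly_length_kbp × total_reads); a
Mash-cluster's abundance is the mean over its representatives. As a
documented conversion only, 2 RPKM corresponds to roughly 1% relative
abundance by FISH calibration; the package never computes with it.
%NSAF is the percent share of length-normalized spectral counts,
%NSAF_i = 100·(SpC_i/L_i)/Σ_j(SpC_j/L_j); each sample column sums to
100 and a protein holding 1% of the length-normalized counts scores
exactly 1. Technical duplicate runs are merged per sample before
normalization (mean by default, sum optionally). `linkExpression()`
links an expressed protein to the representative cluster with the
highest global amino acid identity when that identity reaches 90%.

## What the synthetic data emulates — and what it does not

The generator (`makeGenome()`, `mutateGenome()`, `plantPuls()`,
`simulateCounts()`, `simulateSpectra()`) is first-class, tested code.
Genomes are i.i.d. nucleotide sequences with controlled GC; divergence is
i.i.d. per-site substitution, so a pair at p = 0.03 has 97% ANI by
construction. Planted loci follow the ten template gene lists and are
emitted both as truth-level role labels and as raw evidence tables whose
scores pass the filters, alongside decoys that each violate exactly one
retention rule (no susC/D; one GH/PL; markers 10 genes apart; GT-only)
and noise hits that must be filtered out. Counts are multinomial with
probabilities proportional to abundance × length (reads) or
expression × length (spectra).

Real data differ in ways the generator deliberately ignores: genomes have
repeats, skewed k-mer spectra and indels (so real Mash distances scatter
more around 1 − ANI than i.i.d. substitution does); real annotation
evidence contains borderline scores rather than clearly passing/failing
ones; real loci deviate from templates; read mapping has reference and
mismapping biases that the multinomial model omits. Green tests therefore
demonstrate that the *rules are implemented exactly as stated*, not that
the rules are robust to noisy evidence.

## Numerical and design choices

* Default problem sizes keep the suite fast while leaving no estimator
  degenerate: 1 Mbp genome pairs for the distance/ANI check, 5 kb pairs
  against the exact brute-force Jaccard oracle (binomial error of the
  1000-hash estimator stays within 0.05), a 90-contig corpus (50 planted
  loci, 40 decoys) for caller recall/precision, and 100 replicates of
  3-MAG × 5-sample multinomial counts for rank recovery.
* Hash truncation to 53 bits loses nothing at these scales (collision
  probability among ≤ a few million k-mers is negligible) and keeps hash
  values exact in doubles.
* All thresholds live in one validated `PULConfig` object whose defaults
  are the published values; every output file header carries the full
  configuration stamp for provenance.
* Strict inequalities are used exactly where the source wording says
  "exceeding" (abundance flags) and inclusive ones where it says "at
  least"/"up to" (marker counts, identity and coverage thresholds);
  boundary fixtures pin each of these in the test suite.
* Degenerate inputs fail loudly: all-zero %NSAF columns, empty
  sequences, asymmetric distance matrices, hits referencing unknown
  genes, and negative RPKM are errors rather than silent zeros.

## A small worked example

```{r example, eval = FALSE}
td <- tempfile()
run <- runSyntheticPipeline(td, seed = 1)
run$puls
scoreAgainstTruth(run$puls, run$truth)
```

On the default corpus (one contig per template and decoy mode) the
caller recovers every planted locus, rejects every decoy, and each locus
classifies to the substrate its template encodes.

## Limitations

* Noncanonical PULs whose susC/D pair lies elsewhere in the genome are
  invisible to the caller — a stated property of the locus definition,
  not an implementation gap.
* Substrate rules are composition heuristics; they support, but cannot
  replace, biochemical validation.
* Greedy centroid clustering approximates the tree-based grouping it
  stands in for; near-threshold sequences can depend on centroid choice,
  which the fixed processing order makes deterministic but not
  order-free in the mathematical sense.
* Completeness/contamination estimation, read mapping, phylogenetic tree
  building and mass-spectrometry searching are out of scope; their
  outputs are inputs here.
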