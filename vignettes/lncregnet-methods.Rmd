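---
title: "Methods: lncRNA identification, regulatory networks, and miRNA decoys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA identification, regulatory networks, and miRNA decoys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncregnet)
```

`lncregnet` implements a complete desk-scale pipeline for the analysis
of long noncoding RNAs (lncRNAs) in a stress-treatment transcriptome
time course, of the kind produced for Chinese cabbage under heat
treatment: a five-stage design (control plus four heating durations),
three biological replicates per stage, an assembled transcriptome, and
FPKM expression values. This vignette is the package's account of the
models and procedures it implements, the parameters that matter, and
the choices made where the methods literature leaves the design open.

## 1. lncRNA identification

Assembled transcripts are screened by an ordered cascade
(`filter_candidates()`); a transcript is removed at its first failing
step, and the full trace is kept:

1. **Length** — transcripts shorter than 200 nt are excluded, so a
   200-nt transcript is kept (`min_length`, nt).
2. **Mono-exonic reliability** — single-exon models are the least
   reliable product of reference-guided assembly. With no assembler
   internals available post hoc, expression is the only usable
   reliability signal: mono-exonic transcripts whose maximum FPKM over
   all samples is below 2 are removed
   (`drop_monoexonic_below_fpkm`). The cutoff is configurable and is
   recorded with each run.
3. **Coding-exon overlap** — transcripts with at least 1 bp of exonic
   overlap with a protein-coding exon *on the same strand* are
   removed. Antisense overlap is deliberately *not* a removal
   criterion, because antisense overlappers are a retained lncRNA class
   (lncNAT, below). A direct strand-aware interval test replaces
   assembler class codes.
4. **Coding potential** — external coding/noncoding labels are the
   preferred input (the dedicated coding-potential classifiers are out
   of this package's scope). When labels are absent, a documented
   stand-in is used: longest ATG..stop open reading frame across the
   three forward frames, calling a transcript coding at ≥ 100 aa
   (`orf_aa_cutoff`). The stand-in is *not* equivalent to the
   dedicated classifiers and is labelled as such.

Survivors are classified by genomic position (`classify_lncrnas()`):

* **lncNAT** — ≥ 1 bp exon overlap with a coding exon on the opposite
  strand;
* **incRNA** — transcript span wholly inside one intron of a coding
  transcript, either strand (the literature does not constrain the
  strand; we allow both);
* **lincRNA** — everything else (intergenic).

Precedence is lncNAT > incRNA > lincRNA, which resolves transcripts
that are simultaneously inside an intron of one gene and
antisense-overlapping an exon of another. The partition is exact:
every retained transcript receives exactly one class.

Two boundary readings deserve a note. The length rule follows the
"shorter than 200 bp are excluded" formulation (200 kept), which we
take over the looser "> 200 nt" shorthand common in abstracts. All
internal coordinates are 0-based half-open; GFF3/GTF conversion happens
only at the I/O boundary (`read_annotation()` / `write_annotation()`),
which eliminates whole classes of off-by-one errors.

## 2. Expression, detection, and differential expression

The expression container (`fpkm_matrix()`) is a features-by-samples
FPKM table carrying the sample-to-stage design. A feature is *detected*
at a stage when its mean FPKM over that stage's replicates exceeds 0.1
(`min_fpkm`); no universal threshold exists in the field, so the value
is configurable and recorded. Stage-exclusive features are exact set
arithmetic over the per-stage detection sets.

Differential expression between a treatment stage and the control is a
deliberately simple stand-in (`de_call()`): per-feature two-sample
t-test on `log2(FPKM + 1)` with Benjamini–Hochberg adjustment across
features within the comparison, significant at `q < 0.05`. It is not
equivalent to assembly-aware DE frameworks; pipelines that have a
precomputed DE table can supply it downstream and skip the stand-in.

Pearson correlation (`pcc()`) is computed by direct summation with the
two-sided p-value from `t = r·sqrt((n−2)/(1−r²))` on `n − 2` degrees
of freedom. The correlation basis for network inference defaults to
the five per-stage means (`pcc_basis = "stages"`, n = 5) because the
design's natural unit is the treatment stage; all fifteen replicate
columns can be used instead (`"replicates"`), and the two give
materially different p-values at fixed r — with n = 5, |r| must exceed
0.9587 to reach p < 0.01. Both bases are first-class; neither is
asserted as "the" original computation.

## 3. Regulatory networks (cis, trans, SA)

* **cis** (`cis_targets()`): protein-coding genes whose span lies
  within 100 kb upstream or downstream of a lncRNA span. Distance is 0
  for any overlap, otherwise the gap between nearest boundaries, and
  the window boundary is inclusive (distance ≤ 100,000); a strict
  variant is available (`window_exclusive`). Distance is measured
  boundary-to-boundary, not TSS-to-TSS, since the window is anchored
  on the lncRNA as a whole.
* **trans** (`trans_targets()`): an edge for every (DE lncRNA, DE
  mRNA) pair with `|r| > 0.95` *and* `p < 0.01`, both strict, per the
  conventional wording of these cutoffs. Constant features are skipped
  with a message, never fatal. When a DE table is supplied, each edge
  records the comparisons in which *both* endpoints are DE — the
  per-comparison Venn semantics of a four-comparison design.
* **both** (`combine_cis_trans()`): the pair-key intersection,
  retaining distance, r and p.
* **SA pairs** (`sa_pairs()`): opposite strands and ≥ 1 bp of span
  overlap. SA pairs are by construction a subset of the
  distance-zero cis edges.

## 4. miRNA decoys (eTMs) and the ceRNA network

The package's central algorithm is a rule-based search for endogenous
target mimicry sites: lncRNA sites that bind a miRNA with a bulged,
near-perfect duplex and thereby sequester it.

`duplex_search()` enumerates *every* candidate: all target windows of
length `L + b` (miRNA length L, bulge length `b ∈ {0, 2, 3, 4}`) at
all offsets, and for bulged windows all insertion points
`k ∈ {9, 10, 11}` — the bulged target bases sit between the bases
paired to miRNA positions k and k+1, i.e. opposite the 9th–12th
positions counted from the miRNA's 5′ end. ("9th to 12th positions" is
read as this opposite-interval; the eTM literature centres bulges at
positions 10–11, which this reading covers.) Strands pair
antiparallel, each position classed Watson–Crick, G:U wobble, or
mismatch.

`decoy_filter()` applies four rules; all must hold:

1. hybridization energy strictly below −25 kcal/mol;
2. bulge absent, or length 2–4 at an allowed insertion point;
3. perfect Watson–Crick pairing at miRNA positions 2–8 (the seed):
   G:U counts as a violation under the strictest reading of "perfect
   pairing" (`seed_allow_gu` relaxes this);
4. at most 4 mismatches over the pairing region, bulged bases not
   counted.

Every failed rule is recorded, so rejections are attributable.

**Energy model.** `duplex_mfe()` sums nearest-neighbor stacking free
energies over consecutive paired positions, using the published
Turner-2004 RNA/RNA stack table at 37 °C shipped as a versioned CSV
(`inst/extdata/turner2004_rna_stacks.csv`, kcal/mol; symmetric under
helix reversal, all WC/WC entries negative — both asserted at load).
A bulge adds a length-dependent loop initiation penalty (+2.8, +3.2,
+3.6 kcal/mol for lengths 2–4) and each interior mismatch a flat
+1.5 kcal/mol; a duplex with no paired position scores exactly 0.
This is a transparent stack-sum, not a full secondary-structure
folder: coaxial effects, dangles and suboptimal hybridizations are
out of scope. An extreme-value duplex p-value would require
calibration against a sequence background that the original tooling
does not publish; it is therefore omitted, with the energy cutoff as
the operative rule.

**Targets.** `predict_targets()` scans mRNAs gaplessly with an
expectation-style penalty score (`expectation_score()`): 0 per WC
pair, 0.5 per G:U, 1 per mismatch (2 per gapped nt, were gaps
allowed), doubled at miRNA positions 2–13 — the extended-seed
weighting conventional in plant target prediction. A site is accepted
at expectation ≤ 3 (inclusive) with complementarity-scored length
≥ 20 nt. Target-site accessibility (the "energy to unpair" cutoff
≤ 25) would need a partition-function fold; a documented proxy (the
sign-flipped stack-sum energy of the site against its own reverse
complement) is available behind `check_upe` and disabled by default.

`build_triads()` cross-references accepted decoy (lncRNA, miRNA) pairs
with accepted target (miRNA, mRNA) pairs: one ceRNA triad per
(lncRNA, miRNA, mRNA) sharing the miRNA.

## 5. Conservation and precursor families

`homology_search()` is a deterministic seeded aligner: exact 11-mer
seeds, ungapped best-segment extension per diagonal (match +1,
mismatch −2), and a Karlin–Altschul-style E-value
`E = K·m·N·exp(−λS)` with fixed λ = 1.33, K = 0.621 for this scoring
scheme (documented constants, not tuned). Hits require `E < 1e-5`,
strict. The aligner exists so the whole pipeline is testable with no
external binary; BLAST tabular output (`read_blast_tab()`, same strict
cutoff) is the interchangeable production path. Precursor scanning
(`precursor_scan()`) searches lncRNAs against miRNA hairpins and
collapses hits to the family level (header token before the species
suffix), and `family_presence()` / `unique_common()` implement the
common-to-a-subset / unique-to-one-species set accounting.

One reporting convention: printed percentages use `round()`
half-even at 2 digits (`percent_of()`), which makes every printed
number in tests deterministic. Published tables occasionally truncate
instead (285/524 = 54.389% appearing as 54.38%); the package reports
the rounded value.

## 6. What the simulators emulate — and what they do not

The generators (`simulate_annotation()`, `simulate_expression()`,
`simulate_cerna()`, `simulate_species_sets()`) produce every input the
pipeline consumes, with planted ground truth, as a pure function of
the seed. Every planted object is re-verified against the consuming
module's own predicate before emission, so a generator cannot hand the
tests an inconsistent truth table.

* The toy genome lays coding genes (three exons, two introns) on a
  fixed grid and plants lncRNAs that satisfy each positional-class
  definition exactly, plus one violator per filter step.
* Expression uses a small profile library — early-spike (the classic
  rapid heat-shock response), early-drop (ABA-receptor-like), late
  rise — with multiplicative log-normal noise (s.d. 0.05 on the log2
  scale by default) and zero-truncation. Planted coexpressed pairs
  share a profile.
* Decoy fixtures construct, per miRNA, one rule-conformant site
  (bulge of 3 at k = 10, perfect seed, strong GC-rich helix) and one
  site per rule violating exactly that rule. The energy violator
  exploits composition: an A/U-only 21-mer helix cannot reach
  −25 kcal/mol (its best alternating stack sum is ≈ −24), so a perfect
  A/U duplex fails energy and nothing else.
* Species panels copy reference sequences with ≤ 5% mutation (planted
  homologs) and embed hairpin copies according to a presence plan with
  known common/unique answers.

Default scale — 200 coding genes, 30 lncRNAs per class, 10 per filter
violation, a 5 × 3 matrix over 330 features, 100 planted coexpressed
pairs, 10 miRNAs (50 decoy-site hosts), 5 species — keeps the full
end-to-end run under a minute on one CPU; the test suite uses a
smaller variant of the same structure per file.

What passing on these fixtures does *not* show: real assemblies
contain fragmented and strand-ambiguous models, expression is not
log-normal around three clean archetypes, real decoy sites live in
structured RNA contexts the stack-sum energy ignores, and genuine
homology search contends with repeats and compositional bias. The
fixtures validate the *logic* — boundaries, rules, set arithmetic,
recovery under calibrated noise — not biological discovery
performance.

## 7. Numerical and design notes

* All thresholds live in `default_config()` with the conventional
  values as defaults, so any deviation is explicit and recorded in the
  run manifest (`run_pipeline()` writes per-file md5 checksums;
  identical configurations reproduce byte-identical outputs).
* Strict vs inclusive boundaries are pinned by tests: length 200 kept;
  E = 1e-5 dropped; |r| = 0.95 dropped; p = 0.01 dropped; expectation
  = 3.0 kept; cis distance = 100,000 kept; mfe = −25 rejected.
* Enrichment (`hypergeom_enrich()`) is a plain hypergeometric upper
  tail with BH correction; the background defaults to expressed genes
  (the more conservative choice when the original background is
  unstated) and is configurable. No ontology-graph propagation is
  performed; length-bias correction is out of scope.
* Degenerate inputs: empty candidate sets flow through every module as
  empty tibbles; constant expression vectors are skipped with a
  message; a mono-exonic transcript absent from the expression table
  counts as FPKM 0 (and is therefore removed by the reliability
  filter at the default cutoff).
* This package is a fresh implementation built for testability; it is
  not a wrapper around, nor a drop-in reimplementation of, the
  external alignment, assembly, coding-potential or hybridization
  tools whose roles its modules occupy.
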