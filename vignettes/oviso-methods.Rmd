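---
title: "Methods: isoform catalogs, splicing events and differential analyses in oviso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform catalogs, splicing events and differential analyses in oviso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oviso)
```

## Scope and data model

`oviso` re-implements, as a tested pipeline, the downstream analysis of a
long-read (Iso-seq) + short-read (RNA-seq) + CTCF ChIP-seq study of muscle
isoform diversity in two crossbred sheep groups (DDH and DHH, three animals
each). The package takes over where alignment ends: full-length
non-concatemer (FLNC) isoform candidates arrive as spliced alignments, and
everything downstream — candidate filtering, annotation updating, splicing
event classification, differential testing, peak annotation, gene-set
overlap and trait statistics — is computed here.

All coordinates are held internally as 0-based half-open intervals;
GFF3 I/O converts to and from the 1-based inclusive dialect at the file
boundary. Strand `"."` is rejected at parse time because every downstream
rule (junction identity, promoter orientation, 5′/3′ labelling) is
strand-conditional. A transcript model is an ordered chain of disjoint
exons; its intron chain — the ordered gaps between consecutive exons — is
the identity used throughout: two transcripts with the same intron chain
have the same splicing structure. Single-exon transcripts are valid
everywhere and have an empty chain.

## Candidate retention (the four-criterion filter)

An FLNC candidate is kept when it meets **any** of:

* **C1** — supported by at least two FLNC reads;
* **C2** — a single read with alignment percent identity (PID) strictly
  above 99;
* **C3** — every intron confirmed by the short-read junction set;
* **C4** — every intron already present in the reference annotation.

Two reading choices deserve comment. The fourth criterion is stated in the
source methodology at the level of "alternative splicing events", which is
not computable without an event inventory on both sides; `oviso`
operationalizes it as intron-level containment in the reference intron
universe, isolated behind a single predicate so an event-level variant can
be swapped in. Mono-exonic candidates satisfy C3 and C4 vacuously — the
criteria quantify over splice sites, and none exist.

## Redundancy collapse and locus assignment (the 20% rule)

Candidates overlapping less than 20% of their length on the same strand are
distinct isoforms; at or above 20% they are treated as redundant
observations of one isoform and collapsed by single-linkage clustering.
"Length" here is **exonic** length (the sum of exon sizes), not genomic
span: span-based fractions inflate overlap for genes with long introns,
while exonic overlap is what junction-level identity actually reflects. The
fraction is taken relative to the **shorter** model, the permissive reading
that an unstated reciprocal rule would only tighten. Cluster
representatives are chosen by FLNC support, then exonic length, then
lexicographic id, and carry the cluster's summed read count, so support is
conserved.

The same rule assigns representatives to known genes (the gene with the
largest qualifying fraction wins) and clusters the remainder into novel
loci named `NG.<chrom>.<k>`, numbering leftmost starts per chromosome.

## Known versus novel isoforms

An isoform is **known** when some transcript of its locus has an identical
intron chain and a 3′ terminus within 50 bases (configurable). The
tolerance exists because long-read 3′ ends jitter; exact matching would
classify essentially every faithful read as novel. Otherwise the isoform is
novel, with the first applicable reason:

1. `novel_locus` — the locus itself is new. This is checked first, a
   deliberate reordering: in a novel locus there are no reference
   transcripts, so any intron would be trivially "new" and the more
   specific label would never be reached.
2. `new_intron` — an intron absent from every locus transcript (exon
   skipping, alternative splice sites and mutually exclusive exons all
   leave this signature).
3. `new_exon` — an exonic region more than 50 bases outside the locus exon
   union, **restricted to the locus span**. The restriction matters:
   without it a long 3′ extension would be miscalled as a new exon, when
   the defining rule treats changed 3′ ends as their own category.
   Intron retention leaves this signature.
4. `changed_3prime_end` — structure otherwise explained by a reference
   transcript, but the 3′ terminus moved beyond tolerance. 5′-only
   differences deliberately do **not** confer novelty, mirroring the
   asymmetric definition in the source methodology.

Novel isoforms are merged into the annotation with ids
`<chrom>.<locus index>.<isoform index>` (the visible id shape of the
study, e.g. `7.524.18`), indices assigned in genomic order for
determinism. Feeding the updated annotation's own transcripts back through
the pipeline adds nothing — idempotence is a tested invariant.

## Splicing event classification

Events are found by comparing intron chains of two isoforms **within their
shared genomic span only**, so transcript end differences are never
reported as splicing events. Five canonical types are recognized: exon
skipping (an intron of one model strictly contains a full exon of the
other, with both intron boundaries present as splice sites of that other
model), intron retention (an exon covers an intron plus parts of both
flanking exons), alternative 5′/3′ splice sites (two introns sharing
exactly one boundary; the changed side is labelled by transcription
direction, so a strand flip maps one label onto the other), and mutually
exclusive exons (distinct internal exons between a shared pair of outer
splice sites). Alternative-site calls are suppressed when the differing
region swallows a complete exon — that configuration belongs to the
skipping/mutually-exclusive rules, and the suppression is what keeps the
five types disjoint. Alternative first/last exons and the full structural
grammar of graph-based event tools are out of scope.

A genome-wide count deduplicates events by `(type, variant region)` rather
than by isoform pair, matching the notion of an event inventory.

## Differential testing

One negative-binomial engine serves both isoform counts and peak counts,
because the two tools cited for these steps in the source methodology both
reduce to NB generalized linear models. Exact numeric parity with either
tool is a non-goal; the engine is deliberately simple and fully specified:

1. **Normalization** — median-of-ratios size factors (features with any
   zero count are excluded from the geometric-mean reference; a
   pseudo-reference fallback over positive counts is available by flag).
2. **Dispersion** — per-feature method-of-moments on normalized counts,
   floored at `1e-8`, then shrunk halfway toward the mean dispersion of the
   feature's expression decile. With three samples per group the raw
   estimate is extremely noisy; the trend borrows strength across features.
3. **Test** — an NB log-link GLM of the group effect with log size-factor
   offsets, dispersion held fixed at its shrunk value; the Wald statistic
   is referred to a t distribution with `4 * (n_samples - 2)` degrees of
   freedom. The df follows from variance matching: the raw
   method-of-moments dispersion carries `n_samples - 2` residual df, the
   decile trend pools hundreds of features and is effectively exact, and
   averaging the two quarters the estimator's variance — a fourfold
   effective df. At the study design (n = 3 vs 3, dispersion 0.1) this
   reference is calibrated: the empirical type-I error at nominal 0.05
   lies near 0.04 across simulation seeds, where a plain normal reference
   is measurably liberal and a `n_samples - 2` df reference has too little
   power to clear multiple-testing thresholds at all.
4. **FDR** — Benjamini–Hochberg step-up (`stats::p.adjust`).

The displayed fold change is `log2((mean2 + 0.5)/(mean1 + 0.5))` of
normalized group means; the +0.5 pseudo-count only guards the display
against infinities — the test uses the GLM estimate. Differentially
expressed isoforms (DEIs) require `|FC| > 2` and `FDR < 0.05`, in both
directions. Differential peaks require `FDR < 0.05` and a strictly nonzero
log2 enrichment in either direction — the "fold greater than zero" rule is
read as two-sided because the study reports both up- and down-regulated
peak sets.

## Peak feature annotation and gene-set overlap

A peak (or read) is classified by its **midpoint** with priority promoter >
5′ UTR > 3′ UTR > exon > intron > intergenic. The promoter window defaults
to ±3000 bases around the TSS (the default of the annotation tool cited
for this step), oriented by the gene's strand; peaks themselves are
strand-less. Under this default the 5′ UTR category is unreachable — UTRs
sit at the TSS, inside the window — which is a documented consequence of
the priority order, not a bug; narrowing `promoter_downstream` exposes it.
An any-overlap variant is deliberately not the default: midpoint
classification makes the six categories a partition, so counts always sum
to the number of subjects.

"Genes located in differential peaks" means any peak overlapping the gene
span **or** its promoter window by at least one base. Overlap significance
between two gene sets is the exact hypergeometric upper tail
`P(X >= overlap)` with the sample odds ratio of the 2×2 table; the
universe defaults to the number of loci in the annotation in use, since
the original universe is unstated.

## Trait statistics and qPCR

Group summaries (mean ± SD, n) are compared with Welch's t test — the
default of R's `t.test`, which is what the source analysis used — with the
pooled-variance form available as an option (for n₁ = n₂ the statistic is
identical; only df and p differ). Reproducing a printed statistic from
rounded summaries warrants a ~2% agreement band, which the shear-force
check meets comfortably.

Relative expression from qPCR follows the Livak 2^−ΔΔCt formulation:
replicate Cts averaged per sample, ΔCt = target − reference gene,
ΔΔCt baselined on the calibrator group's **mean ΔCt** (so the calibrator's
mean ΔΔCt is exactly zero; its mean relative expression need not be
exactly 1 — the geometric/arithmetic gap). Primer-efficiency-corrected
(Pfaffl) quantification is out of scope.

## The synthetic-data generator

Raw study data live in a sequencing archive and are out of scope for
testing; every pipeline input is instead simulated with the statistical
structure the analysis assumes, with ground-truth tables, as pure
functions of `(config, seed)`:

* **Annotation** — non-overlapping loci with 10–30 kb gaps on chromosomes
  `chr1..chrN` plus `chrX` (exercising non-numeric naming), 4–10 exons of
  80–300 bases, introns of 250–1500 bases, 1–3 isoforms per locus
  (truncation variants), UTRs with probability 0.7.
* **FLNC candidates** — copies of reference transcripts, half of them (by
  default) perturbed with exactly **one** planted change: an event from
  the mix (30% exon skipping, 25% intron retention, 15% each alternative
  site, 15% mutually exclusive) or, for 20% of novel candidates, a 3′-end
  shift of 80–300 bases. One planted change per candidate keeps classifier
  recovery unambiguous; the generator additionally rejects perturbations
  whose product collides with a sibling isoform's chain (e.g. retaining
  the last intron can reproduce a truncated sibling) and plants 3′ shifts
  only on transcripts forming their locus's 3′ extreme — in both corner
  cases the "planted" novelty would be genuinely ambiguous, and the
  classifier's answer would be defensible either way. Read support is
  `1 + NB(1.5, 1)` and PID is `100 − Gamma(2, 0.8)`, giving realistic
  mixes of single-read and low-identity candidates.
* **Junctions** — every true intron enters the short-read set independently
  with probability 0.85 (support is never complete in practice).
* **Counts** — the study design: two groups of three samples, log-normal
  (log 100, 1) baselines, NB dispersion 0.1, log-normal (sd 0.15)
  per-sample depth factors, 10% of features carrying |log2FC| = 2 with
  random sign.
* **Peaks** — 200 peaks placed by a category mix over the six feature
  classes (5′ UTR weighted 0 under the default promoter window, see
  above), three replicates per condition mirroring the three animals per
  group, 20% differential at |log2FC| = 3 — differential transcription
  factor occupancy is typically near presence/absence.

What the generator does **not** emulate: read-level errors and coverage
biases, alignment artefacts, correlated dispersion structure, overlapping
and nested genes, alternative promoters, and genuinely ambiguous splicing
configurations. Passing tests therefore demonstrate that the
implementations compute their definitions correctly under the stated
statistical model — not that the pipeline is robust to every pathology of
real sheep data.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at the sizes the
analyses were designed around: 2000 features × 6 samples for calibration
and recovery (three seeds), 500 perturbation pairs for classifier
recovery, 60-gene annotations for pipeline runs, and exhaustive
enumeration up to universe 30 for the hypergeometric check — sizes chosen
so each property is measured with useful precision while the whole suite
stays interactive. Ties anywhere (representative choice, gene assignment,
locus numbering) break by support, then length, then lexicographic id, so
every output is reproducible byte for byte. Dispersion estimates are
floored at `1e-8`; degenerate inputs (all-zero features, empty junction
sets, single-transcript loci, empty annotations) are all defined cases
with tested behavior, not errors.

## Known limitations

* The four-criterion filter's C4 is junction-level, not event-level (see
  above); both readings are consistent with the source text.
* The 20% rule's reference (shorter / query / reciprocal) is configurable
  because the original is unstated; results at other settings differ.
* The NB engine is a simplified stand-in: it will not numerically match
  DESeq2 or DiffBind, and it fits no multi-factor designs.
* Isoform quantification from reads, motif discovery, GO/KEGG enrichment
  and all upstream alignment stages are out of scope.
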