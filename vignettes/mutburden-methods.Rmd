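---
title: "Measuring chemically induced mutation load from multi-sample resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chemically induced mutation load from multi-sample resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chemical mutagens such as EMS (ethyl methanesulfonate) are used in
breeding programs to inflate the mutation supply available to
selection. To know whether a treatment worked, one resequences treated
and untreated individuals and asks: how many *extra* mutations does a
treated genome carry, of what kind, and where? The difficulty is that
any two individuals already differ at millions of standing polymorphic
sites, so raw variant calls overwhelmingly reflect population variation,
not mutagenesis. `mutburden` implements the downstream analysis for
such screens, starting from per-sample variant calls (VCF), a reference
genome (FASTA) and gene models (GFF3).

## Shared-type removal

Each call is reduced to a five-field identity — chromosome, position,
reference allele, alternate allele, and a two-class genotype code
(heterozygous / homozygous-alternate). A treated sample's
"group-specific" (unique) mutations are its calls whose identity occurs
in *no* control sample. Because published screens of this design also
report nonzero unique counts for the controls themselves, control
samples are filtered leave-one-out by default: each control subtracts
the key union of the *other* controls. Two alternatives are available
(`control_union`, where controls subtract the full union including
themselves, and `group_intersection`, which subtracts only keys present
in both group unions), and the genotype class can be dropped from the
key (`ignore_geno = TRUE`) for callers with unstable genotype calls.

The genotype code is part of the key because the source tables for this
analysis list it among the matched fields; whether it separates het from
hom calls is a convention, not a biological fact, hence the switch.
Variants are normalized before keying (shared suffix then prefix
trimmed; InDels shifted left while the preceding reference base
continues the repeat they sit in) so that keys are comparable across
callers. The left-shift deliberately stops at the boundary of the local
repeat window — the anchor base is kept inside the repeat rather than
extended to an arbitrary 5' base — and is idempotent; tests verify that
the normalized representation always reproduces the same edited
haplotype as the input.

## Annotation

Region labels follow the usual annotator conventions: `exonic` if the
position overlaps any exon, else `intronic` inside a gene span, else
`upstream` within a window 5' of a gene's strand-aware start (default
1,000 bp, the common annotator default; the source analysis names an
upstream class without stating a window), else `intergenic`, with
precedence exonic > intronic > upstream across overlapping genes.
Coding effects are computed for SNPs inside CDS by rebuilding the codon
in transcript orientation, substituting the allele and translating with
the standard genetic code: `synonymous`, `nonsynonymous`, `stopgain`,
`stoploss`. Exonic-but-untranslated positions keep the `exonic` region
label but no effect, because the effect classes are codon-defined. When
a SNP hits several transcripts the most severe effect is kept
(stopgain > stoploss > nonsynonymous > synonymous) — a deterministic
tie-break matching common annotator behaviour. InDels are not given
frameshift classes; they are only flagged `cds_indel` when their
reference span intersects coding sequence, which is all the downstream
tables need. Splice-site and UTR classes are intentionally absent: the
summaries this package reproduces never report them.

## Burden statistics

Per-sample mutation rates are percentages of the sample's *clean-base*
total: `100 * count / clean_bases`. This denominator — each sample's
post-QC sequenced bases rather than a fixed genome size — is the
convention under which the published per-sample rates reproduce exactly
(e.g. 144,157 unique SNPs over 10,730,101,234 clean bases gives
0.001343%); a fixed-genome denominator can be substituted by passing a
constant `clean_bases`. The total rate is the SNP rate plus the InDel
rate for the same sample. Group summaries are means with *sample*
standard deviations (n−1), which is the convention that reproduces the
published ±10,115 for the four control SNP counts. Values are kept at
full precision internally; print methods round rates to 6 decimals of
percent and percentages to 2, matching the table layout.

Group comparisons follow the screening literature's SPSS-style
workflow: Shapiro-Wilk and Lilliefors (Kolmogorov-Smirnov with
estimated parameters) normality checks per group; Levene's test
(centered at the mean) for variance homogeneity; for two groups a
Student's t test when Levene's p > 0.05, otherwise Welch's t; for more
than two groups one-way ANOVA with Tukey HSD. If normality fails,
square-root and then natural-log transformations are tried and the one
used is recorded in the result. Whether the original workflow used
Student or Welch for its two-group contrasts is not stated anywhere we
could check; gating on Levene is this package's declared policy. All
tests are two-sided at alpha = 0.05, with no correction across summary
metrics (none is applied in the source workflow either). Groups with
zero variance are reported with a `degenerate` flag instead of
crashing; two constant, separated groups get p = 0.

## Enrichment

Term enrichment is an upper-tail hypergeometric test per term —
`P(X >= k)` for `k` query genes among `K` term genes in a universe of
`N` — with Benjamini-Hochberg adjustment applied within each term
category (BP/CC/MF/pathway), mirroring how GO namespaces are usually
treated; a global mode exists. The universe defaults to all genes in
the annotation because the original universe is unstated. Term maps are
plain 3-column TSVs; no ontology structure (DAG propagation, pathway
topology) is modelled. Because the hypergeometric p-value is discrete,
its null distribution is conservative: the attainable fraction of terms
below 0.05 depends on (N, K, n) and the calibration tests compute that
attainable level exactly rather than assuming 5%.

## The exclusive-gene screen

The phenotype screen builds a gene-by-sample matrix of
amino-acid-changing SNP presence (nonsynonymous, stopgain and stoploss
all change the protein and count by default; a switch restricts to
missense) from the filtered, annotated calls, then returns genes present
in at least `min_target_samples` samples of the target group and absent
from every sample of the excluded groups. The source procedure requires
presence "only" in the target group without saying in how many of its
members; the default is any one member, and `min_target_samples` can
demand all of them. Lists for two disjoint target groups (largest vs
smallest animals) are disjoint by construction whenever each excludes
the other.

## The synthetic cohort

`simulate_cohort()` generates the full study design so every stage is
testable without any external data: a random genome (default 1 Mb over
2 chromosomes at 35% GC, matching the sequenced animals' base
composition) carrying non-overlapping multi-exon genes whose CDS are
written in as valid ORFs; a shared variant pool; and one variant set
per individual for 4 controls and 12 treated animals (5 large, 5
normal, 2 small).

Key generator choices, fixed once as the study conditions:

* **Private mutation rates.** Controls 1.55e-5 and treated 1.4e-4
  events per bp — a 9.0 ratio, the fold change the analysis is built to
  detect; the treated rate's InDel share is 0.166, the ratio of the
  published InDel and total rates.
* **Spectrum.** Transitions with probability 0.53 (Ts/Tv about 1.13, the
  published regime for treated samples); treated transitions originate
  at G:C pairs with probability 0.8, reflecting alkylation chemistry.
  The direction of the G:C bias is exposed as a parameter rather than
  hard-coded because descriptions of EMS chemistry disagree on whether
  the product is G:C→A:T or G:C→T:A; only the transition *fraction*
  affects the summaries tested here.
* **Selection-like depletion.** Events landing in CDS are thinned by a
  factor 0.95, emulating the survivor bias that depletes exonic and
  nonsynonymous hits.
* **Shared pool.** 1e-3 sites per bp, of which 2% segregate at
  intermediate frequency (genotypes drawn per sample under
  Hardy-Weinberg) and 98% are fixed differences against the reference
  (homozygous-alternate in everyone). Fixed differences are removed
  perfectly by shared-type filtering, as in real data; segregating sites
  occasionally evade it when a sample's genotype class is absent from
  the control panel, leaving a realistic residue of "unique" calls in
  control samples. The segregating share is kept small so that this
  residue stays well below the private-mutation signal — with a large
  segregating pool the filter residue would dominate the control
  numerator and no rate configuration could make the estimated fold
  change track the configured ratio.
* **Clean bases.** Per-sample normal draws around 11.2x the genome
  length with 9% spread (clipped positive), emulating the spread of the
  published sequencing yields, so rate denominators vary by sample as
  in real data.
* **Planted signal.** A handful of designated genes (3 "large", 2
  "small") each receive one deterministic nonsynonymous SNP in every
  sample of the matching phenotype group. Random private events and the
  pool are masked out of these genes' CDS, so the planted signal is
  group-exclusive by construction and screen recovery has zero false
  negatives by design; false positives still arise from chance private
  mutations elsewhere, as they would in a real screen.
* **What is not modelled.** Read-level errors, caller artefacts,
  mosaicism/inheritance (each individual is an independent draw), and
  dose-response. Passing the recovery tests therefore shows the
  *analysis* is correct under its assumptions, not that any particular
  wet-lab protocol behaves this way.

All randomness derives from a single integer seed (sub-seeds are fixed
offsets), and identical seeds give byte-identical FASTA/GFF3/VCF
outputs and reports.

## Problem sizes and numerical choices

The test suite exercises most properties on a 120 kb, 24-gene cohort
and the end-to-end recovery checks on the default 1 Mb cohort; these
sizes give a few thousand calls — enough for the binomial 3-sigma bands
on the transition fraction and the delta-method band on the fold change
to be informative, while keeping a full run in tens of seconds. The
fold-change check uses a delta-method standard error of the ratio of
group mean rates; the spectrum check excludes the truth-known planted
sites (which are deterministic transitions) so the remaining tally is an
exact binomial. Hypergeometric tail probabilities are evaluated in log
space; p-values of empty overlaps are exactly 1; Ts/Tv with zero
transversions and percentages with zero denominators are reported as
`NA` markers rather than errors.

## Known limitations

* MNPs (equal-length multi-base substitutions) are rejected rather than
  decomposed; upstream callers in this setting emit SNPs and InDels.
* One transcript per gene is assumed in the simulator (the annotator
  itself handles overlapping transcripts).
* The published InDel tables contain internal inconsistencies (per-type
  sums exceeding the printed genome totals in some treated rows); only
  row totals are consumed.
* Enrichment treats terms independently; genes annotated to many terms
  inflate neither universe nor term counts beyond their set membership.
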