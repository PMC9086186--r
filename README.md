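# mutburden

Mutation-burden analysis for chemical-mutagenesis genome screens.

Screens that treat embryos with a mutagen such as EMS (ethyl
methanesulfonate) and then resequence treated and untreated individuals
need to answer: how many *extra* mutations did the treatment induce, of
what spectrum, and in which genes? Raw variant calls are dominated by
standing population variation, so the analysis hinges on removing
mutation *types* shared with an untreated control panel before any
counting. `mutburden` implements that workflow end to end for
per-sample VCFs against a reference FASTA and GFF3 gene models:

* **Five-field keying and shared-type removal** — each call is keyed by
  (CHROM, POS, REF, ALT, GENO); treated samples subtract the control
  panel's key union, controls are filtered leave-one-out. Variants are
  normalized (trimmed, InDels left-shifted through their repeat
  context) so keys are caller-comparable.
* **Annotation** — region labels (exonic / intronic / upstream /
  intergenic, precedence in that order) and codon-level effects for CDS
  SNPs (synonymous / nonsynonymous / stopgain / stoploss), plus a CDS
  flag for InDels.
* **Burden statistics** — per-sample clean-base mutation rates
  (`100 * count / clean_bases`), Ts/Tv, class percentages; group means
  with sample SD (n−1); the treated/control fold change; and
  normality- and variance-gated group tests (Shapiro-Wilk, Lilliefors,
  Levene, Student/Welch t, ANOVA + Tukey HSD).
* **Enrichment** — upper-tail hypergeometric over-representation of
  mutated-gene sets against generic term maps, BH-FDR within category.
* **Exclusive-gene screen** — a gene × sample matrix of
  amino-acid-changing SNP presence, and the genes hit only in a target
  phenotype group (e.g. only in the largest, or only in the smallest,
  animals).
* **Synthetic cohorts** — a truth-annotated generator (genome, gene
  models, shared polymorphism pool, per-sample VCFs under control/EMS
  spectra, planted phenotype-exclusive genes) so the whole pipeline is
  testable from a single seed.

The central quantity is the per-sample mutation rate
`r_i = 100 * n_i / B_i` (percent), with `n_i` the sample's
group-specific variant count and `B_i` its clean sequenced bases; group
summaries are `mean ± SD` over samples and the headline fold change is
`mean(r, treated) / mean(r, control)`.

## Worked example

The package ships the per-sample summary tables of a published EMS
screen of bay scallops (4 controls, 12 treated: 5 largest, 5 normal, 2
smallest) as plain TSVs, and recomputes every group statistic from
them:

```r
library(mutburden)
summarize_burden_tables()
#> <burden_summary> 16 samples (4 control, 12 treated)
#> Group means (sample SD, n-1):
#>   n_snp          control 134,841 +/- 10,116 (n=4) | treated 1,151,380 +/- 258,189 (n=12)
#>   n_indel        control 42,605 +/- 5,136 (n=4) | treated 229,256 +/- 51,715 (n=12)
#>   ts_tv          control 1.08 +/- 0.01 (n=4) | treated 1.12 +/- 0.00 (n=12)
#>   rate_snp       control 0.001153 +/- 0.000151 (n=4) | treated 0.011438 +/- 0.002221 (n=12)
#>   rate_indel     control 0.000365 +/- 0.000064 (n=4) | treated 0.002281 +/- 0.000473 (n=12)
#>   rate_total     control 0.001518 +/- 0.000192 (n=4) | treated 0.013720 +/- 0.002560 (n=12)
#>   pct_exonic     control 3.63 +/- 0.13 (n=4) | treated 3.47 +/- 0.12 (n=12)
#>   pct_syn        control 1.73 +/- 0.03 (n=4) | treated 1.93 +/- 0.06 (n=12)
#>   pct_nonsyn     control 1.83 +/- 0.10 (n=4) | treated 1.49 +/- 0.06 (n=12)
#>   pct_stop       control 0.048 +/- 0.006 (n=4) | treated 0.031 +/- 0.002 (n=12)
#>   pct_indel_cds  control 1.52 +/- 0.15 (n=4) | treated 0.81 +/- 0.16 (n=12)
#> Fold change (treated/control total rate): 9.035 (~9x)
#>   rate_total: welch_t p = 2.952e-09 *
#>   pct_exonic: student_t p = 0.03744 *
#>   pct_nonsyn: student_t p = 4.749e-07 *
#>   pct_syn: welch_t p = 2.287e-06 *
#>   ts_tv: student_t p = 7.895e-10 *
```

Reading: treated animals carry ~1.15 M group-specific SNPs against
~135 k in controls; the total mutation rate is 0.0137% of clean bases
vs 0.0015% — a 9-fold induction. The treated spectrum is shifted
*away* from consequential sites (lower exonic, nonsynonymous and
stop-changing percentages, higher synonymous), the signature of repair
and survivor selection.

The same machinery runs on files. A fully synthetic screen:

```r
sim <- simulate_cohort(cohort_config(seed = 1))   # 1 Mb, 4 + 12 samples
paths <- write_cohort(sim, "cohort_dir")
run <- run_pipeline(paths$vcfs, paths$fasta, paths$gff3, paths$cohort,
                    out_dir = "cohort_dir/out")
run$summary$fold_change      # ~7.4-8.1 across seeds (configured ratio 9.03)
run$exclusive$large          # contains all planted large-exclusive genes
```

A thin CLI wrapper with the same entry points lives at
`inst/cli/mutburden.R` (`simulate`, `run`, `from-tables`).

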