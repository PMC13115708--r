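---
title: "Cumulative gene-burden scoring of somatic SNVs: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative gene-burden scoring of somatic SNVs: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvburden)
```

## The model

`snvburden` scores protein-coding genes by the cumulative deleteriousness of
their somatic nonsynonymous SNVs in a paired tumor/normal patient cohort.
The score of gene $G$ with observed transcripts $t_1,\dots,t_{N_G}$ is

$$Q(G) = \frac{1}{N_G} \sum_{j=1}^{N_G} \frac{1}{\ln l(t_j)}
  \sum_{v \in t_j} \mathrm{Score}(v)\,\bigl[\mathrm{tumor}_v -
  \mathrm{normal}_v\bigr]$$

with $l(t_j)$ the transcript length in nucleotides, $\mathrm{Score}(v)$ a
normalized deleteriousness in $[0,1]$, and $\mathrm{tumor}_v$,
$\mathrm{normal}_v$ the numbers of *distinct patients* carrying $v$ in
tumor and normal samples. The three ingredients encode three assumptions:

* **Recurrence matters.** A variant seen in many tumors but few normals is
  weighted by its excess patient frequency. The difference may be negative
  for normal-enriched variants and is deliberately not floored: such
  variants are expected to be rare and weakly scored, so their influence is
  small, and keeping the signed value preserves the linear structure of the
  sum.
* **Length is a nuisance.** Longer transcripts accumulate more variants by
  chance alone; dividing by $\ln l(t_j)$ discounts this. The logarithmic
  penalty is the default because it discounts gently compared with
  $1/\sqrt{l}$ or $1/l$; both alternatives remain selectable via
  `length_penalty` in `score_genes()` for sensitivity analysis.
* **Isoforms are averaged, unweighted.** Every transcript of $G$ observed
  in the cohort annotation counts in $N_G$, including transcripts carrying
  no deleterious variant (they contribute 0). Expression-weighted averaging
  would be preferable when matched transcriptomics exist, but is out of
  scope here.

A gene is *pathogenic* — scored and ranked at all — iff it carries at least
one deleterious SNV under the scoring mode. Ranking is by descending score
with competition ranks (ties share the minimal rank of their block) and a
secondary alphabetical sort for deterministic output.

## Score normalization and integration

Each analyzer has its own scale, direction, and deleteriousness cutoff:

| analyzer  | range | deleterious | granularity    |
|-----------|-------|-------------|----------------|
| FATHMM-XF | 0–1   | $\ge$ 0.5   | per variant    |
| CADD      | 0–99  | $\ge$ 10    | per transcript |
| SIFT      | 0–1   | $\le$ 0.05  | per transcript |
| PolyPhen  | 0–1   | $\ge$ 0.447 | per transcript |

Scores are harmonized to higher-is-deleterious (SIFT is reflected,
$x \mapsto 1-x$) and min–max normalized with *cutoff anchoring*: the lower
anchor $x_{\min}$ is the harmonized cutoff, the upper anchor $x_{\max}$ the
harmonized range maximum, so the deleterious part of every scale maps onto
$[0,1]$ with the cutoff at exactly 0 and the extreme at exactly 1 (for
FATHMM-XF, $x_{\min} = 0.5$ and $x_{\max} = 1$).

**Clamping.** With the anchor at the cutoff, sub-cutoff (benign) scores
would normalize to negative values. We clamp to $[0,1]$, so benign scores
contribute exactly 0. This keeps the per-variant average in $[0,1]$ and
makes the integrative score consistent with averaging over analyzers that
disagree: a variant flagged by one analyzer but scored benign by another
gets the benign analyzer's 0 averaged in, rather than a negative penalty.
This is a genuine design choice — the alternative (letting negative values
enter the average) changes few rankings in practice but breaks the
$[0,1]$ interpretation.

In single-analyzer mode, a variant contributes iff *that* analyzer flags it
deleterious, using that analyzer's normalized score; variants the analyzer
did not score are skipped. In integrative mode (`iQ`), a variant
contributes iff *any* analyzer flags it, and its score is
$\mathrm{AveScore}(v)$: the arithmetic mean of **all available** normalized
scores, deleterious or not. Integration therefore helps twice: it averages
out individual analyzers' noise, and it rescues variants missing from any
single analyzer's output (missing scores are common in practice — roughly
5–10% per analyzer).

## Ranking evaluation: SAR

To judge a ranking, the standardized average rank of a $k$-gene list within
the $p$ ranked genes is

$$\mathrm{SAR} = \frac{\sum_{i=1}^{k} r_i}{k\,p} - \frac{1}{p},$$

with absent genes assigned rank $p+1$. This algebraic form is our adopted
reading of the statistic: it is the unique affine standardization of the
mean rank satisfying the three defining constraints — SAR lies in $[0,1]$,
equals 0 when every listed gene has rank 1, and equals 1 when every listed
gene is absent. The null distribution resamples `n_resamples` (default
1000) random size-$k$ sets without replacement from a user-supplied
background (all human protein-coding genes, in the intended application).

**z denominator.** The z-test uses the null *standard deviation*, not the
standard error of the null mean: the known gene list is a single draw from
the null, not an average of 1000 draws. The SE is reported alongside for
comparability with mean ± SE summaries, and the empirical tail proportion
of null draws at or below the observed SAR is reported as a
distribution-free check.

## Ingestion contract and edge cases

* CSQ field names are declared in the VCF metadata and mapped via
  `default_csq_map()` (VEP defaults), overridable per project since CSQ
  layouts drift between annotation sources.
* Transcript length is parsed from the denominator of `cDNA_position`
  ("`123/2034`"), the VEP field that actually carries a length; a bare
  numeric or a dedicated field can be configured instead. Lengths below 2
  are a hard error ($\ln$ undefined or zero).
* Tumor/normal columns are matched by name (`TUMOR`/`NORMAL`, the common
  somatic convention) with a positional fallback (second/first genotype
  column). A sample carries an SNV iff its genotype includes the alt
  allele; `./.` counts as not carrying.
* Multi-allelic records split into one SNV per alt allele, with CSQ entries
  matched by their `Allele` field. Indels and multi-base substitutions are
  skipped and counted.
* Within-patient duplicates (one SNV in several files of one patient) count
  once; distinct patients count separately. Chromosome names are normalized
  (`chr` prefix stripped) on both sides of every external join.
* SIFT/PolyPhen CSQ cells of the form `tolerated(0.32)` are parsed from the
  parenthesized numeric; bare numerics are accepted.

## The synthetic cohort generator

Real somatic VCF cohorts are controlled-access, so the package ships a
generator (`simulate_cohort()`) whose outputs exercise the exact input
contract: per-patient VCFs with CSQ annotation and paired genotype columns,
per-variant (CSV) and per-variant-per-transcript (TSV) external score
tables, known-gene and background lists, plus a ground-truth manifest.

What it emulates, and the defaults chosen as the study conditions:

* 50 patients, 300 protein-coding genes, 3 planted driver genes;
* ~95% tumor-only variants, 0.5% normal-only, the rest common — matching
  the composition observed in real paired-exome somatic calls;
* 7.5% missing scores per analyzer (the middle of the 5–10% range seen in
  practice);
* a latent deleteriousness per variant — Beta(8, 2) for driver variants,
  Beta(1.5, 6) for passengers — mapped linearly onto each analyzer's native
  scale and direction with Gaussian noise (SD 0.1 on the latent scale,
  truncated to range). Drivers also receive more variants (Poisson mean 12
  vs 1.5 per gene) carried by more patients (1 + Poisson(2.5) vs
  1 + Poisson(0.3));
* a fraction of synonymous (25%) and non-coding-gene variants to exercise
  the filters, and duplicate VCF files for two patients to exercise
  deduplication.

What it does **not** emulate: mutational signatures (substitution types are
uniform), linkage or clonal structure, demographic stratification,
indels/SVs, and realistic gene/transcript models. Passing tests on
synthetic cohorts therefore demonstrate correctness of the computation and
recoverability of planted signal under the stated noise model — not
calibration on real tumors.

## Test and verification strategy

Gene scores are verified against an independent brute-force triple loop
over (gene, transcript, variant) with the normalization written out by
hand, to within 1e-12, on random micro-cohorts of at most 5 genes and 20
variants. Normalization and classification are checked jointly on dense
raw-score grids for all four analyzers. End-to-end recovery uses the
default 50 × 300 cohort (drivers must occupy the top three ranks and their
SAR must fall below the 5th percentile of the 1000-draw null); the
integrative-vs-single-analyzer comparison runs 20 seeds of a 25-patient,
120-gene cohort, requiring the integrative SAR to match or beat the best
single analyzer in at least 60% of seeds. These problem sizes keep the full
suite comfortably fast while leaving the statistical checks well-powered.

## Known limitations

* $N_G$ counts transcripts observed in the cohort's annotation, not a full
  external transcript catalog; genes annotated against sparse transcript
  sets are penalized less than a catalog-based $N_G$ would imply.
* The score is unbounded above and scales with cohort size; scores are
  comparable within a cohort, not across cohorts.
* Equal analyzer weighting in $\mathrm{AveScore}$ is a choice, not an
  optimum; analyzers correlated with each other effectively vote twice.
* The SAR z-test assumes approximate normality of the null; for very small
  $k$ the null is discrete and skewed, which is why the empirical tail is
  reported alongside.
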