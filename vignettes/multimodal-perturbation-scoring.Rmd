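---
title: "Methods: tag processing and combination scoring for high-MOI perturbation CITE-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag processing and combination scoring for high-MOI perturbation CITE-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbtag)
```

This vignette documents the models, rules and numerical choices behind
`perturbtag`, in the order the pipeline applies them, and states what the
synthetic-data generator does and does not emulate.

## 1. UMI-level tag counting

Tag reads carry a cell barcode (CBC), a unique molecular identifier (UMI)
and a feature barcode identifying an antibody tag (ADT), hashtag (HTO) or
guide oligo (GDO). `count_tags()` groups reads by (CBC, UMI) and applies
three rules:

* **Barcode resolution.** Tag and cell barcodes match the reference exactly
  or by a *unique* correction at Hamming distance `max_hamming` (default 1);
  ambiguous corrections are treated as unmatched. This is the standard
  behaviour of tag counters in this field; we do not attempt
  quality-weighted or network-based correction.
* **Purity filtering.** A (CBC, UMI) pair is retained only when its
  most-supported feature holds *strictly more than* a fraction
  `purity_threshold` (default 0.75) of the pair's matched reads. UMIs
  claimed substantially by two features are PCR chimeras or barcode
  collisions and are discarded whole rather than assigned to the majority:
  with two plausible features, the molecule's identity is simply unknown.
  Any threshold above 0.5 guarantees at most one feature can win, so the
  rule is deterministic and single-parameter. The choice of 0.75 is a
  package default, configurable.
* **GDO read floor.** A retained UMI whose winning feature is a guide oligo
  additionally needs `gdo_min_reads_per_umi` total reads (default 5).
  Ambient guide molecules typically carry one or two reads; genuine
  integrations are sequenced deep. ADT and HTO UMIs have no floor — their
  quantitative use tolerates shallow UMIs, and a floor would bias
  low-expression antibodies.

UMI collapsing is exact-string within a CBC (no directional-network
deduplication); identical UMIs on different features are exactly the
conflicts the purity rule adjudicates. The counter reports a conservation
identity — retained + discarded + unmatched + off-whitelist groups equals
the number of distinct (CBC, UMI) pairs — which the test suite asserts, and
its output is checked bit-exactly against a literal brute-force counter on
randomized instances.

## 2. Per-cell QC

`apply_qc_filters()` removes droplets with (i) total GDO UMIs above the
95th percentile (linear-interpolation quantile, R type 7; strictly-above
removed) — high-MOI droplets rich in guide material are disproportionately
multiplets; (ii) fewer than 5000 cDNA UMIs; (iii) fewer than 200 detected
genes. The three filters are evaluated independently on the full input and
intersected, so the result is order-independent.

## 3. Hashtag classification

HTO counts are transformed per cell by the centered log-ratio
(`clr_normalize()`, natural log, pseudocount 1, centering across features),
the conventional transform for tag counts. The axis choice follows the
per-cell-across-features reading; the per-feature-across-cells alternative
can be obtained by transposing the input.

`classify_hashtags()` then thresholds each hashtag independently:
deterministic 1-D two-means on the CLR values (centers initialized at the
minimum and maximum, Lloyd iterations to a fixed point), positive strictly
above the midpoint of the final centers. A cell is a singlet iff exactly
one hashtag is positive. The procedure is seed-free and deterministic, and
satisfies the same negative/singlet/doublet contract as the quantile-sweep
demultiplexers it replaces; we chose it because its behaviour is fully
reproducible and unit-testable. Constant-valued hashtags yield no positive
calls and a warning.

Because each cell receives one hashtag, droplets containing two cells carry
two different hashtags with probability $1 - 1/n_\mathrm{HTO}$ and are
called doublets; same-hashtag doublets (a fifth of doublets at five
hashtags) are the method's intrinsic blind spot, exactly as in the real
assay.

## 4. Guide calling and combination labels

A gRNA is assigned to a cell iff it has at least `min_umis` (default 5)
GDO UMIs *and* at least `min_fraction` (default 0.20) of the cell's GDO
total. Both thresholds are read inclusively (at least). The fraction bound
caps calls at five guides per cell. Guide sets collapse to gene-level
labels: sorted distinct target genes joined with `+`; two guides for one
gene collapse to the single-gene label; non-targeting (NT) guides are
dropped from mixed sets (NT is biologically neutral, and cells with only NT
guides form the control group). Both collapses are configurable — the
handling of NT-plus-targeting cells is a package decision, not an inference
about how any particular study labelled them. Combinations with fewer than
`min_cells_per_combo` cells (default 10; mainly triplets and higher orders)
are discarded with a report.

## 5. Normalization and the combined protein score

ADT counts are normalized to relative counts (`rc_normalize()`): count over
the cell's ADT total, times a common scale factor (default 1). With a
two-antibody panel this makes CD86 and PD-L1 values complementary fractions,
invariant to per-cell depth.

`compute_hto_max()` groups hashtag singlets by their called hashtag and
divides each cell's dominant-hashtag count by the group mean (median
optional). Grouping is what gives the normalization content: dividing
within a hashtag group cancels that antibody's staining efficiency while
preserving cell-to-cell variation in the epitope (MHC-I/CD45). A per-cell
normalization would make the grouping a no-op. The group mean of the
resulting values is 1 by construction.

The combined score is $S = \mathrm{RC}(\mathrm{CD86}) +
\mathrm{HTOmax} - \mathrm{RC}(\mathrm{PDL1})$, computed per cell from the
modality-appropriate normalizations (HTO-Max is the HTO-derived per-cell
scalar entering the sum; a raw-CLR alternative can be substituted by the
caller). `summarize_and_rank()` takes per-label medians and subtracts the
NT median, so NT sits at exactly 0 and the ranking reads as differences
around the control; subtraction (not division) matches a score that is
already on a normalized, approximately additive scale. Ties break by cell
count, then label, making the ranking deterministic.

## 6. Expression analyses

* `normalize_expression()`: $\ln(1 + 10^4\,c_{gj}/C_j)$ per cell.
* `rank_signature_score()`: UCell-style — per-cell ranks by decreasing
  count (average ties), ranks beyond `r_max = 1500` squashed to
  `r_max + 1`, Mann-Whitney $U$ of the signature ranks rescaled to
  $1 - U/(n\,r_\mathrm{max}) \in [0, 1]$. The 1500 ceiling and average-rank
  ties follow the algorithm's published defaults. Rank-based scoring is
  invariant to monotone per-cell transforms, so raw and log-normalized
  counts give identical scores.
* `assign_cell_state()`: arg-max of competing signature scores; exact ties
  are left unassigned rather than broken arbitrarily. State marker lists
  are user inputs; the synthetic generator plants its own.
* `wilcoxon_de()`: per-gene two-sided rank-sum test via `stats::wilcox.test`
  (exact below 50 per group without ties, otherwise normal approximation
  with tie and continuity corrections; all-tied genes get $p = 1$), BH
  adjustment across genes. The reported fold change is
  $\ln((\bar x_A + 1)/(\bar x_B + 1))$ on depth-normalized, unlogged group
  means — natural log, the scale on which small reported LFCs of rank-sum
  analyses are conventionally read; a log2 variant is a trivial rescale.
* `fold_change_matrix()`: per-label mean depth-normalized expression with
  pseudocount 1 in numerator and denominator, against the NT reference;
  bounded and symmetric for absent genes. Restricting the gene list to the
  targeted genes gives the cross-regulation view.
* `select_de_genes()`: `padj < 0.1`, `baseMean > 5`, and
  $|\log_2 FC| > 5/\sqrt{\mathrm{baseMean}} + 0.3$ — a noise-adaptive
  threshold that demands larger fold changes of weakly expressed genes.
  The package consumes DE tables (e.g. DESeq2 exports); it does not fit the
  models.
* `cluster_zscore_kmeans()`: rows standardized (constant rows to zero),
  `stats::kmeans` with 25 restarts under a caller-fixed seed; determinism
  is documented because k-means otherwise is not.

## 7. Screen statistics

Guide enrichment between sorted bins uses counts-per-million per bin
(median-ratio optional) and $\log_2$ with pseudocount 1 after scaling.
Gene ranking standardizes guide LFCs against the non-targeting
distribution and combines per-gene z-scores by Stouffer's rule
($\sum z_i/\sqrt{m}$) — the conventional choice when a z-score ranking is
specified without its combination formula; it is exact under the null and
rewards consistent guides. The overlap test is the exact hypergeometric
upper tail via `phyper` (log-space, stable at genome scale); the default
universe of 19,674 genes is the gene count of the genome-wide library
design behind the regulator lists and is configurable. Contingency
analyses report *adjusted* standardized residuals,
$(O - E)/\sqrt{E(1 - r_i/N)(1 - c_j/N)}$, matching the `stdres` convention
of R's `chisq.test` (asserted against it in the tests).

## 8. The synthetic-data generator

`simulate_dataset()` emulates the study design end to end: $n$ cells
(default 4000) each receive $K \sim$ zero-truncated Poisson($\lambda = 1.6$)
integrations — zero-truncated because antibiotic selection removes
uninfected cells; a plain-Poisson flag exists — drawn uniformly with
replacement from a pool of 32 targeting guides over 11 genes plus 4
non-targeting guides; one of 5 hashtags; and one of three expression
states. A `doublet_rate` (default 0.05) fraction of droplets holds two
cells. All counts are negative binomial (shared size 10; tag counts in
droplet data are overdispersed, and a single moderate dispersion keeps the
generator honest without per-feature tuning), with means:

| quantity | default | meaning |
|---|---|---|
| `gdo_mu` | 40 | GDO UMIs per integration copy |
| `gdo_ambient_mu` | 0.05 | ambient UMIs per guide per cell |
| `hto_mu_pos` / `hto_mu_bg` | 200 / 10 | own vs background hashtag |
| `hto_efficiency` | 1, 1.4, 0.8, 1.2, 0.9 | per-antibody staining factors |
| `adt_baseline` | 150 / 150 | CD86 / PD-L1 baseline |

Perturbation effects are per-gene $\Delta\log_2$ triples on (CD86, PD-L1,
MHC-I), composing additively in log2 space across a cell's perturbed genes,
plus optional pairwise interaction terms — the default plants its strongest
synergy on Cebpb+Med12 (+0.5, −0.5, +0.3 beyond the additive sum), so
recovery tests have a known rank-1 target with single-gene effect sizes
below one log2 unit, the scale of realistic surface-marker shifts.
Expression uses a ~500-gene panel with log-normal baselines, state programs
(25 genes, +2 log2), per-knockout transcript programs (each knockout
silences its own transcript; Cebpb additionally shifts Cd86, Marco, Mrc1),
and per-cell log-normal depth factors. `simulate_tag_reads()` expands
matrices into (CBC, UMI, tag, reads) records with per-modality reads-per-UMI
distributions and a configurable chimera rate for exercising the purity
filter.

**What the generator does not emulate:** transcriptome-wide expression
structure, ambient mRNA, variable guide efficiency or escape, integration-
site effects, cell-cycle structure, and batch effects. Recovery results on
synthetic data therefore demonstrate the pipeline's correctness under its
own model assumptions — clean separations, honest noise — not performance
on any real dataset.

## 9. Problem sizes and determinism

The test suite and acceptance script run the default 4000-cell design for
recovery checks, 10,000 cells for the zero-truncated Poisson law, 20 seeds
of the full chain for ranking stability, and 100 randomized read instances
(up to $10^4$ read groups) for counting-oracle equivalence; these sizes give
Monte-Carlo standard errors comfortably inside the asserted bounds while
keeping a full run in the order of a minute. Every stochastic component
draws from a caller-supplied seed; the pipeline report excludes timestamps
so that identical configs reproduce identical bytes.

## 10. Known limitations

* The purity rule discards conflicted UMIs rather than modelling chimera
  formation; at extreme chimera rates this deflates counts uniformly.
* Two-means hashtag thresholding assumes a bimodal CLR distribution per
  hashtag; heavily skewed designs (one dominant sample) may need explicit
  thresholds.
* Same-hashtag droplet doublets are undetectable by construction; with
  five hashtags, a fifth of doublets survive to guide calling and appear
  as spurious combinations — the combination-size floor absorbs most.
* Guide calling is threshold-based, not model-based; cells with four or
  more integrations lose guides to the 20% fraction bound by arithmetic
  necessity, which is also why higher-order combinations are discarded
  downstream.
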