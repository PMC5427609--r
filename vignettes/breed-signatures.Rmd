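---
title: "Discovering breed-specific genetic signatures with breedsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering breed-specific genetic signatures with breedsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedsig)
```

## The problem

Indigenous livestock breeds that have adapted to distinct environments —
the classic example being trypanotolerant West African taurine cattle
compared with trypanosusceptible zebu breeds — carry genomic regions where
one breed is near-fixed for haplotypes that are rare elsewhere.  `breedsig`
implements a combined information-theoretic and population-genetic workflow
for finding such regions in phased multi-breed genotype panels:

1. **Discriminative SNP selection by mutual information.**  Binary
   major/minor allele codes are treated as random variables and scored
   against the breed label.
2. **Gene ranking by weighted mutual information (wMI).**
3. **Cross-population selection scans** (XP-EHH, and a simplified
   XP-CLR-style differentiation scan) with windowed empirical p-values.
4. **Contingency-table statistics**: per-chromosome enrichment of selected
   SNPs, and case-control genotype tests under dominant / recessive /
   codominant codings.
5. **Gene correlation networks** built from genotype zygosity profiles,
   with hub-gene ranking.

Because real resequencing panels are far beyond desk scale, the package
ships a seeded simulator that plants known signatures into a drifted
multi-breed panel; every claim the test suite makes is checked against
that planted truth or against an independent oracle.

## Data representation

All analyses run on two encodings derived from phased biallelic VCF input:

* **Binary haplotype codes.**  Per site, the most frequent allele across
  *all* haplotypes of *all* samples is recoded to 0 ("conserved") and the
  other allele to 1 ("mutated").  An exact 50/50 tie keeps the REF allele
  as major, so the encoding never depends on sample order.  Monomorphic
  sites become all-0 and stay in the matrix; downstream estimators treat
  them as zero-information columns rather than dropping them.
* **Ternary genotype codes.**  Per sample, the sum of its two binary
  allele codes: 0 = major homozygote, 1 = heterozygote, 2 = alternative
  homozygote.

Multi-allelic records are dropped at ingest (the binary encoding is
defined for a major/minor pair), and missing genotypes are rejected by
default — the intended input is an imputed, phased panel.  An opt-in
modal-genotype imputation exists for convenience and is logged when used.
Internally all coordinates are 0-based half-open; the 1-based convention
of VCF and GFF3 is converted at the boundary.

## Mutual information machinery

All information measures are plug-in estimates in **nats** (natural log).
The choice of base matters: for a panel of 10 target and 9 contrast
samples, a marker that perfectly separates the breeds attains
`H(C) = -(10/19) log(10/19) - (9/19) log(9/19) = 0.6918` nats, the
theoretical ceiling for any marker on such a panel.  MI is computed in the
joint-sum form and verified in tests against the entropy-difference form
`H(SNP) - H(SNP|C)` to 1e-12.

Haplotype-level MI treats each haplotype as one observation carrying its
sample's breed label (2N observations per site); a genotype-level variant
over ternary codes is available via `site_mi(level = "genotype")`.

Two-locus effects are captured by the MIE `I(C; SNP1, SNP2)`, the MI
between the class and the joint symbol of two loci; the chain-rule
identity `I(C; S1, S2) = I(C; S1 | S2) + I(C; S2)` is enforced to 1e-12 in
tests.  Pair selection (`select_discriminative_pairs()`) scores every
*consecutive same-chromosome* site pair — the natural reading of
"adjacent-locus haplotypes", and linear rather than quadratic in the
number of sites — and keeps pairs with `MIE > theta` whose
label-permutation p-value clears the configured cutoff.  The pipeline
default is `theta = 0.5 * H(C)`: halfway between the null (MIE near 0)
and the perfect-separator ceiling, so a selected pair carries at least
half the attainable discriminative information.

Significance is assessed by **label permutation** with the add-one
convention `p = (1 + #{permuted >= observed}) / (n_perm + 1)`.  Labels are
permuted at the *sample* level so the two haplotypes of a sample always
travel together.  With the pipeline default of 1,999 permutations the
smallest attainable p-value is 5e-4, which is what makes the conventional
`p < 1e-3` gene-selection cutoff reachable.

## Gene scores

Per-site MI values are aggregated per gene (mean, max, sum, SNP count) via
the SNP-to-gene map (a site may belong to several overlapping genes).  The
wMI score interpolates discriminative information and gene variability:

wMI_i = alpha * mean-MI(g_i) + (1 - alpha) * |g_i| / max_g |g|

with `alpha = 0.5` by default.  The formula is a convex interpolation; at
`alpha = 1` it reduces to the gene's mean MI, at `alpha = 0` to its
normalised SNP count.  Gene-level significance permutes labels and
recomputes the full per-site MI vector each round (vectorised as a single
cross-product per permutation batch, which is what keeps 1,999
permutations over 20,000 sites in the tens of seconds).  Zero-SNP genes
get `p = 1` by convention.

Breed-pair analyses are compared per gene by MI ratios (with an `epsilon
= 1e-6` pseudocount against zero-MI genes) and distributionally by KL
divergence over histograms with shared edges spanning the pooled range
(50 bins by default; both directions are reported because KL is not
symmetric).  The per-gene ratio — rather than a ratio of binned densities
— is the implemented interpretation.

## Selection scans

**EHH / iHH.**  From a core site, haplotypes are progressively partitioned
by their alleles at successive flanking sites;
`EHH(d) = sum_h C(n_h, 2) / C(n, 2)` over the resulting groups.  The walk
stops at the first site whose EHH drops below the truncation level
(0.05, the convention of existing EHH software), and that below-threshold
point is excluded from the trapezoidal integral, so a curve that collapses
immediately integrates to zero.  iHH integrates against *physical*
distance: the simulator has no recombination map, so bp substitutes for
genetic distance (a map can be supplied to real-data analyses by
preprocessing positions).  The genome scan runs in compiled code; the
plain-R `ehh()` + `ihh()` path is retained and the two are required to
agree to 1e-9 in the tests.

**XP-EHH.**  Per site, `raw = ln(iHH_A / iHH_B)` (positive = selection in
population A), normalised to genome-wide mean 0 / sd 1.  Sites where
either population's iHH is 0 are skipped and counted.  The genome is tiled
into non-overlapping 50-kb windows; the window statistic is the maximum
normalised score of its SNPs (a flag switches to raw scores).  Windows are
binned by SNP count in increments of 500 and the empirical p-value of a
window is the fraction of same-bin windows with a *strictly* greater
statistic; windows with positive statistic and empirical p below 0.01 are
selected.

**XP-CLR-style scan.**  A deliberately simplified composite-likelihood
scan for excess multi-locus allele-frequency differentiation, keeping the
published program's operational rules — 50-kb windows, at most 600 SNPs
per window (most-differentiated first, a deterministic rule the original
leaves unstated), zero weight for any SNP whose genotype correlation with
an already-kept SNP exceeds 0.95, top 1% of windows flagged — around a
one-parameter drift model: under neutrality population A's frequency
varies around B's with variance `omega * p(1-p)` (omega estimated
genome-wide), under differentiation that variance is inflated by a factor
maximised over a grid.  It is *not* the full sweep-trajectory likelihood
of the original program; an external score file can be dropped in via
`read_score_file()` + `window_scores()` instead.

Candidate genes are assigned to selected windows when their interval
intersects the window extended by 25 kb on each side (partial overlap
counts), and candidate lists from different measures are combined by plain
set intersection.

## Association statistics

Per-chromosome enrichment of a selected SNP set uses a two-sided Fisher
exact test on (on-chromosome vs off) x (selected vs not), Bonferroni
corrected, alongside the negative-log10 selected/total ratio.  Case-control
genotype tests collapse ternary codes under the dominant ({1,2} vs {0}) or
recessive ({2} vs {0,1}) model into 2x2 Fisher tests, or apply the
Cochran-Armitage trend test with scores (0, 1, 2) and no continuity
correction for the codominant model; monomorphic sites report `p = 1` and
are flagged.  All three models are always reported.  Bonferroni is the
only multiplicity correction offered, matching the workflow this package
reimplements.

## Zygosity networks

For each selected gene and sample, the *gene variation* is the mean of the
sample's ternary codes over the gene's SNPs — near 0 when the sample is
reference-like across the gene, near 1 when predominantly heterozygous,
near 2 when alternative-homozygous.  Pearson correlations between gene
profiles (computed jointly over both breeds' samples) define a network in
which genes are connected iff `r` is *strictly* above the positive cut or
below the negative cut — strict, because the thresholds are published as
"larger than / smaller than".  Zero-variance profiles are excluded with a
message rather than assigned `r = 0` (the coefficient is undefined for
them).  `network_presets` ships the five published threshold pairs; the
lenient (0.45, -0.25) pair belongs to networks of a few dozen genes, while
networks of a hundred-plus genes use (0.9, -0.4) or stricter — at lenient
cuts a dense network accumulates so many moderate chance correlations
that hub ranking degenerates, which is why the pipeline default is the
strict preset (its selected gene lists are large).  Hubs
are ranked by degree with positive- and negative-edge degrees reported
separately; a top *negative*-edge hub is a gene whose zygosity runs
opposite to most of the network.

## The simulator and what it does (not) emulate

`simulate_panel()` draws ancestral ALT frequencies from Beta(1, 1)
(uniform — the common convention in Balding-Nichols association
simulations), clamps them into [0.01, 0.99], and gives each breed
Balding-Nichols frequencies `Beta(p(1-F)/F, (1-p)(1-F)/F)` with
`F = 0.1`, a typical between-breed FST for cattle.  Haplotype alleles are
independent Bernoulli draws per site.  The standard study conditions are
two breeds of 10 and 9 diploid samples, 20,000 SNPs on one 10-Mb
chromosome and 200 genes of 20 kb tiling it.

Planted features define the recoverable truth:

* **Signature genes** (10 by default): breed 1 is set homozygous for the
  minor allele at every gene SNP.  Ancestral frequencies inside planted
  genes are drawn from Beta(1, 19) (mean 0.05): a breed-specific signature
  is near-fixation for haplotypes *rare* in the other breeds — planting at
  a site whose alternative allele is already common in the contrast breed
  would not be a signature at all.
* **One heterozygous gene**: every breed-1 sample is made heterozygous at
  every gene SNP while the contrast breed is set major-homozygous, so its
  zygosity profile anti-correlates with the signature genes and it should
  surface as the top negative-edge hub.
* **One sweep** (breed 1, carrier fraction 0.9, 500-kb footprint): each
  carrier haplotype copies one core haplotype *exactly* over a contiguous
  extent whose endpoints are uniform within the footprint half on each
  side.  Marginal per-site copy fidelity therefore decays linearly from 1
  at the core to the drifted background at the edges, while pairs of
  carriers stay identical over long ranges — the recombination-erosion
  shape of a hard sweep.  (An earlier per-site-independent decay model was
  rejected: it erodes haplotype identity within a few kb of the core and
  produces no long-range homozygosity to detect.)  The 500-kb footprint
  matches the scale of strong recent sweeps reported in livestock.

What the simulator does **not** emulate: background linkage
disequilibrium (sites are independent outside sweep footprints),
recombination-rate variation, mutation-rate heterogeneity, genotyping
error and missingness, and multi-chromosome structure.  Passing tests
therefore demonstrate that the estimators recover planted structure under
drift and sampling noise — not that the pipeline's power or false-positive
behaviour transfers quantitatively to real resequencing data, where
background LD in particular will raise the EHH noise floor.

## Null calibration: what counts as a false positive

Under Balding-Nichols drift at FST 0.1 the two breeds differ genuinely at
*every* site, and a label-permutation test correctly flags nearly every
gene — that is detection, not error.  The false-positive control therefore
uses exchangeable labels: one drifted population of 19 samples split
arbitrarily 10-vs-9, so the group label carries no information by
construction.  Under that null the wMI selections at `p < 1e-3` cover well
under 1% of genes and the codominant trend test's type-I error sits at the
nominal 5% (both checked over five seeds in the test suite, with
monomorphic sites excluded from the type-I denominator since their p is 1
by convention).

## Numerical and design choices

* Natural-log MI everywhere; negative floating-point MI clamped at 0
  (guard tolerance 1e-9).
* Major-allele ties resolved toward REF; deterministic under any sample
  order.
* Permutation p-values use the add-one convention and a seeded, private
  RNG stream (`with_seed`) that never disturbs the caller's RNG state.
  Permutation draws that exactly reproduce the observed labeling are
  redrawn: the observed labeling is already counted once by the add-one
  term, and with 19 samples a 10-vs-9 split recurs by chance about once
  per 92,000 draws — rare per test, but because all genes share the same
  permutation stream a single recurrence would censor every gene's
  p-value at once.
* KL smoothing epsilon 1e-12, applied to both histograms before
  renormalisation.
* EHH truncation 0.05; per-site skip (with a count) when iHH is 0.
* XP-CLR drift grid c(2.5, 5, 10, 25, 50, 100) versus the neutral factor
  1; contrast-population frequencies shrunk by (x + 0.5)/(n + 1) away from
  0/1 before entering the likelihood.
* Window empirical p uses strict ">" ties, so fully tied bins give p = 0
  for every window.
* The breed-pair focus is target-vs-one-contrast; `combine_contrasts()`
  provides the multi-contrast variants (mean of per-site MI, or
  intersection of per-pair SNP selections) since either reading of
  "averaging across contrasts" is defensible and neither is asserted.
* Problem sizes in the tests and the acceptance script follow the
  standard study conditions above; the heavier permutation counts (999 or
  1,999) are used exactly where the p-value cutoff demands that
  resolution.

## Known limitations

* XP-CLR here is a differentiation scan, not the original sweep-trajectory
  likelihood; its absolute statistic values are not comparable to the
  published program's (use the external-score reader for that).
* Physical distance stands in for genetic distance in iHH integration.
* The permutation null for wMI conditions on the observed genotype matrix;
  with very few samples the discreteness of the permutation distribution
  limits attainable p-values (the reason the default permutation counts
  are 999/1,999).
* Haplotype-level estimators require phased input; unphased ingestion is
  possible but restricts the workflow to genotype-level statistics.
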