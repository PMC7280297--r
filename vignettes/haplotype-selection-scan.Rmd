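---
title: "From mixed-model GWAS to haplotype-based selection signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From mixed-model GWAS to haplotype-based selection signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapsweep)
options(hapsweep.verbose = FALSE)
```

## The question the pipeline answers

A quantitative trait measured across a panel of inbred accessions — pollen
grains per flower is the motivating example — can be mapped by genome-wide
association. A separate question is whether the loci that come out of that
scan have been targets of recent natural selection. An incomplete
("partial") sweep, in which selection has pushed an allele to intermediate
frequency, leaves a characteristic footprint: the selected allele sits on an
unusually long shared haplotype, because recombination has not yet had time
to break up the background on which it rose. `hapsweep` implements the whole
chain that connects these two analyses:

1. flower-level phenotype records are filtered, batch-harmonized and reduced
   to one value per accession;
2. a mixed-model association scan with a genome-wide kinship random effect
   maps the trait while controlling population structure;
3. an iHS selection scan finds SNPs where one allele carries an unusually
   long haplotype;
4. a circular-shift permutation test asks whether the GWAS peaks fall in the
   extreme tails of the iHS landscape more often than chance placement would
   allow.

Everything runs on a synthetic study generated by the package itself, so
each stage is testable end to end without any external data.

## Haplotype statistics

**EHH.** For a core SNP and one of its alleles, the extended haplotype
homozygosity at position $x$ is the probability that two randomly drawn
carriers of that allele are identical over the whole interval from the core
to $x$:

$$\mathrm{EHH}(x) = \sum_h \binom{n_h}{2} \Big/ \binom{n_a}{2},$$

where the $n_h$ are the sizes of the groups of carriers with identical
haplotypes over the interval and $n_a$ is the carrier count. EHH is 1 at the
core and non-increasing outward. `compute_ehh()` walks outward SNP by SNP,
refining the partition of carriers; the walk stops once EHH drops below a
cutoff (default 0.05, the conventional choice for this statistic family —
below it the integrand contributes little and estimates get noisy), keeping
the first sub-cutoff point.

**iHH and iHS.** `integrate_ihh()` integrates the EHH decay curve over
physical distance (trapezoid rule, exact on the piecewise-linear profile;
distances in bp because no genetic map is assumed). The raw score is

$$\mathrm{uniHS} = \ln(\mathrm{iHH}_A / \mathrm{iHH}_D),$$

strongly negative when the derived allele rides the long haplotype. Because
haplotype length depends mechanically on allele frequency, raw scores are
standardized to mean 0 and SD 1 within derived-allele-frequency bins (width
0.025). The population SD (denominator $n$) is used so the per-bin
unit-variance property is exact rather than asymptotic. Bins with fewer than
two scores cannot be standardized and are flagged invalid, as are SNPs whose
EHH walk hits a chromosome border before decaying (the default
border-truncation policy discards them; `truncation = "integrate"` keeps
the integral up to the border instead). SNPs with derived frequency outside
[0.05, 0.95] are not scored — iHH ratios at rare alleles are unstable.
A genome scan (`ihs_scan()`) runs the same walk in compiled code; the R
walker is retained and the two are cross-checked against each other (and
against an exhaustive pairwise-identity oracle) in the test suite.

One floating-point detail: bin indices are `floor(p / w + 1e-9)`, because
frequencies such as 0.3 divided by a bin width of 0.025 land representably
*below* the intended integer and would otherwise be mis-binned.

## The mixed model

The association scan follows the EMMA/EMMAX recipe. The null model is
$y = X\beta + u + e$ with $u \sim N(0, \sigma_g^2 K)$ and
$e \sim N(0, \sigma_e^2 I)$, where $K$ is identity-by-state kinship over the
haplotype panel ($K_{ij}$ = fraction of SNPs with the same allele; a sum of
two Gram matrices, hence positive semi-definite, with unit diagonal on
complete data; a centered-genotype kinship is available via
`compute_kinship(method = "centered")`). The restricted likelihood is
profiled in $\delta = \sigma_e^2/\sigma_g^2$ using the spectrum of the
projected kinship, maximized on a 100-point grid over
$\log\delta \in [-10, 10]$ followed by local refinement to tolerance
$10^{-6}$ — the grid-plus-refine strategy is robust to the multimodal
surfaces that derivative methods can mishandle, and boundary optima at the
grid edges are kept when the interior refinement cannot beat them.

Per-SNP tests reuse the null variance components (the EMMAX approximation,
which keeps the scan linear in the number of SNPs; an exact per-SNP refit
would change P values negligibly at these sample sizes): phenotype and
design are rotated by the eigenvectors of $K$, weighted by
$(\lambda_i + \delta)^{-1/2}$, and the SNP coefficient is tested two-sided
against a $t$ distribution with $n - q$ degrees of freedom — $t$ rather than
normal so small panels are exact. SNPs below the minor-allele-frequency
threshold (default 0.15 for the scan itself) are excluded;
monomorphic SNPs are skipped and logged. With $K = I$ the whole machinery
collapses to ordinary least squares, which the tests assert to $10^{-6}$.

Scan calibration is summarized by the genomic inflation factor
$\lambda_{GC}$ (median 1-df $\chi^2$ quantile of the P values over 0.4549)
and a Q–Q plot (`qq_and_lambda()`, `plot_qq()`).

## Windows, empirical P values and the permutation test

The genome is tiled into fixed 10-kb windows (linkage disequilibrium decays
within roughly that distance in selfing panels, which is also what makes a
window-level statistic meaningful). Each window's statistic is the maximum
|iHS| over its valid SNPs — absolute value, because extremeness in either
direction flags one allele on a long haplotype; signed one-tail variants are
available (`window_max_stat(signed =)`) since the choice is a genuine
convention. Windows are ranked into empirical P values (rank / N, most
extreme first, mean rank on ties); windows with no valid SNP stay undefined
and never enter the denominators.

A window is a *GWAS peak* if it contains at least one SNP with association
$P < 10^{-4}$ and MAF $> 0.1$ (both strict). For a tail threshold $t$ the
observed statistic is the number of peak windows with empirical
$P \le t$; its expectation under uniform placement is $t$ times the number
of peak windows with a defined statistic, and their ratio is the fold
enrichment.

Significance comes from a circular-shift permutation: all peak windows are
shifted together by a uniform offset modulo the genome-wide concatenated
window sequence, preserving the multiset of pairwise gaps — and therefore
the spatial clustering of peaks, which is exactly what an SNP-level
resampling null would destroy. The default is a single genome-wide shift
(the strictest reading of preserving relative positions; per-chromosome
shifts would be a straightforward config extension but are not the
default). A zero shift is permitted in the draw (probability $1/W$; a flag
excludes it). The reported P value uses the add-one convention
$(1 + \#\{\text{permuted} \ge \text{observed}\})/(1 + B)$, so it is never
zero and is conservative under ties. With $B = 1000$ the granularity
matches the scale of P values this kind of analysis reports (0.001–0.05).

A per-SNP variant of the same chain (`snp_enrichment()`) skips windows
entirely: empirical P values over SNP-level |iHS|, peak SNPs from the same
thresholds, shifts over the SNP sequence.

`phenotype_panel_comparison()` ranks a focal phenotype's fold enrichment,
per tail, against a set of comparison phenotypes analyzed on the same
window grid (rank by fold, descending, minimum on ties — fold is what the
multi-phenotype comparison plot shows; the permutation P accompanies each
row).

## The synthetic study

The generator exists so that every stage above has a ground truth.

**Panel.** A founder-mosaic (Li–Stephens-like) copying process: $F$ founder
haplotypes with iid Bernoulli(0.5) alleles; each accession copies a founder,
switching to a uniformly chosen founder between adjacent SNPs with
probability $1 - e^{-\rho \cdot \mathrm{gap}}$, then each allele flips with
the mutation probability $\mu$. This produces tunable LD and realistic
relatedness structure without simulating a demographic history, which none
of the downstream statistics require. Ancestral/derived labels are known by
construction, standing in for outgroup-based polarization of real data.

**Sweep.** A partial sweep is injected by copying a donor haplotype into a
random fraction $f$ of accessions over an interval around a core SNP, with
flank lengths drawn per carrier from an exponential with mean
$\lambda_e$ — one interpretable parameter controlling how far recombination
has eroded the swept segment. The core allele is set to 1 in carriers and 0
elsewhere, so its derived frequency is exactly $f$ after rounding.

**Phenotype.** On the log scale, accession value
$z_i = \beta x_i + u_i + e_i$ with $u \sim N(0, \sigma_g^2 K)$ computed from
the panel's own kinship and $\sigma_g^2 = \sigma_e^2\, h^2/(1 - h^2)$, so
$h^2$ is the polygenic fraction of the accession-level variance
($h^2 > 0$ therefore requires $\sigma_e > 0$). Flower-level counts are
normal around $e^{z_i + \mathrm{baseline}}$ with a constant coefficient of
variation, clipped at zero; plants are split evenly into two batches and
batch 2 receives an affine artifact $x \mapsto a x + b$. The log-scale
construction makes the pipeline's log transform the natural inverse, and
the affine artifact is exactly what median/SD harmonization removes.

**Default study conditions** (all exposed in `sim_config()`, none
hard-coded): 200 accessions, 5 Mb chromosome, 5000 SNPs (about one per kb),
12 founders, switch rate $5\times10^{-5}$/bp (LD decays within ~10 kb),
mutation rate $10^{-3}$; sweep at mid-chromosome with $f = 0.3$ and
$\lambda_e = 20$ kb; $\beta = -0.4243$ (one accession-level phenotypic SD
at the default $h^2 = 0.5$, $\sigma_e = 0.3$, i.e. carriers of the swept
haplotype produce fewer grains), baseline $\log 4000$, four plants per
accession, three flowers per plant, flower CV 0.2, batch shift 200 and
scale 1.2. Test code uses smaller panels where a property does not need the
full geometry.

What the generator does *not* emulate: coalescent genealogies, recombination
hotspots, genotyping or imputation error, multi-allelic sites, and selfing
dynamics. Passing tests therefore demonstrate correctness of the statistics
and the internal consistency of the chain on LD structures of this general
kind — not robustness to every feature of real resequencing panels.

## Phenotype preparation conventions

The order is fixed: low-count filtering first (counts below 10 reflect
unopened anthers, and leaving them in would distort the batch statistics),
then batch harmonization, then the per-accession median and natural log.
Harmonization maps each batch onto the pooled median and the pooled
*within-batch* SD (the usual pooled variance estimator); with that target
the transform is exactly idempotent, which the concatenated-data SD would
not be. The natural log is a convention — the base shifts and scales the
phenotype without affecting rank-based or linear inference — and the median
(standard midpoint for even counts) matches how a per-accession
representative value resists outlier flowers.

## Degenerate inputs and numerical edges

* Panels must be complete: heterozygous or missing calls invalidate a site
  at read time (imputation is out of scope by design).
* SNPs whose ancestral state is unknown are dropped before scoring by
  default (`unknown_policy = "keep_ref"` retains them, flagged), since a
  mis-polarized SNP silently flips the sign of its iHS.
* A constant phenotype, a batch with zero SD, an EHH core with fewer than
  two carriers, and an enrichment run with no peak windows all raise
  immediate errors rather than propagating NaNs.
* All generators and the permutation test are bit-reproducible given a
  seed; doubling the permutation count moves P values by less than
  $2/B$ on fixed data.

## Known limitations

* With a single injected sweep, the association scan typically yields only
  one or two peak windows. The window-level permutation P value of a single
  peak window is bounded below by roughly the tail fraction itself, so at
  the 5% tail a lone peak can never be called significant, however extreme
  its iHS — the test's granularity comes from having many peak windows, as
  a real multi-locus architecture provides. The per-SNP variant and the
  frequency-matched outlier rank of the core SNP are the sharper readouts
  in the single-locus regime.
* The add-one permutation convention is conservative when the overlap
  distribution is very discrete (few peaks, coarse tails).
* IBS kinship on haplotypes has a high off-diagonal baseline in mosaic
  panels; variance-component estimates are well calibrated against the same
  kinship, but pseudo-heritability is not comparable across kinship
  definitions.
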