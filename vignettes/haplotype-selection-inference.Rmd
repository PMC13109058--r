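---
title: "Haplotype-based selection inference with haplosel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based selection inference with haplosel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplosel)
```

## The problem

Small, genetically isolated populations — the motivating case is a phased
whole-genome panel of 22 diploid individuals from an Oceanic island
population — carry detectable footprints of recent natural selection in
their haplotype structure. `haplosel` implements the full inferential chain
from such a panel to selection conclusions:

1. **Single-locus scans.** Extended haplotype homozygosity (EHH) and the
   integrated haplotype score (iHS) flag alleles that rose in frequency too
   fast for recombination to shorten their haplotypes.
2. **Polygenic adaptation.** The trait-integrated haplotype score (tiHS)
   aggregates iHS over GWAS trait-associated SNPs, polarized by effect
   direction, and tests the mean against a covariate-matched resampling
   null, with Benjamini–Hochberg correction across traits.
3. **Trajectories.** A discretized Wright–Fisher hidden Markov model
   reconstructs allele-frequency trajectories and epoch-wise selection
   coefficients; per-SNP trajectories aggregate into the population-average
   polygenic score $Z(t) = \sum_i \beta_i p_i(t)$.
4. **Synthetic data.** A forward-in-time diploid simulator with
   recombination and selective sweeps generates every input format the
   pipeline reads, with known ground truth, so every stage is testable
   without restricted genotype data.

## EHH, iHH and iHS

For a core SNP and one of its two allele classes, EHH at offset $x$ is the
probability that two randomly drawn carrier haplotypes are identical at
every SNP between the core and $x$:
$$\mathrm{EHH}(x) = \frac{\sum_g \binom{n_g}{2}}{\binom{n_c}{2}},$$
where the $n_g$ count carriers in groups identical over the interval.
`compute_ehh()` walks outward site by site, independently per side,
stopping when EHH drops below a truncation threshold (default 0.05; the
terminal sub-threshold point closes the final trapezoid) or a maximum
physical extension (default 1 Mb) is reached. Curves that reach the panel
edge above the threshold are integrated to the edge and flagged — small
synthetic regions make such edge hits common, and the flag travels with the
record rather than silently censoring it.

`integrate_ihh()` integrates the curve against genetic distance (cM via a
piecewise-linear map; physical distance is available behind the `scale`
argument) and `compute_uihs()` forms
$\mathrm{uiHS} = \ln(\mathrm{iHH}_D / \mathrm{iHH}_A)$; positive values
mean extended derived haplotypes. `standardize_ihs()` centers and scales
within 25 equal-width derived-allele-frequency bins using the sample
(n−1) standard deviation — fixed so exact tests can assert per-bin mean 0
and SD 1 to 1e-12. Equal-count bins are available as an option but are not
the default: on the simulated panels they calibrate the sparse extreme-DAF
bins slightly worse (measured directly in the detection study). The
two-sided normal tail $2(1-\Phi(|\mathrm{siHS}|))$ reproduces the printed
worked example $z = 4.40 \mapsto P = 1.1\times10^{-5}$.

## The tiHS test of polygenic adaptation

Effect sizes are aligned to the derived allele (`polarize_effects()`):
if a GWAS effect allele is the ancestral allele the sign of $\beta$ is
inverted. A trait's SNP set contains the suggestively significant GWAS
SNPs (strictly $P < 5\times10^{-2}$) that carry a defined siHS, minus
explicit exclusions (individually tested large-effect candidates).
The default tiHS is $\mathrm{siHS} \cdot \mathrm{sign}(\beta_D)$
("polarizing"); weighting by $\beta_D$ itself is retained behind
`mode = "weighted"` because both readings of the statistic are defensible
and they differ; the sign mode is the default because polarization is the
operative definition in the method description.

The null distribution of the trait-set mean resamples, for every trait
SNP, a random scanned SNP from the same joint covariate bin — derived
allele frequency (deciles), local recombination rate (terciles), GERP
score (terciles); joint rather than marginal binning is the default, and
all bin counts are configurable. Strata are defined over the scanned,
pool-eligible SNPs; a covariate that is numerically constant (for
example the recombination rate under a uniform map) collapses to a
single stratum; and a bin occupied by a trait SNP but lacking at least
two eligible pool SNPs is a hard error naming the bin, because silently
relaxing the matching would bias the null. The decile/tercile defaults
suit genome-scale pools; the bundled validation studies, whose pools
hold only 1,000–2,500 scanned SNPs, scale the strata down (for example
DAF quintiles) so every occupied stratum stays populated. Draws are without replacement within a
replicate; the pool excludes the trait set itself. The empirical
two-sided p-value is $P = (1+r)/(N+1)$ with ties counted toward $r$ —
conservative and consistent with the +1 correction; the direction call
compares the observed mean with the null mean. The draw protocol
(bin-by-bin in ascending bin id, vectorized paths for bins matched by one
or two trait SNPs) is fixed and documented so a brute-force
re-implementation can replay the same RNG stream exactly — this oracle
equivalence is asserted in the tests. Replicate counts are configurable;
the tests use $10^4$–$10^5$, and $10^7$-scale runs are supported but not
required for validation.

## Wright–Fisher trajectories and epoch-wise selection

The trajectory machinery replaces genealogy-based inference (tree
reconstruction plus importance sampling over branch lengths) with a
frequency-grid hidden Markov model: 101 equally spaced frequencies,
binomial resampling of $2N_e$ gametes per generation with selection
applied to the expected frequency first ($p' = p(1+s)/(1+ps)$), absorbing
boundaries, a uniform prior at the oldest time, and a binomial emission
for the present-day sample count. The constants follow the target study
design: $N_e = 10{,}000$, generation time 28 years, selection allowed in
epochs 0–50, 50–100 and 100–150 generations before present and fixed at
zero earlier. Beyond the last epoch boundary the model evolves neutrally,
which is how trajectories are extended past 150 generations for plotting.

`estimate_epoch_s()` profiles the likelihood on an $s$ grid. When full
trajectories are observed (simulation studies), the binomial transition
likelihood factorizes over generations, so each epoch's $s$ is estimated
independently and exactly; with only a present-day count the HMM marginal
likelihood is profiled over a single shared $s$. Parameter-recovery
simulations at the study constants (50 replicates each) recover $s = 0$
to within ±0.005 and bracket $s = 0.013$ — the headline single-locus
estimate — within [0.008, 0.018].

$Z(t)$ uses posterior-mean frequencies (a sampling mode exists for
credible bands); $\beta$ is per derived-allele copy and $Z$ lives on the
allele-frequency scale, so the sample mean of individual scores
$\sum_i \beta_i g_i / 2$ equals $Z(0)$ computed from sample frequencies —
asserted in the tests. `ps_model_comparison()` fits the age-only, PS-only
and age+PS ordinary-least-squares models on age-defined subsets
(mirroring the all/<55/<50/<45-year design with $n = 22/15/12/10$) and
reports $R^2$, adjusted $R^2$ and AIC.

## What the simulator emulates, and what it does not

`simulate_sweep_panel()` is a forward diploid Wright–Fisher simulator
(compiled inner loop) with per-generation recombination — crossovers per
gamete Poisson with mean equal to the region's map length, uniform
breakpoints — and multiplicative viability selection at one site.
Standing variation is initialized in linkage equilibrium; the sweep
allele arises once, on a single haplotype, at the onset generation. Sweep
simulations are two-phase: a cheap single-locus sampler accepts a
selected-allele count path (conditioned on survival and, optionally, an
ascertainment window for the present-day frequency), then a single
haplotype-level pass is run conditioned on that path, anchoring each
gamete's copying strand at the selected site. The retry cap is fixed
(default 1,000) and the attempt count is reported.

Default conditions were chosen once, to emulate the study setting, and
the self-validation studies use them unchanged:

* 22 diploids sampled from $N_e = 10{,}000$; generation time 28 years.
* Sweep ascertainment `final_freq_range = c(0.3, 0.6)`: sweep loci enter
  haplotype scans because their allele segregates at appreciable but
  unfixed frequency, as the motivating missense variant does.
* Standing frequencies from `standing_freq_sampler()`: half the sites
  intermediate (0.3–0.8, the scannable iHS cores), half near-fixed
  (0.88–0.97). The near-fixed majority mimics the dominant feature of
  real site-frequency spectra that matters here — low per-site
  heterozygosity slows per-marker EHH decay, so iHH integrals average
  over many markers instead of being quantized by two or three.
* Detection studies standardize the sweep chromosome (5 Mb, 2,000 sites)
  jointly with a neutral background chromosome (6.25 Mb, 2,500 sites at
  the same marker density), which plays the role of the genome-wide site
  set in the 25-bin standardization. Standardizing a sweep region against
  itself demonstrably destroys the scan: the hitchhiking zone piles into
  the selected site's own DAF bin and inflates its bin SD.

Features of real data deliberately not emulated: coalescent-depth
genealogy at neutral sites (standing variation starts in linkage
equilibrium, so deep haplotype block structure is absent), recurrent
mutation (ancestral polarization stays exact), demographic change,
genotyping or phasing error, and ascertainment of GWAS effect sizes from
finite discovery samples. Passing tests therefore establish that the
statistics behave correctly under controlled Wright–Fisher dynamics, not
that any particular empirical dataset would yield the same numbers.

The score-level generator `simulate_polyadapt_study()` bypasses haplotype
simulation entirely for tiHS power and calibration studies: it draws
standardized scores with a DAF-dependent mean, covariates, and effect
sizes, and emulates coordinated selection by shifting the causal SNPs'
scores against the sign of their trait effect (default shift 0.5 on 80
trait SNPs among 2,000 — chosen to match, at desk scale, the signal size
implied by a mean-tiHS z-score of roughly 4–5, the order observed for the
strongest trait in the motivating analysis).

## Numerical and design choices

* Coordinates are 1-based inclusive in files (VCF convention), 0-based
  only inside compiled code; conversion is confined to the interfaces.
* Multi-allelic and indel records are skipped on read with a logged
  count; sites whose ancestral state is missing or matches neither
  allele are dropped with a warning. How ambiguous ancestral calls were
  treated upstream of this package is unknowable from the method
  description, so the drop-with-warning policy is this package's own.
* `interpolate_cM()` extrapolates beyond terminal map anchors with the
  terminal segment's slope, keeping local recombination rates continuous.
* Bins with fewer than two defined scores, or zero variance, flag their
  records unstandardizable rather than emitting infinities; a scan with
  fewer than twice as many eligible sites as bins collapses to fewer
  bins with a warning.
* Monomorphic trajectory observations yield a flat likelihood and an
  `NA` selection estimate, flagged rather than guessed.
* Per-trait null seeds are derived deterministically from the run seed,
  so adding or removing a trait never changes another trait's raw
  p-value (asserted in the tests).

## Known limitations

* **Scan resolution at n = 22.** With 44 haplotypes, the siHS ranking
  among a sweep's tightly linked hitchhikers is noise-limited: a site
  tagging a recombination-defined sub-clade more cleanly than the true
  driver can out-score it. In the detection study (s = 0.1, onset 70
  generations, 25 replicates per seed set) the selected site is its
  chromosome's top scorer in roughly 55–70% of replicates depending on
  the seed set, and among the top handful in essentially all of them,
  with driver siHS values centred near 4 — the same order as the
  printed worked example. Expecting the driver to be the *exact*
  regional maximum much more often than this appears unattainable at
  this sample size. Detection uses the signed maximum: under the
  absolute-value maximum, alleles pushed *down* by linkage to the sweep
  double the competitor set and halve the hit rate.
* **Validity of external GWAS weights.** The PS regression comparison
  quantifies, but cannot repair, the transferability of effect sizes
  estimated in a different population.
* **The $10^7$-replicate nulls** of the published analysis are supported
  but validation uses $10^4$–$10^5$; empirical p-values below
  $1/(N+1)$ are unobtainable at the smaller N, which matters only for
  traits whose true p is below that floor.

## Problem sizes used in the validation studies

Simulation studies are scaled to desk hardware: sweep-detection uses 25
replicate genomes of 4,500 sites at $N_e = 10{,}000$; tiHS calibration
uses one neutral 2,000-SNP genome, 12 pseudo-traits and $10^4$ null
replicates; power uses 20 score-level genomes at $10^5$ replicates;
trajectory recovery uses 50 single-locus paths per condition. These sizes
are stated here as the package's validation design.
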