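# haplosel

Haplotype-based selection inference for small phased genome panels:
EHH/iHS selection scans, trait-integrated haplotype score (tiHS) tests of
polygenic adaptation, Wright–Fisher HMM allele-frequency trajectories
with epoch-wise selection coefficients, and polygenic-score trajectory
reconstruction — plus a forward-in-time simulator that generates every
input the pipeline reads.

## Who this is for

Population geneticists analysing recent positive selection in small,
phased, ancestrally polarized panels (tens of diploids), where the
questions are: *which alleles swept?*, *did many small-effect
trait-associated alleles shift together?*, and *when?* The motivating
setting is metabolic-trait adaptation during the peopling of Remote
Oceania, analysed from a 22-diploid panel, but every stage runs on any
phased VCF with ancestral-allele annotation, a recombination map, and
GWAS summary statistics.

## The statistics

* **EHH** at offset *x* from a core allele: the probability that two
  random carrier haplotypes are identical from the core through *x*.
* **iHS**: `uihs = ln(iHH_D / iHH_A)` — the log ratio of the
  trapezoid-integrated EHH curves (against genetic distance) for the
  derived and ancestral alleles — standardized to mean 0, SD 1 within
  25 derived-allele-frequency bins. Large positive values flag derived
  alleles on unusually long haplotypes; `2(1 − Φ(|siHS|))` gives a
  two-sided normal-tail p-value.
* **tiHS**: siHS polarized by the GWAS effect direction of the derived
  allele (`siHS · sign(β_D)`), so positive values mean extended
  haplotypes around trait-increasing alleles. A trait's mean tiHS is
  tested against replicates of random scanned SNPs matched on DAF,
  local recombination rate and GERP score, with
  `P = (1 + r)/(N + 1)` two-sided on absolute means, and
  Benjamini–Hochberg adjustment across traits.
* **Trajectories**: a 101-point frequency-grid Wright–Fisher HMM
  (binomial resampling of 2·Ne gametes, selection on the expected
  frequency, absorbing boundaries) with piecewise-constant selection in
  epochs 0–50, 50–100, 100–150 generations before present; grid-search
  maximum likelihood for the per-epoch selection coefficient; and the
  population-average polygenic score `Z(t) = Σ_i β_i p_i(t)`.

## Worked example

```r
library(haplosel)

# simulate a 22-diploid panel with a recent partial sweep
cfg <- sim_config(n_diploids = 22, region_length = 5e6, n_sites = 2000,
                  per_site_recomb = 1e-8, Ne = 10000, seed = 42,
                  init_freq_sampler = standing_freq_sampler)
sw  <- sweep_spec(selected_site_index = 1000, s = 0.1,
                  onset_generation = 70, final_freq_range = c(0.3, 0.6))
sim <- simulate_sweep_panel(cfg, sw)

scan <- scan_chromosome(sim$panel, sim$map, min_carriers = 5)
#> scanned 1238/2000 sites (762 skipped, 0 unstandardizable, 379 edge-flagged)
scan[which.max(scan$sihs), c("snp_id", "daf", "uihs", "sihs", "p_normal")]
#>        snp_id       daf     uihs     sihs     p_normal
#> 616 snp_01000 0.2727273 4.278327 4.192272 2.761743e-05
```

The top-scoring site is the simulated sweep locus: its derived allele
(sample frequency 0.27) sits on haplotypes whose integrated homozygosity
is e^4.28 ≈ 72 times that of the ancestral allele, 4.2 bin-standard
deviations above sites of comparable frequency — normal-tail
p ≈ 3 × 10⁻⁵. A score of 4.40 — the worked example the scan reproduces —
maps to p = 1.1 × 10⁻⁵.

Epoch-wise selection inference on a simulated trajectory:

```r
set.seed(1)
model <- epoch_selection_model(c(0, 50, 100, 150), s = c(0.013, 0.013, 0),
                               Ne = 10000)
tr  <- simulate_wf_trajectory(0.05, model, 150)
fit <- estimate_epoch_s(tr, boundaries = c(0, 50, 100, 150))
fit$s_hat
#> [1] 0.0135 0.0145 0.0045
```

The two selected epochs recover estimates near the simulated s = 0.013,
while the unselected oldest epoch estimates near zero (it sees only 50
generations of drift at a low frequency). `generations_to_years(100)`
converts the onset to 2800 years.

End-to-end, driven by one seeded configuration:

```r
manifest <- run_pipeline(list(outdir = "run1", seed = 7))
render_report(manifest)   # EHH decay, iHS scatter, Z(t), trait table
```

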