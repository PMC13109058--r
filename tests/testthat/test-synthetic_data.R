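test_that("config constructors enforce their invariants", {
  expect_error(sim_config(n_sites = 1), "at least 2")
  expect_error(sim_config(Ne = 10, n_diploids = 22), "at least n_diploids")
  expect_error(sweep_spec(1, s = 1.2, onset_generation = 50), "0 <= s < 1")
  expect_error(sweep_spec(1, s = 0.1, onset_generation = 0), "positive")
  expect_error(gwas_architecture(5, effect_allele_rule = 2), "\\[0, 1\\]")
})

test_that("absorbing boundaries and negligible drift behave as expected", {
  model <- epoch_selection_model(c(0, 100), s = 0.5, Ne = 100)
  tr <- simulate_wf_trajectory(0, model, 100)
  expect_true(all(tr$freq == 0))
  big <- epoch_selection_model(c(0, 100), s = 0, Ne = 1e9)
  tr2 <- simulate_wf_trajectory(0.5, big, 100)
  expect_true(all(tr2$freq > 0.49 & tr2$freq < 0.51))
})

test_that("selected trajectories track the deterministic logistic curve", {
  set.seed(123)
  model <- epoch_selection_model(c(0, 100), s = 0.013, Ne = 10000)
  finals <- replicate(200, {
    tr <- simulate_wf_trajectory(0.05, model, 100)
    tr$freq[tr$time == 0]
  })
  logistic <- 0.05 * exp(0.013 * 100) / (1 - 0.05 + 0.05 * exp(0.013 * 100))
  expect_equal(mean(finals), logistic, tolerance = 0.03 / logistic)
})

test_that("neutral trajectories are a martingale with decaying heterozygosity", {
  set.seed(99)
  Ne <- 50L
  model <- epoch_selection_model(c(0, 30), s = 0, Ne = Ne)
  paths <- replicate(1000, simulate_wf_trajectory(0.5, model, 30)$freq)
  # rows are times 0 (present) .. 30; expectation stays at p0
  # (per-path SD ~0.25 after 30 generations at 2Ne = 100, so the mean
  # of 1000 paths has SE ~0.008)
  expect_lt(abs(mean(paths[1, ]) - 0.5), 0.03)
  # E[2p(1-p)] decays by (1 - 1/(2Ne)) per generation
  het <- rowMeans(2 * paths * (1 - paths))
  expected <- 2 * 0.5 * 0.5 * (1 - 1 / (2 * Ne))^(30 - (0:30))
  expect_equal(het, expected, tolerance = 0.05)
})

test_that("a zero-recombination sweep from one origin leaves identical cores", {
  cfg <- sim_config(n_diploids = 10, region_length = 1e5, n_sites = 20,
                    per_site_recomb = 0, Ne = 60, seed = 8)
  sim <- suppressMessages(
    simulate_sweep_panel(cfg, sweep_spec(10, 0.3, 40)))
  H <- sim$panel$alleles
  carriers <- which(H[, 10] == 1)
  expect_gte(length(carriers), 2)
  # no recombination, no post-onset mutation: every derived-core
  # haplotype is a copy of the single origin haplotype
  expect_true(all(apply(H[carriers, , drop = FALSE], 2,
                        function(col) length(unique(col)) == 1)))
  curve <- compute_ehh(sim$panel, 10, "derived", truncation_ehh = 0)
  expect_true(all(curve$ehh == 1))
})

test_that("panel simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_diploids = 6, region_length = 1e5, n_sites = 30,
                    Ne = 50, seed = 33)
  a <- simulate_sweep_panel(cfg)
  b <- simulate_sweep_panel(cfg)
  expect_identical(a$panel$alleles, b$panel$alleles)
  expect_identical(a$panel$pos_bp, b$panel$pos_bp)
})

test_that("gwas tables honour the architecture", {
  cfg <- sim_config(n_diploids = 6, region_length = 1e5, n_sites = 40,
                    Ne = 50, seed = 2)
  panel <- simulate_sweep_panel(cfg)$panel
  arch <- gwas_architecture(n_causal = 5, beta_sd = 0.1,
                            effect_allele_rule = 1)
  g <- generate_gwas_table(panel, arch, seed = 4)
  expect_equal(nrow(g), 40)
  # every effect allele is the derived base
  expect_equal(g$effect_allele, panel$der_allele)
  expect_length(attr(g, "causal"), 5)
  expect_true(all(g$p[match(attr(g, "causal"), g$snp_id)] < 0.05))
  # beta_sd = 0 makes all effects zero
  g0 <- generate_gwas_table(panel, gwas_architecture(2, beta_sd = 0),
                            seed = 4)
  expect_true(all(g0$beta == 0))
  expect_identical(generate_gwas_table(panel, arch, seed = 4), g)
  expect_error(generate_gwas_table(panel, gwas_architecture(100), seed = 1),
               "exceeds")
})

test_that("site annotations count DAF and read the map slope", {
  m <- matrix(0L, 44, 3)
  m[1:11, 2] <- 1L
  m[1:4, c(1, 3)] <- 1L
  panel <- haplotype_panel(m, pos_bp = c(1e5, 2e5, 3e5))
  map <- genetic_map(c(0, 1e6), c(0, 2))  # uniform 2 cM/Mb
  a <- generate_site_annotations(panel, map, seed = 1)
  expect_equal(a$daf[2], 11 / 44)
  # uniform map: identical local rate everywhere
  expect_true(all(abs(a$recomb_rate - 2) < 1e-12))
  a2 <- generate_site_annotations(panel, map, seed = 1)
  expect_identical(a$gerp, a2$gerp)
  bad_map <- genetic_map(c(1.5e5, 2.5e5), c(0, 1))
  expect_error(generate_site_annotations(panel, bad_map), "outside")
})

test_that("fixture bundles round-trip and are byte-stable under a seed", {
  outdir <- withr::local_tempdir()
  cfg <- sim_config(n_diploids = 6, region_length = 2e5, n_sites = 30,
                    Ne = 50, seed = 77)
  sw <- sweep_spec(15, 0.2, 30)
  files <- suppressMessages(write_fixture_bundle(outdir, cfg, sw))
  expect_true(all(file.exists(files)))
  p <- read_phased_vcf(files["vcf"])
  truth <- read.delim(files["truth"])
  expect_equal(sum(truth$selected), 1)
  expect_equal(truth$snp_id[truth$selected], p$site_ids[15])
  # round-trip: the written VCF reproduces the simulated panel
  sim <- suppressMessages(simulate_sweep_panel(cfg, sw))
  expect_equal(p$alleles, sim$panel$alleles, ignore_attr = TRUE)
  # regenerating with the same seed is byte-identical
  outdir2 <- withr::local_tempdir()
  files2 <- suppressMessages(write_fixture_bundle(outdir2, cfg, sw))
  for (k in names(files)) {
    expect_identical(readLines(files[[k]]), readLines(files2[[k]]),
                     label = k)
  }
})

test_that("score-level study generator shifts causal SNPs as configured", {
  s0 <- simulate_polyadapt_study(n_snps = 400, n_trait_snps = 20,
                                 direction = "none", seed = 9)
  s1 <- simulate_polyadapt_study(n_snps = 400, n_trait_snps = 20,
                                 shift = 0.7, direction = "decrease",
                                 seed = 9)
  # same seed: non-causal scores identical, causal scores shifted
  # against the trait-effect sign
  causal <- match(s1$causal, s1$scan$snp_id)
  expect_equal(s0$scan$sihs[-causal], s1$scan$sihs[-causal])
  b <- s1$gwas$beta_derived[match(s1$causal, s1$gwas$snp_id)]
  expect_equal(s1$scan$sihs[causal] - s0$scan$sihs[causal],
               -0.7 * sign(b))
  set <- build_trait_set(s1$gwas, s1$scan)
  expect_lt(mean(set$members$tihs), 0)
})
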