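make_panel_for_polarize <- function() {
  m <- matrix(rep(c(0L, 1L), 8), nrow = 4)
  haplotype_panel(m, pos_bp = c(10L, 20L, 30L, 40L),
                  site_ids = c("s1", "s2", "s3", "s4"),
                  anc_allele = c("A", "A", "C", "T"),
                  der_allele = c("G", "C", "T", "A"))
}

test_that("effect sizes are aligned to the derived allele", {
  panel <- make_panel_for_polarize()
  gwas <- validate_gwas_table(data.frame(
    snp_id = c("s1", "s2", "s3", "s5"),
    effect_allele = c("G", "A", "G", "A"),   # derived, ancestral, neither
    beta = c(0.05, 0.05, 0.1, 0.2),
    p = rep(0.01, 4), trait = "BMI"))
  out <- suppressMessages(polarize_effects(gwas, panel))
  expect_equal(out$snp_id, c("s1", "s2"))
  expect_equal(out$beta_derived, c(0.05, -0.05))
  expect_equal(unname(attr(out, "dropped")), c(1L, 1L))
  # literal derived/ancestral flags also work
  gwas2 <- validate_gwas_table(data.frame(
    snp_id = c("s1", "s2"), effect_allele = c("derived", "ancestral"),
    beta = c(0.3, 0.3), p = c(0.5, 0.5), trait = "x"))
  out2 <- polarize_effects(gwas2, panel)
  expect_equal(out2$beta_derived, c(0.3, -0.3))
})

test_that("tiHS polarizes (or weights) standardized scores by effect direction", {
  expect_equal(tihs_value(2.0, 0.05), 2.0)
  expect_equal(tihs_value(2.0, -0.05), -2.0)
  expect_equal(tihs_value(2.0, -0.05, mode = "weighted"), -0.10)
  expect_error(tihs_value(1.0, 0), "nonzero")
})

test_that("trait sets apply the strict suggestive threshold and exclusions", {
  scan <- data.frame(snp_id = sprintf("s%d", 1:6),
                     sihs = c(1, -1, 2, NA, 0.5, 1.5))
  gwas <- data.frame(snp_id = sprintf("s%d", 1:6),
                     beta_derived = c(0.1, -0.2, 0.3, 0.1, 0.2, 0.1),
                     p = c(0.049, 0.05, 0.01, 0.01, 0.2, 0.001),
                     trait = "BMI")
  set <- build_trait_set(gwas, scan, exclusions = "s6")
  # s1 in (p < .05 strictly, so s2 at exactly 0.05 is out); s3 in;
  # s4 has no sihs; s5 not suggestive; s6 excluded
  expect_equal(set$members$snp_id, c("s1", "s3"))
  expect_equal(set$n_reported, sum(gwas$p < 0.05))
  expect_lte(set$n_retained, set$n_reported)
  expect_equal(set$members$tihs, c(1, 2))
  expect_error(build_trait_set(gwas[5, ], scan), "empty trait SNP set")
})

test_that("empirical p follows (1 + r) / (N + 1) with tie counting", {
  res <- empirical_two_sided_p(5, rep(1, 100))
  expect_equal(res$p, 1 / 101)
  expect_equal(res$r, 0)
  expect_equal(res$direction, "Increasing")
  # every replicate at least as extreme -> p = 1
  res2 <- empirical_two_sided_p(1, rep(1, 50))  # ties count toward r
  expect_equal(res2$p, 1)
  res3 <- empirical_two_sided_p(-2, rnorm(100))
  expect_equal(res3$direction, "Decreasing")
  # order of replicate means is irrelevant; minimum attainable p
  x <- rnorm(200)
  expect_equal(empirical_two_sided_p(0.5, x)$p,
               empirical_two_sided_p(0.5, rev(x))$p)
  expect_gte(empirical_two_sided_p(99, x)$p, 1 / 201)
})

test_that("BH adjustment is monotone and preserves order", {
  p <- c(a = 0.04, b = 0.001, c = 0.5, d = 0.04)
  adj <- bh_adjust(p)
  expect_equal(names(adj), names(p))
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(unname(bh_adjust(rep(0.03, 5))), rep(0.03, 5))
  expect_error(bh_adjust(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("matched null resampling is seeded, matched, and oracle-equivalent", {
  study <- simulate_polyadapt_study(n_snps = 300, n_trait_snps = 8,
                                    direction = "none", seed = 21)
  set <- build_trait_set(study$gwas, study$scan)
  # covariate strata scaled to the 300-SNP pool
  a <- sample_matched_null(set, study$annotations, study$scan,
                           n_replicates = 500, seed = 99, daf_breaks = 5,
                           recomb_breaks = 2, gerp_breaks = 2)
  b <- sample_matched_null(set, study$annotations, study$scan,
                           n_replicates = 500, seed = 99, daf_breaks = 5,
                           recomb_breaks = 2, gerp_breaks = 2)
  expect_identical(a, b)
  # independent naive re-implementation under the same draw protocol
  oracle <- naive_matched_null(set, study$annotations, study$scan, 500, 99,
                               daf_breaks = 5, recomb_breaks = 2,
                               gerp_breaks = 2)
  expect_equal(a, oracle)
  # null replicate means center near zero for a neutral genome
  se <- sd(a) / sqrt(length(a))
  expect_lt(abs(mean(a)), max(4 * se, 0.1))
})

test_that("degenerate pool equal to the trait set itself gives p = 1", {
  # pool restricted to SNPs statistically identical to the trait set:
  # every annotation field constant -> one joint bin; pool sihs all
  # equal to the members' sihs value
  scan <- data.frame(snp_id = sprintf("s%d", 1:10), sihs = rep(1.3, 10))
  annotations <- data.frame(snp_id = sprintf("s%d", 1:10), daf = 0.5,
                            recomb_rate = 1, gerp = 0)
  gwas <- data.frame(snp_id = c("s1", "s2"), beta_derived = c(0.2, 0.1),
                     p = c(0.01, 0.02), trait = "t")
  set <- build_trait_set(gwas, scan)
  nulls <- sample_matched_null(set, annotations, scan, n_replicates = 50,
                               seed = 1)
  expect_true(all(nulls == mean(set$members$tihs)))
  res <- empirical_two_sided_p(mean(set$members$tihs), nulls)
  expect_equal(res$p, 1)
  expect_equal(res$r, 50)
})

test_that("underpopulated covariate bins raise an informative error", {
  scan <- data.frame(snp_id = c("s1", "s2", "s3"), sihs = c(1, 2, 3))
  annotations <- data.frame(snp_id = c("s1", "s2", "s3"),
                            daf = c(0.1, 0.9, 0.9),
                            recomb_rate = 1, gerp = 0)
  gwas <- data.frame(snp_id = "s1", beta_derived = 0.1, p = 0.01,
                     trait = "t")
  set <- build_trait_set(gwas, scan)
  expect_error(
    sample_matched_null(set, annotations, scan, n_replicates = 10, seed = 1),
    "pool SNP")
})

test_that("negating all effects flips direction but not the p-value", {
  study <- simulate_polyadapt_study(n_snps = 400, n_trait_snps = 10,
                                    direction = "decrease", shift = 0.6,
                                    seed = 5)
  set <- build_trait_set(study$gwas, study$scan)
  nulls <- sample_matched_null(set, study$annotations, study$scan,
                               n_replicates = 300, seed = 7,
                               daf_breaks = 5, recomb_breaks = 2,
                               gerp_breaks = 2)
  res <- empirical_two_sided_p(mean(set$members$tihs), nulls)

  g2 <- study$gwas
  g2$beta_derived <- -g2$beta_derived
  g2$beta <- -g2$beta
  set2 <- build_trait_set(g2, study$scan)
  expect_equal(set2$members$tihs, -set$members$tihs)
  nulls2 <- sample_matched_null(set2, study$annotations, study$scan,
                                n_replicates = 300, seed = 7,
                                daf_breaks = 5, recomb_breaks = 2,
                                gerp_breaks = 2)
  res2 <- empirical_two_sided_p(mean(set2$members$tihs), nulls2)
  expect_equal(res2$p, res$p)
  expect_true(res$direction != res2$direction)
})

test_that("run_polyadapt assembles the trait table and BH across traits", {
  study <- simulate_polyadapt_study(n_snps = 500, n_trait_snps = 12,
                                    direction = "decrease", shift = 0.8,
                                    seed = 31)
  neutral <- simulate_polyadapt_study(n_snps = 500, n_trait_snps = 12,
                                      direction = "none", seed = 32)
  traits <- list(selected = study$gwas, neutral = neutral$gwas)
  # both traits share the selected genome scan/annotations; the neutral
  # trait is a random SNP set on it
  neutral_ids <- sample(setdiff(study$scan$snp_id, study$gwas$snp_id), 12)
  traits$neutral$snp_id <- neutral_ids
  tab <- run_polyadapt(traits, study$scan, study$annotations,
                       n_replicates = 2000, seed = 3, daf_breaks = 5,
                       recomb_breaks = 2, gerp_breaks = 2)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$p_adjusted >= tab$p_empirical))
  expect_equal(tab$p_adjusted, unname(bh_adjust(tab$p_empirical)))
  expect_equal(tab$direction[tab$trait == "selected"], "Decreasing")
  # dropping one trait leaves the other's raw p unchanged
  tab1 <- run_polyadapt(traits["selected"], study$scan, study$annotations,
                        n_replicates = 2000, seed = 3, daf_breaks = 5,
                        recomb_breaks = 2, gerp_breaks = 2)
  expect_equal(tab1$p_empirical,
               tab$p_empirical[tab$trait == "selected"])
})
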