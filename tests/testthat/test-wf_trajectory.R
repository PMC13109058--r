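test_that("transition operator rows are stochastic with correct expectations", {
  cfg <- wf_hmm_config(grid_size = 101)
  x <- seq(0, 1, length.out = 101)
  M <- wf_transition(cfg, Ne = 500, s = 0)
  expect_equal(rowSums(M), rep(1, 101))
  # neutral martingale up to discretization error
  expect_equal(as.numeric(M %*% x), x, tolerance = 1 / 202)
  # absorbing boundaries
  expect_equal(M[1, ], c(1, rep(0, 100)))
  expect_equal(M[101, ], c(rep(0, 100), 1))
  # selection moves the expectation to p(1+s)/(1+ps) = 0.10117 at
  # p = 0.1, s = 0.013; on the 101-point grid the binomial mass at
  # Ne = 10,000 spans less than one bin, so the operator mean agrees
  # up to half a bin width
  expect_equal(0.1 * 1.013 / 1.0013, 0.101168, tolerance = 1e-5)
  Ms <- wf_transition(cfg, Ne = 10000, s = 0.013)
  i <- which.min(abs(x - 0.1))
  expect_lt(abs(sum(Ms[i, ] * x) - 0.1 * 1.013 / 1.0013), 1 / 200)
  # repeated application preserves total probability
  v <- rep(1 / 101, 101)
  for (k in 1:10) v <- as.numeric(v %*% Ms)
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("posterior trajectories are normalized and anchored at the data", {
  model <- epoch_selection_model(s = c(0, 0, 0))
  post <- trajectory_posterior(k = 30, n = 44, model)
  expect_equal(rowSums(post$posterior), rep(1, 151), tolerance = 1e-9)
  # at the observed time the binomial emission dominates under a
  # neutral prior: mode at the grid point nearest k/n
  expect_equal(post$grid[which.max(post$posterior[1, ])], 30 / 44,
               tolerance = 0.02)
  # fixation observed under strong recent selection: the mean rises
  # toward the present across the selected epoch
  m2 <- epoch_selection_model(s = c(0.1, 0.1, 0.1))
  post2 <- trajectory_posterior(k = 44, n = 44, m2)
  mean_curve <- post2$mean[post2$times <= 100]
  expect_true(all(diff(mean_curve) <= 1e-9))  # decreasing into the past
  expect_error(trajectory_posterior(45, 44, model), "0 <= k <= n")
})

test_that("epoch-wise s is recovered from simulated trajectories", {
  set.seed(202)
  grid <- seq(-0.03, 0.05, by = 5e-4)
  # neutral: mean estimate near zero
  model0 <- epoch_selection_model(c(0, 150), s = 0, Ne = 2000)
  est0 <- replicate(20, {
    tr <- simulate_wf_trajectory(0.3, model0, 150)
    fit <- estimate_epoch_s(tr, boundaries = c(0, 150), s_grid = grid)
    fit$s_hat
  })
  expect_lt(abs(mean(est0)), 0.005)
  # selected: true s inside the recovered interquartile neighbourhood
  model1 <- epoch_selection_model(c(0, 100), s = 0.04, Ne = 2000)
  est1 <- replicate(20, {
    tr <- simulate_wf_trajectory(0.1, model1, 100)
    estimate_epoch_s(tr, boundaries = c(0, 100), s_grid = grid)$s_hat
  })
  expect_gt(median(est1), 0.02)
  expect_lt(median(est1), 0.06)
  # likelihood at the true s beats a wrong-signed alternative
  tr <- simulate_wf_trajectory(0.1, model1, 100)
  fit <- estimate_epoch_s(tr, boundaries = c(0, 100),
                          s_grid = c(-0.05, 0.04))
  expect_gt(fit$logLik[1, 2], fit$logLik[1, 1])
})

test_that("monomorphic observations flag a flat likelihood", {
  model <- epoch_selection_model(c(0, 50), s = 0, Ne = 500)
  tr <- simulate_wf_trajectory(0, model, 50)
  fit <- estimate_epoch_s(tr, boundaries = c(0, 50))
  expect_true(fit$flat[1])
  expect_true(is.na(fit$s_hat[1]))
})

test_that("polygenic-score trajectories are exact linear functionals", {
  t1 <- data.frame(time = 0:10, freq = seq(0.5, 0.3, length.out = 11))
  t2 <- data.frame(time = 0:10, freq = seq(0.2, 0.4, length.out = 11))
  # single SNP with beta 1: Z(t) = p(t) exactly
  z1 <- ps_trajectory(list(a = t1), c(a = 1))
  expect_identical(z1$z, t1$freq)
  # equal and opposite effects on identical trajectories cancel
  z0 <- ps_trajectory(list(a = t1, b = t1), c(a = 0.5, b = -0.5))
  expect_identical(z0$z, rep(0, 11))
  # additivity over SNP-set unions
  za <- ps_trajectory(list(a = t1), c(a = 0.3))
  zb <- ps_trajectory(list(b = t2), c(b = -0.2))
  zab <- ps_trajectory(list(a = t1, b = t2), c(a = 0.3, b = -0.2))
  expect_equal(zab$z, za$z + zb$z)
  expect_equal(attr(zab, "contributing_snps"), 2L)
  # mismatched grids refuse silently interpolating
  t3 <- data.frame(time = 0:9, freq = rep(0.5, 10))
  expect_error(ps_trajectory(list(a = t1, b = t3), c(a = 1, b = 1)),
               "mismatched")
})

test_that("sample-average individual scores equal Z(0) from frequencies", {
  set.seed(5)
  n_dip <- 22L
  H <- matrix(rbinom(2 * n_dip * 6, 1, 0.4), 2 * n_dip)
  beta <- rnorm(6, 0, 0.1)
  freqs <- colMeans(H)
  z0 <- sum(beta * freqs)
  # beta per derived allele copy; individual dosage g in 0..2, score
  # sum(beta * g) / 2 on the allele-frequency scale
  dosage <- H[seq(1, 2 * n_dip, 2), ] + H[seq(2, 2 * n_dip, 2), ]
  indiv <- as.numeric(dosage %*% beta) / 2
  expect_equal(mean(indiv), z0)
})

test_that("generation-year conversion uses the 28-year generation time", {
  expect_equal(generations_to_years(100), 2800)
  expect_equal(generations_to_years(50), 1400)
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(10, generation_time = 25), 250)
  expect_error(generations_to_years(-1), "non-negative")
})

test_that("PS regression comparison ranks models sensibly", {
  set.seed(17)
  age <- runif(22, 30, 70)
  ps <- rnorm(22)
  bmi_lin <- 20 + 3 * ps
  tab <- suppressWarnings(
    ps_model_comparison(bmi_lin, age, ps, age_cutoffs = Inf))
  expect_equal(tab$r_squared[tab$model == "ps_only"], 1)
  # deterministic: identical inputs give identical tables
  expect_identical(tab, suppressWarnings(
    ps_model_comparison(bmi_lin, age, ps, age_cutoffs = Inf)))
  # subsets below the minimum size are skipped
  expect_message(
    out <- suppressWarnings(
      ps_model_comparison(bmi_lin, age, ps, age_cutoffs = c(Inf, 10))),
    "skipped")
  expect_equal(unique(out$cutoff), Inf)
  # independent PS: adding it to age rarely improves AIC
  better <- replicate(100, {
    bmi <- 25 + 0.1 * age + rnorm(22)
    t2 <- ps_model_comparison(bmi, age, rnorm(22), age_cutoffs = Inf)
    t2$aic[t2$model == "age_and_ps"] < t2$aic[t2$model == "age_only"] - 1e-9
  })
  expect_lt(mean(better), 0.5)
})
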