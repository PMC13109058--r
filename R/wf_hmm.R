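#' Epoch-wise selection model
#'
#' Piecewise-constant selection coefficients over intervals of
#' generations before present. The defaults follow the analysis design
#' this package targets: selection allowed in the epochs 0-50, 50-100
#' and 100-150 generations before present, an effective population size
#' of 10,000 diploids and a generation time of 28 years; beyond the
#' last boundary the selection coefficient is fixed at 0.
#'
#' @param boundaries strictly increasing epoch boundaries starting at 0
#'   (generations before present).
#' @param s one selection coefficient per interval
#'   (`length(boundaries) - 1`).
#' @param Ne effective population size (diploids).
#' @param generation_time years per generation.
#' @return An `epoch_selection_model` list.
#' @export
epoch_selection_model <- function(boundaries = c(0, 50, 100, 150),
                                  s = c(0, 0, 0), Ne = 10000L,
                                  generation_time = 28) {
  if (boundaries[1L] != 0) stop("epoch boundaries must start at 0")
  if (any(diff(boundaries) <= 0)) {
    stop("epoch boundaries must be strictly increasing")
  }
  if (length(s) != length(boundaries) - 1L) {
    stop("need one selection coefficient per epoch interval")
  }
  if (any(abs(s) >= 1)) stop("selection coefficients must satisfy |s| < 1")
  structure(list(boundaries = boundaries, s = s, Ne = as.integer(Ne),
                 generation_time = generation_time),
            class = "epoch_selection_model")
}

#' Wright-Fisher HMM configuration
#'
#' @param grid_size number of equally spaced frequency grid points on
#'   `[0, 1]` (default 101).
#' @param prior prior over the grid at the oldest time: `"uniform"`
#'   (default) or a numeric vector of length `grid_size`.
#' @return A `wf_hmm_config` list.
#' @export
wf_hmm_config <- function(grid_size = 101L, prior = "uniform") {
  grid_size <- as.integer(grid_size)
  if (grid_size < 3L) stop("grid_size must be at least 3")
  structure(list(grid_size = grid_size, prior = prior),
            class = "wf_hmm_config")
}

.wf_grid <- function(cfg) seq(0, 1, length.out = cfg$grid_size)

.wf_prior <- function(cfg) {
  if (is.numeric(cfg$prior)) {
    if (length(cfg$prior) != cfg$grid_size) {
      stop("prior length must equal grid_size")
    }
    cfg$prior / sum(cfg$prior)
  } else {
    rep(1 / cfg$grid_size, cfg$grid_size)
  }
}

#' One-generation Wright-Fisher transition operator on a frequency grid
#'
#' Row `i` of the returned matrix is the distribution of the
#' next-generation (one step toward the present) grid frequency given
#' current frequency `p_i`: binomial sampling of `2 Ne` gametes at the
#' post-selection expectation `p' = p (1 + s) / (1 + p s)`, with the
#' binomial mass aggregated onto the grid bins. The boundary states 0
#' and 1 are absorbing. Every row sums to 1.
#'
#' @param cfg a [wf_hmm_config()].
#' @param Ne effective population size (diploids).
#' @param s selection coefficient, `|s| < 1`.
#' @return A `grid_size x grid_size` stochastic matrix.
#' @export
wf_transition <- function(cfg, Ne, s) {
  stopifnot(inherits(cfg, "wf_hmm_config"))
  if (abs(s) >= 1) stop("|s| must be < 1")
  x <- .wf_grid(cfg)
  n <- length(x)
  two_ne <- 2L * as.integer(Ne)
  pp <- x * (1 + s) / (1 + x * s)
  # bin j collects binomial counts in (cut[j-1], cut[j]]
  mid <- (x[-1L] + x[-n]) / 2
  cut <- floor(two_ne * mid)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cdf <- stats::pbinom(cut, two_ne, pp[i])
    M[i, ] <- c(cdf[1L], diff(cdf), 1 - cdf[n - 1L])
  }
  M
}

.epoch_matrices <- function(model, cfg, horizon) {
  s_steps <- .s_at_generation(model, seq_len(horizon))
  s_vals <- unique(s_steps)
  mats <- lapply(s_vals, function(s) wf_transition(cfg, model$Ne, s))
  list(step_s = s_steps, s_vals = s_vals, mats = mats)
}

#' Posterior allele-frequency trajectory from a present-day count
#'
#' Forward-backward smoothing on the frequency grid: a configurable
#' prior at the oldest time (`horizon` generations before present), the
#' epoch-wise Wright-Fisher transition operator between generations, and
#' a single binomial emission at time 0 for the observed derived count
#' `k` out of `n` sampled haplotypes.
#'
#' @param k observed derived allele count at present.
#' @param n number of sampled haplotypes.
#' @param model an [epoch_selection_model()].
#' @param cfg a [wf_hmm_config()].
#' @param horizon generations before present covered (default: last
#'   epoch boundary; beyond the last boundary `s = 0`).
#' @return A `freq_posterior` list: `times` (0..horizon), `grid`,
#'   `posterior` (`(horizon+1) x grid_size` matrix, rows summing to 1,
#'   row order matching `times`), `mean` (posterior-mean frequency per
#'   time) and `logLik` (marginal log-likelihood of the observation).
#' @export
trajectory_posterior <- function(k, n, model, cfg = wf_hmm_config(),
                                 horizon = NULL) {
  stopifnot(inherits(model, "epoch_selection_model"),
            inherits(cfg, "wf_hmm_config"))
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  horizon <- as.integer(horizon %||% max(model$boundaries))
  x <- .wf_grid(cfg)
  em <- .epoch_matrices(model, cfg, horizon)
  emission <- stats::dbinom(k, n, x)

  # forward: prior at the oldest time propagated toward the present
  f <- matrix(0, horizon + 1L, length(x))   # row t+1 = time t
  f[horizon + 1L, ] <- .wf_prior(cfg)
  for (t in horizon:1L) {
    M <- em$mats[[match(em$step_s[t], em$s_vals)]]
    f[t, ] <- f[t + 1L, ] %*% M
  }
  # backward: emission at time 0 propagated into the past
  b <- matrix(0, horizon + 1L, length(x))
  b[1L, ] <- emission
  for (t in seq_len(horizon)) {
    M <- em$mats[[match(em$step_s[t], em$s_vals)]]
    b[t + 1L, ] <- as.numeric(M %*% b[t, ])
  }
  post <- f * b
  norm <- rowSums(post)
  if (any(norm <= 0)) stop("observation has zero likelihood on the grid")
  post <- post / norm
  structure(list(times = 0:horizon, grid = x, posterior = post,
                 mean = as.numeric(post %*% x),
                 logLik = log(sum(f[1L, ] * emission)),
                 model = model),
            class = "freq_posterior")
}

#' Epoch-wise selection-coefficient estimation by grid search
#'
#' Maximum-likelihood estimation of the selection coefficient in each
#' epoch. Two observation modes:
#' \describe{
#'   \item{full trajectory}{`observed` is a `wf_trajectory` with gamete
#'     counts (as produced by [simulate_wf_trajectory()]): the
#'     Wright-Fisher transition likelihood factorizes over generations,
#'     so each epoch's `s` is profiled independently on `s_grid`.}
#'   \item{present-day count}{`observed` is `list(k =, n =)`: the HMM
#'     marginal likelihood from [trajectory_posterior()] is profiled
#'     over a single `s` shared by all epochs (selection allowed in
#'     every epoch up to the last boundary).}
#' }
#' Epochs whose likelihood surface is flat (e.g. the allele is fixed or
#' lost throughout) are flagged with `s_hat = NA`.
#'
#' @param observed a `wf_trajectory` or `list(k, n)`.
#' @param boundaries epoch boundaries (generations before present,
#'   starting at 0).
#' @param cfg a [wf_hmm_config()] (used in present-day-count mode).
#' @param s_grid candidate selection coefficients.
#' @param Ne effective population size; defaults to the trajectory's
#'   own `Ne` attribute, else 10,000.
#' @return An `epoch_s_fit` list: `boundaries`, `s_grid`, `s_hat` (one
#'   per epoch), `logLik` (epochs x grid matrix of profile
#'   log-likelihoods) and `flat` (logical per epoch).
#' @export
estimate_epoch_s <- function(observed, boundaries = c(0, 50, 100, 150),
                             cfg = wf_hmm_config(),
                             s_grid = seq(-0.05, 0.05, by = 5e-4),
                             Ne = NULL) {
  n_ep <- length(boundaries) - 1L
  if (inherits(observed, "wf_trajectory")) {
    counts <- attr(observed, "counts")
    if (is.null(counts)) {
      stop("trajectory carries no gamete counts; was it simulated?")
    }
    Ne <- Ne %||% attr(observed, "Ne") %||% 10000L
    two_ne <- 2L * as.integer(Ne)
    times <- observed$time                    # ascending from 0
    ll <- matrix(NA_real_, n_ep, length(s_grid))
    for (e in seq_len(n_ep)) {
      # rows are ordered time 0, 1, ..., T; step from time t uses rows
      # t+1 (older) -> t (newer)
      steps <- which(times >= 1L & times > boundaries[e] &
                       times <= boundaries[e + 1L])
      if (length(steps) == 0L) next
      k_from <- counts[steps]
      k_to <- counts[steps - 1L]
      p <- k_from / two_ne
      for (si in seq_along(s_grid)) {
        pp <- p * (1 + s_grid[si]) / (1 + p * s_grid[si])
        ll[e, si] <- sum(stats::dbinom(k_to, two_ne, pp, log = TRUE))
      }
    }
  } else if (is.list(observed) && all(c("k", "n") %in% names(observed))) {
    Ne <- Ne %||% 10000L
    ll <- matrix(NA_real_, n_ep, length(s_grid))
    for (si in seq_along(s_grid)) {
      model <- epoch_selection_model(boundaries,
                                     rep(s_grid[si], n_ep), Ne = Ne)
      lp <- trajectory_posterior(observed$k, observed$n, model, cfg)$logLik
      ll[, si] <- lp
    }
  } else {
    stop("observed must be a wf_trajectory or list(k =, n =)")
  }
  flat <- apply(ll, 1L, function(v) {
    all(is.na(v)) || (max(v, na.rm = TRUE) - min(v, na.rm = TRUE)) < 1e-9
  })
  s_hat <- ifelse(flat, NA_real_, s_grid[apply(ll, 1L, which.max)])
  structure(list(boundaries = boundaries, s_grid = s_grid,
                 s_hat = s_hat, logLik = ll, flat = flat),
            class = "epoch_s_fit")
}

#' Population-average polygenic-score trajectory
#'
#' `Z(t) = sum_i beta_i p_i(t)` over SNPs with derived-allele-aligned
#' effect sizes, using each SNP's (posterior mean) frequency trajectory.
#' Z is on the allele-frequency scale: beta is the effect per derived
#' allele copy and frequencies are not doubled, so the individual-level
#' score `sum_i beta_i g_i / 2` averaged over a sample equals Z(0)
#' computed from sample frequencies.
#'
#' @param trajectories named list of per-SNP trajectories: each either a
#'   `freq_posterior` (its posterior mean curve is used), a
#'   `wf_trajectory`, or a data frame with `time` and `freq`. All must
#'   share the same time grid (no silent interpolation).
#' @param betas numeric effect sizes, one per trajectory (matched by
#'   name when both are named).
#' @param generation_time years per generation for the `time_years`
#'   column.
#' @return A `ps_trajectory` data frame (`time`, `time_years`, `z`) with
#'   attribute `contributing_snps`.
#' @export
ps_trajectory <- function(trajectories, betas, generation_time = 28) {
  if (length(trajectories) == 0L) stop("no trajectories supplied")
  as_curve <- function(tr) {
    if (inherits(tr, "freq_posterior")) {
      data.frame(time = tr$times, freq = tr$mean)
    } else {
      data.frame(time = tr$time, freq = tr$freq)
    }
  }
  curves <- lapply(trajectories, as_curve)
  times <- curves[[1L]]$time
  same <- vapply(curves, function(d) {
    length(d$time) == length(times) && all(d$time == times)
  }, logical(1))
  if (!all(same)) {
    stop("trajectories are on mismatched time grids (no silent ",
         "interpolation is performed)")
  }
  if (length(betas) != length(curves)) {
    stop("need one beta per trajectory")
  }
  if (!is.null(names(betas)) && !is.null(names(curves))) {
    betas <- betas[names(curves)]
    if (anyNA(betas)) stop("beta names do not cover all trajectories")
  }
  fmat <- vapply(curves, `[[`, numeric(length(times)), "freq")
  z <- as.numeric(fmat %*% betas)
  structure(data.frame(time = times,
                       time_years = generations_to_years(times,
                                                         generation_time),
                       z = z),
            contributing_snps = length(curves),
            class = c("ps_trajectory", "data.frame"))
}

#' Convert generations before present to years
#'
#' @param g generations (non-negative).
#' @param generation_time years per generation (default 28).
#' @return Years before present.
#' @export
generations_to_years <- function(g, generation_time = 28) {
  if (any(g < 0)) stop("generations must be non-negative")
  g * generation_time
}

#' Compare age-only, PS-only and age+PS models of a trait
#'
#' Fits three ordinary-least-squares models of the trait (age only, PS
#' only, both) on age-defined subsets and reports their fit statistics,
#' used to check whether a polygenic score built from external GWAS
#' effect sizes carries predictive information in the study sample.
#'
#' @param bmi per-individual trait values.
#' @param age per-individual ages (years).
#' @param ps per-individual polygenic scores.
#' @param age_cutoffs upper age limits defining the subsets (`Inf`
#'   means all individuals).
#' @param min_n subsets smaller than this are skipped with a message.
#' @return Data frame with one row per subset x model: `cutoff`, `n`,
#'   `model`, `r_squared`, `adj_r_squared`, `aic`.
#' @export
ps_model_comparison <- function(bmi, age, ps,
                                age_cutoffs = c(Inf, 55, 50, 45),
                                min_n = 4L) {
  stopifnot(length(bmi) == length(age), length(bmi) == length(ps))
  rows <- list()
  for (cut in age_cutoffs) {
    sel <- age < cut
    n <- sum(sel)
    if (n < min_n) {
      message("age subset < ", cut, " skipped: only ", n, " individual(s)")
      next
    }
    d <- data.frame(bmi = bmi[sel], age = age[sel], ps = ps[sel])
    fits <- list(age_only = stats::lm(bmi ~ age, data = d),
                 ps_only = stats::lm(bmi ~ ps, data = d),
                 age_and_ps = stats::lm(bmi ~ age + ps, data = d))
    for (m in names(fits)) {
      sm <- summary(fits[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = cut, n = n, model = m,
        r_squared = sm$r.squared,
        adj_r_squared = sm$adj.r.squared,
        aic = stats::AIC(fits[[m]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
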