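#' Simulation configuration
#'
#' Conditions under which synthetic haplotype panels are generated. The
#' defaults emulate the study design the pipeline is built for: a small
#' phased panel of 22 diploid individuals over a ~1 Mb region, with a
#' human-scale per-bp recombination probability and a 28-year generation
#' time. `Ne` is the simulated effective population size for forward
#' panel simulation; panel simulations are run at a desk-scale `Ne`
#' (default 500 diploids) while single-locus trajectory machinery uses
#' the full `Ne = 10000` (see [epoch_selection_model()]).
#'
#' @param n_diploids number of diploid individuals sampled (default 22).
#' @param region_length region size in bp.
#' @param n_sites number of segregating sites simulated.
#' @param per_site_recomb recombination probability per bp per
#'   generation (Morgans/bp).
#' @param Ne effective population size (diploids) for forward
#'   simulation; must be at least `n_diploids`.
#' @param generation_time years per generation (default 28).
#' @param seed integer RNG seed; a fixed seed makes output reproducible.
#' @param init_freq_range range of initial derived-allele frequencies
#'   for standing variation (uniform draw); kept wide so sampled panels
#'   cover the full DAF spectrum used in standardization bins.
#' @param init_freq_sampler optional `function(n)` drawing the n
#'   initial derived-allele frequencies, overriding `init_freq_range`;
#'   lets panels mix intermediate-frequency scan targets with the
#'   near-fixed sites that dominate real site-frequency spectra.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_diploids = 22L, region_length = 1e6L,
                       n_sites = 400L, per_site_recomb = 1e-8,
                       Ne = 500L, generation_time = 28,
                       seed = NULL, init_freq_range = c(0.05, 0.95),
                       init_freq_sampler = NULL) {
  n_sites <- as.integer(n_sites)
  if (n_sites < 2L) stop("n_sites must be at least 2")
  if (per_site_recomb < 0) stop("per_site_recomb must be non-negative")
  if (Ne < n_diploids) stop("Ne must be at least n_diploids")
  structure(list(n_diploids = as.integer(n_diploids),
                 region_length = as.integer(region_length),
                 n_sites = n_sites,
                 per_site_recomb = per_site_recomb,
                 Ne = as.integer(Ne),
                 generation_time = generation_time,
                 seed = seed,
                 init_freq_range = init_freq_range,
                 init_freq_sampler = init_freq_sampler),
            class = "sim_config")
}

#' Selective sweep specification
#'
#' @param selected_site_index site index (column) of the selected SNP.
#' @param s selection coefficient per generation, `0 <= s < 1`.
#' @param onset_generation generations before present at which the
#'   beneficial allele arises on a single haplotype and selection
#'   switches on.
#' @param dominance dominance coefficient in `[0, 1]` (0.5 = genic).
#' @param final_freq_range optional ascertainment conditioning: the
#'   simulation is retried until the present-day population frequency
#'   of the selected allele falls in this range. Emulates the fact that
#'   sweep loci are studied because their allele segregates at
#'   appreciable (but not fixed) frequency; `NULL` conditions on
#'   survival only.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(selected_site_index, s, onset_generation,
                       dominance = 0.5, final_freq_range = NULL) {
  if (s < 0 || s >= 1) stop("s must satisfy 0 <= s < 1")
  if (onset_generation <= 0) stop("onset_generation must be positive")
  if (dominance < 0 || dominance > 1) stop("dominance must lie in [0, 1]")
  if (!is.null(final_freq_range)) {
    stopifnot(length(final_freq_range) == 2L,
              final_freq_range[1L] < final_freq_range[2L])
  }
  structure(list(selected_site_index = as.integer(selected_site_index),
                 s = s, onset_generation = as.integer(onset_generation),
                 dominance = dominance,
                 final_freq_range = final_freq_range),
            class = "sweep_spec")
}

#' GWAS architecture for synthetic summary tables
#'
#' @param n_causal number of causal (suggestively significant) SNPs.
#' @param beta_sd standard deviation of simulated effect sizes.
#' @param p_assign_rule optional `function(beta, causal)` returning a
#'   p-value per SNP; default gives causal SNPs p < 0.05 and the rest
#'   uniform on [0.05, 1].
#' @param effect_allele_rule probability that the reported effect allele
#'   is the derived allele (default 1).
#' @return A `gwas_architecture` list.
#' @export
gwas_architecture <- function(n_causal, beta_sd = 0.1, p_assign_rule = NULL,
                              effect_allele_rule = 1) {
  if (effect_allele_rule < 0 || effect_allele_rule > 1) {
    stop("effect_allele_rule must lie in [0, 1]")
  }
  structure(list(n_causal = as.integer(n_causal), beta_sd = beta_sd,
                 p_assign_rule = p_assign_rule,
                 effect_allele_rule = effect_allele_rule),
            class = "gwas_architecture")
}

.s_at_generation <- function(model, t) {
  # s for the step ending the interval containing generation t (before
  # present); beyond the last boundary selection is off.
  b <- model$boundaries
  i <- findInterval(t, b, left.open = TRUE)
  ifelse(t > b[length(b)] | i < 1L | i > length(model$s), 0, model$s[pmax(i, 1L)])
}

#' Simulate a single-locus Wright-Fisher allele-frequency trajectory
#'
#' Forward binomial Wright-Fisher sampling of `2 Ne` gametes per
#' generation, with selection applied deterministically to the expected
#' frequency before sampling: `p' = p (1 + s) / (1 + p s)` (genic
#' selection). Frequencies 0 and 1 are absorbing. Selection coefficients
#' are epoch-wise: each generation before present takes the `s` of the
#' epoch containing it, and 0 beyond the last epoch boundary.
#'
#' @param p0 initial derived-allele frequency at `n_generations` before
#'   present.
#' @param model an [epoch_selection_model()] (or a single numeric `s`,
#'   taken as constant over the whole horizon).
#' @param n_generations number of generations simulated forward to the
#'   present.
#' @param cfg optional [sim_config()]; if supplied its `Ne` overrides
#'   the model's.
#' @return A `wf_trajectory` data frame with columns `time`
#'   (generations before present, 0 first) and `freq`, with attributes
#'   `counts` (derived gamete counts, same order) and `Ne`.
#' @export
simulate_wf_trajectory <- function(p0, model, n_generations, cfg = NULL) {
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (is.numeric(model) && length(model) == 1L) {
    model <- epoch_selection_model(boundaries = c(0, n_generations),
                                   s = model)
  }
  stopifnot(inherits(model, "epoch_selection_model"))
  Ne <- if (!is.null(cfg)) cfg$Ne else model$Ne
  two_ne <- 2L * as.integer(Ne)
  n_generations <- as.integer(n_generations)
  k <- integer(n_generations + 1L)       # index g+1 = time g before present
  k[n_generations + 1L] <- as.integer(round(p0 * two_ne))
  for (t in n_generations:1L) {
    p <- k[t + 1L] / two_ne
    s <- .s_at_generation(model, t)
    pp <- p * (1 + s) / (1 + p * s)
    k[t] <- stats::rbinom(1L, two_ne, pp)
  }
  structure(data.frame(time = 0:n_generations, freq = k / two_ne),
            counts = k, Ne = Ne, class = c("wf_trajectory", "data.frame"))
}

#' Forward-simulate a haplotype panel, optionally with a selective sweep
#'
#' Diploid forward Wright-Fisher simulation with per-generation
#' recombination (crossovers per gamete Poisson with mean equal to the
#' region's total map length, breakpoints uniform) and multiplicative
#' viability selection at the selected site. Neutral sites segregate
#' from standing variation initialized in linkage equilibrium at
#' frequencies drawn from `cfg$init_freq_range`; the sweep allele arises
#' once, on a single haplotype, at the sweep onset. If the sweep allele
#' is lost before sampling the simulation restarts, up to `max_retries`
#' attempts.
#'
#' @param cfg a [sim_config()].
#' @param sweep a [sweep_spec()], or `NULL` for a neutral panel.
#' @param n_generations generations simulated; defaults to the sweep
#'   onset (neutral panels default to 70).
#' @param max_retries retry cap when the sweep allele is lost.
#' @return A list with `panel` (a [haplotype_panel] of
#'   `2 * cfg$n_diploids` haplotypes), `trajectory` (true
#'   population frequency of the selected allele per generation; `NULL`
#'   for neutral runs), `map` (the uniform [genetic_map] implied by
#'   `per_site_recomb`) and `attempts`.
#' @export
simulate_sweep_panel <- function(cfg, sweep = NULL, n_generations = NULL,
                                 max_retries = 1000L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(sweep)) {
    stopifnot(inherits(sweep, "sweep_spec"))
    if (sweep$selected_site_index < 1L ||
        sweep$selected_site_index > cfg$n_sites) {
      stop("selected_site_index outside the simulated region")
    }
    n_generations <- n_generations %||% sweep$onset_generation
  } else {
    n_generations <- n_generations %||% 70L
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  two_ne <- 2L * cfg$Ne
  pos <- sort(sample.int(cfg$region_length, cfg$n_sites))
  q <- if (!is.null(cfg$init_freq_sampler)) {
    cfg$init_freq_sampler(cfg$n_sites)
  } else {
    stats::runif(cfg$n_sites, cfg$init_freq_range[1L],
                 cfg$init_freq_range[2L])
  }
  total_r <- cfg$per_site_recomb * cfg$region_length  # Morgans per gamete
  sel <- if (!is.null(sweep)) sweep$selected_site_index else NA_integer_

  init_panel <- function() {
    H <- matrix(stats::rbinom(two_ne * cfg$n_sites, 1L,
                              rep(q, each = two_ne)),
                nrow = two_ne, ncol = cfg$n_sites)
    storage.mode(H) <- "integer"
    H
  }

  attempts <- 0L
  if (is.null(sweep)) {
    out <- cpp_wf_forward(init_panel(), pos, cfg$region_length, total_r,
                          n_generations, -1L, 0, 0.5)
    res <- list(H = out$H, traj = NULL)
    attempts <- 1L
  } else {
    # phase 1: accept a selected-site count path from the cheap
    # single-locus sampler (survival + ascertainment conditioning)
    counts <- NULL
    while (is.null(counts)) {
      attempts <- attempts + 1L
      if (attempts > max_retries) {
        stop("sweep allele lost (or conditioning unmet) in all ",
             max_retries, " attempts")
      }
      k <- 1L
      cand <- integer(n_generations)
      ok <- TRUE
      for (t in seq_len(n_generations)) {
        p <- k / two_ne
        pp <- p * (1 + sweep$s) / (1 + p * sweep$s)
        k <- stats::rbinom(1L, two_ne, pp)
        if (k == 0L || k == two_ne) { ok <- FALSE; break }
        cand[t] <- k
      }
      if (!ok) next
      rng <- sweep$final_freq_range
      final <- cand[n_generations] / two_ne
      if (!is.null(rng) && (final < rng[1L] || final > rng[2L])) next
      counts <- cand
    }
    # phase 2: one haplotype-level pass conditioned on that path
    H <- init_panel()
    H[, sel] <- 0L
    H[sample.int(two_ne, 1L), sel] <- 1L
    out <- cpp_wf_conditional(H, pos, cfg$region_length, total_r,
                              counts, sel - 1L)
    if (!isTRUE(out$ok)) stop("conditional simulation lost a class")
    res <- list(H = out$H, traj = c(1 / two_ne, counts / two_ne))
  }
  if (attempts > 1L) {
    message("sweep conditioning required ", attempts, " attempt(s)")
  }

  idx <- sample.int(two_ne, 2L * cfg$n_diploids)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, cfg$n_sites, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1L), "")
  panel <- haplotype_panel(res$H[idx, , drop = FALSE], chrom = "1",
                           pos_bp = pos,
                           pos_cM = pos * cfg$per_site_recomb * 100,
                           anc_allele = anc, der_allele = unname(der))
  map <- genetic_map(bp = c(1, cfg$region_length),
                     cM = c(0, cfg$per_site_recomb * 100 * cfg$region_length))
  traj <- NULL
  if (!is.null(sweep)) {
    traj <- structure(
      data.frame(time = 0:n_generations, freq = rev(res$traj)),
      Ne = cfg$Ne, class = c("wf_trajectory", "data.frame"))
  }
  list(panel = panel, trajectory = traj, map = map, attempts = attempts)
}

#' Generate a synthetic GWAS summary table from a panel
#'
#' One record per panel site: effect sizes drawn normal with SD
#' `arch$beta_sd`, a known causal subset assigned suggestive p-values
#' (p < 0.05 under the default rule), the rest non-suggestive, and the
#' reported effect allele set to the derived base with probability
#' `arch$effect_allele_rule` (else the ancestral base).
#'
#' @param panel a [haplotype_panel] (or list of panels; sites pooled).
#' @param arch a [gwas_architecture()].
#' @param seed optional integer seed.
#' @param trait trait label.
#' @return A `gwas_table` with attribute `causal` (the causal snp_ids).
#' @export
generate_gwas_table <- function(panel, arch, seed = NULL, trait = "BMI") {
  if (inherits(panel, "haplotype_panel")) panel <- list(panel)
  if (length(panel) == 0L) stop("empty panel pool")
  snp_id <- unlist(lapply(panel, `[[`, "site_ids"))
  anc <- unlist(lapply(panel, function(p)
    p$anc_allele %||% rep("A", length(p$site_ids))))
  der <- unlist(lapply(panel, function(p)
    p$der_allele %||% rep("G", length(p$site_ids))))
  n <- length(snp_id)
  if (arch$n_causal > n) stop("n_causal exceeds the ", n, " available SNPs")
  if (!is.null(seed)) set.seed(seed)
  causal_idx <- sample.int(n, arch$n_causal)
  causal <- logical(n); causal[causal_idx] <- TRUE
  beta <- stats::rnorm(n, 0, arch$beta_sd)
  rule <- arch$p_assign_rule %||% function(beta, causal) {
    p <- stats::runif(length(beta), 0.05, 1)
    p[causal] <- 10^(-stats::runif(sum(causal), 1.40, 8))
    p
  }
  p <- rule(beta, causal)
  eff_derived <- stats::runif(n) < arch$effect_allele_rule
  out <- data.frame(
    snp_id = snp_id,
    effect_allele = ifelse(eff_derived, der, anc),
    beta = ifelse(eff_derived, beta, -beta),
    p = p,
    trait = trait,
    stringsAsFactors = FALSE)
  out <- validate_gwas_table(out)
  attr(out, "causal") <- snp_id[causal_idx]
  out
}

#' Per-site matching covariates for a panel
#'
#' Derived allele frequency from the panel, local recombination rate
#' from the genetic map slope in a window, and a GERP-like conservation
#' score from a configurable distribution.
#'
#' @param panel a [haplotype_panel].
#' @param map a [genetic_map] covering every site position.
#' @param seed optional integer seed (for the GERP-like draw).
#' @param gerp_dist `function(n)` drawing n conservation scores.
#' @param window_bp window for the local recombination rate.
#' @return Annotation data frame (`snp_id`, `daf`, `recomb_rate`,
#'   `gerp`).
#' @export
generate_site_annotations <- function(panel, map, seed = NULL,
                                      gerp_dist = function(n)
                                        stats::rnorm(n, 0, 2),
                                      window_bp = 2e5) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(map, "genetic_map"))
  if (any(panel$pos_bp < min(map$bp) | panel$pos_bp > max(map$bp))) {
    stop("site position(s) outside the genetic map range")
  }
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    snp_id = panel$site_ids,
    daf = unname(panel_daf(panel)),
    recomb_rate = local_recomb_rate(map, panel$pos_bp, window_bp),
    gerp = gerp_dist(length(panel$site_ids)),
    stringsAsFactors = FALSE)
}

#' Write a complete synthetic fixture bundle
#'
#' Simulates a panel (with or without a sweep), a GWAS summary table and
#' matching covariates, and writes every input format the pipeline
#' consumes: a phased VCF with `AA` INFO tags, a genetic map, GWAS and
#' annotation TSVs, plus a truth TSV (causal/selected flags) and the
#' true selected-allele trajectory.
#'
#' @param outdir output directory (created if needed).
#' @param cfg a [sim_config()]; its `seed` drives all randomness.
#' @param sweep optional [sweep_spec()].
#' @param arch optional [gwas_architecture()]; defaults to 10% causal
#'   SNPs with `beta_sd = 0.1`.
#' @return Named character vector of written file paths.
#' @export
write_fixture_bundle <- function(outdir, cfg, sweep = NULL, arch = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  arch <- arch %||% gwas_architecture(n_causal = max(1L, cfg$n_sites %/% 10L))
  sim <- simulate_sweep_panel(cfg, sweep)
  gwas_seed <- (cfg$seed %||% 0L) + 1L
  gwas <- generate_gwas_table(sim$panel, arch, seed = gwas_seed)
  annot <- generate_site_annotations(sim$panel, sim$map,
                                     seed = gwas_seed + 1L)
  files <- c(vcf = file.path(outdir, "panel.vcf"),
             map = file.path(outdir, "map.txt"),
             gwas = file.path(outdir, "gwas_BMI.tsv"),
             annotations = file.path(outdir, "annotations.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             trajectory = file.path(outdir, "trajectory.tsv"))
  write_phased_vcf(sim$panel, files["vcf"])
  write_genetic_map(sim$map, files["map"])
  write_gwas_summary(gwas, files["gwas"])
  write_annotations(annot, files["annotations"])
  truth <- data.frame(
    snp_id = sim$panel$site_ids,
    causal = sim$panel$site_ids %in% attr(gwas, "causal"),
    selected = seq_along(sim$panel$site_ids) ==
      (if (!is.null(sweep)) sweep$selected_site_index else 0L))
  utils::write.table(truth, files["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  traj <- sim$trajectory %||% data.frame(time = integer(0), freq = numeric(0))
  utils::write.table(as.data.frame(traj), files["trajectory"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files
}

#' Default standing-variation frequency sampler
#'
#' Mixture emulating the two features of real panels that matter for
#' haplotype scans: intermediate-frequency sites that are scannable
#' iHS cores, and the near-fixed majority of the site-frequency
#' spectrum, whose low heterozygosity sets the per-marker rate of EHH
#' decay.
#'
#' @param n number of frequencies to draw.
#' @param p_mid fraction of intermediate-frequency sites.
#' @return Numeric vector of initial derived-allele frequencies.
#' @export
standing_freq_sampler <- function(n, p_mid = 0.5) {
  mid <- stats::runif(n) < p_mid
  ifelse(mid, stats::runif(n, 0.3, 0.8), stats::runif(n, 0.88, 0.97))
}

#' One replicate of the sweep-detection simulation study
#'
#' Simulates a sweep chromosome (5 Mb, 2,000 sites, selected site at
#' the centre) and a neutral background chromosome (10 Mb, 4,000
#' sites) for a 22-diploid sample at `Ne = 10,000`, scans both,
#' standardizes the scores jointly in 25 DAF bins (the background
#' plays the role of the genome-wide site set), and reports whether
#' the selected site attains the maximum standardized iHS on its
#' chromosome. The sweep is ascertained at an intermediate present-day
#' frequency (0.3-0.6), matching how partially swept loci enter
#' haplotype scans in practice.
#'
#' @param seed integer seed for this replicate.
#' @param s selection coefficient (default 0.1).
#' @param onset_generation sweep onset, generations before present.
#' @param n_diploids sampled diploids (default 22).
#' @param Ne effective population size for the forward simulation.
#' @param min_carriers minimum carrier count per allele for a site to
#'   be scanned (default 5, a minor-allele filter on 44 haplotypes).
#' @return List with `hit` (selected site is its chromosome's siHS
#'   maximum), `hit_abs` (same under max |siHS|), `driver_sihs`,
#'   `driver_rank`, `max_sihs`, `final_freq` and the sweep-chromosome
#'   scan records.
#' @export
sweep_detection_replicate <- function(seed, s = 0.1,
                                      onset_generation = 70L,
                                      n_diploids = 22L, Ne = 10000L,
                                      min_carriers = 5L) {
  cfg_sweep <- sim_config(n_diploids = n_diploids, region_length = 5e6,
                          n_sites = 2000L, per_site_recomb = 1e-8,
                          Ne = Ne, seed = seed,
                          init_freq_sampler = standing_freq_sampler)
  sw <- sweep_spec(1000L, s, onset_generation,
                   final_freq_range = c(0.3, 0.6))
  sim_sweep <- simulate_sweep_panel(cfg_sweep, sw)
  cfg_bg <- sim_config(n_diploids = n_diploids, region_length = 6.25e6,
                       n_sites = 2500L, per_site_recomb = 1e-8,
                       Ne = Ne, seed = seed + 500000L,
                       init_freq_sampler = standing_freq_sampler)
  sim_bg <- simulate_sweep_panel(cfg_bg)

  scan_records <- function(sim) {
    H <- sim$panel$alleles
    dac <- colSums(H)
    ok <- which(dac >= min_carriers & nrow(H) - dac >= min_carriers)
    bind_uihs_rows(lapply(ok, function(j) {
      compute_uihs(sim$panel, j, sim$map, min_carriers = min_carriers)
    }))
  }
  rec_s <- scan_records(sim_sweep)
  rec_b <- scan_records(sim_bg)
  rec_s$chromosome <- "sweep"
  rec_b$chromosome <- "background"
  std <- standardize_ihs(rbind(rec_s, rec_b), n_bins = 25L)$records
  sw_scan <- std[std$chromosome == "sweep" & !is.na(std$sihs), ,
                 drop = FALSE]
  driver_id <- sim_sweep$panel$site_ids[1000L]
  di <- match(driver_id, sw_scan$snp_id)
  driver_sihs <- if (is.na(di)) NA_real_ else sw_scan$sihs[di]
  list(hit = isTRUE(sw_scan$snp_id[which.max(sw_scan$sihs)] == driver_id),
       hit_abs = isTRUE(
         sw_scan$snp_id[which.max(abs(sw_scan$sihs))] == driver_id),
       driver_sihs = driver_sihs,
       driver_rank = if (is.na(di)) NA_integer_ else
         match(driver_id, sw_scan$snp_id[order(-sw_scan$sihs)]),
       max_sihs = max(sw_scan$sihs),
       final_freq = sim_sweep$trajectory$freq[1L],
       scan = sw_scan)
}

#' Score-level synthetic genome for tiHS test studies
#'
#' Generates an annotated iHS scan and a GWAS table directly at the
#' summary level (per-SNP DAF, standardized iHS, covariates, effect
#' sizes), bypassing haplotype simulation. Coordinated polygenic
#' selection is emulated by shifting the standardized iHS of the causal
#' trait SNPs against the direction of their trait effect:
#' `direction = "decrease"` subtracts `shift * sign(beta_derived)`, so
#' trait-increasing derived alleles get negative scores and
#' trait-decreasing derived alleles positive ones, as expected when
#' selection lowers the trait.
#'
#' @param n_snps total scanned SNPs.
#' @param n_trait_snps suggestively significant SNPs for the focal
#'   trait.
#' @param n_causal number of trait SNPs whose scores carry the
#'   selection shift (default: all of them).
#' @param shift magnitude of the standardized-iHS shift per causal SNP.
#' @param direction `"decrease"`, `"increase"`, or `"none"` (neutral).
#' @param seed optional integer seed.
#' @param trait trait label.
#' @return List with `scan` (snp_id, pos, daf, uihs, sihs, ...), `gwas`
#'   (with `beta_derived`), `annotations`, and `causal` snp ids.
#' @export
simulate_polyadapt_study <- function(n_snps = 2000L, n_trait_snps = 80L,
                                     n_causal = n_trait_snps, shift = 0.5,
                                     direction = c("decrease", "increase",
                                                   "none"),
                                     seed = NULL, trait = "BMI") {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  n_snps <- as.integer(n_snps)
  daf <- stats::runif(n_snps, 0.02, 0.98)
  # unstandardized scores with a DAF-dependent mean, removed by binning
  uihs <- stats::rnorm(n_snps, mean = 0.8 * (0.5 - daf), sd = 0.6)
  records <- data.frame(
    snp_id = sprintf("snp_%05d", seq_len(n_snps)),
    pos = sort(sample.int(5e7, n_snps)),
    daf = daf, ihh_d = NA_real_, ihh_a = NA_real_, uihs = uihs,
    edge_hit = FALSE, low_freq = FALSE, stringsAsFactors = FALSE)
  scan <- standardize_ihs(records, n_bins = 25L)$records

  trait_idx <- sample.int(n_snps, n_trait_snps)
  beta <- stats::rnorm(n_trait_snps, 0, 0.1)
  beta[beta == 0] <- 0.01
  causal_idx <- trait_idx[seq_len(min(n_causal, n_trait_snps))]
  if (direction != "none" && shift != 0) {
    sgn <- if (direction == "decrease") -1 else 1
    j <- match(causal_idx, seq_len(n_snps))
    b <- beta[match(causal_idx, trait_idx)]
    scan$sihs[j] <- scan$sihs[j] + sgn * shift * sign(b)
  }
  gwas <- data.frame(
    snp_id = scan$snp_id[trait_idx],
    effect_allele = "derived",
    beta = beta,
    beta_derived = beta,
    p = 10^(-stats::runif(n_trait_snps, 1.40, 8)),
    trait = trait, stringsAsFactors = FALSE)
  gwas <- validate_gwas_table(gwas)
  annotations <- data.frame(
    snp_id = scan$snp_id,
    daf = scan$daf,
    recomb_rate = stats::rgamma(n_snps, shape = 2, rate = 2),
    gerp = stats::rnorm(n_snps, 0, 2),
    stringsAsFactors = FALSE)
  list(scan = scan, gwas = gwas, annotations = annotations,
       causal = scan$snp_id[match(causal_idx, seq_len(n_snps))])
}
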