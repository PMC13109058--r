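#' Align GWAS effect sizes to the derived allele
#'
#' For each GWAS SNP present in the panel, computes `beta_derived`: the
#' reported effect size if the effect allele is the derived allele, and
#' its negation if the effect allele is the ancestral allele, so that a
#' positive `beta_derived` always means the derived allele increases the
#' trait. Effect alleles may be given as bases (matched against the
#' panel's ancestral/derived bases) or as the literal strings
#' `"derived"` / `"ancestral"`. SNPs absent from the panel, or whose
#' effect allele matches neither panel allele, are dropped with a logged
#' count.
#'
#' @param gwas a `gwas_table` (see [read_gwas_summary()]).
#' @param panel a [haplotype_panel] with ancestral/derived bases.
#' @return The GWAS table restricted to alignable SNPs, with a
#'   `beta_derived` column added; dropped counts in attribute `dropped`.
#' @export
polarize_effects <- function(gwas, panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  idx <- match(gwas$snp_id, panel$site_ids)
  absent <- is.na(idx)
  gwas2 <- gwas[!absent, , drop = FALSE]
  idx <- idx[!absent]
  ea <- toupper(as.character(gwas2$effect_allele))
  anc <- toupper(panel$anc_allele %||% rep(NA_character_,
                                           length(panel$site_ids)))[idx]
  der <- toupper(panel$der_allele %||% rep(NA_character_,
                                           length(panel$site_ids)))[idx]
  is_der <- ea == "DERIVED" | (!is.na(der) & ea == der)
  is_anc <- ea == "ANCESTRAL" | (!is.na(anc) & ea == anc)
  keep <- is_der | is_anc
  out <- gwas2[keep, , drop = FALSE]
  out$beta_derived <- ifelse(is_der[keep], out$beta, -out$beta)
  n_mismatch <- sum(!keep)
  if (sum(absent) + n_mismatch > 0) {
    message(sum(absent), " GWAS SNP(s) absent from panel; ", n_mismatch,
            " dropped (effect allele matches neither panel allele)")
  }
  attr(out, "dropped") <- c(absent = sum(absent), mismatch = n_mismatch)
  out
}

#' Trait-integrated haplotype score
#'
#' Polarizes a standardized iHS by the direction of the GWAS effect of
#' the derived allele. In `"sign"` mode (default)
#' `tihs = sihs * sign(beta_derived)`, so a positive tiHS means extended
#' haplotypes around the trait-increasing allele. In `"weighted"` mode
#' the score is weighted by the effect size itself,
#' `tihs = sihs * beta_derived`.
#'
#' @param sihs standardized iHS value(s).
#' @param beta_derived derived-allele-aligned effect size(s); must be
#'   nonzero.
#' @param mode `"sign"` or `"weighted"`.
#' @return tiHS value(s).
#' @export
tihs_value <- function(sihs, beta_derived, mode = c("sign", "weighted")) {
  mode <- match.arg(mode)
  if (any(beta_derived == 0, na.rm = TRUE)) {
    stop("beta_derived must be nonzero (zero-effect SNPs should be dropped)")
  }
  if (mode == "sign") sihs * sign(beta_derived) else sihs * beta_derived
}

#' Build the trait-associated SNP set for the tiHS test
#'
#' Intersects suggestively significant GWAS SNPs (strictly `p <
#' p_threshold`) with the set of scanned SNPs that carry a defined
#' standardized iHS, removes excluded SNPs (e.g. individually tested
#' large-effect candidates), and computes each member's tiHS.
#'
#' @param gwas a GWAS table carrying a `beta_derived` column (see
#'   [polarize_effects()]).
#' @param scan an `ihs_scan` or scan table with `snp_id` and `sihs`.
#' @param p_threshold suggestive-significance threshold (default 0.05,
#'   strict inequality).
#' @param exclusions SNP ids never admitted to the set.
#' @param trait trait label; defaults to the table's trait.
#' @param mode tiHS mode passed to [tihs_value()].
#' @return A `trait_snp_set`: list with `trait`, `members` (data frame
#'   `snp_id`, `sihs`, `beta_derived`, `tihs`), `n_reported` (suggestive
#'   GWAS SNPs before intersection) and `n_retained`.
#' @export
build_trait_set <- function(gwas, scan, p_threshold = 5e-2,
                            exclusions = character(), trait = NULL,
                            mode = c("sign", "weighted")) {
  mode <- match.arg(mode)
  if (is.null(gwas$beta_derived)) {
    stop("GWAS table lacks beta_derived; run polarize_effects() first")
  }
  trait <- trait %||% (gwas$trait[1L] %||% "trait")
  suggestive <- gwas$p < p_threshold
  n_reported <- sum(suggestive)
  sihs <- scan$sihs[match(gwas$snp_id, scan$snp_id)]
  keep <- suggestive & is.finite(sihs) & !(gwas$snp_id %in% exclusions) &
    is.finite(gwas$beta_derived) & gwas$beta_derived != 0
  if (!any(keep)) stop("empty trait SNP set for trait '", trait, "'")
  members <- data.frame(
    snp_id = gwas$snp_id[keep],
    sihs = sihs[keep],
    beta_derived = gwas$beta_derived[keep],
    stringsAsFactors = FALSE)
  members$tihs <- tihs_value(members$sihs, members$beta_derived, mode)
  structure(list(trait = trait, members = members,
                 n_reported = n_reported, n_retained = nrow(members),
                 mode = mode),
            class = "trait_snp_set")
}

#' @export
print.trait_snp_set <- function(x, ...) {
  cat(sprintf("trait_snp_set '%s': %d reported, %d retained, mean tiHS %.4f\n",
              x$trait, x$n_reported, x$n_retained, mean(x$members$tihs)))
  invisible(x)
}

#' Joint covariate bins for null matching
#'
#' Assigns every annotated SNP to a joint bin of derived allele
#' frequency, local recombination rate and GERP score. Bin edges are
#' sample quantiles of the annotation table (DAF deciles and
#' recombination/GERP terciles by default), so null SNPs are matched on
#' the joint covariate stratum.
#'
#' @param annotations annotation table (see [read_annotations()]).
#' @param daf_breaks,recomb_breaks,gerp_breaks number of quantile bins
#'   per covariate.
#' @return Integer vector of joint bin ids (named by snp_id), with the
#'   per-covariate edges in attribute `edges`.
#' @export
assign_covariate_bins <- function(annotations, daf_breaks = 10L,
                                  recomb_breaks = 3L, gerp_breaks = 3L) {
  qbin <- function(x, k) {
    if (diff(range(x)) <= 1e-8 * max(1, abs(mean(x)))) {
      # (numerically) constant covariate: a single stratum
      return(list(bin = rep(1L, length(x)), nb = 1L, edges = range(x)))
    }
    edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1L),
                                    names = FALSE))
    if (length(edges) < 2L) {
      return(list(bin = rep(1L, length(x)), nb = 1L, edges = edges))
    }
    list(bin = findInterval(x, edges, rightmost.closed = TRUE,
                            all.inside = TRUE),
         nb = length(edges) - 1L, edges = edges)
  }
  bd <- qbin(annotations$daf, daf_breaks)
  br <- qbin(annotations$recomb_rate, recomb_breaks)
  bg <- qbin(annotations$gerp, gerp_breaks)
  joint <- (bd$bin - 1L) + bd$nb * (br$bin - 1L) +
    bd$nb * br$nb * (bg$bin - 1L) + 1L
  structure(stats::setNames(joint, annotations$snp_id),
            edges = list(daf = bd$edges, recomb = br$edges, gerp = bg$edges))
}

#' Covariate-matched resampling null for the mean tiHS
#'
#' Generates the empirical null distribution of the trait-set mean tiHS:
#' each replicate draws, for every trait SNP, one SNP uniformly at
#' random from the pool of scanned SNPs in the same joint
#' (DAF, recombination rate, GERP) bin, without replacement within a
#' replicate, and polarizes the drawn SNP's standardized iHS with the
#' trait SNP's own effect direction (or effect size in weighted mode).
#' The replicate statistic is the mean over the drawn set.
#'
#' Random draws are consumed bin by bin in increasing joint-bin id: for
#' a bin matched by a single trait SNP all replicates are drawn in one
#' vectorized call; for bins matched by several trait SNPs each
#' replicate draws that many distinct pool SNPs. This draw protocol is
#' fixed so seeded runs are exactly reproducible.
#'
#' @param trait_set a [build_trait_set()] result.
#' @param annotations annotation table covering trait and pool SNPs.
#' @param scan scan table supplying pool `sihs` values.
#' @param n_replicates number of null replicates.
#' @param seed optional integer seed.
#' @param daf_breaks,recomb_breaks,gerp_breaks binning passed to
#'   [assign_covariate_bins()].
#' @param pool_exclude additional SNP ids barred from the pool (the
#'   trait set itself is always excluded).
#' @return Numeric vector of `n_replicates` replicate mean tiHS values.
#' @export
sample_matched_null <- function(trait_set, annotations, scan,
                                n_replicates = 1e4L, seed = NULL,
                                daf_breaks = 10L, recomb_breaks = 3L,
                                gerp_breaks = 3L,
                                pool_exclude = character()) {
  stopifnot(inherits(trait_set, "trait_snp_set"))
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_replicates >= 1L)
  # strata are defined over the SNPs the null can actually draw from:
  # annotated sites with a defined standardized score
  sihs_all <- scan$sihs[match(annotations$snp_id, scan$snp_id)]
  annotations <- annotations[is.finite(sihs_all), , drop = FALSE]
  bins <- assign_covariate_bins(annotations, daf_breaks, recomb_breaks,
                                gerp_breaks)
  sihs <- scan$sihs[match(annotations$snp_id, scan$snp_id)]
  members <- trait_set$members
  mbin <- bins[match(members$snp_id, names(bins))]
  if (anyNA(mbin)) {
    stop("trait SNP(s) missing from the annotation table: ",
         members$snp_id[is.na(mbin)][1L])
  }
  w <- if (trait_set$mode == "weighted") members$beta_derived else
    sign(members$beta_derived)
  pool_ok <- is.finite(sihs) &
    !(annotations$snp_id %in% c(members$snp_id, pool_exclude))

  total <- numeric(n_replicates)
  for (b in sort(unique(mbin))) {
    jj <- which(mbin == b)
    k_b <- length(jj)
    vals <- sihs[pool_ok & bins == b]
    m_b <- length(vals)
    if (m_b < max(2L, k_b)) {
      stop("covariate bin ", b, " has ", m_b, " eligible pool SNP(s) but ",
           "needs at least ", max(2L, k_b))
    }
    wv <- w[jj]
    if (!is.null(seed)) { set.seed(seed); seed <- NULL }
    if (k_b == 1L) {
      total <- total + wv * vals[sample.int(m_b, n_replicates, replace = TRUE)]
    } else if (k_b == 2L) {
      i <- sample.int(m_b, n_replicates, replace = TRUE)
      j <- sample.int(m_b - 1L, n_replicates, replace = TRUE)
      j <- j + (j >= i)
      total <- total + wv[1L] * vals[i] + wv[2L] * vals[j]
    } else {
      total <- total + vapply(seq_len(n_replicates), function(r) {
        sum(wv * vals[sample.int(m_b, k_b)])
      }, numeric(1))
    }
  }
  total / nrow(members)
}

#' Empirical two-sided p-value against a resampling null
#'
#' `p = (1 + r) / (N + 1)` where `r` counts replicates whose absolute
#' mean is at least the absolute observed mean (ties count toward `r`).
#' Direction is `"Increasing"` when the observed mean exceeds the
#' average replicate mean, else `"Decreasing"`.
#'
#' @param observed_mean observed mean tiHS of the trait set.
#' @param replicate_means vector of null replicate means.
#' @return List with `p`, `r`, `N`, `direction`, `null_mean`.
#' @export
empirical_two_sided_p <- function(observed_mean, replicate_means) {
  if (length(replicate_means) == 0L) stop("no null replicates supplied")
  r <- sum(abs(replicate_means) >= abs(observed_mean))
  N <- length(replicate_means)
  list(p = (1 + r) / (N + 1), r = r, N = N,
       direction = if (observed_mean > mean(replicate_means)) "Increasing"
       else "Decreasing",
       null_mean = mean(replicate_means))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a set of p-values; a thin
#' wrapper over [stats::p.adjust()] that validates the input range and
#' preserves names and order.
#'
#' @param p p-values in (0, 1], optionally named by trait.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p <= 0 | p > 1 | !is.finite(p))) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Run the tiHS polygenic-adaptation test over multiple traits
#'
#' For each trait: build the trait SNP set, generate the
#' covariate-matched resampling null, compute the empirical two-sided
#' p-value and direction of selection, then adjust across the tested
#' traits with Benjamini-Hochberg. Traits whose retained SNP count falls
#' below `min_retained` are dropped with a message. Per-trait null seeds
#' are derived deterministically from `seed`.
#'
#' @param traits named list of GWAS tables, each carrying
#'   `beta_derived` (see [polarize_effects()]).
#' @param scan scan table with standardized iHS.
#' @param annotations covariate annotation table.
#' @param n_replicates null replicates per trait.
#' @param seed integer seed for the resampling nulls.
#' @param mode tiHS mode, `"sign"` (default) or `"weighted"`.
#' @param p_threshold suggestive GWAS threshold (strict `<`).
#' @param exclusions SNP ids excluded from every trait set.
#' @param min_retained minimum retained SNPs for a trait to be tested.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param daf_breaks,recomb_breaks,gerp_breaks covariate binning.
#' @return Data frame with one row per tested trait: `trait`,
#'   `n_reported`, `n_retained`, `observed_mean_tihs`, `null_mean`, `r`,
#'   `N`, `p_empirical`, `p_adjusted`, `direction`, `significant`.
#' @export
run_polyadapt <- function(traits, scan, annotations, n_replicates = 1e4L,
                          seed = 1L, mode = c("sign", "weighted"),
                          p_threshold = 5e-2, exclusions = character(),
                          min_retained = 1L, alpha = 0.05,
                          daf_breaks = 10L, recomb_breaks = 3L,
                          gerp_breaks = 3L) {
  mode <- match.arg(mode)
  if (is.null(names(traits))) {
    names(traits) <- vapply(traits, function(g) g$trait[1L] %||% "trait", "")
  }
  rows <- list()
  for (i in seq_along(traits)) {
    trait <- names(traits)[i]
    set <- build_trait_set(traits[[i]], scan, p_threshold, exclusions,
                           trait = trait, mode = mode)
    if (set$n_retained < min_retained) {
      message("trait '", trait, "' dropped: ", set$n_retained,
              " retained SNP(s) < floor of ", min_retained)
      next
    }
    nulls <- sample_matched_null(
      set, annotations, scan, n_replicates,
      seed = (as.integer(seed) + i) %% .Machine$integer.max,
      daf_breaks = daf_breaks, recomb_breaks = recomb_breaks,
      gerp_breaks = gerp_breaks, pool_exclude = exclusions)
    obs <- mean(set$members$tihs)
    res <- empirical_two_sided_p(obs, nulls)
    rows[[trait]] <- data.frame(
      trait = trait, n_reported = set$n_reported,
      n_retained = set$n_retained, observed_mean_tihs = obs,
      null_mean = res$null_mean, r = res$r, N = res$N,
      p_empirical = res$p, direction = res$direction,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no trait passed the retention floor")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- bh_adjust(out$p_empirical)
  out$significant <- out$p_adjusted < alpha
  out
}
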