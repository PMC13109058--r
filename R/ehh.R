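#' Extended haplotype homozygosity around a core allele
#'
#' EHH at offset x is the probability that two distinct, randomly chosen
#' haplotypes carrying the core allele are identical at every site from
#' the core out to x: `sum over groups g of C(n_g, 2) / C(n_c, 2)`,
#' where the groups partition the carriers by their haplotype over the
#' interval. The curve is computed site by site outward from the core,
#' independently on each side, and extension stops once EHH drops below
#' `truncation_ehh` (that terminal sub-threshold point is retained, so
#' integration can close the final trapezoid) or `max_extension_bp` is
#' exceeded.
#'
#' @param panel a [haplotype_panel].
#' @param core_site site index (column) of the core SNP.
#' @param allele `"derived"` or `"ancestral"`: which carrier class to
#'   follow.
#' @param truncation_ehh stop extending once EHH falls below this value
#'   (default 0.05).
#' @param max_extension_bp maximum physical extension per side
#'   (default 1 Mb).
#' @return An `ehh_curve`: data frame with columns `site`, `pos_bp`,
#'   `offset_bp` (signed, negative upstream) and `ehh`, containing the
#'   core point (offset 0, EHH 1). Attributes: `core_site`, `core_pos`,
#'   `allele`, `n_carriers`, `edge_left`/`edge_right` (`TRUE` when the
#'   curve reached the panel edge or the extension cap before dropping
#'   below the threshold) and `low_freq` (carrier frequency < 0.05).
#' @export
compute_ehh <- function(panel, core_site, allele = c("derived", "ancestral"),
                        truncation_ehh = 0.05, max_extension_bp = 1e6) {
  stopifnot(inherits(panel, "haplotype_panel"))
  allele <- match.arg(allele)
  code <- if (allele == "derived") 1L else 0L
  H <- panel$alleles
  core_site <- as.integer(core_site)
  if (core_site < 1L || core_site > ncol(H)) stop("core_site out of range")
  carriers <- which(H[, core_site] == code)
  n_c <- length(carriers)
  if (n_c < 2L) {
    stop("fewer than 2 carriers of the ", allele, " allele at site ",
         panel$site_ids[core_site])
  }
  walk <- function(idx_seq) {
    if (length(idx_seq) == 0L) {
      return(list(site = integer(0), ehh = numeric(0), edge = TRUE))
    }
    cpp_ehh_walk(H, carriers - 1L, as.integer(idx_seq),
                 as.numeric(panel$pos_bp),
                 as.numeric(panel$pos_bp[core_site]),
                 truncation_ehh, max_extension_bp)
  }

  left <- if (core_site > 1L) walk((core_site - 1L):1L) else
    list(site = integer(0), ehh = numeric(0), edge = TRUE)
  right <- if (core_site < ncol(H)) walk((core_site + 1L):ncol(H)) else
    list(site = integer(0), ehh = numeric(0), edge = TRUE)

  site <- c(rev(left$site), core_site, right$site)
  ehh <- c(rev(left$ehh), 1.0, right$ehh)
  curve <- data.frame(
    site = site,
    pos_bp = panel$pos_bp[site],
    offset_bp = panel$pos_bp[site] - panel$pos_bp[core_site],
    ehh = ehh)
  structure(curve,
            class = c("ehh_curve", "data.frame"),
            core_site = core_site,
            core_pos = panel$pos_bp[core_site],
            allele = allele,
            n_carriers = n_c,
            edge_left = left$edge,
            edge_right = right$edge,
            low_freq = n_c / nrow(H) < 0.05)
}

#' Integrate an EHH curve into iHH
#'
#' Trapezoidal integral of the EHH decay curve against genetic distance
#' (centimorgans via the map), summed over the two sides of the core.
#' With `scale = "bp"` the integration is against physical distance in
#' Mb instead.
#'
#' @param curve an `ehh_curve` from [compute_ehh()].
#' @param map a [genetic_map]; required for `scale = "cM"`.
#' @param scale integration scale, `"cM"` (default) or `"bp"`.
#' @return iHH, a single non-negative number.
#' @export
integrate_ihh <- function(curve, map = NULL, scale = c("cM", "bp")) {
  stopifnot(inherits(curve, "ehh_curve"))
  scale <- match.arg(scale)
  core_pos <- attr(curve, "core_pos")
  if (scale == "cM") {
    if (is.null(map)) stop("a genetic map is required for cM integration")
    x <- interpolate_cM(map, curve$pos_bp) - interpolate_cM(map, core_pos)
  } else {
    x <- (curve$pos_bp - core_pos) / 1e6
  }
  one_side <- function(sel) {
    xs <- abs(x[sel]); ys <- curve$ehh[sel]
    o <- order(xs)
    xs <- c(0, xs[o]); ys <- c(1, ys[o])
    if (length(xs) < 2L) return(0)
    sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)
  }
  one_side(curve$offset_bp < 0) + one_side(curve$offset_bp > 0)
}

#' Unstandardized iHS at one site
#'
#' Computes EHH curves for the derived and ancestral carrier classes,
#' integrates both into iHH on the genetic scale, and forms the
#' unstandardized score `uihs = ln(iHH_D / iHH_A)`. Positive values mean
#' the derived allele sits on unusually extended haplotypes.
#'
#' @inheritParams compute_ehh
#' @param site site index of the focal SNP.
#' @param map a [genetic_map].
#' @param min_carriers minimum carrier count per allele class (default 2).
#' @return One-row data frame with `snp_id`, `pos`, `daf`, `ihh_d`,
#'   `ihh_a`, `uihs`, `edge_hit`, `low_freq`. `uihs` is `NA` (flagged)
#'   when either iHH is zero.
#' @export
compute_uihs <- function(panel, site, map, truncation_ehh = 0.05,
                         max_extension_bp = 1e6, min_carriers = 2L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  site <- as.integer(site)
  n_hap <- nrow(panel$alleles)
  n_der <- sum(panel$alleles[, site])
  if (n_der == 0L || n_der == n_hap) {
    stop("site ", panel$site_ids[site], " is monomorphic")
  }
  if (n_der < min_carriers || n_hap - n_der < min_carriers) {
    stop("site ", panel$site_ids[site], " has fewer than ", min_carriers,
         " carriers of one allele")
  }
  cd <- compute_ehh(panel, site, "derived", truncation_ehh, max_extension_bp)
  ca <- compute_ehh(panel, site, "ancestral", truncation_ehh, max_extension_bp)
  ihh_d <- integrate_ihh(cd, map)
  ihh_a <- integrate_ihh(ca, map)
  uihs <- if (ihh_d > 0 && ihh_a > 0) log(ihh_d / ihh_a) else NA_real_
  data.frame(
    snp_id = panel$site_ids[site],
    pos = panel$pos_bp[site],
    daf = n_der / n_hap,
    ihh_d = ihh_d,
    ihh_a = ihh_a,
    uihs = uihs,
    edge_hit = attr(cd, "edge_left") || attr(cd, "edge_right") ||
      attr(ca, "edge_left") || attr(ca, "edge_right"),
    low_freq = attr(cd, "low_freq") || attr(ca, "low_freq"),
    stringsAsFactors = FALSE)
}

#' Combine per-site iHS records into one scan table
#'
#' Column-wise binding of [compute_uihs()] rows; much faster than
#' `rbind` on thousands of one-row data frames.
#'
#' @param rows list of one-row data frames from [compute_uihs()].
#' @return A single data frame.
#' @export
bind_uihs_rows <- function(rows) {
  data.frame(
    snp_id = vapply(rows, `[[`, "", "snp_id"),
    pos = vapply(rows, `[[`, 0, "pos"),
    daf = vapply(rows, `[[`, 0, "daf"),
    ihh_d = vapply(rows, `[[`, 0, "ihh_d"),
    ihh_a = vapply(rows, `[[`, 0, "ihh_a"),
    uihs = vapply(rows, `[[`, 0, "uihs"),
    edge_hit = vapply(rows, `[[`, TRUE, "edge_hit"),
    low_freq = vapply(rows, `[[`, TRUE, "low_freq"),
    stringsAsFactors = FALSE)
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Centers and scales unstandardized iHS within equal-width DAF bins:
#' `sihs = (uihs - bin mean) / bin SD`, using the sample (n-1) standard
#' deviation. Records falling in bins with fewer than two defined values,
#' or with zero variance, are flagged unstandardizable (`sihs = NA`).
#'
#' @param records data frame with at least `daf` and `uihs` columns
#'   (e.g. rows from [compute_uihs()]).
#' @param n_bins number of equal-width DAF bins on (0, 1); default 25.
#' @param binning `"width"` (default) for equal-width bins, `"count"`
#'   for equal-count (quantile) bins.
#' @return A list with `records` (input plus `bin`, `sihs`, `p_normal`
#'   columns) and `bins` (per-bin count, mean, SD and edges).
#' @export
standardize_ihs <- function(records, n_bins = 25L,
                            binning = c("width", "count")) {
  binning <- match.arg(binning)
  n_bins <- as.integer(n_bins)
  ok <- is.finite(records$uihs)
  if (binning == "width") {
    edges <- seq(0, 1, length.out = n_bins + 1L)
  } else {
    edges <- unique(stats::quantile(records$daf[ok],
                                    probs = seq(0, 1, length.out = n_bins + 1L),
                                    names = FALSE))
    edges[1L] <- 0; edges[length(edges)] <- 1
    n_bins <- length(edges) - 1L
  }
  bin <- findInterval(records$daf, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mu <- rep(NA_real_, n_bins); sdv <- rep(NA_real_, n_bins)
  cnt <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    v <- records$uihs[ok & bin == b]
    cnt[b] <- length(v)
    if (length(v) >= 2L) {
      mu[b] <- mean(v)
      sdv[b] <- stats::sd(v)
    }
  }
  usable <- !is.na(sdv) & sdv > 0
  sihs <- rep(NA_real_, nrow(records))
  idx <- ok & usable[bin]
  sihs[idx] <- (records$uihs[idx] - mu[bin[idx]]) / sdv[bin[idx]]
  records$bin <- bin
  records$sihs <- sihs
  records$p_normal <- ihs_normal_p(sihs)
  bins <- data.frame(bin = seq_len(n_bins),
                     daf_lo = edges[-length(edges)],
                     daf_hi = edges[-1L],
                     n = cnt, mean = mu, sd = sdv,
                     usable = usable)
  list(records = records, bins = bins)
}

#' Two-sided normal-tail p-value for a standardized iHS
#'
#' `p = 2 * (1 - Phi(|sihs|))`, the probability that a standard normal
#' deviate is at least as extreme as the observed standardized score.
#'
#' @param sihs standardized iHS value(s).
#' @return p-value(s) in `[0, 1]`; `NA` propagates.
#' @export
ihs_normal_p <- function(sihs) {
  2 * stats::pnorm(-abs(sihs))
}

#' iHS scan over every eligible site of a panel
#'
#' Applies [compute_uihs()] to every segregating site with at least
#' `min_carriers` carriers of each allele, then standardizes the scores
#' in DAF bins. Sites that are monomorphic, low-carrier, or yield a zero
#' iHH are skipped or flagged, and their counts reported in a message.
#'
#' @inheritParams compute_uihs
#' @inheritParams standardize_ihs
#' @param verbose emit a message with skip/flag counts (default `TRUE`).
#' @return An `ihs_scan` data frame (one row per scanned site with
#'   `snp_id`, `pos`, `daf`, `ihh_d`, `ihh_a`, `uihs`, `bin`, `sihs`,
#'   `p_normal`, flags), with the standardization bin table attached as
#'   attribute `bins`.
#' @export
scan_chromosome <- function(panel, map, truncation_ehh = 0.05,
                            max_extension_bp = 1e6, n_bins = 25L,
                            min_carriers = 2L, binning = "width",
                            verbose = TRUE) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n_hap <- nrow(panel$alleles)
  dac <- colSums(panel$alleles)
  eligible <- which(dac >= min_carriers & n_hap - dac >= min_carriers)
  n_skipped <- ncol(panel$alleles) - length(eligible)
  if (length(eligible) == 0L) stop("no eligible sites to scan")
  if (length(eligible) < 2L * n_bins) {
    warning("only ", length(eligible), " eligible sites for ", n_bins,
            " DAF bins; collapsing to fewer bins")
    n_bins <- max(1L, length(eligible) %/% 8L)
  }
  rows <- lapply(eligible, function(j) {
    compute_uihs(panel, j, map, truncation_ehh, max_extension_bp,
                 min_carriers)
  })
  records <- bind_uihs_rows(rows)
  std <- standardize_ihs(records, n_bins = n_bins, binning = binning)
  if (verbose) {
    message(sprintf(
      "scanned %d/%d sites (%d skipped, %d unstandardizable, %d edge-flagged)",
      length(eligible), ncol(panel$alleles), n_skipped,
      sum(is.na(std$records$sihs)), sum(std$records$edge_hit)))
  }
  structure(std$records, bins = std$bins,
            class = c("ihs_scan", "data.frame"))
}
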