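#' Phased, ancestrally polarized haplotype panel
#'
#' Container for a phased haplotype matrix in which every site has been
#' polarized so that 0 is the ancestral allele and 1 the derived allele.
#' Rows are haplotypes (two consecutive rows per diploid individual),
#' columns are sites ordered by physical position.
#'
#' @param alleles integer (or coercible) matrix over \{0, 1\}, haplotypes
#'   in rows and sites in columns; no missing entries.
#' @param chrom chromosome label (single string).
#' @param pos_bp strictly increasing integer physical positions, one per
#'   column of `alleles`.
#' @param pos_cM optional non-decreasing genetic positions (centimorgans);
#'   attached by readers when a map is available, otherwise `NULL`.
#' @param site_ids unique site identifiers; defaults to `snp_<index>`.
#' @param anc_allele,der_allele optional per-site ancestral/derived bases
#'   (single characters); kept so GWAS effect alleles given as bases can
#'   be aligned to the panel.
#'
#' @return An object of class `haplotype_panel`: a list with the validated
#'   fields above plus a logical `monomorphic` flag per site.
#' @export
haplotype_panel <- function(alleles, chrom = "1", pos_bp, pos_cM = NULL,
                            site_ids = NULL, anc_allele = NULL,
                            der_allele = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (anyNA(alleles)) stop("haplotype matrix contains missing entries")
  if (!all(alleles %in% c(0L, 1L))) {
    stop("haplotype matrix must contain only 0 (ancestral) and 1 (derived)")
  }
  if (nrow(alleles) %% 2L != 0L) {
    stop("number of haplotypes must be even (phased diploids)")
  }
  pos_bp <- as.integer(pos_bp)
  if (length(pos_bp) != ncol(alleles)) {
    stop("pos_bp length does not match the number of sites")
  }
  if (ncol(alleles) > 1L && any(diff(pos_bp) <= 0L)) {
    stop("physical positions must be strictly increasing")
  }
  if (!is.null(pos_cM)) {
    if (length(pos_cM) != ncol(alleles)) {
      stop("pos_cM length does not match the number of sites")
    }
    if (ncol(alleles) > 1L && any(diff(pos_cM) < 0)) {
      stop("genetic positions must be non-decreasing")
    }
  }
  if (is.null(site_ids)) {
    site_ids <- sprintf("snp_%05d", seq_len(ncol(alleles)))
  }
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids)) stop("site_ids must be unique")
  if (length(site_ids) != ncol(alleles)) {
    stop("site_ids length does not match the number of sites")
  }
  dac <- colSums(alleles)
  structure(list(
    alleles = alleles,
    chrom = as.character(chrom)[1L],
    pos_bp = pos_bp,
    pos_cM = pos_cM,
    site_ids = site_ids,
    anc_allele = anc_allele,
    der_allele = der_allele,
    monomorphic = dac == 0L | dac == nrow(alleles)
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d haplotypes (%d diploids) x %d sites on %s\n",
    nrow(x$alleles), nrow(x$alleles) / 2L, ncol(x$alleles), x$chrom))
  cat(sprintf("  positions %d-%d bp; %d monomorphic site(s)\n",
              min(x$pos_bp), max(x$pos_bp), sum(x$monomorphic)))
  invisible(x)
}

#' Derived allele frequency per site
#'
#' @param panel a [haplotype_panel].
#' @return Numeric vector of per-site derived allele frequencies, named by
#'   site id.
#' @export
panel_daf <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  stats::setNames(colMeans(panel$alleles), panel$site_ids)
}

#' Genetic recombination map
#'
#' A piecewise-linear bp-to-centimorgan map given by anchor points, in the
#' style of PLINK/HapMap recombination map tables.
#'
#' @param bp strictly increasing physical anchor positions.
#' @param cM non-decreasing genetic positions at the anchors.
#' @return A `genetic_map` object (data frame with columns `bp`, `cM`).
#' @export
genetic_map <- function(bp, cM) {
  if (length(bp) == 0L) stop("genetic map must contain at least one anchor")
  if (length(bp) != length(cM)) stop("bp and cM must have equal length")
  bp <- as.numeric(bp); cM <- as.numeric(cM)
  if (length(bp) > 1L) {
    if (any(diff(bp) <= 0)) stop("map bp positions must be strictly increasing")
    if (any(diff(cM) < 0)) stop("map cM positions must be non-decreasing")
  }
  structure(data.frame(bp = bp, cM = cM),
            class = c("genetic_map", "data.frame"))
}

#' Interpolate genetic position
#'
#' Piecewise-linear interpolation of centimorgan position at arbitrary
#' physical coordinates. Beyond the terminal anchors the map is
#' extrapolated with the slope of the terminal segment, so local
#' recombination rate is continuous at the ends.
#'
#' @param map a [genetic_map].
#' @param bp physical positions (vectorized).
#' @return Numeric vector of interpolated cM positions.
#' @export
interpolate_cM <- function(map, bp) {
  stopifnot(inherits(map, "genetic_map"))
  n <- nrow(map)
  if (n == 0L) stop("empty genetic map")
  bp <- as.numeric(bp)
  if (n == 1L) return(rep(map$cM, length(bp)))
  slope <- diff(map$cM) / diff(map$bp)
  seg <- findInterval(bp, map$bp, all.inside = TRUE)
  map$cM[seg] + (bp - map$bp[seg]) * slope[seg]
}

#' Local recombination rate from a map
#'
#' Average recombination rate (cM/Mb) in a window centred on each query
#' position, computed from the slope of the genetic map.
#'
#' @param map a [genetic_map].
#' @param bp query positions.
#' @param window_bp window width in bp (default 200 kb).
#' @return Numeric vector of rates in cM/Mb.
#' @export
local_recomb_rate <- function(map, bp, window_bp = 2e5) {
  half <- window_bp / 2
  d_cM <- interpolate_cM(map, bp + half) - interpolate_cM(map, bp - half)
  d_cM / (window_bp / 1e6)
}
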