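# Independent brute-force oracles used to cross-check the fast
# implementations, plus small fixture builders.

# EHH by direct pair enumeration: for every offset site, count carrier
# pairs identical at every site between the core and that offset.
brute_force_ehh <- function(H, core, allele, site) {
  carriers <- which(H[, core] == allele)
  n <- length(carriers)
  stopifnot(n >= 2)
  rng <- if (site >= core) core:site else site:core
  rng <- setdiff(rng, core)
  same <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (length(rng) == 0L ||
          all(H[carriers[i], rng] == H[carriers[j], rng])) {
        same <- same + 1L
      }
    }
  }
  same / choose(n, 2)
}

# trapezoid integral of an (x, y) polyline
trapz <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# small deterministic panel builder
toy_panel <- function(mat, pos = NULL, cM = NULL) {
  mat <- as.matrix(mat)
  if (is.null(pos)) pos <- seq_len(ncol(mat)) * 1000L
  haplosel::haplotype_panel(mat, chrom = "1", pos_bp = pos, pos_cM = cM)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform 1 cM/Mb map over a generous range
toy_map <- function(max_bp = 2e6) {
  haplosel::genetic_map(bp = c(0, max_bp), cM = c(0, max_bp / 1e6))
}

# naive re-implementation of the matched-null draw protocol: consumes
# the RNG exactly as sample_matched_null documents, but accumulates the
# statistic with plain loops over an explicit index matrix.
naive_matched_null <- function(trait_set, annotations, scan, n_rep, seed,
                               daf_breaks = 10, recomb_breaks = 3,
                               gerp_breaks = 3) {
  keep <- is.finite(scan$sihs[match(annotations$snp_id, scan$snp_id)])
  annotations <- annotations[keep, , drop = FALSE]
  bins <- haplosel::assign_covariate_bins(annotations, daf_breaks,
                                          recomb_breaks, gerp_breaks)
  sihs <- scan$sihs[match(annotations$snp_id, scan$snp_id)]
  members <- trait_set$members
  mbin <- bins[match(members$snp_id, names(bins))]
  w <- if (trait_set$mode == "weighted") members$beta_derived else
    sign(members$beta_derived)
  pool_ok <- is.finite(sihs) & !(annotations$snp_id %in% members$snp_id)
  total <- numeric(n_rep)
  set.seed(seed)
  for (b in sort(unique(mbin))) {
    jj <- which(mbin == b)
    k_b <- length(jj)
    vals <- sihs[pool_ok & bins == b]
    m_b <- length(vals)
    wv <- w[jj]
    if (k_b == 1L) {
      idx <- sample.int(m_b, n_rep, replace = TRUE)
      for (rep in seq_len(n_rep)) total[rep] <- total[rep] + wv * vals[idx[rep]]
    } else if (k_b == 2L) {
      i <- sample.int(m_b, n_rep, replace = TRUE)
      j <- sample.int(m_b - 1L, n_rep, replace = TRUE)
      j <- j + (j >= i)
      for (rep in seq_len(n_rep)) {
        total[rep] <- total[rep] + wv[1L] * vals[i[rep]] + wv[2L] * vals[j[rep]]
      }
    } else {
      for (rep in seq_len(n_rep)) {
        total[rep] <- total[rep] + sum(wv * vals[sample.int(m_b, k_b)])
      }
    }
  }
  total / nrow(members)
}
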