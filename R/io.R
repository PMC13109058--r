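#' Read a phased VCF into a polarized haplotype panel
#'
#' Reads a phased VCF 4.2 file, restricts it to biallelic SNPs, and
#' polarizes every site to ancestral (0) / derived (1) using either an
#' INFO tag carrying the ancestral base (default `AA`) or a side table.
#' Sites whose ancestral state is missing, or matches neither REF nor
#' ALT, are dropped with a warning; counts of dropped records are
#' reported in a message.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @param ancestral_source either the name of an INFO tag holding the
#'   ancestral base (default `"AA"`), or a data frame with columns
#'   `pos` and `aa` giving the ancestral base per physical position.
#' @return A [haplotype_panel]. Haplotypes are ordered sample by sample
#'   (first then second haplotype of each individual).
#' @export
read_phased_vcf <- function(path, ancestral_source = "AA") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)

  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    message(n_skip, " multi-allelic or non-SNP record(s) skipped")
  }
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic SNP records in ", path)

  bad <- which(grepl("/", gt, fixed = TRUE) | is.na(gt))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1L) %% nrow(gt)) + 1L
    stop("unphased or missing genotype at ", fix$CHROM[i], ":", fix$POS[i])
  }

  if (is.data.frame(ancestral_source)) {
    if (!all(c("pos", "aa") %in% names(ancestral_source))) {
      stop("ancestral side table must have columns 'pos' and 'aa'")
    }
    aa <- ancestral_source$aa[match(as.integer(fix$POS), ancestral_source$pos)]
  } else {
    aa <- vcfR::extract.info(v, element = ancestral_source)[snp]
  }
  aa <- toupper(as.character(aa))

  known <- !is.na(aa) & aa %in% c("A", "C", "G", "T")
  match_ref <- known & aa == fix$REF
  match_alt <- known & aa == fix$ALT
  keep <- match_ref | match_alt
  n_noanc <- sum(!known)
  n_mismatch <- sum(known & !keep)
  if (n_noanc > 0) message(n_noanc, " site(s) dropped: ancestral state missing")
  if (n_mismatch > 0) {
    warning(n_mismatch,
            " site(s) dropped: ancestral allele matches neither REF nor ALT")
  }
  if (!any(keep)) stop("no polarizable sites left in ", path)

  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  flip <- match_alt[keep]  # ancestral is ALT => allele 0 in GT is derived

  a1 <- substr(gt, 1L, 1L) == "1"
  a2 <- substr(gt, 3L, 3L) == "1"
  n_samp <- ncol(gt)
  n_site <- nrow(gt)
  # interleave haplotypes: sample 1 hap 1, sample 1 hap 2, sample 2 hap 1, ...
  H <- matrix(0L, nrow = 2L * n_samp, ncol = n_site)
  H[seq(1L, 2L * n_samp, by = 2L), ] <- t(a1)
  H[seq(2L, 2L * n_samp, by = 2L), ] <- t(a2)
  if (any(flip)) H[, flip] <- 1L - H[, flip]

  anc <- ifelse(flip, fix$ALT, fix$REF)
  der <- ifelse(flip, fix$REF, fix$ALT)
  ids <- fix$ID
  if (any(is.na(ids) | ids == ".")) {
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, ":", fix$POS), ids)
  }
  haplotype_panel(H, chrom = fix$CHROM[1L], pos_bp = as.integer(fix$POS),
                  site_ids = ids, anc_allele = anc, der_allele = der)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits VCF 4.2 with phased GT fields and an `AA` INFO tag carrying the
#' ancestral base, so the file round-trips through [read_phased_vcf()].
#'
#' @param panel a [haplotype_panel].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  anc <- panel$anc_allele %||% rep("A", length(panel$site_ids))
  der <- panel$der_allele %||% rep("G", length(panel$site_ids))
  n_dip <- nrow(panel$alleles) / 2L
  h1 <- panel$alleles[seq(1L, by = 2L, length.out = n_dip), , drop = FALSE]
  h2 <- panel$alleles[seq(2L, by = 2L, length.out = n_dip), , drop = FALSE]
  gts <- matrix(paste0(t(h1), "|", t(h2)), nrow = ncol(panel$alleles))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%03d", seq_len(n_dip))), collapse = "\t"))
  body <- paste(panel$chrom, panel$pos_bp, panel$site_ids, anc, der, ".",
                "PASS", paste0("AA=", anc), "GT",
                apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
  tryCatch(writeLines(c(header, body), path),
           error = function(e) stop("failed writing VCF ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read / write a two-column genetic map
#'
#' Plain-text genetic map with one `bp cM` pair per line and a header.
#'
#' @param path file path.
#' @return [read_genetic_map()] returns a [genetic_map];
#'   `write_genetic_map()` returns `path` invisibly.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("genetic map file not found: ", path)
  d <- utils::read.table(path, header = TRUE)
  if (!all(c("bp", "cM") %in% names(d))) {
    stop("genetic map must have header columns: bp cM")
  }
  genetic_map(d$bp, d$cM)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map].
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genetic_map"))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.check_columns <- function(d, required, what) {
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         "; expected header: ", paste(required, collapse = " "))
  }
}

#' Read GWAS summary statistics
#'
#' Tab-separated table with columns `snp_id`, `effect_allele`, `beta`,
#' `p` (and optionally `trait`). Enforces p in (0, 1], finite beta, and
#' unique SNP ids.
#'
#' @param path file path.
#' @param trait trait label attached to the table (overrides any `trait`
#'   column).
#' @return A `gwas_table` data frame.
#' @export
read_gwas_summary <- function(path, trait = NULL) {
  if (!file.exists(path)) stop("GWAS summary file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_columns(d, c("snp_id", "effect_allele", "beta", "p"), "GWAS table")
  if (!is.null(trait)) d$trait <- trait
  if (is.null(d$trait)) d$trait <- "trait"
  validate_gwas_table(d)
}

#' @rdname read_gwas_summary
#' @param gwas a `gwas_table` data frame to validate or write.
#' @export
validate_gwas_table <- function(gwas) {
  .check_columns(gwas, c("snp_id", "effect_allele", "beta", "p"), "GWAS table")
  if (anyDuplicated(gwas$snp_id)) {
    stop("duplicate snp_id in GWAS table: ",
         gwas$snp_id[duplicated(gwas$snp_id)][1L])
  }
  if (any(!is.finite(gwas$beta))) stop("GWAS table contains non-finite beta")
  if (any(gwas$p <= 0 | gwas$p > 1 | !is.finite(gwas$p))) {
    stop("GWAS p-values must lie in (0, 1]")
  }
  class(gwas) <- c("gwas_table", "data.frame")
  gwas
}

#' @rdname read_gwas_summary
#' @export
write_gwas_summary <- function(gwas, path) {
  gwas <- validate_gwas_table(as.data.frame(gwas))
  cols <- c("snp_id", "effect_allele", "beta", "p", "trait")
  utils::write.table(gwas[, intersect(cols, names(gwas))], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-site matching covariates
#'
#' Tab-separated annotation table with columns `snp_id`, `daf`,
#' `recomb_rate`, `gerp` used to build the covariate-matched resampling
#' null.
#'
#' @param path file path.
#' @return A validated data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_columns(d, c("snp_id", "daf", "recomb_rate", "gerp"),
                 "annotation table")
  if (anyDuplicated(d$snp_id)) stop("duplicate snp_id in annotation table")
  if (any(d$daf < 0 | d$daf > 1)) stop("annotation daf must lie in [0, 1]")
  d
}

#' @rdname read_annotations
#' @param annotations annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  .check_columns(annotations, c("snp_id", "daf", "recomb_rate", "gerp"),
                 "annotation table")
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an iHS scan table
#'
#' Fixed-column tab-separated output of [scan_chromosome()]:
#' `snp_id pos daf ihh_d ihh_a uihs sihs p_normal`.
#'
#' @param records scan records data frame.
#' @param path file path.
#' @return `write_scan_table()` returns `path` invisibly;
#'   `read_scan_table()` returns the records data frame.
#' @export
write_scan_table <- function(records, path) {
  cols <- c("snp_id", "pos", "daf", "ihh_d", "ihh_a", "uihs", "sihs",
            "p_normal")
  .check_columns(records, cols, "scan table")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  if (!file.exists(path)) stop("scan table not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_columns(d, c("snp_id", "pos", "daf", "uihs", "sihs"), "scan table")
  if (anyDuplicated(d$snp_id)) stop("duplicate snp_id in scan table")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
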