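.default_run_config <- function() {
  list(
    outdir = "haplosel_run",
    seed = 1L,
    stages = list(simulate = TRUE, scan = TRUE, polyadapt = TRUE,
                  trajectory = TRUE, report = FALSE),
    sim = list(n_diploids = 22L, region_length = 1e6L, n_sites = 400L,
               per_site_recomb = 1e-8, Ne = 500L,
               sweep = list(selected_site_index = 200L, s = 0.1,
                            onset_generation = 70L)),
    gwas = list(n_causal = 40L, beta_sd = 0.1, effect_allele_rule = 1),
    scan = list(n_bins = 25L, truncation_ehh = 0.05,
                max_extension_bp = 1e6, min_carriers = 2L),
    polyadapt = list(n_replicates = 1e4L, mode = "sign",
                     p_threshold = 0.05, min_retained = 1L,
                     daf_breaks = 5L, recomb_breaks = 2L,
                     gerp_breaks = 2L),
    trajectory = list(boundaries = c(0, 50, 100, 150), Ne = 10000L,
                      generation_time = 28, grid_size = 101L,
                      horizon = 150L, n_snps = 20L))
}

.merge_config <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        is.list(user[[key]])) {
      defaults[[key]] <- .merge_config(user[[key]], defaults[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Run the simulate -> scan -> polyadapt -> trajectory pipeline
#'
#' Executes the enabled stages in order against one output directory,
#' with every stochastic stage seeded from `config$seed`, and writes a
#' JSON manifest recording the configuration, the output files and
#' their md5 digests. Re-running with an identical configuration
#' reproduces identical outputs.
#'
#' @param config a nested configuration list (see
#'   `haplosel:::.default_run_config()` for the full key set and
#'   defaults) or the path to a YAML file with the same structure.
#'   Unknown keys raise an error naming the key.
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json` in the output directory.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(config, .default_run_config())
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  run_stage <- function(name, f) {
    tryCatch(f(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (isTRUE(cfg$stages$simulate)) {
    run_stage("simulate", function() {
      sc <- sim_config(n_diploids = cfg$sim$n_diploids,
                       region_length = cfg$sim$region_length,
                       n_sites = cfg$sim$n_sites,
                       per_site_recomb = cfg$sim$per_site_recomb,
                       Ne = cfg$sim$Ne, seed = cfg$seed)
      sw <- if (is.null(cfg$sim$sweep)) NULL else
        sweep_spec(cfg$sim$sweep$selected_site_index, cfg$sim$sweep$s,
                   cfg$sim$sweep$onset_generation)
      arch <- gwas_architecture(n_causal = cfg$gwas$n_causal,
                                beta_sd = cfg$gwas$beta_sd,
                                effect_allele_rule =
                                  cfg$gwas$effect_allele_rule)
      files <- write_fixture_bundle(outdir, sc, sw, arch)
      outputs <<- c(outputs, files)
    })
  }

  if (isTRUE(cfg$stages$scan)) {
    run_stage("scan", function() {
      panel <- read_phased_vcf(file.path(outdir, "panel.vcf"))
      map <- read_genetic_map(file.path(outdir, "map.txt"))
      scan <- scan_chromosome(panel, map,
                              truncation_ehh = cfg$scan$truncation_ehh,
                              max_extension_bp = cfg$scan$max_extension_bp,
                              n_bins = cfg$scan$n_bins,
                              min_carriers = cfg$scan$min_carriers,
                              verbose = FALSE)
      write_scan_table(scan, file.path(outdir, "scan.tsv"))
      outputs <<- c(outputs, scan = file.path(outdir, "scan.tsv"))
    })
  }

  if (isTRUE(cfg$stages$polyadapt)) {
    run_stage("polyadapt", function() {
      panel <- read_phased_vcf(file.path(outdir, "panel.vcf"))
      scan <- read_scan_table(file.path(outdir, "scan.tsv"))
      annot <- read_annotations(file.path(outdir, "annotations.tsv"))
      gwas_files <- list.files(outdir, pattern = "^gwas_.*\\.tsv$",
                               full.names = TRUE)
      traits <- lapply(gwas_files, function(f) {
        polarize_effects(read_gwas_summary(f), panel)
      })
      names(traits) <- sub("^gwas_(.*)\\.tsv$", "\\1", basename(gwas_files))
      tab <- run_polyadapt(traits, scan, annot,
                           n_replicates = cfg$polyadapt$n_replicates,
                           seed = cfg$seed, mode = cfg$polyadapt$mode,
                           p_threshold = cfg$polyadapt$p_threshold,
                           min_retained = cfg$polyadapt$min_retained,
                           daf_breaks = cfg$polyadapt$daf_breaks,
                           recomb_breaks = cfg$polyadapt$recomb_breaks,
                           gerp_breaks = cfg$polyadapt$gerp_breaks)
      utils::write.table(tab, file.path(outdir, "table1.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, table1 = file.path(outdir, "table1.tsv"))
    })
  }

  if (isTRUE(cfg$stages$trajectory)) {
    run_stage("trajectory", function() {
      panel <- read_phased_vcf(file.path(outdir, "panel.vcf"))
      gwas <- polarize_effects(
        read_gwas_summary(list.files(outdir, pattern = "^gwas_.*\\.tsv$",
                                     full.names = TRUE)[1L]), panel)
      tc <- cfg$trajectory
      model <- epoch_selection_model(tc$boundaries,
                                     rep(0, length(tc$boundaries) - 1L),
                                     Ne = tc$Ne,
                                     generation_time = tc$generation_time)
      hmm <- wf_hmm_config(grid_size = tc$grid_size)
      suggestive <- gwas[gwas$p < cfg$polyadapt$p_threshold, , drop = FALSE]
      suggestive <- suggestive[order(suggestive$p), , drop = FALSE]
      use <- utils::head(suggestive, tc$n_snps)
      n_hap <- 2L * cfg$sim$n_diploids
      daf <- panel_daf(panel)[use$snp_id]
      trajs <- lapply(daf, function(f) {
        trajectory_posterior(round(f * n_hap), n_hap, model, hmm,
                             horizon = tc$horizon)
      })
      zt <- ps_trajectory(trajs, stats::setNames(use$beta_derived,
                                                 use$snp_id),
                          generation_time = tc$generation_time)
      utils::write.table(as.data.frame(zt), file.path(outdir, "z.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, z = file.path(outdir, "z.tsv"))
    })
  }

  manifest <- list(
    package = "haplosel",
    version = as.character(utils::packageVersion("haplosel")),
    seed = cfg$seed,
    config = cfg,
    outdir = outdir,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (isTRUE(cfg$stages$report)) render_report(outdir)
  invisible(manifest)
}

#' Render report figures and tables from pipeline outputs
#'
#' Produces the standard figure set from an existing pipeline output
#' directory: an EHH decay plot at the focal (selected or top-scoring)
#' site, the chromosome-wide standardized-iHS scatter, the
#' polygenic-score trajectory with the 50-100-generation settlement
#' window marked, and a Table-1-shaped trait summary. Missing outputs
#' are listed and the report is rendered for whatever is available.
#'
#' @param outdir pipeline output directory (or a manifest list with an
#'   `outdir` element).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(outdir) {
  if (is.list(outdir)) outdir <- outdir$outdir
  written <- character(0)
  missing <- character(0)
  have <- function(f) file.exists(file.path(outdir, f))

  if (have("panel.vcf") && have("map.txt") && have("scan.tsv")) {
    panel <- read_phased_vcf(file.path(outdir, "panel.vcf"))
    scan <- read_scan_table(file.path(outdir, "scan.tsv"))
    focal_id <- if (have("truth.tsv")) {
      tr <- utils::read.delim(file.path(outdir, "truth.tsv"))
      if (any(tr$selected)) tr$snp_id[tr$selected][1L] else
        scan$snp_id[which.max(abs(scan$sihs))]
    } else scan$snp_id[which.max(abs(scan$sihs))]
    focal <- match(focal_id, panel$site_ids)
    if (!is.na(focal)) {
      cd <- compute_ehh(panel, focal, "derived")
      ca <- compute_ehh(panel, focal, "ancestral")
      ed <- rbind(data.frame(offset_bp = cd$offset_bp, ehh = cd$ehh,
                             allele = "derived"),
                  data.frame(offset_bp = ca$offset_bp, ehh = ca$ehh,
                             allele = "ancestral"))
      p1 <- ggplot2::ggplot(ed, ggplot2::aes(.data$offset_bp, .data$ehh,
                                             colour = .data$allele)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "distance from core (bp)", y = "EHH",
                      title = paste("EHH decay at", focal_id)) +
        ggplot2::theme_minimal()
      f <- file.path(outdir, "ehh_decay.pdf")
      ggplot2::ggsave(f, p1, width = 6, height = 4)
      written <- c(written, f)
    }
    p2 <- ggplot2::ggplot(scan, ggplot2::aes(.data$pos, .data$sihs)) +
      ggplot2::geom_point(alpha = 0.6, size = 0.8) +
      ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
      ggplot2::labs(x = "position (bp)", y = "standardized iHS") +
      ggplot2::theme_minimal()
    f <- file.path(outdir, "ihs_scan.pdf")
    ggplot2::ggsave(f, p2, width = 7, height = 4)
    written <- c(written, f)
  } else {
    missing <- c(missing, "panel.vcf/map.txt/scan.tsv")
  }

  if (have("z.tsv")) {
    z <- utils::read.delim(file.path(outdir, "z.tsv"))
    p3 <- ggplot2::ggplot(z, ggplot2::aes(.data$time, .data$z)) +
      ggplot2::geom_line() +
      ggplot2::annotate("rect", xmin = 50, xmax = 100, ymin = -Inf,
                        ymax = Inf, alpha = 0.15) +
      ggplot2::scale_x_reverse() +
      ggplot2::labs(x = "generations before present",
                    y = "population-average polygenic score Z(t)") +
      ggplot2::theme_minimal()
    f <- file.path(outdir, "ps_trajectory.pdf")
    ggplot2::ggsave(f, p3, width = 6, height = 4)
    written <- c(written, f)
  } else {
    missing <- c(missing, "z.tsv")
  }

  f <- file.path(outdir, "report_summary.md")
  lines <- c("# Run summary", "")
  if (have("table1.tsv")) {
    tab <- utils::read.delim(file.path(outdir, "table1.tsv"))
    lines <- c(lines, "## Polygenic adaptation (tiHS) results", "",
               paste(colnames(tab), collapse = " | "),
               paste(rep("---", ncol(tab)), collapse = " | "),
               apply(tab, 1L, paste, collapse = " | "))
  } else {
    lines <- c(lines, "_No trait table available for this run._")
    missing <- c(missing, "table1.tsv")
  }
  if (length(missing) > 0) {
    lines <- c(lines, "", paste("Missing outputs:",
                                paste(missing, collapse = ", ")))
  }
  writeLines(lines, f)
  written <- c(written, f)
  invisible(written)
}
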