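#' Run the full dosage-QTL pipeline
#'
#' Orchestrates simulate (or load) -> anatomy -> trait statistics -> genome
#' scan -> report, writing every stage product as plain-text TSV/BED under
#' `out_dir` together with a YAML run report and a stage log. Identical
#' configuration and seed give identical outputs.
#'
#' The configuration is a plain-text YAML file (or an equivalent nested
#' list) with sections:
#' \describe{
#'   \item{`seed`}{integer, fixes all randomness (default 1).}
#'   \item{`alpha`, `cutoff`, `granularity`, `boxcox_screen_alpha`,
#'     `contact_tolerance`}{scan and anatomy parameters; defaults 0.05,
#'     0.7, `"means"`, 0.01, 1.}
#'   \item{`simulate`}{optional generator overrides passed to
#'     [sim_config()] (`n_lines`, `frac_lesion_lines`, `planted_effects`,
#'     ...). Used when no `inputs` section is given.}
#'   \item{`inputs`}{optional paths: `indels`, `traits`, and optionally
#'     `vessels` + `sections` (per-section anatomy is then computed and
#'     merged into the trait table by `line_id` parsed from
#'     `section_id` as `<line>_<ramet>`).}
#'   \item{`out_dir`}{output directory (default `"dosetra_out"`).}
#' }
#'
#' @param config Path to a YAML config file, or a nested list.
#' @return An object of class `"dqtl_report"`: per-stage row counts, bin
#'   count and coverage, effective bin count, heritability table,
#'   correlation matrix, dQTL regions, the fitted [dqtl_scan] object and
#'   the configuration in effect.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, alpha = 0.05, cutoff = 0.7,
                   granularity = "means", boxcox_screen_alpha = 0.01,
                   contact_tolerance = 1, out_dir = "dosetra_out",
                   simulate = list(), inputs = NULL)
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$cutoff > 0, cfg$cutoff < 2)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat("", file = log_path)
  logf("dosetra pipeline (seed %d, alpha %g, cutoff %g, granularity %s)",
       cfg$seed, cfg$alpha, cfg$cutoff, cfg$granularity)

  gen <- populus_genome()
  truth <- NULL
  if (is.null(cfg$inputs)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    if (!is.null(sim_args$planted_effects))
      sim_args$planted_effects <- as.data.frame(
        do.call(rbind, lapply(sim_args$planted_effects, as.data.frame)))
    scfg <- do.call(sim_config, sim_args)
    pop <- simulate_population(gen, scfg)
    indels <- pop$indels; traits <- pop$traits; truth <- pop$truth
    write_indels(indels, file.path(cfg$out_dir, "indels.tsv"))
    write_traits(traits, file.path(cfg$out_dir, "traits.tsv"))
    write_ground_truth(truth, file.path(cfg$out_dir, "ground_truth.yaml"))
    logf("stage simulate: %d lines (%d with lesions), %d indels, %d ramets",
         scfg$n_lines, length(truth$lesion_lines), nrow(indels), nrow(traits))
  } else {
    indels <- read_indels(cfg$inputs$indels)
    traits <- read_traits(cfg$inputs$traits)
    logf("stage load: %d indels, %d trait rows", nrow(indels), nrow(traits))
    if (!is.null(cfg$inputs$vessels)) {
      vess <- read_vessels(cfg$inputs$vessels)
      secs <- read_sections(cfg$inputs$sections)
      anat <- summarize_sections(vess, secs,
                                 tolerance = cfg$contact_tolerance)
      ids <- strsplit(as.character(anat$section_id), "_", fixed = TRUE)
      anat$line_id <- vapply(ids, `[`, character(1), 1)
      anat$ramet_id <- vapply(ids, function(z)
        if (length(z) > 1) z[2] else "1", character(1))
      write_traits(anat, file.path(cfg$out_dir, "section_traits.tsv"))
      keep <- setdiff(names(anat), c("section_id", "xylem_area_mm2",
                                     "n_vessels", "n_groups",
                                     setdiff(names(traits),
                                             c("line_id", "ramet_id"))))
      traits <- merge(traits, anat[keep], by = c("line_id", "ramet_id"),
                      all.x = TRUE)
      logf("stage anatomy: %d sections summarised", nrow(anat))
    }
  }

  prep <- prepare_traits(traits, screen_alpha = cfg$boxcox_screen_alpha)
  trait_names <- colnames(prep$means)
  herit <- do.call(rbind, lapply(trait_names, function(tr) {
    h <- tryCatch(repeatability(prep$ramets[[tr]], prep$ramets$line_id),
                  error = function(e) NULL)
    if (is.null(h)) return(NULL)
    data.frame(trait = tr, H2 = h$H2, ci_lo = h$ci[1], ci_hi = h$ci[2],
               V_g = h$V_g, MS_error = h$MS_error, r_bar = h$r_bar)
  }))
  cors <- correlation_matrix(as.data.frame(prep$means))
  utils::write.table(herit, file.path(cfg$out_dir, "heritability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(trait = rownames(cors$r), cors$r,
                                check.names = FALSE),
                     file.path(cfg$out_dir, "correlations_r.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("stage traits: %d traits, genotype means over %d lines",
       length(trait_names), nrow(prep$means))

  fit <- dqtl_scan(indels, traits, gen, alpha = cfg$alpha,
                   cutoff = cfg$cutoff, granularity = cfg$granularity,
                   screen_alpha = cfg$boxcox_screen_alpha)
  write_bins_bed(fit$bins, file.path(cfg$out_dir, "bins.bed"))
  write_dosage(fit$dosage, file.path(cfg$out_dir, "dosage.tsv"))
  utils::write.table(fit$scan, file.path(cfg$out_dir, "scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  regions_out <- fit$regions
  if (nrow(regions_out)) {
    regions_out$start_Mbp <- regions_out$start / 1e6
    regions_out$end_Mbp <- regions_out$end / 1e6
  }
  utils::write.table(regions_out, file.path(cfg$out_dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("stage scan: %d bins (coverage %.1f%%), N_eff = %d, %d region(s)",
       nrow(fit$bins), 100 * fit$coverage, fit$n_eff, nrow(fit$regions))

  report <- structure(list(
    config = cfg,
    n_lines = nrow(prep$means), n_indels = nrow(indels),
    n_ramets = nrow(traits), n_bins = nrow(fit$bins),
    coverage = fit$coverage, n_eff = fit$n_eff,
    traits_scanned = unique(fit$scan$trait),
    n_significant_bins = sum(fit$scan$significant, na.rm = TRUE),
    regions = fit$regions, heritability = herit,
    correlations = cors, scan = fit, truth = truth,
    version = as.character(utils::packageVersion("dosetra"))),
    class = "dqtl_report")
  rep_out <- report[c("n_lines", "n_indels", "n_ramets", "n_bins",
                      "coverage", "n_eff", "traits_scanned",
                      "n_significant_bins", "version")]
  rep_out$regions <- if (nrow(fit$regions)) lapply(
    seq_len(nrow(fit$regions)), function(i) as.list(fit$regions[i, ])) else
      list()
  rep_out$config <- cfg[setdiff(names(cfg), c("inputs", "out_dir"))]
  yaml::write_yaml(rep_out, file.path(cfg$out_dir, "report.yaml"))
  logf("stage report: written to %s", file.path(cfg$out_dir, "report.yaml"))
  report
}

#' @export
print.dqtl_report <- function(x, ...) {
  cat("dosetra pipeline report\n")
  cat(sprintf("  lines: %d  ramets: %d  indels: %d\n",
              x$n_lines, x$n_ramets, x$n_indels))
  cat(sprintf("  bins: %d  coverage: %.1f%%  N_eff: %d\n",
              x$n_bins, 100 * x$coverage, x$n_eff))
  cat(sprintf("  traits scanned: %s\n", paste(x$traits_scanned, collapse = ", ")))
  cat(sprintf("  significant bins: %d in %d region(s)\n",
              x$n_significant_bins, nrow(x$regions)))
  invisible(x)
}
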