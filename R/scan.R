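#' Genome-wide dosage-QTL scan
#'
#' The central model fit of the package. From an indel table and a clonally
#' replicated trait table it (1) segments the genome into bins at indel
#' breakpoints, (2) scores relative dosage (RDS) for every line and bin,
#' (3) prepares the traits — optional Box-Cox transformation behind a
#' normality screen, allometric height correction producing `c`-prefixed
#' traits, genotype means — (4) tests each bin-trait pair with tie-corrected
#' Kendall tau-b, (5) adjusts p-values by the effective number of
#' independent bins (hierarchical clustering of bin-bin dosage
#' correlations, cut at `cutoff`), and (6) merges adjacent significant bins
#' into dQTL regions with the percent trait variance they explain.
#'
#' @param indels Indel data frame (`chrom`, `start`, `end`, `line_id`,
#'   `kind`, `ploidy`).
#' @param traits Per-ramet trait data frame (`line_id`, `ramet_id`, one
#'   numeric column per trait). Lines absent from the indel table are
#'   dosage-normal controls.
#' @param genome A [genome] object.
#' @param scan_traits Traits to scan; default all numeric trait columns
#'   plus the height-corrected ones.
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @param cutoff Clustering cutoff for the effective bin count (default 0.7).
#' @param granularity `"means"` (default) scans genotype means; `"ramets"`
#'   scans individual ramets.
#' @param transform Apply the screened Box-Cox transform to raw traits
#'   before scanning.
#' @param correct_height Character vector of traits to height-correct by
#'   log-log residuals (default `c("MVD", "VF")` when a `TH` column is
#'   present); corrected traits are added as `cMVD`, `cVF`, ...
#' @param screen_alpha Shapiro-Wilk level for the Box-Cox screen.
#' @return An object of class `"dqtl_scan"` with components `bins`,
#'   `coverage`, `dosage`, `n_eff`, `eff_labels`, `scan` (long data frame:
#'   `trait`, `bin_id`, `tau`, `p`, `p_adj`, `significant`), `regions`
#'   (per-trait dQTL regions with `variance_explained_pct`), `means`
#'   (genotype-mean matrix of prepared traits), `transforms` (Box-Cox
#'   record), `alpha`, `cutoff`.
#' @examples
#' pop <- simulate_population(config = sim_config(n_lines = 40, seed = 2))
#' fit <- dqtl_scan(pop$indels, pop$traits, populus_genome(),
#'                  scan_traits = "MVD")
#' print(fit)
#' @export
dqtl_scan <- function(indels, traits, genome,
                      scan_traits = NULL, alpha = 0.05, cutoff = 0.7,
                      granularity = c("means", "ramets"),
                      transform = TRUE,
                      correct_height = c("MVD", "VF"),
                      screen_alpha = 0.01) {
  granularity <- match.arg(granularity)
  genome <- as_genome(genome)
  stopifnot(alpha > 0, alpha < 1, cutoff > 0, cutoff < 2)
  seg <- segment_bins(indels, genome)
  bins <- seg$bins
  if (nrow(bins) == 0L) stop("no genomic bins: indel table is empty")
  lines <- sort(unique(as.character(traits$line_id)))
  dosage <- dosage_matrix(indels, bins, lines = lines)
  prep <- prepare_traits(traits, transform = transform,
                         correct_height = correct_height,
                         screen_alpha = screen_alpha)
  if (is.null(scan_traits)) scan_traits <- colnames(prep$means)
  missing_tr <- setdiff(scan_traits, colnames(prep$means))
  if (length(missing_tr))
    stop("unknown trait(s): ", paste(missing_tr, collapse = ", "))
  eff <- effective_bin_count(dosage, cutoff = cutoff)
  scan <- do.call(rbind, lapply(scan_traits, function(tr) {
    y <- if (granularity == "means") prep$means[lines, tr]
    else prep$ramets[[tr]]
    x_rows <- if (granularity == "means") lines
    else as.character(prep$ramets$line_id)
    res <- t(vapply(seq_len(nrow(bins)), function(j) {
      x <- dosage[x_rows, j]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3L || length(unique(x[ok])) < 2L)
        return(c(NA_real_, NA_real_))
      kt <- kendall_tau(x[ok], y[ok])
      c(kt$tau, kt$p)
    }, numeric(2)))
    data.frame(trait = tr, bin_id = bins$bin_id,
               tau = res[, 1], p = res[, 2])
  }))
  scan$p_adj <- adjust_p(scan$p, eff$n_eff)
  scan$significant <- !is.na(scan$p_adj) & scan$p_adj < alpha
  regions <- do.call(rbind, lapply(scan_traits, function(tr) {
    rg <- call_regions(scan[scan$trait == tr, ], bins, alpha = alpha)
    if (nrow(rg) == 0L) return(NULL)
    ve <- variance_explained(prep$means[lines, tr], dosage, rg)
    cbind(trait = tr, rg, variance_explained_pct = ve)
  }))
  if (is.null(regions))
    regions <- data.frame(trait = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          n_bins = integer(0), bin_ids = character(0),
                          top_bin = character(0), min_p_adj = numeric(0),
                          variance_explained_pct = numeric(0))
  structure(list(bins = bins, coverage = seg$coverage, dosage = dosage,
                 n_eff = eff$n_eff, eff_labels = eff$labels,
                 scan = scan, regions = regions,
                 means = prep$means, transforms = prep$transforms,
                 alpha = alpha, cutoff = cutoff,
                 granularity = granularity, call = match.call()),
            class = "dqtl_scan")
}

#' Prepare a ramet trait table for scanning
#'
#' Adds height-corrected traits (log-log residuals against `TH`), applies
#' the screened Box-Cox transform to raw traits, and computes genotype
#' means.
#'
#' @inheritParams dqtl_scan
#' @param traits Per-ramet trait data frame.
#' @return List with `ramets` (augmented per-ramet table), `means`
#'   (genotype x trait matrix) and `transforms` (data frame of Box-Cox
#'   decisions per trait).
#' @export
prepare_traits <- function(traits, transform = TRUE,
                           correct_height = c("MVD", "VF"),
                           screen_alpha = 0.01) {
  stopifnot(all(c("line_id", "ramet_id") %in% names(traits)))
  tr_cols <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1))],
                     c("ramet_id"))
  ramets <- traits
  if ("TH" %in% names(ramets)) {
    for (tr in intersect(correct_height, tr_cols)) {
      fit <- height_correct(ramets[[tr]], ramets$TH)
      ramets[[paste0("c", tr)]] <- fit$residuals
    }
  }
  all_cols <- setdiff(names(ramets)[vapply(ramets, is.numeric, logical(1))],
                      "ramet_id")
  transforms <- data.frame(trait = all_cols, lambda = NA_real_,
                           applied = FALSE)
  if (transform) {
    for (i in seq_along(all_cols)) {
      tr <- all_cols[i]
      if (startsWith(tr, "c") && substring(tr, 2) %in% tr_cols) next
      v <- ramets[[tr]]
      if (any(is.na(v)) || any(v <= 0)) next
      bc <- boxcox_transform(v, screen_alpha = screen_alpha)
      if (bc$applied) {
        ramets[[tr]] <- bc$values
        transforms$lambda[i] <- bc$lambda
        transforms$applied[i] <- TRUE
      }
    }
  }
  lines <- sort(unique(as.character(ramets$line_id)))
  means <- vapply(all_cols, function(tr)
    tapply(ramets[[tr]], as.character(ramets$line_id), mean,
           na.rm = TRUE)[lines],
    numeric(length(lines)))
  rownames(means) <- lines
  usable <- colSums(!is.na(means)) >= 3
  means <- means[, usable, drop = FALSE]
  list(ramets = ramets, means = means,
       transforms = transforms[transforms$trait %in% colnames(means), ])
}

#' @export
print.dqtl_scan <- function(x, ...) {
  cat("Dosage-QTL genome scan\n")
  cat(sprintf("  %d bins on %d chromosomes (%.1f%% genome coverage), %d lines\n",
              nrow(x$bins), length(unique(x$bins$chrom)),
              100 * x$coverage, nrow(x$dosage)))
  cat(sprintf("  effective independent bins: %d (cutoff %.2f); alpha = %g on adjusted p\n",
              x$n_eff, x$cutoff, x$alpha))
  cat(sprintf("  traits scanned (%s): %s\n", x$granularity,
              paste(unique(x$scan$trait), collapse = ", ")))
  if (nrow(x$regions)) {
    cat(sprintf("  %d dQTL region(s) in %d trait(s)\n", nrow(x$regions),
                length(unique(x$regions$trait))))
  } else cat("  no significant dQTL regions\n")
  invisible(x)
}

#' @export
summary.dqtl_scan <- function(object, ...) {
  structure(list(scan = object), class = "summary.dqtl_scan")
}

#' @export
print.summary.dqtl_scan <- function(x, ...) {
  s <- x$scan
  print(s)
  tab <- s$regions
  if (nrow(tab)) {
    cat("\ndQTL regions:\n")
    show <- tab[c("trait", "chrom", "start", "end", "n_bins", "min_p_adj",
                  "variance_explained_pct")]
    show$start <- sprintf("%.2f", show$start / 1e6)
    show$end <- sprintf("%.2f", show$end / 1e6)
    names(show)[3:4] <- c("start_Mbp", "end_Mbp")
    show$min_p_adj <- signif(show$min_p_adj, 3)
    show$variance_explained_pct <- round(show$variance_explained_pct, 1)
    print(show, row.names = FALSE)
  }
  tr <- s$transforms
  if (any(tr$applied)) {
    cat("\nBox-Cox transformed traits:\n")
    print(tr[tr$applied, ], row.names = FALSE)
  }
  invisible(x)
}

#' Manhattan plot of a dosage-QTL scan
#'
#' Plots `-log10` adjusted p per bin against cumulative genomic position,
#' with alternating chromosome shading and the significance threshold.
#'
#' @param x A `dqtl_scan` object.
#' @param trait Trait to plot (default: the first scanned trait).
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot.dqtl_scan <- function(x, trait = NULL, ...) {
  if (is.null(trait)) trait <- x$scan$trait[1]
  s <- x$scan[x$scan$trait == trait, ]
  chroms <- unique(x$bins$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(ch)
    max(x$bins$end[x$bins$chrom == ch]), numeric(1))))
  names(offs) <- c(chroms, "end")
  pos <- (x$bins$start + x$bins$end) / 2 + offs[x$bins$chrom]
  y <- -log10(pmax(s$p_adj, 1e-300))
  ci <- match(x$bins$chrom, chroms)
  graphics::plot(pos / 1e6, y, pch = 16, cex = 0.6,
                 col = c("grey25", "steelblue")[1 + ci %% 2],
                 xlab = "genomic position (Mb)",
                 ylab = expression(-log[10] ~ "adjusted p"),
                 main = sprintf("dQTL scan: %s", trait), ...)
  graphics::abline(h = -log10(x$alpha), col = "red", lty = 2)
  invisible(data.frame(pos = pos, neglog10_p_adj = y))
}
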