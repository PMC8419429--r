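#' Segment the genome into bins at indel breakpoints
#'
#' Collects all indel start/end positions per chromosome, sorts and
#' deduplicates them, forms the half-open intervals between consecutive
#' breakpoints and keeps only intervals overlapped by at least one indel.
#' These bins are the genomic unit of the dosage scan: within a bin every
#' line's copy number is constant, because no indel boundary falls inside it.
#'
#' @param indels Data frame of indel events with columns `chrom`, `start`,
#'   `end` (bp, 0-based half-open), `line_id`, `kind` (`"INS"`/`"DEL"`),
#'   `ploidy`.
#' @param genome A [genome] object (or named vector of chromosome lengths).
#' @return A list with `bins` (data frame: `bin_id`, `chrom`, `start`,
#'   `end`, `n_indels`) and `coverage` (fraction of the genome covered by
#'   bins, in `[0, 1]`).
#' @examples
#' g <- genome(c(chr1 = 20))
#' ind <- data.frame(chrom = "chr1", start = c(2, 6), end = c(10, 14),
#'                   line_id = c("A", "B"), kind = c("DEL", "INS"), ploidy = 2)
#' segment_bins(ind, g)
#' @export
segment_bins <- function(indels, genome) {
  genome <- as_genome(genome)
  validate_indels(indels, genome)
  bins <- NULL
  for (chr in names(genome)) {
    ev <- indels[indels$chrom == chr, , drop = FALSE]
    if (nrow(ev) == 0L) next
    bp <- sort(unique(c(ev$start, ev$end)))
    s <- bp[-length(bp)]
    e <- bp[-1]
    # keep intervals overlapped by >= 1 indel; count overlapping indels
    n_ov <- vapply(seq_along(s), function(i)
      sum(ev$start <= s[i] & ev$end >= e[i]), integer(1))
    keep <- n_ov >= 1L
    if (!any(keep)) next
    bins <- rbind(bins, data.frame(
      chrom = chr, start = s[keep], end = e[keep], n_indels = n_ov[keep]))
  }
  if (is.null(bins)) {
    bins <- data.frame(bin_id = character(0), chrom = character(0),
                       start = numeric(0), end = numeric(0),
                       n_indels = integer(0))
    return(list(bins = bins, coverage = 0))
  }
  bins <- bins[order(match(bins$chrom, names(genome)), bins$start), ]
  bins <- data.frame(bin_id = sprintf("bin%04d", seq_len(nrow(bins))), bins,
                     row.names = NULL)
  list(bins = bins, coverage = sum(bins$end - bins$start) / sum(genome))
}

validate_indels <- function(indels, genome = NULL) {
  need <- c("chrom", "start", "end", "line_id", "kind", "ploidy")
  if (!all(need %in% names(indels)))
    stop("indel table must have columns: ", paste(need, collapse = ", "))
  if (nrow(indels) == 0L) return(invisible(indels))
  if (any(indels$start >= indels$end))
    stop("indel start must be < end")
  if (!all(indels$kind %in% c("INS", "DEL")))
    stop("indel kind must be 'INS' or 'DEL'")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(indels$chrom), names(genome))
    if (length(unknown))
      stop("indels on unknown chromosome(s): ", paste(unknown, collapse = ", "))
    len <- unclass(genome)[indels$chrom]
    if (any(indels$end > len))
      stop("indel extends beyond its chromosome")
    if (any(indels$start < 0))
      stop("indel start must be >= 0")
  }
  invisible(indels)
}

#' Relative dosage score matrix
#'
#' For each line and bin, the copy number is the background ploidy plus the
#' number of insertions minus the number of deletions that line carries over
#' the bin; the relative dosage score (RDS) is copy number divided by
#' ploidy. For a diploid line carrying single-copy indels this gives 0.5
#' (deletion), 1.0 (unchanged) or 1.5 (insertion). Lines listed in `lines`
#' but absent from the indel table are dosage-normal controls (RDS 1
#' everywhere).
#'
#' Bins must come from [segment_bins()] on the same indel set, which
#' guarantees each indel either fully covers or misses each bin; a partial
#' overlap is rejected as inconsistent input.
#'
#' @param indels Indel data frame (see [segment_bins()]).
#' @param bins Bin data frame from [segment_bins()].
#' @param lines Optional character vector of line ids to include (rows of
#'   the matrix). Defaults to the lines present in `indels`.
#' @param ploidy Default background ploidy for lines without indel records.
#' @return Numeric matrix, lines x bins, with `dimnames` set.
#' @export
dosage_matrix <- function(indels, bins, lines = NULL, ploidy = 2) {
  if (is.null(lines)) lines <- sort(unique(indels$line_id))
  lines <- as.character(lines)
  m <- matrix(1, nrow = length(lines), ncol = nrow(bins),
              dimnames = list(lines, bins$bin_id))
  if (nrow(indels) > 0L) {
    pl <- tapply(indels$ploidy, indels$line_id, function(p) p[1])
    for (i in seq_len(nrow(indels))) {
      ev <- indels[i, ]
      if (!ev$line_id %in% lines) next
      j <- which(bins$chrom == ev$chrom & bins$start < ev$end & bins$end > ev$start)
      if (length(j)) {
        partial <- bins$start[j] < ev$start | bins$end[j] > ev$end
        if (any(partial))
          stop("bin partially overlapped by an indel; bins must be derived from the same indel set")
        m[ev$line_id, j] <- m[ev$line_id, j] +
          (if (ev$kind == "INS") 1 else -1) / ev$ploidy
      }
    }
    neg <- m < 0
    if (any(neg)) {
      warning(sprintf("%d line-bin copy numbers below 0; floored at 0", sum(neg)))
      m[neg] <- 0
    }
  }
  m
}

#' Kendall tau-b association with tie-corrected normal p-value
#'
#' Tie-corrected Kendall rank correlation between a dosage vector (heavily
#' tied: most lines are dosage-normal at any bin) and a trait. The tau-b
#' denominator corrects for ties in both variables; the two-sided p-value
#' uses the normal approximation with the tie-adjusted variance of the
#' concordance statistic S, appropriate at population sizes of hundreds of
#' lines where exact enumeration is impractical.
#'
#' Pair counting is done group-wise over the distinct values of `x` (O(k^2)
#' group pairs with sorted-vector counting), which is fast when `x` takes
#' few values, as relative dosage scores do.
#'
#' @param x,y Paired numeric vectors, `length >= 3`; `x` must take at least
#'   two distinct values.
#' @return A list with `tau` (tau-b), `p` (two-sided), `S` (concordant minus
#'   discordant pairs) and `n`.
#' @examples
#' kendall_tau(c(1, 2, 3), c(10, 20, 30))$tau  # 1
#' @export
kendall_tau <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L) stop("x is constant; tau undefined")
  ux <- sort(unique(x))
  idx <- split(seq_len(n), match(x, ux))
  k <- length(ux)
  S <- 0
  for (a in seq_len(k - 1L)) {
    ya <- y[idx[[a]]]
    for (b in (a + 1L):k) {
      yb <- sort(y[idx[[b]]])
      nless <- sum(findInterval(ya, yb, left.open = TRUE))   # y_b < y_a
      nleq <- sum(findInterval(ya, yb))                      # y_b <= y_a
      ngreater <- length(ya) * length(yb) - nleq
      S <- S + (ngreater - nless)
    }
  }
  tx <- lengths(idx)
  ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) stop("degenerate tie structure; tau undefined")
  tau <- S / denom
  # tie-adjusted variance of S (normal approximation)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  p <- if (varS <= 0) 1 else 2 * stats::pnorm(-abs(S) / sqrt(varS))
  list(tau = tau, p = min(p, 1), S = S, n = n)
}

#' Effective number of independent bins
#'
#' Contiguous bins are spanned by the same indels, so their dosage columns
#' are strongly correlated and a plain Bonferroni correction over all bins
#' would be far too severe. The effective count is obtained by hierarchical
#' clustering of the bin-bin dosage correlation structure: pairwise Pearson
#' correlation r between RDS columns, dissimilarity `1 - r` (signed, since
#' insertions and deletions make dosage correlations naturally signed),
#' average linkage, tree cut at `cutoff`. Bins with constant dosage across
#' lines have no defined correlation and form their own singleton clusters.
#'
#' @param dosage Lines x bins RDS matrix from [dosage_matrix()].
#' @param cutoff Dissimilarity height at which branches are merged
#'   (default 0.7).
#' @return A list with `n_eff` (number of clusters), `labels` (integer
#'   cluster label per bin, named) and `cutoff`.
#' @export
effective_bin_count <- function(dosage, cutoff = 0.7) {
  if (is.null(dim(dosage)) || ncol(dosage) < 1L) stop("need at least one bin")
  if (nrow(dosage) < 2L) stop("need at least two lines")
  sds <- apply(dosage, 2, stats::sd)
  const <- sds == 0
  labels <- integer(ncol(dosage))
  names(labels) <- colnames(dosage)
  nv <- sum(!const)
  if (nv == 0L) {
    labels[] <- seq_len(ncol(dosage))
    return(list(n_eff = ncol(dosage), labels = labels, cutoff = cutoff))
  }
  if (nv == 1L) {
    labels[!const] <- 1L
  } else {
    r <- stats::cor(dosage[, !const, drop = FALSE])
    d <- stats::as.dist(1 - r)
    hc <- stats::hclust(d, method = "average")
    labels[!const] <- stats::cutree(hc, h = cutoff)
  }
  if (any(const))
    labels[const] <- max(labels[!const]) + seq_len(sum(const))
  list(n_eff = length(unique(labels)), labels = labels, cutoff = cutoff)
}

#' Modified Bonferroni adjustment by effective bin count
#'
#' Multiplies raw per-bin p-values by the effective number of independent
#' bins and caps at 1. Order-preserving.
#'
#' @param p Raw p-values.
#' @param n_eff Effective number of independent bins (>= 1).
#' @return Adjusted p-values, same length as `p`.
#' @examples
#' adjust_p(0.001, 40)  # 0.04
#' @export
adjust_p <- function(p, n_eff) {
  if (length(n_eff) != 1L || is.na(n_eff) || n_eff < 1)
    stop("n_eff must be a single value >= 1")
  pmin(1, p * n_eff)
}

#' Merge significant bins into dQTL regions
#'
#' Flags bins with adjusted p below `alpha` and merges flagged bins that are
#' consecutive in the sorted bin list on the same chromosome into candidate
#' dQTL regions. Each region reports its genomic span, member bins, minimum
#' adjusted p and a representative bin (minimum adjusted p, ties broken by
#' smaller start).
#'
#' @param scan Data frame aligned with `bins`, with columns `bin_id` and
#'   `p_adj` (and optionally `tau`).
#' @param bins Bin data frame from [segment_bins()].
#' @param alpha Significance threshold on adjusted p (default 0.05).
#' @return Data frame with one row per region: `chrom`, `start`, `end`,
#'   `n_bins`, `bin_ids` (comma-separated), `top_bin`, `min_p_adj`. Zero
#'   rows when nothing is significant.
#' @export
call_regions <- function(scan, bins, alpha = 0.05) {
  stopifnot(nrow(scan) == nrow(bins), all(scan$bin_id == bins$bin_id))
  sig <- !is.na(scan$p_adj) & scan$p_adj < alpha
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_bins = integer(0),
                      bin_ids = character(0), top_bin = character(0),
                      min_p_adj = numeric(0))
  if (!any(sig)) return(empty)
  idx <- which(sig)
  new_region <- c(TRUE, diff(idx) != 1L | bins$chrom[idx[-1]] != bins$chrom[idx[-length(idx)]])
  grp <- cumsum(new_region)
  out <- lapply(split(idx, grp), function(ii) {
    p <- scan$p_adj[ii]
    top <- ii[order(p, bins$start[ii])][1]
    data.frame(chrom = bins$chrom[ii[1]],
               start = min(bins$start[ii]), end = max(bins$end[ii]),
               n_bins = length(ii),
               bin_ids = paste(bins$bin_id[ii], collapse = ","),
               top_bin = bins$bin_id[top],
               min_p_adj = min(p))
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

#' Percent trait variance explained by dQTL regions
#'
#' Fits a multiple linear regression of the (genotype-mean) trait on the
#' dosage of one representative bin per region and reports the adjusted
#' R-squared as a percentage, floored at 0. Collinear representative bins
#' are dropped to an independent subset with a warning.
#'
#' @param y Named vector of genotype-mean trait values (names = line ids).
#' @param dosage Lines x bins RDS matrix.
#' @param regions Region data frame from [call_regions()] (uses `top_bin`).
#' @return Percent of variance explained (scalar in `[0, 100]`); `NA` if
#'   `regions` is empty.
#' @export
variance_explained <- function(y, dosage, regions) {
  if (is.null(nrow(regions)) || nrow(regions) == 0L) return(NA_real_)
  lines <- intersect(names(y), rownames(dosage))
  X <- dosage[lines, regions$top_bin, drop = FALSE]
  yy <- y[lines]
  keep <- qr(cbind(1, X))$rank - 1L
  if (keep < ncol(X)) {
    piv <- qr(cbind(1, X))$pivot
    sel <- sort(piv[piv > 1][seq_len(keep)] - 1L)
    warning("collinear representative bins dropped from variance-explained model")
    X <- X[, sel, drop = FALSE]
  }
  if (length(yy) <= ncol(X) + 1L)
    stop("need more lines than regressors + 1")
  fit <- stats::lm(yy ~ X)
  max(0, summary(fit)$adj.r.squared) * 100
}
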