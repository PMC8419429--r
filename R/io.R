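#' Read and write the pipeline's plain-text formats
#'
#' Tab-separated formats with fixed column contracts. All coordinates are
#' 0-based half-open integers and round-trip exactly. Malformed rows are
#' reported with their line numbers.
#'
#' * indels: `chrom, start, end, line_id, kind (INS/DEL), ploidy`
#' * traits: `line_id, ramet_id,` one column per trait
#' * vessels: `section_id, vessel_id, x_um, y_um, area_um2, perimeter_um`
#' * sections: `section_id, xylem_area_mm2, bark_thickness_um`
#' * bins: BED (`chrom, start, end, bin_id`), no header
#' * dosage: lines x bins matrix, first column `line_id`
#' * scan: `trait, bin_id, tau, p, p_adj, significant`
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return data frames (or a matrix for dosage); writers
#'   return `invisible(path)`.
#' @name dosetra-io
NULL

read_tsv_checked <- function(path, cols, numeric_cols, what) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!identical(names(df)[seq_along(cols)], cols))
    stop(sprintf("%s: expected columns %s", what, paste(cols, collapse = ", ")))
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & !(df[[cc]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("%s: non-numeric '%s' at line %d", what, cc, bad[1] + 1L))
    df[[cc]] <- v
  }
  df
}

#' @rdname dosetra-io
#' @export
read_indels <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "line_id", "kind",
                                 "ploidy"),
                         c("start", "end", "ploidy"), "indel table")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("indel table: start >= end at line %d", bad[1] + 1L))
  if (!all(df$kind %in% c("INS", "DEL")))
    stop("indel table: kind must be INS or DEL")
  df
}

#' @rdname dosetra-io
#' @export
write_indels <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "line_id", "kind", "ploidy") %in%
                  names(x)))
  out <- x[c("chrom", "start", "end", "line_id", "kind", "ploidy")]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dosetra-io
#' @export
read_traits <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("line_id", "ramet_id") %in% names(df)))
    stop("trait table: needs line_id and ramet_id columns")
  df$line_id <- as.character(df$line_id)
  df
}

#' @rdname dosetra-io
#' @export
write_traits <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dosetra-io
#' @export
read_vessels <- function(path) {
  read_tsv_checked(path, c("section_id", "vessel_id", "x_um", "y_um",
                           "area_um2", "perimeter_um"),
                   c("x_um", "y_um", "area_um2", "perimeter_um"),
                   "vessel table")
}

#' @rdname dosetra-io
#' @export
write_vessels <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dosetra-io
#' @export
read_sections <- function(path) {
  read_tsv_checked(path, c("section_id", "xylem_area_mm2"),
                   c("xylem_area_mm2", "bark_thickness_um"), "section table")
}

#' @rdname dosetra-io
#' @export
write_sections <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dosetra-io
#' @export
write_bins_bed <- function(x, path) {
  out <- data.frame(chrom = x$chrom,
                    start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE),
                    name = x$bin_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname dosetra-io
#' @export
read_bins_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "bin_id"))
  data.frame(bin_id = df$bin_id, chrom = df$chrom,
             start = df$start, end = df$end)
}

#' @rdname dosetra-io
#' @export
write_dosage <- function(x, path) {
  df <- data.frame(line_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dosetra-io
#' @export
read_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$line_id
  m
}

#' @rdname dosetra-io
#' @export
write_ground_truth <- function(x, path) {
  stopifnot(inherits(x, "ground_truth"))
  out <- list(
    lines = x$lines, lesion_lines = x$lesion_lines,
    h2 = as.list(x$h2),
    allometry = lapply(seq_len(nrow(x$allometry)), function(i)
      as.list(x$allometry[i, ])),
    planted = if (is.null(x$planted)) list() else
      lapply(seq_len(nrow(x$planted)), function(i) as.list(x$planted[i, ]))
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
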