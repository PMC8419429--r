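#' Define a genome as a set of named chromosome lengths
#'
#' A minimal genome description used for bin segmentation and simulation:
#' chromosome names and their lengths in base pairs. All genomic coordinates
#' in this package are 0-based, half-open `[start, end)`.
#'
#' @param chrom_lengths Numeric vector of chromosome lengths in bp, with
#'   unique names. Lengths must be positive.
#' @return An object of class `"genome"`: a named numeric vector of lengths
#'   with the total genome size retrievable via `sum()`.
#' @examples
#' g <- genome(c(chr01 = 5e7, chr02 = 3e7))
#' sum(g)
#' @export
genome <- function(chrom_lengths) {
  if (length(chrom_lengths) == 0L)
    stop("genome must contain at least one chromosome")
  nm <- names(chrom_lengths)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(nm))
    stop("chromosome names must be unique")
  len <- as.numeric(chrom_lengths)
  if (anyNA(len) || any(len <= 0))
    stop("chromosome lengths must be positive")
  structure(stats::setNames(len, nm), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d chromosomes, %.1f Mb total\n",
              length(x), sum(x) / 1e6))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Default Populus-like genome
#'
#' Nineteen chromosomes with lengths close to the published *Populus
#' trichocarpa* assembly (v3), totalling about 390 Mb. Used as the default
#' genome for simulated irradiation-hybrid populations.
#'
#' @return A [genome] object with 19 chromosomes.
#' @export
populus_genome <- function() {
  lengths <- c(50.5, 25.3, 25.0, 24.3, 25.9, 27.9, 15.6, 19.5, 12.9, 22.6,
               18.5, 15.8, 16.1, 18.9, 15.3, 14.5, 16.1, 16.7, 15.9) * 1e6
  genome(stats::setNames(lengths, sprintf("chr%02d", 1:19)))
}

as_genome <- function(x) {
  if (inherits(x, "genome")) return(x)
  genome(x)
}
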