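# Independent brute-force oracles used across tests.

# Kendall tau-b by exhaustive pair enumeration (O(n^2) double loop).
oracle_tau <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  S / sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
}

# Base-resolution union of indel intervals: total covered length.
oracle_covered_length <- function(indels, genome) {
  tot <- 0
  for (chr in names(genome)) {
    ev <- indels[indels$chrom == chr, , drop = FALSE]
    if (nrow(ev) == 0) next
    covered <- logical(unclass(genome)[[chr]])
    for (i in seq_len(nrow(ev)))
      covered[(ev$start[i] + 1):ev$end[i]] <- TRUE
    tot <- tot + sum(covered)
  }
  tot
}

# Connected components of the contact relation by naive union-find.
oracle_groups <- function(vessels, tolerance = 1) {
  n <- nrow(vessels)
  r <- sqrt(vessels$area_um2 / pi)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((vessels$x_um[i] - vessels$x_um[j])^2 +
                (vessels$y_um[i] - vessels$y_um[j])^2)
    if (d <= r[i] + r[j] + tolerance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Two partitions (label vectors) describe the same grouping?
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# RDS of one line at one base position, counting indels directly.
oracle_rds_at <- function(indels, line, chrom, pos, ploidy = 2) {
  ev <- indels[indels$line_id == line & indels$chrom == chrom &
                 indels$start <= pos & indels$end > pos, , drop = FALSE]
  (ploidy + sum(ev$kind == "INS") - sum(ev$kind == "DEL")) / ploidy
}

# small genome for unit tests
tiny_genome <- function() genome(c(chrA = 2000, chrB = 1500, chrC = 900))

random_indels <- function(n, genome, lines = sprintf("L%02d", 1:10)) {
  chr <- sample(names(genome), n, replace = TRUE)
  len <- unclass(genome)[chr]
  start <- floor(runif(n, 0, len * 0.8))
  end <- pmin(len, start + ceiling(runif(n, 1, len * 0.4)))
  data.frame(chrom = chr, start = start, end = end,
             line_id = sample(lines, n, replace = TRUE),
             kind = sample(c("INS", "DEL"), n, replace = TRUE),
             ploidy = rep(2, n))
}
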