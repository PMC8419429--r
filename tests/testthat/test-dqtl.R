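test_that("bin segmentation reproduces the hand-worked example", {
  g <- genome(c(chr1 = 20))
  ind <- data.frame(chrom = "chr1", start = c(2, 6), end = c(10, 14),
                    line_id = c("A", "B"), kind = c("DEL", "INS"), ploidy = 2)
  seg <- segment_bins(ind, g)
  expect_equal(seg$bins$start, c(2, 6, 10))
  expect_equal(seg$bins$end, c(6, 10, 14))
  expect_equal(seg$bins$n_indels, c(1L, 2L, 1L))
  expect_equal(seg$coverage, 0.6)
})

test_that("no indels give zero bins and zero coverage", {
  seg <- segment_bins(random_indels(0, tiny_genome())[0, ], tiny_genome())
  expect_equal(nrow(seg$bins), 0L)
  expect_equal(seg$coverage, 0)
})

test_that("kept bin length equals a base-resolution union oracle", {
  set.seed(99)
  g <- tiny_genome()
  for (rep in 1:100) {
    ind <- random_indels(sample(1:200, 1), g)
    seg <- segment_bins(ind, g)
    expect_equal(sum(seg$bins$end - seg$bins$start),
                 oracle_covered_length(ind, g))
    # bins are disjoint, sorted, each overlapped by >= 1 indel
    for (chr in unique(seg$bins$chrom)) {
      b <- seg$bins[seg$bins$chrom == chr, ]
      expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    }
    expect_true(all(seg$bins$n_indels >= 1))
  }
})

test_that("indels outside the genome are rejected", {
  g <- tiny_genome()
  bad <- data.frame(chrom = "chrZ", start = 1, end = 5, line_id = "A",
                    kind = "DEL", ploidy = 2)
  expect_error(segment_bins(bad, g), "unknown chromosome")
  bad2 <- data.frame(chrom = "chrA", start = 10, end = 99999, line_id = "A",
                     kind = "DEL", ploidy = 2)
  expect_error(segment_bins(bad2, g), "beyond")
})

test_that("dosage matrix encodes deletions, insertions and controls", {
  g <- genome(c(chr1 = 100))
  ind <- data.frame(chrom = "chr1", start = c(10, 40), end = c(30, 70),
                    line_id = c("A", "B"), kind = c("DEL", "INS"),
                    ploidy = c(2, 2))
  seg <- segment_bins(ind, g)
  # interval [30, 40) is overlapped by nothing and is not a bin
  expect_equal(seg$bins$start, c(10, 40))
  m <- dosage_matrix(ind, seg$bins, lines = c("A", "B", "CTRL"))
  expect_equal(unname(m["A", ]), c(0.5, 1))
  expect_equal(unname(m["B", ]), c(1, 1.5))
  expect_equal(unname(m["CTRL", ]), c(1, 1))
  # triploid single-copy deletion -> 2/3
  ind3 <- data.frame(chrom = "chr1", start = 10, end = 30, line_id = "T",
                     kind = "DEL", ploidy = 3)
  m3 <- dosage_matrix(ind3, segment_bins(ind3, g)$bins)
  expect_equal(unname(m3["T", 1]), 2 / 3)
})

test_that("partial bin overlap is rejected as inconsistent input", {
  g <- genome(c(chr1 = 100))
  ind <- data.frame(chrom = "chr1", start = 10, end = 30, line_id = "A",
                    kind = "DEL", ploidy = 2)
  bins <- data.frame(bin_id = "b1", chrom = "chr1", start = 5, end = 20,
                     n_indels = 1L)
  expect_error(dosage_matrix(ind, bins), "partially overlapped")
})

test_that("every line-bin RDS agrees with a per-base midpoint oracle", {
  set.seed(5)
  g <- tiny_genome()
  ind <- random_indels(60, g)
  # drop same-line overlaps to keep copy number well defined per indel count
  seg <- segment_bins(ind, g)
  lines <- sprintf("L%02d", 1:10)
  m <- suppressWarnings(dosage_matrix(ind, seg$bins, lines = lines))
  mid <- floor((seg$bins$start + seg$bins$end) / 2)
  for (ln in lines) for (j in seq_len(nrow(seg$bins))) {
    expect_equal(unname(m[ln, j]),
                 max(0, oracle_rds_at(ind, ln, seg$bins$chrom[j], mid[j])))
  }
})

test_that("kendall tau-b equals exhaustive pair counting and cor.test", {
  expect_equal(kendall_tau(1:3, c(10, 20, 30))$tau, 1)
  kt <- kendall_tau(c(0.5, 0.5, 1, 1, 1.5), c(5, 1, 4, 2, 3))
  expect_equal(kt$tau, oracle_tau(c(0.5, 0.5, 1, 1, 1.5), c(5, 1, 4, 2, 3)))
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(4:60, 1)
    x <- sample(c(0.5, 1, 1.5), n, replace = TRUE)
    if (length(unique(x)) < 2) next
    y <- round(rnorm(n), sample(0:2, 1))
    kt <- kendall_tau(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                           exact = FALSE))
    expect_equal(kt$tau, unname(ct$estimate))
    expect_equal(kt$p, ct$p.value, tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("raw tau p-values are approximately uniform under the null", {
  set.seed(31)
  p <- replicate(600, {
    x <- sample(c(0.5, 1, 1.5), 200, replace = TRUE, prob = c(.15, .7, .15))
    kendall_tau(x, rnorm(200))$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("effective bin count reflects the correlation block structure", {
  set.seed(2)
  # two identical columns -> one effective bin
  x <- rnorm(30)
  expect_equal(effective_bin_count(cbind(a = x, b = x))$n_eff, 1L)
  # two blocks of 5 identical columns, independent between blocks -> 2
  b1 <- rnorm(40); b2 <- rnorm(40)
  m <- cbind(b1, b1, b1, b1, b1, b2, b2, b2, b2, b2)
  expect_equal(effective_bin_count(m)$n_eff, 2L)
  # independent random columns -> as many clusters as bins (20 seeds)
  ok <- vapply(1:20, function(s) {
    set.seed(s)
    mm <- matrix(rnorm(200 * 8), 200, 8, dimnames = list(NULL, letters[1:8]))
    effective_bin_count(mm)$n_eff == 8L
  }, logical(1))
  expect_true(all(ok))
  # constant columns become singleton clusters
  m2 <- cbind(x1 = x, x2 = x, cst = rep(1, 30))
  eff <- effective_bin_count(m2)
  expect_equal(eff$n_eff, 2L)
  expect_error(effective_bin_count(m2[1, , drop = FALSE]), "two lines")
})

test_that("modified Bonferroni adjustment is capped and order preserving", {
  expect_equal(adjust_p(0.001, 40), 0.04)
  expect_equal(adjust_p(0.5, 40), 1)
  p <- runif(20)
  expect_equal(adjust_p(p, 1), p)
  expect_equal(order(adjust_p(sort(p), 7)), 1:20)
  expect_error(adjust_p(0.1, 0), "n_eff")
})

test_that("adjacent significant bins merge into regions", {
  bins <- data.frame(bin_id = sprintf("b%02d", 1:12),
                     chrom = rep("chr1", 12),
                     start = (0:11) * 10, end = (1:12) * 10,
                     n_indels = 1L)
  p_adj <- rep(1, 12)
  p_adj[c(4, 5, 6, 10)] <- c(0.01, 0.002, 0.03, 0.04)
  scan <- data.frame(bin_id = bins$bin_id, p_adj = p_adj)
  rg <- call_regions(scan, bins, alpha = 0.05)
  expect_equal(nrow(rg), 2L)
  expect_equal(rg$n_bins, c(3L, 1L))
  expect_equal(rg$top_bin[1], "b05")
  expect_equal(rg$min_p_adj, c(0.002, 0.04))
  # nothing significant -> empty
  expect_equal(nrow(call_regions(data.frame(bin_id = bins$bin_id,
                                            p_adj = rep(1, 12)),
                                 bins)), 0L)
  # chromosome boundaries split runs even with consecutive indices
  bins2 <- bins; bins2$chrom[6:12] <- "chr2"
  rg2 <- call_regions(scan, bins2, alpha = 0.05)
  expect_equal(nrow(rg2), 3L)
})

test_that("variance explained is exact for perfect fits and ~0 under permutation", {
  set.seed(8)
  x <- sample(c(0.5, 1, 1.5), 200, replace = TRUE)
  names(x) <- sprintf("L%03d", 1:200)
  D <- matrix(x, ncol = 1, dimnames = list(names(x), "b1"))
  rg <- data.frame(top_bin = "b1")
  expect_equal(variance_explained(3 * x + 1, D, rg), 100)
  ve_null <- replicate(100, {
    yp <- sample(unname(3 * x + 1))
    names(yp) <- names(x)
    variance_explained(yp, D, rg)
  })
  expect_lt(mean(ve_null), 3)
  expect_true(all(ve_null >= 0))
  expect_true(is.na(variance_explained(x, D, rg[0, , drop = FALSE])))
})

test_that("collinear representative bins are dropped with a warning", {
  set.seed(9)
  x <- sample(c(0.5, 1, 1.5), 50, replace = TRUE)
  names(x) <- sprintf("L%02d", 1:50)
  D <- cbind(b1 = x, b2 = x)
  rownames(D) <- names(x)
  rg <- data.frame(top_bin = c("b1", "b2"))
  y <- 2 * x + rnorm(50, 0, 0.1); names(y) <- names(x)
  expect_warning(ve <- variance_explained(y, D, rg), "collinear")
  expect_gt(ve, 90)
})

test_that("the scan statistic is invariant to monotone trait transforms", {
  set.seed(14)
  x <- sample(c(0.5, 1, 1.5), 80, replace = TRUE)
  y <- rnorm(80, 10, 2)
  a <- kendall_tau(x, y)
  b <- kendall_tau(x, exp(y / 3))
  expect_equal(a$tau, b$tau)
  expect_equal(a$p, b$p)
})
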