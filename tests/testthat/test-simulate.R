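test_that("lesion line counts and seed determinism hold exactly", {
  g <- tiny_genome()
  cfg0 <- sim_config(n_lines = 10, frac_lesion_lines = 0, seed = 3,
                     indels = list(len_meanlog = log(200), min_len = 10))
  sim0 <- simulate_indel_population(g, cfg0)
  expect_equal(nrow(sim0$indels), 0L)
  expect_equal(length(sim0$truth$lines), 10L)
  cfg <- sim_config(n_lines = 31, frac_lesion_lines = 20 / 31, seed = 7,
                    indels = list(len_meanlog = log(200), min_len = 10))
  a <- simulate_indel_population(g, cfg)
  b <- simulate_indel_population(g, cfg)
  expect_identical(a$indels, b$indels)
  expect_equal(length(a$truth$lesion_lines), 20L)
  expect_setequal(unique(a$indels$line_id), a$truth$lesion_lines)
  # indels lie within chromosome bounds
  expect_true(all(a$indels$start >= 0))
  expect_true(all(a$indels$end <= unclass(g)[a$indels$chrom]))
  ta <- simulate_traits(a$indels, a$truth, cfg)
  tb <- simulate_traits(b$indels, b$truth, cfg)
  expect_identical(ta, tb)
})

test_that("infeasible indel configurations are rejected", {
  g <- genome(c(c1 = 100))
  cfg <- sim_config(n_lines = 4, frac_lesion_lines = 1, seed = 1,
                    indels = list(min_len = 1000))
  expect_error(simulate_indel_population(g, cfg), "reject")
})

test_that("study-shaped populations give published-scale bin structure", {
  g <- populus_genome()
  stats <- sapply(1:20, function(s) {
    sim <- simulate_indel_population(g, sim_config(seed = s))
    seg <- segment_bins(sim$indels, g)
    c(nbin = nrow(seg$bins), ov = mean(seg$bins$n_indels), cov = seg$coverage)
  })
  expect_gt(mean(stats["nbin", ]), 469 / 2)
  expect_lt(mean(stats["nbin", ]), 469 * 2)
  expect_gt(mean(stats["ov", ]), 3)
  expect_lt(mean(stats["ov", ]), 12)
  expect_gt(mean(stats["cov", ]), 0.85)
})

test_that("zero environmental noise makes clone ramets identical", {
  cfg <- sim_config(n_lines = 12, seed = 5, height = list(h2 = 1),
                    traits = list(
                      MVD = list(mean = 26, b = 0.25, V_g = 2, V_e = 0),
                      VF = list(mean = 365, b = -0.8, V_g = 100, V_e = 0),
                      VGI = list(mean = 1.47, b = 0, V_g = 0.005, V_e = 0),
                      MVC = list(mean = 0.78, b = 0, V_g = 5e-4, V_e = 0),
                      NF = list(mean = 0.8, b = 0, V_g = 8e-4, V_e = 0),
                      BT = list(mean = 608, b = 0.6, V_g = 1e4, V_e = 0)))
  pop <- simulate_population(config = cfg)
  sp <- split(pop$traits[-(1:2)], pop$traits$line_id)
  for (tab in sp)
    expect_equal(unname(as.matrix(tab)),
                 unname(as.matrix(tab))[rep(1, nrow(tab)), ])
})

test_that("planted effects shift traits by effect * (RDS - 1) exactly", {
  g <- genome(c(c1 = 1e6))
  pe <- data.frame(chrom = "c1", pos = 5e5, trait = "MVD", effect = 4)
  cfg <- sim_config(n_lines = 30, frac_lesion_lines = 0.5, seed = 11,
                    indels = list(mean_count = 1, len_meanlog = log(7e5),
                                  len_sdlog = 0.01, min_len = 1e5),
                    height = list(h2 = 1, sd = 0, lesion_penalty = 1),
                    traits = list(MVD = list(mean = 26, b = 0, V_g = 0,
                                             V_e = 0)),
                    planted_effects = pe)
  sim <- simulate_indel_population(g, cfg)
  tr <- simulate_traits(sim$indels, sim$truth, cfg)
  rds <- rds_at(sim$indels, sim$truth$lines, "c1", 5e5)
  expect_equal(unname(tr$MVD), unname(26 + 4 * (rds[tr$line_id] - 1)))
  # deleted lines sit exactly 2 um below controls, inserted 2 um above
  expect_true(all(tr$MVD[rds[tr$line_id] == 0.5] == 24))
  expect_true(all(tr$MVD[rds[tr$line_id] == 1.5] == 28))
})

test_that("one-sided planted effects leave the insertion side untouched", {
  g <- genome(c(c1 = 1e6))
  pe <- data.frame(chrom = "c1", pos = 5e5, trait = "MVD", effect = 4,
                   side = "del_only")
  cfg <- sim_config(n_lines = 40, frac_lesion_lines = 0.8, seed = 13,
                    indels = list(mean_count = 1, len_meanlog = log(7e5),
                                  len_sdlog = 0.01, min_len = 1e5),
                    height = list(h2 = 1, sd = 0, lesion_penalty = 1),
                    traits = list(MVD = list(mean = 26, b = 0, V_g = 0,
                                             V_e = 0)),
                    planted_effects = pe)
  sim <- simulate_indel_population(g, cfg)
  tr <- simulate_traits(sim$indels, sim$truth, cfg)
  rds <- rds_at(sim$indels, sim$truth$lines, "c1", 5e5)[tr$line_id]
  expect_true(all(tr$MVD[rds >= 1] == 26))
  expect_true(all(tr$MVD[rds == 0.5] == 24))
})

test_that("simulated heights and allometric correlations match the model", {
  cors <- sapply(1:20, function(s) {
    pop <- simulate_population(config = sim_config(seed = s))
    c(mvd = cor(pop$traits$TH, pop$traits$MVD),
      vf = cor(pop$traits$TH, pop$traits$VF),
      th_mean = mean(pop$traits$TH), th_sd = sd(pop$traits$TH))
  })
  cfg <- sim_config()
  expect_equal(expected_th_correlation(cfg, "MVD"), 0.76, tolerance = 1e-6)
  expect_gt(mean(cors["mvd", ]), 0.66)
  expect_lt(mean(cors["mvd", ]), 0.86)
  expect_lt(abs(mean(cors["mvd", ]) - 0.76), 0.06)
  expect_lt(abs(mean(cors["vf", ]) - (-0.78)), 0.06)
  expect_lt(abs(mean(cors["th_mean", ]) - 64), 6)
  expect_lt(abs(mean(cors["th_sd", ]) - 32), 8)
})

test_that("lesion lines are shorter on average than controls", {
  set.seed(2)
  diffs <- sapply(1:5, function(s) {
    pop <- simulate_population(config = sim_config(seed = s + 100))
    m <- tapply(pop$traits$TH, pop$traits$line_id, mean)
    lesion <- names(m) %in% pop$truth$lesion_lines
    mean(m[!lesion]) - mean(m[lesion])
  })
  expect_gt(mean(diffs), 5)
})

test_that("simulated ANOVA heritability recovers the configured value", {
  # variance accounting: b = 0, no planted effects
  est <- sapply(1:100, function(s) {
    cfg <- sim_config(n_lines = 100, frac_lesion_lines = 0, seed = s,
                      traits = list(MVD = list(mean = 26, b = 0,
                                               V_g = 8, V_e = 8)))
    pop <- simulate_population(genome = tiny_genome(), config = cfg)
    repeatability(pop$traits$MVD, pop$traits$line_id)$H2
  })
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("cross sections respect clustering, packing and shape contracts", {
  # clustering 0: all solitary -> VGI exactly 1
  cs <- simulate_cross_section(60, clustering = 0, xylem_area_mm2 = 0.5,
                               seed = 21)
  s <- summarize_section(cs$vessels, cs$section$xylem_area_mm2)
  expect_equal(s$VGI, 1)
  # two touching pairs -> VGI 2
  cs2 <- simulate_cross_section(4, clustering = 1, max_group_size = 2,
                                xylem_area_mm2 = 0.1, seed = 22)
  s2 <- summarize_section(cs2$vessels, cs2$section$xylem_area_mm2)
  expect_equal(s2$VGI, 2)
  expect_equal(s2$n_groups, 2L)
  # isoperimetric bound holds for every emitted vessel
  expect_true(all(cs$vessels$perimeter_um >=
                    2 * sqrt(pi * cs$vessels$area_um2)))
  # determinism
  cs3 <- simulate_cross_section(60, clustering = 0, xylem_area_mm2 = 0.5,
                                seed = 21)
  expect_identical(cs, cs3)
  expect_error(simulate_cross_section(10000, diameter_mean = 100,
                                      xylem_area_mm2 = 0.05),
               "pack")
})

test_that("section population statistics land where configured", {
  cs <- simulate_cross_section(365, diameter_mean = 26, diameter_sd = 4,
                               xylem_area_mm2 = 1, seed = 30)
  s <- summarize_section(cs$vessels, 1)
  expect_equal(s$VF, 365)
  expect_lt(abs(s$MVD - 26), 3 * 4 / sqrt(365) + 0.2)
  expect_lt(s$MVC, 1)
  expect_gt(s$MVC, 0.9)
})
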