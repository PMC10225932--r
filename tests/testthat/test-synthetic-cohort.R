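test_that("simulators are deterministic given a seed", {
  cfg <- cohort_config(n_individuals = 200, seed = 9)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  ch <- simulate_cohort(cfg)
  map <- marker_map(2, 50)
  la1 <- simulate_local_ancestry(ch, map, g = 8, seed = 9)
  la2 <- simulate_local_ancestry(ch, map, g = 8, seed = 9)
  expect_identical(la1, la2)
  g1 <- simulate_genotypes(la1, 0.7, 0.2, seed = 9)
  expect_identical(g1, simulate_genotypes(la2, 0.7, 0.2, seed = 9))
  y1 <- simulate_copy_number(ch, seed = 9)
  expect_identical(y1, simulate_copy_number(ch, seed = 9))
  d1 <- simulate_depth(c(0, 0.5), seed = 9)
  d2 <- simulate_depth(c(0, 0.5), seed = 9)
  expect_identical(d1, d2)
})

test_that("cohort respects configured haplogroup and Duffy frequencies", {
  ch <- make_cohort(n = 10000, seed = 3)
  frac <- mean(ch$mt_origin == "African")
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(frac - 0.8), 3 * se)

  # fixed allele: fully African ancestry with a fixed null allele
  ch2 <- make_cohort(n = 200, seed = 3, ancestry_mean = 0.99,
                     ancestry_sd = 0.005,
                     duffy_freq_by_ancestry = c(african = 1, european = 0))
  # ancestry is ~1 but not exactly 1 under a Beta law; force the limit
  ch3 <- make_cohort(n = 500, seed = 4,
                     duffy_freq_by_ancestry = c(african = 1, european = 1))
  expect_true(all(ch3$duffy_genotype == 2))
  expect_true(all(ch2$duffy_genotype >= 0 & ch2$duffy_genotype <= 2))

  # invariants
  expect_true(all(ch$african_ancestry >= 0 & ch$african_ancestry <= 1))
  expect_true(all(ch$age > 0))
  cells <- c("neutrophils", "lymphocytes", "monocytes", "eosinophils",
             "basophils", "platelets")
  expect_true(all(as.matrix(ch[cells]) > 0))
  # origin labels consistent with the classification rule
  expect_identical(ch$mt_origin, classify_origin(ch$mt_haplogroup))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(cohort_config(n_individuals = 1), "n_individuals")
  expect_error(cohort_config(haplogroup_freq_african = 1.2),
               "haplogroup_freq_african")
  expect_error(cohort_config(ancestry_sd = 0.6), "ancestry_sd")
  expect_error(cohort_config(duffy_freq_by_ancestry = c(2, 0)),
               "duffy_freq_by_ancestry")
})

test_that("local ancestry tracts follow the map and ancestry fractions", {
  ch <- make_cohort(n = 100, seed = 5)
  map <- marker_map(1, 100, 1)

  # g = 0: no recombination, constant state per haplotype
  la0 <- simulate_local_ancestry(ch, map, g = 0, seed = 5)
  expect_true(all(apply(la0$hap1, 1, function(h) length(unique(h)) == 1)))

  # fully African cohort: every count is 2
  ch1 <- make_cohort(n = 50, seed = 6, ancestry_mean = 0.995,
                     ancestry_sd = 0.002)
  ch1$african_ancestry <- rep(1, nrow(ch1))
  la1 <- simulate_local_ancestry(ch1, map, g = 8, seed = 6)
  expect_true(all(la1$counts == 2))

  # haplotype states conserve the diploid count
  la <- simulate_local_ancestry(ch, map, g = 8, seed = 7)
  expect_true(all(la$hap1 %in% 0:1) && all(la$hap2 %in% 0:1))
  expect_identical(la$counts, la$hap1 + la$hap2)

  # law of large numbers over tracts: realized genome-wide ancestry is an
  # unbiased estimate of the stationary fraction, and its dispersion shrinks
  # as the genome (hence the tract count) grows
  map3 <- marker_map(3, 300, 1)
  la3 <- simulate_local_ancestry(ch, map3, g = 8, seed = 8)
  dev3 <- rowMeans(la3$counts / 2) - ch$african_ancestry
  expect_lt(abs(mean(dev3)), 0.05)
  map1 <- marker_map(1, 300, 1)
  la1b <- simulate_local_ancestry(ch, map1, g = 8, seed = 8)
  dev1 <- rowMeans(la1b$counts / 2) - ch$african_ancestry
  expect_lt(mean(abs(dev3)), mean(abs(dev1)))

  # unsorted map rejected
  bad <- map; bad$gpos[2] <- 2
  expect_error(simulate_local_ancestry(ch, bad, seed = 5), "sorted")
})

test_that("genotypes follow their local-ancestry background frequencies", {
  ch <- make_cohort(n = 2000, seed = 10)
  map <- marker_map(1, 40)
  la <- simulate_local_ancestry(ch, map, g = 8, seed = 10)

  # fixed difference: dosage equals the local African count
  g <- simulate_genotypes(la, 1, 0, seed = 10)
  expect_identical(g$dosage, la$counts)

  # realized frequency matches the ancestry-weighted mean
  g2 <- simulate_genotypes(la, 0.9, 0.1, seed = 11)
  w <- mean(la$counts / 2)
  expected <- 0.9 * w + 0.1 * (1 - w)
  se <- sqrt(expected * (1 - expected) / (2 * nrow(ch)))
  expect_lt(abs(mean(g2$freq) - expected), 3 * se * sqrt(ncol(g2$dosage)))

  # equal frequencies: dosage independent of local ancestry
  g3 <- simulate_genotypes(la, 0.5, 0.5, seed = 12)
  p <- suppressWarnings(
    chisq.test(table(g3$dosage[, 1], la$counts[, 1]))$p.value)
  expect_gt(p, 0.001)
})

test_that("copy-number simulation honors effects, noise, and heritability", {
  ch <- make_cohort(n = 4000, seed = 13)
  # all effects zero, unit noise
  y0 <- simulate_copy_number(ch, effect_spec = list(), noise_sd = 1,
                             seed = 13)
  expect_lt(abs(sd(y0) - 1), 3 / sqrt(2 * 4000))
  # default signs: neutrophils negative, platelets positive
  y <- simulate_copy_number(ch, seed = 13)
  expect_lt(cor(as.numeric(y), ch$neutrophils), 0)
  expect_gt(cor(as.numeric(y), ch$platelets), 0)
  # configuration errors
  expect_error(simulate_copy_number(ch, h2_target = 1.2), "h2_target")
  expect_error(simulate_copy_number(ch, effect_spec = list(nope = 1)),
               "unknown cohort column")
  # realized genetic variance fraction near the target
  g <- simulate_unlinked_genotypes(4000, 500, seed = 13)
  yh <- simulate_copy_number(ch, effect_spec = list(), h2_target = 0.3,
                             genotypes = g, noise_sd = 1, seed = 13)
  gv <- attr(yh, "genetic_value")
  expect_lt(abs(var(gv) / var(as.numeric(yh)) - 0.3), 0.03)
})

test_that("depth simulation has the configured Poisson means", {
  pr <- simulate_depth(rep(log(2), 30), autosomal_mean = 2.8,
                       spike_multiplier = 1, seed = 14)
  mt_mean <- mean(vapply(pr, function(p) mean(p$mt_depths), 1))
  auto_mean <- mean(vapply(pr, function(p) mean(p$auto_depths), 1))
  # closed form: mt mean = 2.8 * 2 = 5.6
  expect_lt(abs(mt_mean - 5.6), 3 * sqrt(5.6 / (30 * 16569)))
  expect_lt(abs(auto_mean - 2.8), 3 * sqrt(2.8 / (30 * 16569)))

  # lrmtcn = 0, no spike: the two means agree
  pr0 <- simulate_depth(rep(0, 30), seed = 15, spike_multiplier = 1)
  m <- vapply(pr0, function(p) mean(p$mt_depths) - mean(p$auto_depths), 1)
  expect_lt(abs(mean(m)), 3 * sqrt(2 * 2.8 / (30 * 16569)))

  expect_error(simulate_depth(0, autosomal_mean = -1), "autosomal_mean")
})

test_that("spike inflates the unmasked mean but not the masked one", {
  pr <- simulate_depth(rep(0, 40), autosomal_mean = 2.8,
                       spike_region = c(2500L, 3000L), spike_multiplier = 10,
                       seed = 16)
  raw <- estimate_rmtcn_cohort(pr, spike_region = NULL)
  masked <- estimate_rmtcn_cohort(pr, spike_region = c(2500L, 3000L))
  # expected inflation of the unmasked mean: 9 * 501/16569 ~ 27%
  expect_gt(mean(raw$rmtcn), 1.2)
  expect_lt(abs(mean(masked$lrmtcn)), 3 * sd(masked$lrmtcn) / sqrt(40))
})

test_that("phenotype simulation reproduces configured prevalences and effects", {
  ch <- make_cohort(n = 20000, seed = 17)
  null_trait <- trait_spec("t0", "binary", prevalence = 0.1)
  ph <- simulate_phenotypes(ch, NULL, list(null_trait), seed = 17)
  status <- assign_case_control(ph$phecodes)
  # case fraction among non-missing statuses: (0.1 * 0.95) / (0.1 * 0.95 +
  # 0.9 * 0.95) = prevalence, since both classes lose the same singleton share
  case_frac <- mean(status[, 1] == 1, na.rm = TRUE)
  expect_lt(abs(case_frac - 0.1), 3 * sqrt(0.1 * 0.9 / (20000 * 0.95)))

  # logistic recovery of a planted copy-number effect
  rl <- rnorm(20000)
  eff <- trait_spec("t1", "binary", prevalence = 0.2,
                    beta_rlrmtcn = log(2), singleton_frac = 0,
                    case_two_plus_prob = 1)
  ph2 <- simulate_phenotypes(ch, rl, list(eff), seed = 18)
  st2 <- assign_case_control(ph2$phecodes)
  rec <- fit_assoc(st2[, 1], rl, model = "logistic")
  expect_lt(abs(rec$beta - log(2)), 2 * rec$se)

  expect_error(trait_spec("bad", "binary", prevalence = 0),
               "prevalence")
})
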