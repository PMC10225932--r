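test_that("linear and logistic association fits recover planted effects", {
  set.seed(1)
  n <- 10000
  x <- rnorm(n)
  y <- 2 * x + rnorm(n)
  rec <- fit_assoc(y, x, model = "linear")
  expect_lt(abs(rec$beta - 2), 2 * rec$se)
  expect_equal(rec$n, n)
  # logistic
  yb <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  recb <- fit_assoc(yb, x, model = "logistic")
  expect_lt(abs(recb$beta - 0.5), 2 * recb$se)
  # covariates respected
  cvr <- cbind(c1 = rnorm(n))
  y2 <- 1.5 * x + 3 * cvr[, 1] + rnorm(n)
  rec2 <- fit_assoc(y2, x, covariates = cvr, model = "linear")
  expect_lt(abs(rec2$beta - 1.5), 2 * rec2$se)
  # degenerate design
  expect_error(fit_assoc(y, x, covariates = cbind(k = rep(1, n)), "linear"),
               "rank-deficient")
  # case-count refusal mirrors the phecode filter
  expect_error(fit_assoc(c(rep(0, 100), rep(1, 5)), rnorm(105),
                         model = "logistic"), "cases")
})

test_that("association p-values are uniform under the null", {
  set.seed(2)
  p <- replicate(400, {
    x <- rnorm(150)
    fit_assoc(rnorm(150), x, model = "linear")$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH discovery flags follow the step-up rule at nested levels", {
  fl <- bh_fdr(c(0.001, 0.2, 0.9), q = c(0.005, 0.05))
  expect_identical(fl$fdr_0.05, c(TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(rep(1, 5))$fdr_0.05, rep(FALSE, 5))
  expect_equal(nrow(bh_fdr(numeric(0))), 0)
  # step-up against p.adjust on random inputs, and nesting of the two levels
  set.seed(3)
  for (i in 1:10) {
    p <- runif(50)^2
    fl <- bh_fdr(p)
    expect_identical(fl$fdr_0.05, p.adjust(p, "BH") <= 0.05)
    expect_true(all(!fl$fdr_0.005 | fl$fdr_0.05))
  }
})

test_that("direction-consistency test equals brute-force binomial enumeration", {
  # independent oracle: two-sided mass of outcomes no more likely than k
  brute <- function(k, n) {
    mass <- dbinom(0:n, n, 0.5)
    sum(mass[mass <= mass[k + 1] + 1e-12])
  }
  for (n in c(1, 5, 8, 14, 25)) {
    for (k in unique(c(0, floor(n / 2), n))) {
      expect_equal(sign_consistency_test(k, n), brute(k, n),
                   tolerance = 1e-10)
    }
  }
})

test_that("replication power behaves like the noncentral chi-square construction", {
  # central case: power equals the test level
  expect_equal(replication_power(0, 0.3, 5000, alpha = 0.01), 0.01,
               tolerance = 1e-10)
  # monotone in n and |beta|
  ns <- seq(1000, 50000, length.out = 20)
  expect_true(all(diff(replication_power(0.05, 0.5, ns)) >= 0))
  bs <- seq(0, 0.2, 0.01)
  expect_true(all(diff(replication_power(bs, 0.5, 10000)) >= 0))
  expect_error(replication_power(0.1, 0, 1000), "frequency")
})

test_that("threshold arithmetic and variance explained are exact", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 110), 0.05 / 110)
  expect_equal(h2_explained(0.1, 0.5), 0.005)
  expect_equal(h2_explained(rep(0, 10), rep(0.3, 10)), 0)
  # simulated additive trait: explained variance matches the realized one
  set.seed(4)
  n <- 20000; m <- 30
  f <- runif(m, 0.1, 0.5)
  G <- matrix(rbinom(n * m, 2, rep(f, each = n)), n, m)
  b <- rnorm(m, 0, 0.05)
  gv <- as.numeric(G %*% b)
  y <- gv + rnorm(n, 0, sqrt(1 - var(gv)))
  y <- y / sd(y)
  betas <- vapply(seq_len(m), function(j) {
    fit_assoc(y, G[, j], model = "linear")$beta
  }, 1)
  expect_lt(abs(h2_explained(betas, colMeans(G) / 2) - var(gv)), 0.02)
})

test_that("polygenic scores are allele-oriented weighted dosage sums", {
  g <- list(dosage = cbind(v1 = c(0, 1, 2), v2 = c(2, 2, 0)),
            variants = data.frame(id = c("v1", "v2"), ref = c("A", "C"),
                                  alt = c("G", "T")))
  class(g) <- "genotype_matrix"
  w <- data.frame(id = "v1", effect_allele = "G", weight = 1)
  expect_equal(as.numeric(prs_score(g, w)), c(0, 1, 2))
  # allele-flip invariance: weight on the ref allele scores 2 - dosage
  w2 <- data.frame(id = c("v1", "v2"), effect_allele = c("G", "C"),
                   weight = c(0.5, -1))
  sc <- prs_score(g, w2)
  expect_equal(as.numeric(sc), 0.5 * c(0, 1, 2) - 1 * (2 - c(2, 2, 0)))
  # unmatched weights dropped with a message; zero matches is an error
  w3 <- rbind(w2, data.frame(id = "zz", effect_allele = "A", weight = 9))
  expect_message(sc3 <- prs_score(g, w3), "unmatched")
  expect_equal(as.numeric(sc3), as.numeric(sc))
  expect_error(quiet(prs_score(g, data.frame(id = "zz", effect_allele = "A",
                                             weight = 1))), "zero matched")
  # a trait simulated from the weights correlates with its score
  set.seed(5)
  gm <- simulate_unlinked_genotypes(10000, 50, seed = 5)
  gm$variants <- data.frame(id = paste0("var", 1:50), ref = "A", alt = "B")
  wts <- data.frame(id = gm$variants$id, effect_allele = "B",
                    weight = rnorm(50, 0, 0.1))
  sc <- prs_score(gm, wts)
  trait <- as.numeric(gm$dosage %*% wts$weight) + rnorm(10000)
  expect_gt(cor(sc, trait), 0.3)
})

test_that("distance clumping emits the smallest-p record per window", {
  recs <- data.frame(chrom = c(1, 1, 2, 1), pos = c(1e6, 1.5e6, 1e6, 5e6),
                     p = c(1e-4, 1e-6, 1e-3, 0.2))
  out <- clump_hits(recs, p_thresh = 0.05, window = 1e6)
  expect_equal(nrow(out), 2)        # two loci: chrom1 (smaller p), chrom2
  expect_equal(out$p[1], 1e-6)      # the 0.5 Mb neighbor absorbed
  expect_setequal(out$chrom, c(1, 2))
  expect_equal(nrow(clump_hits(recs, p_thresh = 1e-10)), 0)
})

test_that("effect-size correlation matches the attenuation closed form", {
  a <- data.frame(predictor_id = paste0("v", 1:2000), beta = rnorm(2000),
                  effect_allele = "A")
  expect_equal(effect_correlation(a, a)$r, 1)
  # adding independent noise of equal variance attenuates r to 1/sqrt(2)
  set.seed(6)
  b <- a; b$beta <- a$beta + rnorm(2000)
  r <- effect_correlation(a, b)$r
  expect_lt(abs(r - 1 / sqrt(2)), 0.04)
  # allele harmonization: flipped alleles with negated betas are equivalent
  b2 <- b
  flip <- seq(1, 2000, 2)
  b2$beta[flip] <- -b2$beta[flip]
  b2$effect_allele[flip] <- "G"
  expect_equal(effect_correlation(a, b2)$r, r)
  expect_error(effect_correlation(a[1:2, ], a[1:2, ]), "3 matched")
})

test_that("the phenome scan returns one calibrated record per trait", {
  ch <- make_cohort(n = 2000, seed = 7)
  set.seed(7)
  rl <- rnorm(2000)
  covars <- cbind(sex = ch$sex, age = ch$age, age2 = ch$age^2)
  traits <- c(list(trait_spec("hit", "binary", prevalence = 0.3,
                              beta_rlrmtcn = 0.6)),
              lapply(1:8, function(i) trait_spec(paste0("null", i), "binary",
                                                 prevalence = 0.3)))
  ph <- simulate_phenotypes(ch, rl, traits, seed = 7)
  st <- assign_case_control(ph$phecodes)
  recs <- run_phewas(rl, status = st, covariates = covars, cohort = "SYN")
  expect_equal(nrow(recs), 9)
  expect_equal(recs$trait_id[which.min(recs$p)], "hit")
  expect_true(all(recs$cohort == "SYN"))
  # deterministic: identical inputs give identical output
  expect_identical(recs, run_phewas(rl, status = st, covariates = covars,
                                    cohort = "SYN"))
  expect_error(run_phewas(rl), "phenotype")
})
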