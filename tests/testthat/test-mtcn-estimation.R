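test_that("spike masking covers the closed interval and nothing else", {
  pr <- depth_profile("a", rep(1L, 16569), rep(1L, 16569))
  m <- mask_spike(pr, c(2500L, 3000L))
  expect_length(m$mask, 501)
  expect_equal(range(m$mask), c(2500, 3000))
  expect_identical(m$mt_depths, pr$mt_depths) # depths untouched
  # empty region: unchanged
  expect_identical(mask_spike(pr, NULL), pr)
  # out-of-range region rejected
  expect_error(mask_spike(pr, c(0L, 10L)), "coordinate range")
  # full mask: averaging fails downstream
  full <- mask_spike(pr, c(1L, 16569L))
  expect_error(estimate_rmtcn(full), "no unmasked sites")
})

test_that("copy-number ratio is exact on constant profiles and scale equivariant", {
  r <- estimate_rmtcn(make_profile(mt = 10, auto = 5))
  expect_equal(r$rmtcn, 2)
  expect_equal(r$lrmtcn, log(2))
  # identity
  r1 <- estimate_rmtcn(make_profile(mt = 7, auto = 7))
  expect_equal(r1$rmtcn, 1)
  expect_equal(r1$lrmtcn, 0)
  # scale equivariance: multiplying all depths leaves the ratio unchanged
  set.seed(1)
  mt <- rpois(200, 5); auto <- rpois(200, 3) + 1
  a <- estimate_rmtcn(depth_profile("x", mt, auto))
  b <- estimate_rmtcn(depth_profile("x", 3 * mt, 3 * auto))
  expect_equal(a$rmtcn, b$rmtcn)
  # degenerate inputs
  expect_error(estimate_rmtcn(depth_profile("x", rep(1, 5), rep(0, 5))),
               "autosomal")
  expect_error(estimate_rmtcn(depth_profile("x", rep(0, 5), rep(1, 5))),
               "zero mean mitochondrial")
})

test_that("masking an inflated region never increases the mitochondrial mean", {
  set.seed(2)
  for (i in 1:5) {
    mt <- rpois(16569, 3)
    mt[2500:3000] <- mt[2500:3000] + rpois(501, 20)
    pr <- depth_profile("x", mt, rpois(16569, 3) + 1)
    raw <- estimate_rmtcn(pr)
    masked <- estimate_rmtcn(mask_spike(pr))
    expect_lte(masked$rmtcn, raw$rmtcn)
  }
})

test_that("residualization is orthogonal, basis-invariant, and recovers noise", {
  ch <- make_cohort(n = 1500, seed = 21)
  # lrmtcn with a known quadratic neutrophil effect plus pure noise
  set.seed(21)
  noise <- rnorm(1500, 0, 0.3)
  rec <- data.frame(individual_id = ch$individual_id,
                    rmtcn = NA,
                    lrmtcn = 0.5 - 0.2 * ch$neutrophils +
                      0.01 * ch$neutrophils^2 + noise)
  res <- residualize(rec, ch)
  expect_lt(abs(mean(res$rlrmtcn)), 1e-10)
  # residuals orthogonal to every design column
  X <- mitocn:::composition_design(ch, "full")
  cors <- abs(cor(res$rlrmtcn, X[, -1]))
  expect_lt(max(cors), 1e-8)
  # residual variance ~ noise variance
  expect_lt(abs(var(res$rlrmtcn) / var(noise) - 1), 0.1)

  # basis invariance: orthogonal polynomials span the same columns
  cell_terms <- paste(sprintf("poly(%s, 2)", c("neutrophils", "platelets",
                                               "lymphocytes", "basophils",
                                               "monocytes", "eosinophils")),
                      collapse = " + ")
  f <- as.formula(paste("lrmtcn ~ (sex + poly(age, 2)) * (", cell_terms, ")"))
  d <- cbind(ch, lrmtcn = rec$lrmtcn)
  ortho_resid <- residuals(lm(f, data = d))
  expect_equal(unname(res$rlrmtcn), unname(ortho_resid), tolerance = 1e-8)
})

test_that("standardization yields unit variance and is affine invariant", {
  rec <- data.frame(individual_id = letters[1:10], rlrmtcn = rnorm(10, 5, 3))
  s <- standardize(rec)
  expect_equal(sd(s$rlrmtcn), 1)
  expect_equal(mean(s$rlrmtcn), 0)
  rec2 <- rec; rec2$rlrmtcn <- 2 * rec$rlrmtcn + 7
  expect_equal(standardize(rec2)$rlrmtcn, s$rlrmtcn)
  expect_error(standardize(data.frame(rlrmtcn = rep(1, 5),
                                      individual_id = letters[1:5])),
               "zero variance")
})

test_that("adjustment-model comparison exposes composition-driven signals", {
  ch <- make_cohort(n = 3000, seed = 22)
  set.seed(22)
  true_cn <- rnorm(3000, 0, 0.3)
  rec <- data.frame(individual_id = ch$individual_id, rmtcn = NA,
                    lrmtcn = true_cn - 0.15 * ch$neutrophils)
  # phenotype depends only on neutrophils: confounded through composition
  pheno_conf <- 0.5 * ch$neutrophils + rnorm(3000)
  # phenotype depends only on true copy number: robust across models
  pheno_cn <- 1.5 * true_cn + rnorm(3000, 0, 0.5)
  cmp <- quiet(compare_adjustment_models(
    rec, ch, list(conf = pheno_conf, cn = pheno_cn),
    model_set = c("none", "full")))
  conf_none <- cmp[cmp$trait_id == "conf" & cmp$covariate_set == "none", ]
  conf_full <- cmp[cmp$trait_id == "conf" & cmp$covariate_set == "full", ]
  expect_lt(conf_none$p, 1e-6)       # raw lrmtcn picks up the confounding
  expect_gt(conf_full$p, 0.01)       # fully adjusted: null
  cn_rows <- cmp[cmp$trait_id == "cn", ]
  expect_true(all(cn_rows$p < 1e-6)) # true signal survives all models
  expect_true(all(!cn_rows$sign_flip))
  expect_error(compare_adjustment_models(rec, ch, list(a = pheno_cn),
                                         model_set = character(0)),
               "model_set")
})

test_that("Duffy effect on copy number attenuates after composition adjustment", {
  # the null allele affects copy number only through neutrophil count, so
  # its association must shrink once composition is modeled
  ch <- make_cohort(n = 4000, seed = 23, duffy_neutrophil_effect = -0.3)
  set.seed(23)
  rec <- data.frame(individual_id = ch$individual_id, rmtcn = NA,
                    lrmtcn = -0.2 * ch$neutrophils + rnorm(4000, 0, 0.3))
  raw <- fit_assoc(rec$lrmtcn, ch$duffy_genotype, model = "linear")
  res <- residualize(rec, ch)
  adj <- fit_assoc(res$rlrmtcn, ch$duffy_genotype, model = "linear")
  expect_lt(abs(adj$beta), abs(raw$beta) / 3)
  expect_lt(raw$p, 1e-10)
})
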