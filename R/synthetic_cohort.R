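#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the configuration used by [simulate_cohort()] and the
#' downstream simulators. Defaults describe a biobank-style admixed cohort of
#' largely African ancestry: nuclear African-ancestry fractions follow a Beta
#' law with mean 0.8 and sd 0.1, mitochondrial haplogroups are African-lineage
#' with probability 0.8, and the Duffy-null allele is near-fixed on African
#' haplotypes and absent on European ones.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param seed Master integer seed; expanded into per-stage substreams.
#' @param haplogroup_freq_african Probability that an individual carries an
#'   African-lineage (L) mitochondrial haplogroup.
#' @param haplogroup_freq_other Probability of a haplogroup outside the
#'   African/European classification (excluded from mito-nuclear analyses).
#' @param ancestry_mean,ancestry_sd Mean and sd of the Beta law for the
#'   nuclear African-ancestry fraction.
#' @param haplogroup_ancestry_coupling In `[0, 1]`; 0 draws the haplogroup
#'   independently of nuclear ancestry (the mito-nuclear null), 1 makes
#'   P(African lineage) equal the individual's ancestry fraction.
#' @param generations_since_admixture Generations used by the local-ancestry
#'   tract process.
#' @param duffy_freq_by_ancestry Length-2 vector: frequency of the Duffy-null
#'   allele on African and European haplotypes.
#' @param duffy_neutrophil_effect Additive effect of each Duffy-null allele on
#'   log neutrophil count (negative: the allele lowers neutrophil counts).
#' @param blood_count_meanlog Named numeric vector of log-scale means for the
#'   six cell types, in 1,000 cells/uL.
#' @param blood_count_sdlog Log-scale sd shared by the blood counts.
#' @param age_range Truncation limits for age in years.
#' @param n_pcs Number of genetic principal components to emit.
#' @return A validated list of class `"mitocn_config"`.
#' @export
cohort_config <- function(n_individuals = 1000L,
                          seed = 1L,
                          haplogroup_freq_african = 0.8,
                          haplogroup_freq_other = 0,
                          ancestry_mean = 0.8,
                          ancestry_sd = 0.1,
                          haplogroup_ancestry_coupling = 0,
                          generations_since_admixture = 8,
                          duffy_freq_by_ancestry = c(african = 0.95, european = 0.0),
                          duffy_neutrophil_effect = -0.15,
                          blood_count_meanlog = c(neutrophils = log(4.0),
                                                  lymphocytes = log(1.9),
                                                  monocytes = log(0.5),
                                                  eosinophils = log(0.15),
                                                  basophils = log(0.04),
                                                  platelets = log(250)),
                          blood_count_sdlog = 0.35,
                          age_range = c(18, 90),
                          n_pcs = 20L) {
  if (!is.numeric(n_individuals) || n_individuals < 2)
    config_error("n_individuals", "must be >= 2")
  probs <- c(haplogroup_freq_african = haplogroup_freq_african,
             haplogroup_freq_other = haplogroup_freq_other,
             ancestry_mean = ancestry_mean,
             haplogroup_ancestry_coupling = haplogroup_ancestry_coupling)
  for (nm in names(probs))
    if (!is.numeric(probs[[nm]]) || probs[[nm]] < 0 || probs[[nm]] > 1)
      config_error(nm, "must be a probability in [0, 1]")
  if (haplogroup_freq_african + haplogroup_freq_other > 1)
    config_error("haplogroup_freq_other",
                 "haplogroup frequencies must sum to at most 1")
  if (ancestry_sd <= 0 || ancestry_sd^2 >= ancestry_mean * (1 - ancestry_mean))
    config_error("ancestry_sd", "incompatible with a Beta law at this mean")
  if (any(duffy_freq_by_ancestry < 0) || any(duffy_freq_by_ancestry > 1))
    config_error("duffy_freq_by_ancestry", "allele frequencies must be in [0, 1]")
  if (generations_since_admixture < 0)
    config_error("generations_since_admixture", "must be >= 0")
  if (blood_count_sdlog <= 0)
    config_error("blood_count_sdlog", "must be > 0")
  cells <- c("neutrophils", "lymphocytes", "monocytes", "eosinophils",
             "basophils", "platelets")
  if (!all(cells %in% names(blood_count_meanlog)))
    config_error("blood_count_meanlog",
                 paste("must name all of:", paste(cells, collapse = ", ")))
  structure(list(n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed),
                 haplogroup_freq_african = haplogroup_freq_african,
                 haplogroup_freq_other = haplogroup_freq_other,
                 ancestry_mean = ancestry_mean,
                 ancestry_sd = ancestry_sd,
                 haplogroup_ancestry_coupling = haplogroup_ancestry_coupling,
                 generations_since_admixture = generations_since_admixture,
                 duffy_freq_by_ancestry = duffy_freq_by_ancestry,
                 duffy_neutrophil_effect = duffy_neutrophil_effect,
                 blood_count_meanlog = blood_count_meanlog[cells],
                 blood_count_sdlog = blood_count_sdlog,
                 age_range = age_range,
                 n_pcs = as.integer(n_pcs)),
            class = "mitocn_config")
}

# African and European top-level haplogroup labels used for simulation;
# classification back to origin is done by classify_origin().
.afr_haplogroups <- c("L0", "L1", "L2", "L3")
.eur_haplogroups <- c("H", "I", "J", "K", "T", "U", "V", "W", "X")
.other_haplogroups <- c("M7", "A2", "B2", "C1", "D1")

#' Simulate a biobank-style admixed cohort
#'
#' Draws demographics, complete blood counts, nuclear ancestry fraction,
#' mitochondrial haplogroup, Duffy-null genotype, and genetic PCs for
#' `config$n_individuals` individuals. The Duffy genotype is drawn per
#' individual under Hardy-Weinberg at the ancestry-weighted allele frequency,
#' and each Duffy-null allele shifts log neutrophil count by
#' `duffy_neutrophil_effect`, reproducing the well-known benign neutropenia
#' association that the copy-number adjustment model must absorb.
#'
#' @param config A [cohort_config()] object.
#' @return A data frame (one row per individual) with columns
#'   `individual_id`, `sex` (1 = male), `age`, the six blood counts,
#'   `african_ancestry`, `mt_haplogroup`, `mt_origin`, `duffy_genotype`, and
#'   `PC1`..`PCk`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mitocn_config"))
  n <- config$n_individuals
  set.seed(substream_seed(config$seed, "cohort"))

  # Beta law for ancestry, parameterized by (mean, sd)
  m <- config$ancestry_mean; v <- config$ancestry_sd^2
  nu <- m * (1 - m) / v - 1
  ancestry <- stats::rbeta(n, m * nu, (1 - m) * nu)

  sex <- stats::rbinom(n, 1, 0.5)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])

  # mitochondrial haplogroup: optionally coupled to nuclear ancestry
  w <- config$haplogroup_ancestry_coupling
  p_afr <- (1 - w) * config$haplogroup_freq_african + w * ancestry
  p_afr <- p_afr * (1 - config$haplogroup_freq_other)
  p_oth <- config$haplogroup_freq_other
  u <- stats::runif(n)
  origin <- ifelse(u < p_afr, "African",
                   ifelse(u < p_afr + p_oth, "other", "European"))
  hap <- character(n)
  hap[origin == "African"] <- sample(.afr_haplogroups,
                                     sum(origin == "African"), replace = TRUE)
  hap[origin == "European"] <- sample(.eur_haplogroups,
                                      sum(origin == "European"), replace = TRUE)
  hap[origin == "other"] <- sample(.other_haplogroups,
                                   sum(origin == "other"), replace = TRUE)

  # Duffy-null genotype: Hardy-Weinberg at ancestry-weighted frequency
  f <- config$duffy_freq_by_ancestry
  p_null <- ancestry * f[[1]] + (1 - ancestry) * f[[2]]
  duffy <- stats::rbinom(n, 2, p_null)

  cells <- names(config$blood_count_meanlog)
  counts <- matrix(NA_real_, n, length(cells), dimnames = list(NULL, cells))
  for (j in seq_along(cells)) {
    mu <- rep(config$blood_count_meanlog[[j]], n)
    if (cells[j] == "neutrophils")
      mu <- mu + config$duffy_neutrophil_effect * duffy
    counts[, j] <- stats::rlnorm(n, mu, config$blood_count_sdlog)
  }

  # PCs: PC1 tracks the admixture axis, the rest are structureless
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  pcs[, 1] <- as.numeric(scale(ancestry)) + stats::rnorm(n, 0, 0.3)
  colnames(pcs) <- paste0("PC", seq_len(config$n_pcs))

  out <- data.frame(individual_id = sprintf("ID%06d", seq_len(n)),
                    sex = sex, age = age, counts,
                    african_ancestry = ancestry,
                    mt_haplogroup = hap, mt_origin = origin,
                    duffy_genotype = duffy,
                    stringsAsFactors = FALSE)
  cbind(out, pcs)
}

#' Build an evenly spaced marker map
#'
#' @param n_chrom Number of chromosomes.
#' @param markers_per_chrom Markers per chromosome.
#' @param morgans_per_chrom Genetic length of each chromosome in Morgans.
#' @return Data frame with `chrom`, `pos` (1-based bp), `gpos` (Morgans).
#' @export
marker_map <- function(n_chrom = 3L, markers_per_chrom = 200L,
                       morgans_per_chrom = 1) {
  do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
    g <- seq(0, morgans_per_chrom, length.out = markers_per_chrom)
    data.frame(chrom = ch,
               pos = as.integer(round(g * 1e8) + 1),
               gpos = g)
  }))
}

#' Simulate local-ancestry tracts along a marker map
#'
#' Each haplotype is a Markov chain in map order: between adjacent markers at
#' genetic distance `d` Morgans, an ancestry-resetting recombination occurs
#' with probability `1 - exp(-g * d)` (`g` = generations since admixture), and
#' the new state is drawn from the individual's stationary African-ancestry
#' fraction. The diploid count at a marker is the sum of the two haplotype
#' states.
#'
#' @param cohort A [simulate_cohort()] data frame (uses `african_ancestry`).
#' @param map A [marker_map()] data frame, sorted by chromosome and position.
#' @param g Generations since admixture.
#' @param seed Integer seed.
#' @param posterior_low_frac Fraction of cells assigned a sub-0.9 calling
#'   posterior (emulating uncertain local-ancestry calls).
#' @return An object of class `"local_ancestry"`: list with `counts`
#'   (n x m integer matrix in `{0,1,2}`), `hap1`/`hap2` (n x m in `{0,1}`),
#'   `posterior` (n x m in `[0,1]`), and `map`.
#' @export
simulate_local_ancestry <- function(cohort, map, g = 8, seed = 1L,
                                    posterior_low_frac = 0) {
  ord_ok <- all(unlist(tapply(map$gpos, map$chrom, function(x) !is.unsorted(x))))
  if (!ord_ok) stop("marker map must be sorted by (chromosome, position)",
                    call. = FALSE)
  set.seed(substream_seed(seed, "local_ancestry"))
  n <- nrow(cohort); m <- nrow(map)
  q <- cohort$african_ancestry

  # per-interval recombination probability; new chromosome => forced redraw
  d <- c(0, diff(map$gpos))
  new_chrom <- c(TRUE, diff(map$chrom) != 0)
  p_switch <- 1 - exp(-g * d)
  p_switch[new_chrom] <- 1

  draw_haplotype <- function() {
    h <- matrix(0L, n, m)
    state <- stats::rbinom(n, 1, q)
    h[, 1] <- state
    for (j in 2:m) {
      redraw <- stats::runif(n) < p_switch[j]
      state <- ifelse(redraw, stats::rbinom(n, 1, q), state)
      h[, j] <- state
    }
    h
  }
  hap1 <- draw_haplotype()
  hap2 <- draw_haplotype()

  post <- matrix(1, n, m)
  if (posterior_low_frac > 0) {
    k <- round(posterior_low_frac * n * m)
    idx <- sample.int(n * m, k)
    post[idx] <- stats::runif(k, 0.5, 0.9)
  }
  structure(list(counts = hap1 + hap2, hap1 = hap1, hap2 = hap2,
                 posterior = post, map = map,
                 individual_id = cohort$individual_id),
            class = "local_ancestry")
}

#' Simulate genotypes conditional on local ancestry
#'
#' Each allele on each haplotype is drawn from the allele frequency of that
#' haplotype's local-ancestry background, producing ancestry-differentiated
#' variants (the Duffy-like alleles admixture mapping is designed to detect).
#'
#' @param local A [simulate_local_ancestry()] object.
#' @param freq_african,freq_european Per-marker effect-allele frequencies on
#'   African and European backgrounds (recycled if scalar).
#' @param seed Integer seed.
#' @return A list of class `"genotype_matrix"`: `dosage` (n x m in
#'   `{0,1,2}`), `map`, `freq` (realized in-sample frequencies), plus the
#'   per-ancestry frequencies used.
#' @export
simulate_genotypes <- function(local, freq_african, freq_european, seed = 1L) {
  stopifnot(inherits(local, "local_ancestry"))
  m <- ncol(local$counts)
  fa <- rep_len(freq_african, m); fe <- rep_len(freq_european, m)
  if (any(fa < 0 | fa > 1 | fe < 0 | fe > 1))
    stop("allele frequencies must be in [0, 1]", call. = FALSE)
  set.seed(substream_seed(seed, "genotypes"))
  n <- nrow(local$counts)
  draw <- function(h) {
    p <- sweep(h, 2, fa, "*") + sweep(1 - h, 2, fe, "*")
    matrix(stats::rbinom(n * m, 1, p), n, m)
  }
  dosage <- draw(local$hap1) + draw(local$hap2)
  structure(list(dosage = dosage, map = local$map,
                 freq = colMeans(dosage) / 2,
                 freq_african = fa, freq_european = fe,
                 individual_id = local$individual_id),
            class = "genotype_matrix")
}

#' Simulate an unlinked genotype matrix
#'
#' Independent Hardy-Weinberg variants without ancestry structure; the
#' workhorse input for heritability experiments.
#'
#' @param n Individuals; @param m Variants.
#' @param maf_range Range from which per-variant minor allele frequencies are
#'   drawn uniformly.
#' @param seed Integer seed.
#' @return A `"genotype_matrix"` object (no map positions beyond an index).
#' @export
simulate_unlinked_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                                        seed = 1L) {
  set.seed(substream_seed(seed, "unlinked_genotypes"))
  f <- stats::runif(m, maf_range[1], maf_range[2])
  dosage <- matrix(stats::rbinom(n * m, 2, rep(f, each = n)), n, m)
  map <- data.frame(chrom = rep(1L, m), pos = seq_len(m), gpos = NA_real_)
  structure(list(dosage = dosage, map = map, freq = colMeans(dosage) / 2,
                 freq_african = f, freq_european = f,
                 individual_id = sprintf("ID%06d", seq_len(n))),
            class = "genotype_matrix")
}

#' Simulate true log relative mtDNA copy number
#'
#' Builds `lrmtCN` as a sum of configured covariate effects (possibly
#' nonlinear), an additive genetic value scaled to a target heritability, and
#' Gaussian noise. Default covariate effects carry the documented signs:
#' neutrophil counts lower copy number and platelet counts raise it.
#'
#' @param cohort A [simulate_cohort()] data frame.
#' @param effect_spec Named list. Each element is either a single coefficient
#'   (linear in the named column), a length-2 vector `c(b1, b2)` (linear +
#'   quadratic), or a function of the column. Names must be cohort columns.
#' @param h2_target Fraction of total variance from the genetic value, in
#'   `[0, 1)`; requires `genotypes` when positive.
#' @param genotypes A `"genotype_matrix"` whose variants carry the genetic
#'   effects (all variants causal, Gaussian effect sizes).
#' @param noise_sd Residual sd of the non-genetic noise.
#' @param seed Integer seed.
#' @return Numeric vector of true `lrmtCN`, with the realized genetic values
#'   in attribute `"genetic_value"`.
#' @export
simulate_copy_number <- function(cohort,
                                 effect_spec = default_lrmtcn_effects(),
                                 h2_target = 0, genotypes = NULL,
                                 noise_sd = 0.45, seed = 1L) {
  if (h2_target < 0 || h2_target >= 1)
    config_error("h2_target", "must be in [0, 1)")
  if (h2_target > 0 && is.null(genotypes))
    config_error("genotypes", "required when h2_target > 0")
  bad <- setdiff(names(effect_spec), names(cohort))
  if (length(bad))
    config_error("effect_spec", paste("unknown cohort column(s):",
                                      paste(bad, collapse = ", ")))
  set.seed(substream_seed(seed, "copy_number"))
  n <- nrow(cohort)

  fixed <- rep(0, n)
  for (nm in names(effect_spec)) {
    v <- cohort[[nm]]; ef <- effect_spec[[nm]]
    if (is.function(ef)) fixed <- fixed + ef(v)
    else if (length(ef) == 1L) fixed <- fixed + ef * v
    else fixed <- fixed + ef[1] * v + ef[2] * v^2
  }
  eps <- stats::rnorm(n, 0, noise_sd)
  ng <- fixed + eps

  gval <- rep(0, n)
  if (h2_target > 0) {
    b <- stats::rnorm(ncol(genotypes$dosage))
    g <- as.numeric(genotypes$dosage %*% b)
    g <- g - mean(g)
    # scale genetic value so var(g) / (var(g) + var(nongenetic)) = h2_target
    g <- g * sqrt(h2_target / (1 - h2_target) * stats::var(ng) / stats::var(g))
    gval <- g
  }
  out <- ng + gval
  attr(out, "genetic_value") <- gval
  out
}

#' Default covariate effects on log relative copy number
#'
#' Negative neutrophil and positive platelet contributions, a weak quadratic
#' age decline, and a small male deficit, on scales producing effect sizes of
#' a few percent of an sd per count unit.
#'
#' @return Named list usable as `effect_spec` in [simulate_copy_number()].
#' @export
default_lrmtcn_effects <- function() {
  list(sex = -0.05,
       age = function(a) -0.002 * (a - 55) - 2e-5 * (a - 55)^2,
       neutrophils = c(-0.12, 0.006),
       platelets = c(0.0012, -8e-7),
       lymphocytes = c(-0.03, 0.002),
       monocytes = -0.05,
       eosinophils = -0.04,
       basophils = -0.1)
}

#' Simulate per-individual sequencing depth profiles
#'
#' Per-site depths are Poisson: autosomal sites at the configured mean depth,
#' mitochondrial sites at `autosomal_mean * exp(true_lrmtcn)`, multiplied by
#' `spike_multiplier` inside the spike region (emulating the known coverage
#' artifact on the mitochondrial reference).
#'
#' @param true_lrmtcn Numeric vector of true log relative copy numbers.
#' @param autosomal_mean Mean autosomal depth (default 2.8x).
#' @param spike_region Length-2 integer vector (1-based, closed) or `NULL`.
#' @param spike_multiplier Depth multiplier inside the spike region.
#' @param n_sites Number of mitochondrial (and autosomal) sites.
#' @param seed Integer seed.
#' @param ids Optional individual ids.
#' @return List of [depth_profile()] objects, one per individual.
#' @export
simulate_depth <- function(true_lrmtcn, autosomal_mean = 2.8,
                           spike_region = c(2500L, 3000L),
                           spike_multiplier = 1, n_sites = 16569L,
                           seed = 1L, ids = NULL) {
  if (autosomal_mean <= 0)
    config_error("autosomal_mean", "must be > 0")
  set.seed(substream_seed(seed, "depth"))
  n <- length(true_lrmtcn)
  if (is.null(ids)) ids <- sprintf("ID%06d", seq_len(n))
  spike <- integer(0)
  if (!is.null(spike_region) && spike_multiplier != 1)
    spike <- seq.int(spike_region[1], spike_region[2])
  lapply(seq_len(n), function(i) {
    mu_mt <- rep(autosomal_mean * exp(true_lrmtcn[i]), n_sites)
    if (length(spike)) mu_mt[spike] <- mu_mt[spike] * spike_multiplier
    depth_profile(individual_id = ids[i],
                  mt_depths = stats::rpois(n_sites, mu_mt),
                  auto_depths = stats::rpois(n_sites, autosomal_mean))
  })
}

#' Specify one synthetic phenotype
#'
#' @param name Trait id.
#' @param type `"binary"` or `"quantitative"`.
#' @param prevalence Baseline prevalence (binary traits).
#' @param beta_rlrmtcn Effect of (standardized) residual copy number.
#' @param beta_ancestry Effect of the nuclear African-ancestry fraction.
#' @param beta_haplogroup Effect of the mitochondrial haplogroup code
#'   (+1 African lineage, -1 European).
#' @param beta_interaction Haplogroup x ancestry interaction effect.
#' @param beta_sex,beta_age Covariate effects.
#' @param noise_sd Residual sd (quantitative traits).
#' @param singleton_frac Fraction of unaffected individuals receiving a
#'   single (missing-status) occurrence record.
#' @param case_two_plus_prob Probability an affected individual accrues >= 2
#'   occurrence records (the rest become singletons).
#' @return A list of class `"trait_spec"`.
#' @export
trait_spec <- function(name, type = c("binary", "quantitative"),
                       prevalence = 0.1, beta_rlrmtcn = 0, beta_ancestry = 0,
                       beta_haplogroup = 0, beta_interaction = 0,
                       beta_sex = 0, beta_age = 0, noise_sd = 1,
                       singleton_frac = 0.05, case_two_plus_prob = 0.95) {
  type <- match.arg(type)
  if (type == "binary" && (prevalence <= 0 || prevalence >= 1))
    config_error("prevalence", "must be in (0, 1)")
  structure(list(name = name, type = type, prevalence = prevalence,
                 beta_rlrmtcn = beta_rlrmtcn, beta_ancestry = beta_ancestry,
                 beta_haplogroup = beta_haplogroup,
                 beta_interaction = beta_interaction,
                 beta_sex = beta_sex, beta_age = beta_age,
                 noise_sd = noise_sd, singleton_frac = singleton_frac,
                 case_two_plus_prob = case_two_plus_prob),
            class = "trait_spec")
}

#' Simulate a synthetic phenome
#'
#' Binary traits are drawn through a logistic model whose linear predictor
#' combines the configured effects of standardized residual copy number,
#' nuclear ancestry, haplogroup code, their interaction, and covariates;
#' occurrence counts then encode the case (>= 2 records), control (0) and
#' missing (1 record) classes. Quantitative traits are Gaussian with the same
#' linear predictor.
#'
#' @param cohort A [simulate_cohort()] data frame.
#' @param rlrmtcn Standardized residual copy number vector (0 effects allowed
#'   with `NULL`).
#' @param traits List of [trait_spec()] objects.
#' @param seed Integer seed.
#' @return List with `phecodes` (individuals x binary-trait occurrence-count
#'   matrix) and `labs` (individuals x quantitative-trait value matrix).
#' @export
simulate_phenotypes <- function(cohort, rlrmtcn = NULL, traits, seed = 1L) {
  set.seed(substream_seed(seed, "phenotypes"))
  n <- nrow(cohort)
  if (is.null(rlrmtcn)) rlrmtcn <- rep(0, n)
  x_hap <- ifelse(cohort$mt_origin == "African", 1,
                  ifelse(cohort$mt_origin == "European", -1, NA))
  z <- cohort$african_ancestry
  bin <- list(); quant <- list()
  for (tr in traits) {
    if (!inherits(tr, "trait_spec"))
      config_error("traits", "each element must be a trait_spec")
    eta <- tr$beta_rlrmtcn * rlrmtcn + tr$beta_ancestry * z +
      tr$beta_haplogroup * ifelse(is.na(x_hap), 0, x_hap) +
      tr$beta_interaction * ifelse(is.na(x_hap), 0, x_hap) * z +
      tr$beta_sex * cohort$sex + tr$beta_age * cohort$age
    if (tr$type == "binary") {
      b0 <- stats::qlogis(tr$prevalence)
      affected <- stats::rbinom(n, 1, stats::plogis(b0 + eta))
      counts <- integer(n)
      is_case <- affected == 1 &
        stats::runif(n) < tr$case_two_plus_prob
      counts[is_case] <- 2L + stats::rpois(sum(is_case), 1)
      counts[affected == 1 & !is_case] <- 1L
      unaff <- affected == 0
      singles <- unaff & stats::runif(n) < tr$singleton_frac
      counts[singles] <- 1L
      bin[[tr$name]] <- counts
    } else {
      quant[[tr$name]] <- eta + stats::rnorm(n, 0, tr$noise_sd)
    }
  }
  list(phecodes = if (length(bin)) do.call(cbind, bin) else NULL,
       labs = if (length(quant)) do.call(cbind, quant) else NULL)
}
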