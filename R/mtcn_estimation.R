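#' Construct a per-individual depth profile
#'
#' Holds raw per-site depths over the 16,569 mitochondrial reference
#' positions and an equal number of sampled autosomal sites, plus the set of
#' mitochondrial positions masked from averaging.
#'
#' @param individual_id Identifier.
#' @param mt_depths Integer vector of mitochondrial depths (one per
#'   reference position, 1-based).
#' @param auto_depths Integer vector of autosomal depths, same length.
#' @param mask Integer vector of masked mitochondrial positions.
#' @return An object of class `"depth_profile"`.
#' @export
depth_profile <- function(individual_id, mt_depths, auto_depths,
                          mask = integer(0)) {
  if (length(mt_depths) != length(auto_depths))
    stop("mt_depths and auto_depths must have equal length", call. = FALSE)
  if (any(mt_depths < 0) || any(auto_depths < 0))
    stop("depths must be nonnegative", call. = FALSE)
  structure(list(individual_id = individual_id,
                 mt_depths = as.numeric(mt_depths),
                 auto_depths = as.numeric(auto_depths),
                 mask = as.integer(mask)),
            class = "depth_profile")
}

#' Mask a mitochondrial region from depth averaging
#'
#' The default region is the closed interval 2,500-3,000, covering the known
#' coverage spike on the mitochondrial reference; masking leaves the
#' underlying depths untouched and only excludes the positions from the mean.
#'
#' @param profile A [depth_profile()].
#' @param region Length-2 integer vector (1-based, closed interval), or
#'   `NULL`/zero-length for no change.
#' @return The profile with its mask extended.
#' @export
mask_spike <- function(profile, region = c(2500L, 3000L)) {
  stopifnot(inherits(profile, "depth_profile"))
  if (is.null(region) || length(region) == 0) return(profile)
  nmax <- length(profile$mt_depths)
  if (region[1] < 1 || region[2] > nmax || region[1] > region[2])
    stop("mask region outside the mitochondrial coordinate range 1-", nmax,
         call. = FALSE)
  profile$mask <- sort(union(profile$mask, seq.int(region[1], region[2])))
  profile
}

#' Estimate relative mtDNA copy number from a depth profile
#'
#' Relative copy number is the ratio of mean mitochondrial depth (over
#' unmasked positions) to mean autosomal depth; the log ratio (`lrmtcn`) is
#' the quantity modeled downstream. No factor of two is applied: exome
#' off-target data only support a relative, not absolute, scale.
#'
#' @param profile A [depth_profile()], typically after [mask_spike()].
#' @return One-row data frame with `individual_id`, `rmtcn`, `lrmtcn`.
#' @export
estimate_rmtcn <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  keep <- setdiff(seq_along(profile$mt_depths), profile$mask)
  if (length(keep) == 0) stop("no unmasked sites", call. = FALSE)
  auto_mean <- mean(profile$auto_depths)
  if (auto_mean == 0) stop("undefined ratio: zero mean autosomal depth",
                           call. = FALSE)
  mt_mean <- mean(profile$mt_depths[keep])
  if (mt_mean == 0)
    stop("zero mean mitochondrial depth: rmtcn = 0, log undefined",
         call. = FALSE)
  r <- mt_mean / auto_mean
  data.frame(individual_id = profile$individual_id, rmtcn = r,
             lrmtcn = log(r), stringsAsFactors = FALSE)
}

#' Estimate copy number for a list of profiles
#'
#' @param profiles List of [depth_profile()] objects.
#' @param spike_region Region passed to [mask_spike()] (or `NULL` to skip).
#' @return Data frame with one row per individual.
#' @export
estimate_rmtcn_cohort <- function(profiles, spike_region = c(2500L, 3000L)) {
  do.call(rbind, lapply(profiles, function(p) {
    if (!is.null(spike_region)) p <- mask_spike(p, spike_region)
    estimate_rmtcn(p)
  }))
}

# internal: design matrix for the cell-composition model.
# (sex + age + age^2) crossed with linear+quadratic terms for the six blood
# counts: intercept + 3 + 12 + 36 = 52 columns. Raw polynomials are used;
# residuals are invariant to the choice of basis spanning the same columns.
composition_design <- function(cohort, model = c("full", "linear", "none",
                                                 "full_duffy")) {
  model <- match.arg(model)
  cells <- c("neutrophils", "platelets", "lymphocytes", "basophils",
             "monocytes", "eosinophils")
  if (model == "none")
    return(stats::model.matrix(~1, data = cohort))
  if (model == "linear") {
    f <- stats::reformulate(c("sex", "age", cells))
    return(stats::model.matrix(f, data = cohort))
  }
  cell_terms <- paste(sprintf("poly(%s, 2, raw = TRUE)", cells),
                      collapse = " + ")
  f <- stats::as.formula(paste(
    "~ (sex + poly(age, 2, raw = TRUE)) * (", cell_terms, ")"))
  X <- stats::model.matrix(f, data = cohort)
  if (model == "full_duffy") {
    X <- cbind(X, duffy_add = cohort$duffy_genotype,
               duffy_het = as.numeric(cohort$duffy_genotype == 1))
  }
  X
}

#' Residualize log copy number on demographics and blood composition
#'
#' Fits ordinary least squares of `lrmtcn` on the full composition model:
#' sex, age, age squared, linear and quadratic terms for the six blood cell
#' counts, and all pairwise interactions between the demographic and
#' cell-count blocks (52 coefficients). The residual, `rlrmtcn`, carries the
#' copy-number variation not attributable to cell composition.
#'
#' @param records Data frame with `individual_id` and `lrmtcn` (from
#'   [estimate_rmtcn_cohort()]).
#' @param cohort A cohort data frame aligned by `individual_id`.
#' @param model Covariate set: `"full"` (default), `"linear"`, `"none"`, or
#'   `"full_duffy"` (adds the additive + heterozygote Duffy coding).
#' @return `records` with columns `rlrmtcn` and `model_label` added. Rows
#'   with missing covariates are dropped with a message.
#' @export
residualize <- function(records, cohort, model = "full") {
  idx <- match(records$individual_id, cohort$individual_id)
  if (anyNA(idx)) stop("records contain individuals absent from the cohort",
                       call. = FALSE)
  cov <- cohort[idx, , drop = FALSE]
  X <- composition_design(cov, model)
  ok <- stats::complete.cases(X) & is.finite(records$lrmtcn)
  if (!all(ok))
    message(sum(!ok), " row(s) excluded for missing covariates")
  if (sum(ok) < 2 * ncol(X))
    stop("too few individuals for the design (need >= ", 2 * ncol(X), ")",
         call. = FALSE)
  fit <- fast_lm(records$lrmtcn[ok], X[ok, , drop = FALSE])
  out <- records
  out$rlrmtcn <- NA_real_
  out$rlrmtcn[ok] <- fit$residuals
  out$model_label <- model
  out
}

#' Standardize residual copy number to unit variance
#'
#' @param records Data frame with `rlrmtcn`.
#' @return The records with `rlrmtcn` centered and scaled to sd 1.
#' @export
standardize <- function(records) {
  v <- records$rlrmtcn
  ok <- is.finite(v)
  if (sum(ok) < 2) stop("need >= 2 records", call. = FALSE)
  s <- stats::sd(v[ok])
  if (s == 0) stop("zero variance: cannot standardize", call. = FALSE)
  records$rlrmtcn <- (v - mean(v[ok])) / s
  records
}

#' Compare phenotype associations across composition-adjustment models
#'
#' Re-runs the copy-number/phenotype association under several covariate
#' models for the composition adjustment and flags phenotypes whose effect
#' sign flips between models — the sensitivity analysis showing that
#' copy-number associations can be driven by how blood composition is
#' modeled.
#'
#' @param records Data frame with `lrmtcn` per individual.
#' @param cohort Cohort covariates.
#' @param phenotypes Named list (or matrix with named columns) of numeric
#'   phenotype vectors aligned to `records`.
#' @param model_set Subset of `c("none", "linear", "full", "full_duffy")`.
#' @param covariates Optional extra covariate matrix for the association fit.
#' @return Data frame of association records (one per phenotype x model) with
#'   a `sign_flip` flag per phenotype.
#' @export
compare_adjustment_models <- function(records, cohort, phenotypes,
                                      model_set = c("none", "linear", "full"),
                                      covariates = NULL) {
  if (length(model_set) == 0)
    config_error("model_set", "must name at least one adjustment model")
  if (is.matrix(phenotypes))
    phenotypes <- as.list(as.data.frame(phenotypes))
  out <- list()
  for (mod in model_set) {
    res <- if (mod == "none") {
      r <- records; r$rlrmtcn <- r$lrmtcn - mean(r$lrmtcn); r
    } else residualize(records, cohort, mod)
    for (ph in names(phenotypes)) {
      rec <- fit_assoc(phenotypes[[ph]], res$rlrmtcn, covariates,
                       model = "linear", predictor_id = "rlrmtcn",
                       trait_id = ph)
      rec$covariate_set <- mod
      out[[paste(mod, ph)]] <- rec
    }
  }
  out <- do.call(rbind, out)
  flips <- tapply(sign(out$beta), out$trait_id,
                  function(s) length(unique(s[s != 0])) > 1)
  out$sign_flip <- as.logical(flips[out$trait_id])
  rownames(out) <- NULL
  out
}
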