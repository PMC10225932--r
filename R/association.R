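#' Fit a single association model
#'
#' Linear (least squares) or logistic (maximum likelihood) regression of a
#' trait on a predictor with optional covariates, returning the Wald
#' two-sided p-value for the predictor.
#'
#' @param y Trait vector (binary 0/1 for logistic).
#' @param x Predictor vector.
#' @param covariates Optional matrix/data frame of covariates.
#' @param model `"linear"` or `"logistic"`.
#' @param predictor_id,trait_id Labels carried into the record.
#' @param min_cases Minimum case count for logistic fits (mirrors the phecode
#'   filter; default 20).
#' @return One-row association record (`beta`, `se`, `p`, `n`, `model`).
#' @export
fit_assoc <- function(y, x, covariates = NULL,
                      model = c("linear", "logistic"),
                      predictor_id = "x", trait_id = "y", min_cases = 20L) {
  model <- match.arg(model)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- is.finite(y) & is.finite(x)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  y <- y[ok]; x <- x[ok]
  if (!is.null(C)) C <- C[ok, , drop = FALSE]
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, x = x, C)

  if (model == "linear") {
    fit <- fast_lm(y, X)
    return(assoc_record(predictor_id, trait_id, fit$beta[2], fit$se[2],
                        fit$p[2], n, "linear"))
  }
  if (!all(y %in% c(0, 1))) stop("logistic model requires 0/1 outcome",
                                 call. = FALSE)
  if (length(unique(y)) < 2) stop("both outcome classes must be present",
                                  call. = FALSE)
  if (sum(y == 1) < min_cases)
    stop("fewer than ", min_cases, " cases; refusing logistic fit",
         call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  if (!fit$converged || any(abs(fit$coefficients) > 20)) {
    warning("possible separation: flagged record with p = NA")
    return(assoc_record(predictor_id, trait_id, NA_real_, NA_real_,
                        NA_real_, n, "logistic"))
  }
  # Wald inference from the observed information
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  se <- sqrt(diag(chol2inv(chol(XtWX))))
  beta <- fit$coefficients[2]
  z <- beta / se[2]
  assoc_record(predictor_id, trait_id, beta, se[2],
               2 * stats::pnorm(abs(z), lower.tail = FALSE), n, "logistic")
}

#' Phenome-wide association scan of residual copy number
#'
#' One association per phenotype: logistic regression for case/control
#' phecode statuses (missing statuses excluded per trait) and linear
#' regression for quantitative labs, with a shared covariate matrix
#' (conventionally sex, age, age squared and 20 PCs).
#'
#' @param rlrmtcn Standardized residual copy number.
#' @param status Case/control matrix (1/0/`NA`), or `NULL`.
#' @param labs Matrix of quantitative trait values, or `NULL`.
#' @param covariates Covariate matrix.
#' @param cohort Label attached to every record.
#' @return Data frame of association records.
#' @export
run_phewas <- function(rlrmtcn, status = NULL, labs = NULL,
                       covariates = NULL, cohort = NA_character_) {
  if (is.null(status) && is.null(labs))
    config_error("status/labs", "at least one phenotype set is required")
  out <- list()
  if (!is.null(status)) {
    status <- as.matrix(status)
    for (j in seq_len(ncol(status))) {
      nm <- colnames(status)[j]
      if (is.null(nm)) nm <- paste0("phecode_", j)
      rec <- fit_assoc(status[, j], rlrmtcn, covariates, "logistic",
                       predictor_id = "rlrmtcn", trait_id = nm)
      rec$cohort <- cohort
      out[[nm]] <- rec
    }
  }
  if (!is.null(labs)) {
    labs <- as.matrix(labs)
    for (j in seq_len(ncol(labs))) {
      nm <- colnames(labs)[j]
      if (is.null(nm)) nm <- paste0("lab_", j)
      rec <- fit_assoc(labs[, j], rlrmtcn, covariates, "linear",
                       predictor_id = "rlrmtcn", trait_id = nm)
      rec$cohort <- cohort
      out[[nm]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg discovery flags at two FDR levels
#'
#' @param pvalues Numeric p-values.
#' @param q Vector of FDR levels (default both reporting levels, 0.005 and
#'   0.05).
#' @return Data frame with `p`, `q_bh` (BH-adjusted p) and one logical flag
#'   column per level.
#' @export
bh_fdr <- function(pvalues, q = c(0.005, 0.05)) {
  if (length(pvalues) == 0)
    return(data.frame(p = numeric(0), q_bh = numeric(0)))
  adj <- stats::p.adjust(pvalues, method = "BH")
  out <- data.frame(p = pvalues, q_bh = adj)
  for (lev in q) out[[paste0("fdr_", lev)]] <- adj <= lev
  out
}

#' Exact two-sided binomial test for direction consistency
#'
#' Tests whether `k` same-direction effects out of `n` are compatible with
#' coin-flip directions (null probability one half); the two-sided p sums the
#' probabilities of all outcomes no more likely than the observed count.
#'
#' @param k Same-direction count.
#' @param n Total count.
#' @return Two-sided exact p-value.
#' @export
sign_consistency_test <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  stats::binom.test(k, n, p = 0.5)$p.value
}

#' Power to replicate a known association
#'
#' Analytic replication power for a variant with discovery effect `beta`,
#' effect-allele frequency `f`, replication sample size `n` and residual sd
#' `sigma`: the standard error is `sigma / sqrt(2 n f (1 - f))` (additive
#' Hardy-Weinberg genotype variance), the noncentrality is `(beta / SE)^2`,
#' and power is the mass of the noncentral chi-square (1 df) beyond the
#' central quantile at `1 - alpha`.
#'
#' @param beta Discovery effect size per allele.
#' @param f Effect-allele frequency in `(0, 1)`.
#' @param n Replication sample size.
#' @param sigma Residual sd of the phenotype (default 0.8).
#' @param alpha Significance level (default 4.5e-4).
#' @return Power in `[0, 1]` (vectorized over `beta`, `f`, `n`).
#' @export
replication_power <- function(beta, f, n, sigma = 0.8, alpha = 4.5e-4) {
  if (any(f <= 0 | f >= 1))
    stop("undefined SE: effect-allele frequency must be in (0, 1)",
         call. = FALSE)
  stopifnot(sigma > 0, alpha > 0, alpha < 1)
  se <- sigma / sqrt(2 * n * f * (1 - f))
  ncp <- (beta / se)^2
  q <- stats::qchisq(1 - alpha, df = 1)
  stats::pchisq(q, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param n_tests Number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Phenotypic variance explained by a set of variants
#'
#' For a unit-variance phenotype, the additive variance captured by
#' independent variants with per-allele effects `betas` at frequencies
#' `freqs` is `2 * sum(beta^2 * f * (1 - f))`.
#'
#' @param betas Per-allele effect estimates.
#' @param freqs Effect-allele frequencies in `(0, 1)`.
#' @return Variance fraction.
#' @export
h2_explained <- function(betas, freqs) {
  stopifnot(length(betas) == length(freqs), all(freqs > 0 & freqs < 1))
  2 * sum(betas^2 * freqs * (1 - freqs))
}

#' Score individuals with polygenic risk score weights
#'
#' Matches weight rows to genotype variants by id, orients dosages to the
#' effect allele (complementing when the effect allele is the reference), and
#' returns the weighted sum of effect-allele dosages. Unmatched weights are
#' dropped with a message.
#'
#' @param genotypes A `"genotype_matrix"` with `dosage` and a `variants` data
#'   frame (or `map` with ids), including columns `id`, `ref`, `alt`.
#' @param weights Data frame with `id`, `effect_allele`, `weight`.
#' @param average Divide by the number of matched variants instead of summing.
#' @return Numeric vector of per-individual scores; matched variant count in
#'   attribute `"n_matched"`.
#' @export
prs_score <- function(genotypes, weights, average = FALSE) {
  stopifnot(all(c("id", "effect_allele", "weight") %in% names(weights)))
  if (anyDuplicated(weights$id))
    stop("each variant may appear once in the weight file", call. = FALSE)
  v <- genotypes$variants
  if (is.null(v))
    v <- data.frame(id = paste0("var", seq_len(ncol(genotypes$dosage))),
                    ref = "A", alt = "B", stringsAsFactors = FALSE)
  idx <- match(weights$id, v$id)
  matched <- which(!is.na(idx))
  if (length(matched) < length(idx))
    message(length(idx) - length(matched), " weight(s) unmatched and dropped")
  if (length(matched) == 0) stop("zero matched variants", call. = FALSE)
  cols <- idx[matched]
  D <- genotypes$dosage[, cols, drop = FALSE]
  ea <- weights$effect_allele[matched]
  flip <- ea == v$ref[cols]
  bad <- !flip & ea != v$alt[cols]
  if (any(bad)) {
    message(sum(bad), " weight(s) with mismatched alleles dropped")
    D <- D[, !bad, drop = FALSE]; flip <- flip[!bad]
    matched <- matched[!bad]
  }
  if (ncol(D) == 0) stop("zero matched variants", call. = FALSE)
  D[, flip] <- 2 - D[, flip, drop = FALSE]
  sc <- as.numeric(D %*% weights$weight[matched])
  if (average) sc <- sc / ncol(D)
  attr(sc, "n_matched") <- ncol(D)
  sc
}

#' Distance-based clumping of association hits
#'
#' Greedy selection of independent loci: repeatedly take the
#' smallest-p record below the threshold (ties broken by position), emit it,
#' and discard all records within `window` bp on the same chromosome.
#'
#' @param records Data frame with `chrom`, `pos`, `p`.
#' @param p_thresh P-value threshold (default 0.05).
#' @param window Physical distance in bp (default 1 Mb).
#' @return The emitted records, in selection order.
#' @export
clump_hits <- function(records, p_thresh = 0.05, window = 1e6) {
  pool <- records[is.finite(records$p) & records$p < p_thresh, , drop = FALSE]
  pool <- pool[order(pool$p, pool$pos), , drop = FALSE]
  out <- list()
  while (nrow(pool) > 0) {
    top <- pool[1, , drop = FALSE]
    out[[length(out) + 1L]] <- top
    keep <- !(pool$chrom == top$chrom & abs(pool$pos - top$pos) <= window)
    pool <- pool[keep, , drop = FALSE]
  }
  if (length(out) == 0) return(records[0, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlation of effect sizes between two association sets
#'
#' Matches records by predictor id, harmonizes effect directions when the
#' second set reports the opposite allele (via optional `effect_allele`
#' columns), and returns the Pearson correlation and regression slope of the
#' matched effect estimates.
#'
#' @param records_a,records_b Association data frames with `predictor_id`,
#'   `beta`, and optionally `effect_allele`.
#' @return List with `r`, `slope`, `n_matched`.
#' @export
effect_correlation <- function(records_a, records_b) {
  idx <- match(records_a$predictor_id, records_b$predictor_id)
  keep <- which(!is.na(idx))
  if (length(keep) < 3) stop("need >= 3 matched predictors", call. = FALSE)
  ba <- records_a$beta[keep]
  bb <- records_b$beta[idx[keep]]
  if (!is.null(records_a$effect_allele) && !is.null(records_b$effect_allele)) {
    flip <- records_a$effect_allele[keep] !=
      records_b$effect_allele[idx[keep]]
    bb[flip] <- -bb[flip]
  }
  list(r = stats::cor(ba, bb),
       slope = stats::cov(ba, bb) / stats::var(ba),
       n_matched = length(keep))
}

#' Read a PRS weight file
#'
#' Three-column whitespace/tab-separated text: variant id, effect allele,
#' per-allele weight (score-file dialect).
#'
#' @param path File path.
#' @return Data frame `id`, `effect_allele`, `weight`.
#' @export
read_prs_weights <- function(path) {
  w <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(w) >= 3)
  data.frame(id = as.character(w[[1]]), effect_allele = as.character(w[[2]]),
             weight = as.numeric(w[[3]]), stringsAsFactors = FALSE)
}
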