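#' Global ancestry fraction from local-ancestry calls
#'
#' Mean of the diploid African-allele fraction (count/2) over markers called
#' with posterior probability above the cutoff.
#'
#' @param local A `"local_ancestry"` object.
#' @param posterior_min Posterior cutoff (markers at or below it are
#'   excluded; default 0.9).
#' @return Numeric vector, one fraction per individual.
#' @export
global_ancestry <- function(local, posterior_min = 0.9) {
  stopifnot(inherits(local, "local_ancestry"))
  qual <- local$posterior > posterior_min
  n_ok <- rowSums(qual)
  if (any(n_ok == 0))
    stop("no markers above the posterior cutoff for individual(s): ",
         paste(local$individual_id[n_ok == 0], collapse = ", "),
         call. = FALSE)
  rowSums((local$counts / 2) * qual) / n_ok
}

#' Admixture mapping: per-marker local-ancestry association
#'
#' Linear regression of the phenotype on the local African-ancestry count at
#' each marker, with the global ancestry proportion and the Duffy-null
#' genotype (additive count plus heterozygote indicator) as covariates.
#' Markers with posterior calls at or below the cutoff are excluded per
#' individual by dropping those individuals for that marker.
#'
#' @param y Phenotype (residual copy number).
#' @param local A `"local_ancestry"` object.
#' @param global_fraction Per-individual global ancestry (computed via
#'   [global_ancestry()] when `NULL`).
#' @param duffy Duffy-null allele counts in `{0,1,2}`, or `NULL` to omit.
#' @param posterior_min Posterior cutoff.
#' @return Data frame of association records with `chrom` and `pos`;
#'   monomorphic markers are flagged with `p = NA`.
#' @export
local_ancestry_assoc <- function(y, local, global_fraction = NULL,
                                 duffy = NULL, posterior_min = 0.9) {
  stopifnot(inherits(local, "local_ancestry"))
  if (is.null(global_fraction))
    global_fraction <- global_ancestry(local, posterior_min)
  C <- cbind(`(Intercept)` = 1, global = global_fraction)
  if (!is.null(duffy))
    C <- cbind(C, duffy_add = duffy, duffy_het = as.numeric(duffy == 1))
  m <- ncol(local$counts)
  out <- vector("list", m)
  for (j in seq_len(m)) {
    ok <- local$posterior[, j] > posterior_min & is.finite(y)
    xj <- local$counts[ok, j]
    if (length(unique(xj)) < 2) {
      out[[j]] <- assoc_record(paste0("marker_", j), "y", NA_real_, NA_real_,
                               NA_real_, sum(ok), "linear")
      next
    }
    X <- cbind(C[ok, , drop = FALSE], local = xj)
    fit <- tryCatch(fast_lm(y[ok], X), error = function(e) NULL)
    out[[j]] <- if (is.null(fit)) {
      assoc_record(paste0("marker_", j), "y", NA_real_, NA_real_, NA_real_,
                   sum(ok), "linear")
    } else {
      k <- ncol(X)
      assoc_record(paste0("marker_", j), "y", fit$beta[k], fit$se[k],
                   fit$p[k], sum(ok), "linear")
    }
  }
  res <- do.call(rbind, out)
  res$chrom <- local$map$chrom
  res$pos <- local$map$pos
  rownames(res) <- NULL
  res
}

#' Effective sample size of an autocorrelated series
#'
#' Spectral effective size: `N * var(x) / s(0)`, where `s(0)` is the spectral
#' density at frequency zero of an autoregressive fit with Yule-Walker
#' estimates and AIC order selection (order cap `10 log10(N)`). A constant
#' series returns `N` by convention; the result is capped at `N`.
#'
#' @param x Numeric series (length >= 10).
#' @return Effective sample size in `(0, N]`.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10) stop("series must have length >= 10", call. = FALSE)
  v <- stats::var(x)
  if (!is.finite(v)) stop("series must have finite variance", call. = FALSE)
  if (v == 0) return(n)
  fit <- stats::ar(x, aic = TRUE, order.max = floor(10 * log10(n)),
                   method = "yule-walker")
  if (fit$order == 0) return(n)
  spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
  min(n, n * v / spec0)
}

#' Effective number of admixture-mapping tests
#'
#' For each individual and chromosome, the effective sample size of the
#' diploid local-ancestry series (count/2) along marker order; these are
#' summed over chromosomes per individual, and the cohort mean is the
#' effective number of tests. The genome-wide threshold is `0.05 / N_eff`.
#' A chromosome with a constant ancestry series counts as a single effective
#' test (perfect autocorrelation), unlike the standalone
#' [effective_sample_size()] convention for constant input.
#'
#' @param local A `"local_ancestry"` object.
#' @param posterior_min Posterior cutoff for including a marker in the
#'   series.
#' @param alpha Family-wise level for the derived threshold.
#' @return List of class `"effective_tests"`: `per_individual` (genome sums),
#'   `n_eff`, `threshold`, and the per-(individual, chromosome) matrix.
#' @export
effective_tests <- function(local, posterior_min = 0.9, alpha = 0.05) {
  stopifnot(inherits(local, "local_ancestry"))
  chroms <- unique(local$map$chrom)
  n <- nrow(local$counts)
  ess <- matrix(NA_real_, n, length(chroms),
                dimnames = list(NULL, paste0("chr", chroms)))
  for (ci in seq_along(chroms)) {
    cols <- which(local$map$chrom == chroms[ci])
    for (i in seq_len(n)) {
      ok <- local$posterior[i, cols] > posterior_min
      series <- local$counts[i, cols[ok]] / 2
      # a constant chromosome is perfectly autocorrelated: one effective test
      ess[i, ci] <- if (stats::var(series) == 0) 1
                    else if (length(series) >= 10) effective_sample_size(series)
                    else length(series)
    }
  }
  genome <- rowSums(ess)
  n_eff <- mean(genome)
  structure(list(per_chromosome = ess, per_individual = genome,
                 n_eff = n_eff, threshold = alpha / n_eff),
            class = "effective_tests")
}
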