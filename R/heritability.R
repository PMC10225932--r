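#' Build a genetic relationship matrix
#'
#' Standard GRM: entry (j, k) is the mean over variants of
#' `(x_ij - 2 f_i)(x_ik - 2 f_i) / (2 f_i (1 - f_i))`, with in-sample allele
#' frequencies. Variants below the minor-allele-frequency cutoff (and
#' monomorphic variants) are excluded.
#'
#' @param genotypes A `"genotype_matrix"` or a plain dosage matrix
#'   (individuals x variants, values in `[0, 2]`).
#' @param maf_min Minor-allele-frequency cutoff (default 0.01).
#' @return List of class `"grm"`: `A` (n x n), `m` (variants used), `freq`.
#' @export
build_grm <- function(genotypes, maf_min = 0.01) {
  D <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
       else as.matrix(genotypes)
  f <- colMeans(D) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= maf_min & maf > 0
  if (sum(!keep) > 0)
    message(sum(!keep), " variant(s) excluded (monomorphic or MAF < ",
            maf_min, ")")
  if (sum(keep) < 2) stop("fewer than 2 variants after MAF filtering",
                          call. = FALSE)
  D <- D[, keep, drop = FALSE]; f <- f[keep]
  Z <- sweep(D, 2, 2 * f, "-")
  Z <- sweep(Z, 2, sqrt(2 * f * (1 - f)), "/")
  structure(list(A = tcrossprod(Z) / ncol(Z), m = ncol(Z), freq = f),
            class = "grm")
}

# internal: residualize on covariates (with intercept) and standardize
prep_h2_pheno <- function(y, covariates) {
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  r <- fast_lm(y, X)$residuals
  r / stats::sd(r)
}

#' Haseman-Elston SNP heritability
#'
#' Regresses pairwise phenotype cross-products on off-diagonal GRM entries
#' after residualizing the phenotype on covariates and standardizing it. The
#' slope estimates the SNP heritability; its standard error comes from a
#' block jackknife over individuals.
#'
#' @param y Phenotype vector.
#' @param grm A [build_grm()] object.
#' @param covariates Optional covariate matrix (fixed effects).
#' @param n_blocks Jackknife blocks (default 50).
#' @return Data frame of class `"h2_estimate"`: `h2`, `se`, `ci_lo`, `ci_hi`,
#'   `method`, `covariate_set`.
#' @export
estimate_h2_he <- function(y, grm, covariates = NULL, n_blocks = 50L) {
  stopifnot(inherits(grm, "grm"))
  n <- length(y)
  if (n < 100) warning("n < 100: HE regression will be unstable")
  ys <- prep_h2_pheno(y, covariates)
  A <- grm$A
  if (any(!is.finite(A))) stop("degenerate GRM", call. = FALSE)
  P <- tcrossprod(ys)
  Q <- A * P; G2 <- A * A
  diag(Q) <- 0; diag(G2) <- 0
  S1 <- sum(Q) / 2; S2 <- sum(G2) / 2
  if (S2 <= 0) stop("degenerate GRM: no off-diagonal variation", call. = FALSE)
  h2 <- S1 / S2

  # delete-a-block jackknife on the pair sums
  blocks <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
  r1 <- rowSums(Q); r2 <- rowSums(G2)
  theta <- vapply(blocks, function(B) {
    s1 <- S1 - sum(r1[B]) + sum(Q[B, B]) / 2
    s2 <- S2 - sum(r2[B]) + sum(G2[B, B]) / 2
    s1 / s2
  }, numeric(1))
  g <- length(theta)
  se <- sqrt((g - 1) / g * sum((theta - mean(theta))^2))
  structure(data.frame(component = "genome", h2 = h2, se = se,
                       ci_lo = h2 - 1.96 * se, ci_hi = h2 + 1.96 * se,
                       method = "HE",
                       covariate_set = if (is.null(covariates)) "none"
                                       else "supplied",
                       stringsAsFactors = FALSE),
            class = c("h2_estimate", "data.frame"))
}

#' Average-information REML variance components
#'
#' Fits `y = X b + sum_k g_k + e` with `g_k ~ N(0, sigma2_k A_k)` by
#' average-information REML, with an expectation-maximization first step for
#' stability and non-negativity enforced by projection to a small positive
#' floor. Reports each component's variance fraction with a delta-method
#' standard error from the inverse average-information matrix.
#'
#' @param y Phenotype vector.
#' @param grms A single [build_grm()] object or a (optionally named) list of
#'   them (e.g. one per chromosome; at most 25).
#' @param covariates Optional fixed-effect covariate matrix.
#' @param max_iter Iteration cap (default 100).
#' @param tol Relative convergence tolerance on the variance components.
#' @return Data frame of class `"h2_estimate"`, one row per genetic
#'   component (plus attributes `varcomp` and `loglik`).
#' @export
estimate_h2_reml <- function(y, grms, covariates = NULL, max_iter = 100L,
                             tol = 1e-6) {
  if (inherits(grms, "grm")) grms <- list(genome = grms)
  K <- length(grms)
  stopifnot(K >= 1, K <= 25)
  if (is.null(names(grms))) names(grms) <- paste0("component", seq_len(K))
  n <- length(y)
  if (n < 200) warning("n < 200: REML estimates will be unstable")
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  As <- lapply(grms, `[[`, "A")
  vy <- stats::var(y)
  theta <- rep(vy / (K + 1), K + 1)   # genetic components then residual
  floor_v <- 1e-6 * vy
  ll_old <- -Inf

  for (it in seq_len(max_iter)) {
    V <- diag(theta[K + 1], n)
    for (k in seq_len(K)) V <- V + theta[k] * As[[k]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) stop("REML failed: V not positive definite", call. = FALSE)
    Vinv <- chol2inv(ch)
    VinvX <- Vinv %*% X
    XtVinvX <- crossprod(X, VinvX)
    Pmat <- Vinv - VinvX %*% solve(XtVinvX, t(VinvX))
    Py <- Pmat %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                  determinant(XtVinvX, logarithm = TRUE)$modulus +
                  sum(y * Py))

    APy <- lapply(As, function(A) A %*% Py)
    APy[[K + 1]] <- Py
    grad <- numeric(K + 1)
    for (k in seq_len(K))
      grad[k] <- -0.5 * (sum(Pmat * As[[k]]) - sum(Py * APy[[k]]))
    grad[K + 1] <- -0.5 * (sum(diag(Pmat)) - sum(Py * Py))

    AI <- matrix(0, K + 1, K + 1)
    PAPy <- lapply(APy, function(v) Pmat %*% v)
    for (k in seq_len(K + 1))
      for (l in k:(K + 1)) {
        AI[k, l] <- 0.5 * sum(APy[[k]] * PAPy[[l]])
        AI[l, k] <- AI[k, l]
      }

    step <- if (it == 1) {
      # EM step: robust far from the optimum
      th <- theta
      for (k in seq_len(K))
        th[k] <- theta[k] + theta[k]^2 *
          (sum(Py * APy[[k]]) - sum(Pmat * As[[k]])) / n
      th[K + 1] <- theta[K + 1] + theta[K + 1]^2 *
        (sum(Py * Py) - sum(diag(Pmat))) / n
      th - theta
    } else {
      as.numeric(solve(AI, grad))
    }
    theta_new <- pmax(theta + step, floor_v)
    delta <- max(abs(theta_new - theta) / (abs(theta) + floor_v))
    theta <- theta_new
    if (it > 1 && (delta < tol || abs(ll - ll_old) < 1e-8)) {
      ll_old <- ll
      break
    }
    ll_old <- ll
    if (it == max_iter)
      stop("REML did not converge in ", max_iter,
           " iterations; last components: ",
           paste(signif(theta, 4), collapse = ", "), call. = FALSE)
  }

  Sigma <- tryCatch(solve(AI), error = function(e) matrix(NA, K + 1, K + 1))
  total <- sum(theta)
  out <- lapply(seq_len(K), function(k) {
    h2 <- theta[k] / total
    # delta method for theta_k / sum(theta)
    gvec <- rep(-theta[k] / total^2, K + 1)
    gvec[k] <- gvec[k] + 1 / total
    se <- sqrt(max(0, as.numeric(t(gvec) %*% Sigma %*% gvec)))
    data.frame(component = names(grms)[k], h2 = h2, se = se,
               ci_lo = h2 - 1.96 * se, ci_hi = h2 + 1.96 * se,
               method = "REML",
               covariate_set = if (is.null(covariates)) "none" else "supplied",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "varcomp") <- theta
  attr(res, "loglik") <- as.numeric(ll_old)
  class(res) <- c("h2_estimate", "data.frame")
  res
}

#' Heritability under a sequence of covariate sets
#'
#' Re-estimates SNP heritability with the same GRM under each labeled
#' fixed-effect design, reporting the change relative to the first set — the
#' experiment showing whether candidate covariates (Duffy genotype, admixture
#' hits, polygenic scores) absorb the heritable signal.
#'
#' @param y Phenotype vector.
#' @param grm A [build_grm()] object.
#' @param covariate_sets Named list of covariate matrices (`NULL` elements
#'   allowed for "no covariates").
#' @param method `"HE"` or `"REML"`.
#' @return Data frame with one row per set: `h2`, `se`, `delta_vs_first`.
#' @export
covariate_attenuation <- function(y, grm, covariate_sets,
                                  method = c("HE", "REML")) {
  method <- match.arg(method)
  stopifnot(length(covariate_sets) >= 1)
  if (is.null(names(covariate_sets)))
    names(covariate_sets) <- paste0("set", seq_along(covariate_sets))
  est <- lapply(names(covariate_sets), function(nm) {
    cv <- covariate_sets[[nm]]
    e <- if (method == "HE") estimate_h2_he(y, grm, cv)
         else estimate_h2_reml(y, grm, cv)
    e$covariate_set <- nm
    e
  })
  res <- do.call(rbind, est)
  res$delta_vs_first <- res$h2 - res$h2[1]
  rownames(res) <- NULL
  res
}
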