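#' Assign case/control/missing status from phecode occurrence counts
#'
#' An individual is a case for a phecode if it occurs at least twice in their
#' record, a control if it never occurs, and missing if it occurs exactly
#' once (single mentions are treated as unreliable).
#'
#' @param counts Matrix (individuals x phecodes) of nonnegative integer
#'   occurrence counts.
#' @return Matrix of the same shape: 1 = case, 0 = control, `NA` = missing.
#' @export
assign_case_control <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("occurrence counts must be nonnegative integers", call. = FALSE)
  status <- matrix(NA_real_, nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  status[counts == 0] <- 0
  status[counts >= 2] <- 1
  status
}

#' Filter phecodes by minimum case count per cohort
#'
#' A phecode is retained only if its case count strictly exceeds `min_cases`
#' in every cohort analyzed.
#'
#' @param status Case/control matrix from [assign_case_control()].
#' @param cohort_labels Factor/character vector of cohort membership per
#'   individual; `NULL` treats all individuals as one cohort.
#' @param min_cases Threshold (default 20; strictly more than this many cases
#'   required).
#' @return Character vector of retained phecode names (column indices if
#'   unnamed).
#' @export
filter_phecodes <- function(status, cohort_labels = NULL, min_cases = 20L) {
  status <- as.matrix(status)
  if (is.null(colnames(status)))
    colnames(status) <- as.character(seq_len(ncol(status)))
  if (is.null(cohort_labels)) cohort_labels <- rep("all", nrow(status))
  keep <- rep(TRUE, ncol(status))
  for (g in unique(cohort_labels)) {
    cases <- colSums(status[cohort_labels == g, , drop = FALSE] == 1,
                     na.rm = TRUE)
    keep <- keep & (cases > min_cases)
  }
  colnames(status)[keep]
}

#' Collapse repeated lab measurements to per-individual medians
#'
#' @param labs Long-format data frame with columns `individual_id`, `lab`,
#'   `value`.
#' @return Data frame `individual_id`, `lab`, `value` with one row per
#'   (individual, lab), the median of the repeats.
#' @export
collapse_median <- function(labs) {
  stopifnot(all(c("individual_id", "lab", "value") %in% names(labs)))
  agg <- stats::aggregate(value ~ individual_id + lab, data = labs,
                          FUN = stats::median)
  agg[order(agg$lab, agg$individual_id), , drop = FALSE]
}

#' Remove extreme outliers by a single standard-deviation pass
#'
#' One pass on the raw scale: values more than `k` standard deviations from
#' the mean — both computed on the full input — are removed. The pass is
#' deliberately not iterated; repeating it could remove additional values.
#'
#' @param values Numeric vector (>= 3 values).
#' @param k SD multiple (default 7).
#' @return List with `values` (kept), `removed` (indices into the input), and
#'   `n_removed`.
#' @export
trim_outliers <- function(values, k = 7) {
  stopifnot(length(values) >= 3)
  if (k == 0) warning("k = 0 removes every value not equal to the mean")
  m <- mean(values); s <- stats::sd(values)
  removed <- if (s == 0) integer(0) else which(abs(values - m) > k * s)
  list(values = if (length(removed)) values[-removed] else values,
       removed = removed, n_removed = length(removed))
}

#' Box-Cox transform a lab measurement given covariates
#'
#' Chooses the power `lambda` maximizing the Box-Cox profile log-likelihood
#' of a linear model of the transformed value on age, age squared, sex and
#' the genetic PCs, searched on a grid over `[-3, 3]` in steps of 0.01 with a
#' quadratic refinement around the grid maximum. The transform is
#' `(y^lambda - 1)/lambda` (log for `lambda = 0`).
#'
#' @param y Positive lab values.
#' @param covariates Data frame or matrix of covariates (e.g. sex, age, PCs);
#'   age is expanded to age + age^2 when a column named `age` is present.
#' @return List with `lambda` and `transformed`.
#' @export
boxcox_transform <- function(y, covariates = NULL) {
  if (any(y <= 0))
    stop("Box-Cox requires strictly positive values; ",
         "offset or exclude nonpositive measurements before transforming",
         call. = FALSE)
  if (is.null(covariates)) {
    X <- matrix(1, length(y), 1)
  } else {
    covariates <- as.data.frame(covariates)
    if ("age" %in% names(covariates)) covariates$age2 <- covariates$age^2
    X <- stats::model.matrix(~ ., data = covariates)
  }
  # keep the response and qr in the fit so the profile is computed without
  # re-evaluating the call in this function's environment
  fit <- stats::lm(y ~ X - 1, y = TRUE, qr = TRUE)
  grid <- seq(-3, 3, by = 0.01)
  prof <- MASS::boxcox(fit, lambda = grid, plotit = FALSE)
  i <- which.max(prof$y)
  lambda <- prof$x[i]
  # quadratic refinement through the maximum and its neighbors
  if (i > 1 && i < length(prof$x)) {
    xs <- prof$x[(i - 1):(i + 1)]; ys <- prof$y[(i - 1):(i + 1)]
    co <- stats::coef(stats::lm(ys ~ xs + I(xs^2)))
    if (is.finite(co[3]) && co[3] < 0) {
      cand <- -co[2] / (2 * co[3])
      if (cand >= xs[1] && cand <= xs[3]) lambda <- as.numeric(cand)
    }
  }
  transformed <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  list(lambda = lambda, transformed = transformed)
}

#' Prepare a lab table: collapse, trim, transform
#'
#' Runs the standard preparation for each lab independently: collapse repeats
#' to medians, trim values more than `trim_sd` SDs from the mean in a single
#' pass, then Box-Cox transform against the covariate model.
#'
#' @param labs Long-format data frame (`individual_id`, `lab`, `value`).
#' @param covariates Data frame of covariates indexed by `individual_id`.
#' @param trim_sd SD multiple for outlier removal.
#' @return Data frame `individual_id`, `lab`, `value`, `transformed` with the
#'   per-lab `lambda` in attribute `"lambda"`.
#' @export
prep_labs <- function(labs, covariates = NULL, trim_sd = 7) {
  med <- collapse_median(labs)
  out <- list(); lambdas <- c()
  for (lb in unique(med$lab)) {
    d <- med[med$lab == lb, , drop = FALSE]
    tr <- trim_outliers(d$value, k = trim_sd)
    if (tr$n_removed) d <- d[-tr$removed, , drop = FALSE]
    cv <- NULL
    if (!is.null(covariates)) {
      idx <- match(d$individual_id, covariates$individual_id)
      cv <- covariates[idx, setdiff(names(covariates), "individual_id"),
                       drop = FALSE]
    }
    bc <- boxcox_transform(d$value, cv)
    d$transformed <- bc$transformed
    lambdas[lb] <- bc$lambda
    out[[lb]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "lambda") <- lambdas
  res
}
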