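#' Derive a reproducible sub-seed for a named stage
#'
#' A single pipeline seed is expanded into independent per-stage seeds so that
#' any stage can be rerun in isolation and still produce the same stream it
#' would have seen inside the full pipeline.
#'
#' @param seed Integer master seed.
#' @param stage Character scalar naming the stage (e.g. `"cohort"`,
#'   `"depth"`).
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small multiplicative hash of the stage label, kept inside 32-bit range
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647)
}

# internal: stop with a configuration error naming the offending field
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

# internal: fast OLS of y on design X returning beta, se, t, p for every column
# X must be full rank; used by the scan code paths where lm() overhead matters.
fast_lm <- function(y, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(s2 * diag(XtX_inv))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(beta = as.numeric(beta), se = se, t = as.numeric(tval), p = p,
       df = df, sigma2 = s2, residuals = as.numeric(res))
}

# internal: one-row association record
assoc_record <- function(predictor_id, trait_id, beta, se, p, n, model,
                         covariate_set = "default", cohort = NA_character_) {
  data.frame(predictor_id = predictor_id, trait_id = trait_id,
             beta = beta, se = se, p = p, n = n, model = model,
             covariate_set = covariate_set, cohort = cohort,
             stringsAsFactors = FALSE)
}

#' Write a data frame as a tab-separated table
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-separated table with a header row
#'
#' @param path Input path.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
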