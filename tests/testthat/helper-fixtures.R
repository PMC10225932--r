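# Shared fixtures for the test suite. Everything is generated in code; no
# stored data.

quiet <- function(expr) suppressMessages(expr)

# small cohort reused across tests
make_cohort <- function(n = 500, seed = 42, ...) {
  simulate_cohort(cohort_config(n_individuals = n, seed = seed, ...))
}

# constant-depth profile for closed-form ratio checks
make_profile <- function(mt = 10, auto = 5, n_sites = 100,
                         id = "toy") {
  depth_profile(id, rep(mt, n_sites), rep(auto, n_sites))
}

# Monte-Carlo oracle for replication power: brute-force simulation of the
# marginal regression of a unit-variance-noise trait on a Hardy-Weinberg
# dosage, entirely independent of replication_power()'s closed form.
mc_replication_power <- function(beta, f, n, sigma, alpha, reps = 10000,
                                 chunk = 500) {
  hits <- 0
  done <- 0
  while (done < reps) {
    b <- min(chunk, reps - done)
    X <- matrix(stats::rbinom(n * b, 2, f), n, b)
    Y <- beta * X + matrix(stats::rnorm(n * b, 0, sigma), n, b)
    sx <- colSums(X); sy <- colSums(Y)
    sxx <- colSums(X^2) - sx^2 / n
    sxy <- colSums(X * Y) - sx * sy / n
    syy <- colSums(Y^2) - sy^2 / n
    bhat <- sxy / sxx
    s2 <- (syy - bhat * sxy) / (n - 2)
    tval <- bhat / sqrt(s2 / sxx)
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
    hits <- hits + sum(p < alpha)
    done <- done + b
  }
  hits / reps
}
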