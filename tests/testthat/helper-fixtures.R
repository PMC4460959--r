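# Shared fixtures: built in code, cached per test run.

.fixture_env <- new.env(parent = emptyenv())

# small synthetic cohort used by most module tests (fast to generate)
small_cfg <- function(seed = 7, ...) {
  sim_config(n_tumor = 60, n_normal = 20, n_probes = 300,
             probes_per_chrom = 300, n_driver_probes = 10, n_masked = 5,
             n_decoy_tfs = 40, seed = seed, ...)
}

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_cohort(small_cfg())
  }
  .fixture_env$small
}

# brute-force one-sided Mann-Whitney (alternative: x stochastically below y)
# by exhaustive enumeration of group assignments; requires no ties
enum_utest <- function(x, y) {
  m <- length(x); n <- length(y)
  comb <- c(x, y)
  ustat <- function(idx) {
    xs <- comb[idx]; ys <- comb[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- ustat(seq_len(m))
  all_u <- utils::combn(m + n, m, ustat)
  mean(all_u <= u_obs)
}

# brute-force Benjamini-Hochberg: sort, n*p/i, cumulative min from the tail
enum_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(n * p[o] / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  out
}

# independently coded Welch t-test lower-tail p
welch_p_less <- function(x, y) {
  m <- length(x); n <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / m + vy / n
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / m)^2 / (m - 1) + (vy / n)^2 / (n - 1))
  stats::pt(t, df)
}
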