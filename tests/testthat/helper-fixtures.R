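# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Default synthetic study (default design, seed 101) with fractions, both
# EWAS fits and the consensus precomputed.  ~3 s, cached.
default_fixture <- function() {
  if (is.null(.fixture_env$ds)) {
    ds <- simulate_dataset(sim_design(seed = 101))
    ref <- ds$truth$profiles[ds$truth$cpg$is_reference, ]
    ds$fractions <- estimate_cell_fractions(ds$cord, ref)
    ds$r1 <- fit_ewas(ds$cord, ds$sheet, ds$fractions, ewas_model_spec("model1"))
    ds$r2 <- fit_ewas(ds$cord, ds$sheet, ds$fractions, ewas_model_spec("model2"))
    ds$consensus <- intersect_models(ds$r1, ds$r2, 0.05)
    .fixture_env$ds <- ds
  }
  .fixture_env$ds
}

# Small deterministic cord-only sample sheet for exact-arithmetic OLS tests.
# Covariate patterns are pseudo-random (fixed local seed) so the full
# Model 2 design stays full-rank even at n = 12.
tiny_sheet <- function(n = 12L) {
  withr::with_seed(424242L, validate_sample_sheet(data.frame(
    sample_id = sprintf("s%02d", 1:n),
    subject_id = sprintf("t%02d", 1:n),
    tissue = "cord",
    ga_weeks = round(runif(n, 24, 41), 1),
    bw_sd_score = round(rnorm(n, -0.5, 1.2), 2),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4)),
    batch = rep(c("B1", "B1", "B2"), length.out = n),
    cam = rbinom(n, 1L, 0.4),
    iprom = rbinom(n, 1L, 0.3),
    preeclampsia = rbinom(n, 1L, 0.3),
    smoke_before = rbinom(n, 1L, 0.3),
    maternal_bmi = round(runif(n, 17, 29), 1),
    cesarean = rbinom(n, 1L, 0.5),
    stringsAsFactors = FALSE)))
}

# Brute-force BH step-up by the textbook definition (independent oracle).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  q[order(o)]
}

# Hypergeometric upper-tail by enumeration (oracle for enrichment p-values):
# P(X >= k) with X ~ Hypergeom(white = s, black = N - s, drawn = n).
hyper_tail_oracle <- function(k, s, N, n) {
  kk <- max(k, 0):min(s, n)
  sum(choose(s, kk) * choose(N - s, n - kk)) / choose(N, n)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
# (sum of all tables with probability <= observed, with fisher.test's
# relative tolerance).
fisher_oracle <- function(a, b, c_, d) {
  m1 <- a + b; n1 <- c_ + d; k <- a + c_
  support <- max(0, k - n1):min(m1, k)
  pr <- dhyper(support, m1, n1, k)
  p0 <- dhyper(a, m1, n1, k)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}
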