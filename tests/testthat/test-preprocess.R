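# Beta formula, QC filtering rule order, constrained deconvolution.

test_that("compute_beta evaluates the offset formula and is monotone", {
  expect_equal(compute_beta(0, 0), 0)
  expect_equal(compute_beta(900, 0), 0.9)
  expect_equal(compute_beta(100, 100), 1 / 3)
  expect_error(compute_beta(-1, 5), "non-negative")

  set.seed(42)
  M <- runif(50, 0, 5000); U <- runif(50, 0, 5000)
  b <- compute_beta(M, U)
  expect_true(all(b >= 0 & b < 1))
  expect_true(all(compute_beta(M + 10, U) > b))   # increasing in M
  expect_true(all(compute_beta(M, U + 10) < b))   # decreasing in U
})

make_filter_fixture <- function() {
  man <- data.frame(
    probe_id = sprintf("cg%02d", 1:10),
    chrom = c("chr1", "chrX", "chr2", "chrX", "chr3", "chr1", "chr2", "chr3",
              "chr1", "chr2"),
    pos = 1:10 * 100L, gene = "", gene_region = "IGR",
    island_relation = "OpenSea", chromstate_T = "Quies",
    chromstate_B = "Quies", is_cpg = 1L, stringsAsFactors = FALSE)
  qc <- expand.grid(probe_id = man$probe_id, sample_id = c("s1", "s2"),
                    stringsAsFactors = FALSE)
  qc$detection_p <- 0; qc$beadcount <- 10L
  qc$detection_p[qc$probe_id == "cg05" & qc$sample_id == "s2"] <- 0.02
  list(man = man, qc = qc)
}

test_that("filter_probes applies rules in order with first-rule attribution", {
  fx <- make_filter_fixture()
  res <- filter_probes(fx$man, fx$qc,
                       blacklists = list(multi_mapping = "cg07",
                                         cross_reactive = character()))
  # 2 on chrX, 1 detection failure (any-sample policy), 1 blacklisted
  expect_equal(unname(res$report[c("sex_chromosome", "detection",
                                   "multi_mapping", "survivors")]),
               c(2L, 1L, 1L, 6L))
  expect_length(res$kept, 6L)
  expect_false(any(c("cg02", "cg04", "cg05", "cg07") %in% res$kept))

  # probe failing detection AND blacklisted is attributed to detection only
  res2 <- filter_probes(fx$man, fx$qc,
                        blacklists = list(multi_mapping = "cg05",
                                          cross_reactive = character()))
  expect_equal(unname(res2$report[["detection"]]), 1L)
  expect_equal(unname(res2$report[["multi_mapping"]]), 0L)
})

test_that("filter_probes keeps clean probes, is idempotent, checks policy", {
  fx <- make_filter_fixture()
  auto <- fx$man[!fx$man$chrom %in% c("chrX", "chrY"), ]
  qc <- fx$qc[fx$qc$probe_id %in% auto$probe_id, ]
  qc$detection_p <- 0
  res <- filter_probes(auto, qc)
  expect_setequal(res$kept, auto$probe_id)

  again <- filter_probes(auto[auto$probe_id %in% res$kept, ],
                         qc[qc$probe_id %in% res$kept, ])
  expect_identical(sort(again$kept), sort(res$kept))

  expect_error(filter_probes(fx$man, fx$qc, policy = list(detection = "sometimes")),
               "unknown detection policy")
  # fraction policy tolerates a single failing sample out of two at f = 0.6
  res3 <- filter_probes(fx$man, fx$qc,
                        policy = list(detection = "fraction",
                                      detection_fraction = 0.6))
  expect_equal(unname(res3$report[["detection"]]), 0L)
})

test_that("non-CpG probes drop by manifest flag or id prefix", {
  fx <- make_filter_fixture()
  fx$man$is_cpg[1] <- 0L
  res <- filter_probes(fx$man, NULL)
  expect_equal(unname(res$report[["non_cpg"]]), 1L)
  man2 <- fx$man[, setdiff(names(fx$man), "is_cpg")]
  man2$probe_id[2] <- "ch.01.123"
  man2 <- man2[man2$chrom != "chrX" | man2$probe_id == "ch.01.123", ]
  res2 <- filter_probes(man2, NULL)
  expect_equal(unname(res2$report[["non_cpg"]]), 1L)
})

test_that("deconvolution recovers noiseless mixtures and vertices", {
  ds <- default_fixture()
  ref <- ds$truth$profiles[ds$truth$cpg$is_reference, ]
  w <- c(0.2, 0.1, 0.05, 0.15, 0.3, 0.1, 0.1)
  y <- as.vector(ref %*% w)
  beta <- matrix(y, dimnames = list(rownames(ref), "mix1"))
  est <- estimate_cell_fractions(beta, ref)
  expect_equal(unname(unlist(est[1, CELL_TYPES])), w, tolerance = 1e-4)
  expect_lt(est$residual_norm, 1e-8)

  vert <- matrix(ref[, "NK"], dimnames = list(rownames(ref), "pureNK"))
  est_v <- estimate_cell_fractions(vert, ref)
  expect_gt(est_v$NK, 0.99)
  expect_lt(max(unlist(est_v[1, setdiff(CELL_TYPES, "NK")])), 0.01)
})

test_that("constrained solution beats every simplex vertex", {
  ds <- default_fixture()
  ref <- ds$truth$profiles[ds$truth$cpg$is_reference, ]
  set.seed(8)
  w <- as.vector(rbeta(7, 2, 2)); w <- w / sum(w)
  y <- plogis(qlogis(as.vector(ref %*% w)) + rnorm(nrow(ref), 0, 0.2))
  beta <- matrix(y, dimnames = list(rownames(ref), "s"))
  est <- estimate_cell_fractions(beta, ref)
  vertex_res <- apply(diag(7), 2L, function(v) sqrt(sum((y - ref %*% v)^2)))
  expect_lte(est$residual_norm, min(vertex_res) + 1e-10)
})

test_that("rank-deficient reference is rejected with advice", {
  ref <- matrix(runif(14), 2, 7, dimnames = list(c("cg1", "cg2"), CELL_TYPES))
  beta <- matrix(c(0.4, 0.5), dimnames = list(c("cg1", "cg2"), "s"))
  expect_error(estimate_cell_fractions(beta, ref), "at least as many")
  ref2 <- default_fixture()$truth$profiles[default_fixture()$truth$cpg$is_reference, ]
  ref2[, "CD8T"] <- ref2[, "CD4T"]
  beta2 <- matrix(ref2[, 1], dimnames = list(rownames(ref2), "s"))
  expect_error(estimate_cell_fractions(beta2, ref2), "rank-deficient")
})

test_that("noisy mixtures recover with small per-fraction error", {
  ds <- default_fixture()
  ref <- ds$truth$profiles[ds$truth$cpg$is_reference, ]
  set.seed(17)
  n <- 50L
  W <- t(vapply(seq_len(n), function(i) {
    w <- rbeta(7, 2, 2); w / sum(w)
  }, numeric(7)))
  Y <- plogis(qlogis(ref %*% t(W)) + matrix(rnorm(nrow(ref) * n, 0, 0.05),
                                            nrow(ref)))
  colnames(Y) <- sprintf("s%02d", seq_len(n))
  est <- estimate_cell_fractions(Y, ref)
  mae <- mean(abs(as.matrix(est[, CELL_TYPES]) - W))
  expect_lt(mae, 0.05)
})
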