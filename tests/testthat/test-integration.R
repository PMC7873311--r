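# Cis matching, transcript association, methylation-expression correlation.

test_that("cis window boundary is inclusive at exactly 250 kb", {
  cpg_man <- data.frame(probe_id = "cg01", chrom = "chr1", pos = 1000000L,
                        gene = "A", gene_region = "TSS200",
                        island_relation = "Island",
                        chromstate_T = "TssA", chromstate_B = "TssA",
                        stringsAsFactors = FALSE)
  expr_man <- data.frame(
    expr_probe_id = c("xpIN", "xpOUT", "xpCHR"),
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(1250000L, 1250001L, 1250000L), gene = "A",
    stringsAsFactors = FALSE)
  pairs <- match_cis_pairs("cg01", cpg_man, expr_man, window = 250000L)
  expect_equal(pairs$expr_probe_id, "xpIN")
  expect_equal(pairs$distance, 250000L)
  up <- expr_man; up$pos <- c(750000L, 749999L, 750000L)
  pairs_up <- match_cis_pairs("cg01", cpg_man, up, window = 250000L)
  expect_equal(pairs_up$expr_probe_id, "xpIN")
  expect_equal(pairs_up$distance, -250000L)
})

test_that("match_cis_pairs equals a brute-force all-pairs scan", {
  set.seed(14)
  nc <- 400L; ne <- 150L
  cpg_man <- data.frame(
    probe_id = sprintf("cg%04d", 1:nc),
    chrom = sample(paste0("chr", 1:3), nc, replace = TRUE),
    pos = sample.int(2000000L, nc), gene = "", gene_region = "IGR",
    island_relation = "OpenSea", chromstate_T = "Quies",
    chromstate_B = "Quies", stringsAsFactors = FALSE)
  expr_man <- data.frame(
    expr_probe_id = sprintf("xp%04d", 1:ne),
    chrom = sample(paste0("chr", 1:3), ne, replace = TRUE),
    pos = sample.int(2000000L, ne), gene = "g", stringsAsFactors = FALSE)
  w <- 100000L
  got <- match_cis_pairs(cpg_man$probe_id, cpg_man, expr_man, w)
  brute <- do.call(rbind, lapply(seq_len(nc), function(i) {
    hit <- expr_man$chrom == cpg_man$chrom[i] &
      abs(expr_man$pos - cpg_man$pos[i]) <= w
    if (!any(hit)) return(NULL)
    data.frame(cpg_id = cpg_man$probe_id[i],
               expr_probe_id = expr_man$expr_probe_id[hit],
               distance = expr_man$pos[hit] - cpg_man$pos[i])
  }))
  brute <- brute[order(brute$cpg_id, brute$expr_probe_id), ]
  expect_equal(nrow(got), nrow(brute))
  expect_equal(got$cpg_id, brute$cpg_id)
  expect_equal(got$expr_probe_id, brute$expr_probe_id)
  expect_equal(got$distance, brute$distance)
})

test_that("CpGs without coordinates are skipped with a warning and counted", {
  ds <- default_fixture()
  expect_warning(
    pairs <- match_cis_pairs(c("cg_not_there", rownames(ds$cord)[1:50]),
                             ds$manifests$cpg, ds$manifests$expr),
    "skipped")
  expect_equal(attr(pairs, "n_skipped"), 1L)
})

test_that("noiseless transcript association recovers the slope; q scoped to matched set", {
  sheet <- tiny_sheet()
  expr <- rbind(0.1 * sheet$ga_weeks + 2,
                3 + 0.2 * as.numeric(sheet$sex == "male") +
                  seq(0, 1, length.out = nrow(sheet)))
  dimnames(expr) <- list(c("xp1", "xp2"), sheet$sample_id)
  fit <- fit_transcript_assoc(expr, sheet, NULL, probes = "xp1")
  expect_equal(fit$beta_ga, 0.1, tolerance = 1e-9)
  fit_both <- fit_transcript_assoc(expr, sheet, NULL)
  expect_equal(fit$q_ga, bh_adjust(fit$p_ga), tolerance = 1e-12)
  # scoping: q for xp1 changes only via its own family
  expect_equal(fit$p_ga, fit_both$p_ga[fit_both$expr_probe_id == "xp1"],
               tolerance = 1e-12)
  expect_error(fit_transcript_assoc(expr, sheet, NULL, probes = "nope"),
               "lacks")
})

test_that("meth-expr correlation classifies promoter relations", {
  sheet <- tiny_sheet()
  n <- nrow(sheet)
  man <- data.frame(probe_id = c("cgP", "cgB"), chrom = "chr1",
                    pos = c(100L, 200L), gene = "A",
                    gene_region = c("TSS200", "Body"),
                    island_relation = "Island", chromstate_T = "TssA",
                    chromstate_B = "TssA", stringsAsFactors = FALSE)
  meth <- matrix(seq(0.1, 0.8, length.out = n), 2, n, byrow = TRUE,
                 dimnames = list(c("cgP", "cgB"), sheet$sample_id))
  expr <- rbind(1 + 2 * meth[1, ], 5 - meth[2, ])
  dimnames(expr) <- list(c("xp1", "xp2"), sheet$sample_id)
  pairs <- data.frame(cpg_id = c("cgP", "cgB"),
                      expr_probe_id = c("xp1", "xp2"),
                      gene = "A", distance = 0L)
  me <- correlate_meth_expr(pairs, meth, expr, man)
  expect_equal(me$r, c(1, -1), tolerance = 1e-12)
  expect_equal(me$relation, c("discordant", NA))
  expect_equal(me$region_class, c("Promoter", "GeneBody"))
  expect_equal(me$p, c(0, 0), tolerance = 1e-12)
})

test_that("pearson r and p match the definitional forms", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- rnorm(n)
    man <- data.frame(probe_id = "cg1", chrom = "c", pos = 1L, gene = "",
                      gene_region = "IGR", island_relation = "OpenSea",
                      chromstate_T = "Quies", chromstate_B = "Quies")
    meth <- matrix(plogis(x), 1, n,
                   dimnames = list("cg1", paste0("s", 1:n)))
    expr <- matrix(y - min(y), 1, n,
                   dimnames = list("xp1", paste0("s", 1:n)))
    me <- correlate_meth_expr(data.frame(cpg_id = "cg1", expr_probe_id = "xp1",
                                         gene = "", distance = 0L),
                              meth, expr, man)
    r_def <- cov(plogis(x), y) / (sd(plogis(x)) * sd(y))
    expect_equal(me$r, r_def, tolerance = 1e-12)
    expect_equal(me$p, cor.test(plogis(x), y)$p.value, tolerance = 1e-9)
  }
})

test_that("planted negative links classify as concordant >=90%", {
  ds <- default_fixture()
  truth <- ds$truth$cpg
  neg <- truth[!is.na(truth$link_sign) & truth$link_sign == -1L, ]
  pairs <- data.frame(cpg_id = neg$probe_id,
                      expr_probe_id = neg$linked_expr_probe,
                      gene = "g", distance = 0L)
  me <- correlate_meth_expr(pairs, ds$cord, ds$expr, ds$manifests$cpg)
  prom <- me$region_class == "Promoter"
  expect_gt(sum(prom), 10L)
  expect_gte(mean(me$relation[prom] == "concordant"), 0.9)
})
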