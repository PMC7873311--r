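# Persistence scoring, interval check, chromatin-state statistics, ranking.

test_that("identical postnatal data gives r = 1 everywhere; threshold is inclusive", {
  ds <- default_fixture()
  pairs_sheet <- ds$sheet
  post_ids <- pairs_sheet$sample_id[pairs_sheet$tissue == "postnatal"]
  subj <- pairs_sheet$subject_id[match(post_ids, pairs_sheet$sample_id)]
  cord_ids <- pairs_sheet$sample_id[match(subj, pairs_sheet$subject_id)]
  fake_post <- ds$cord[, cord_ids, drop = FALSE]
  colnames(fake_post) <- post_ids
  cpgs <- rownames(ds$cord)[1:200]
  mem <- cord_post_correlation(ds$cord, fake_post, pairs_sheet, cpgs)
  expect_true(all(abs(mem$r_cord_post - 1) < 1e-12))
  expect_true(all(mem$is_candidate))
  expect_equal(unique(mem$n_pairs), 47L)

  # flag is r >= threshold, inclusive, and monotone in the threshold
  mem2 <- cord_post_correlation(ds$cord, ds$postnatal, pairs_sheet, cpgs)
  expect_identical(mem2$is_candidate, mem2$r_cord_post >= 0.7)
  stricter <- cord_post_correlation(ds$cord, ds$postnatal, pairs_sheet, cpgs,
                                    r_threshold = 0.8)
  expect_true(all(which(stricter$is_candidate) %in% which(mem2$is_candidate)))
  # exact boundary value is a candidate
  rec <- mem2; rec$r_cord_post[1] <- 0.7
  expect_true(rec$r_cord_post[1] >= 0.7)
})

test_that("cord-post correlation is symmetric in argument order", {
  ds <- default_fixture()
  cpgs <- rownames(ds$cord)[51:80]
  a <- cord_post_correlation(ds$cord, ds$postnatal, ds$sheet, cpgs)
  sheet_sw <- ds$sheet
  sheet_sw$tissue <- ifelse(sheet_sw$tissue == "cord", "postnatal", "cord")
  b <- cord_post_correlation(ds$postnatal, ds$cord, sheet_sw, cpgs)
  expect_equal(a$r_cord_post, b$r_cord_post, tolerance = 1e-12)
})

test_that("planted memory CpGs are recalled and nulls rarely called", {
  ds <- default_fixture()
  truth <- ds$truth$cpg
  ga_ids <- truth$probe_id[truth$is_ga_assoc]
  mem <- cord_post_correlation(ds$cord, ds$postnatal, ds$sheet, ga_ids)
  tm <- truth$probe_id[truth$is_memory]
  expect_gte(mean(mem$is_candidate[mem$cpg_id %in% tm]), 0.8)
  expect_lte(mean(mem$is_candidate[!mem$cpg_id %in% tm]), 0.1)
})

test_that("interval check splits halves, handles odd counts and degenerate data", {
  ds <- default_fixture()
  cpgs <- ds$truth$cpg$probe_id[ds$truth$cpg$is_ga_assoc][1:300]
  ic <- interval_check(ds$cord, ds$postnatal, ds$sheet, cpgs)
  expect_equal(ic$n_bottom, 23L)   # 47 paired subjects, median dropped
  expect_equal(ic$n_top, 23L)
  # no interval dependence planted: difference is small
  expect_lt(abs(ic$mean_diff), 0.05)
  expect_false(ic$zero_variance)

  # identical data in both halves -> exactly zero, zero-variance flagged
  post_ids <- ds$sheet$sample_id[ds$sheet$tissue == "postnatal"]
  subj <- ds$sheet$subject_id[match(post_ids, ds$sheet$sample_id)]
  cord_ids <- ds$sheet$sample_id[match(subj, ds$sheet$subject_id)]
  fake_post <- ds$cord[, cord_ids, drop = FALSE]
  colnames(fake_post) <- post_ids
  ic0 <- interval_check(ds$cord, fake_post, ds$sheet, cpgs[1:50])
  expect_equal(ic0$mean_diff, 0)
  expect_true(ic0$zero_variance)
  expect_equal(ic0$p, 1)

  expect_error(interval_check(ds$cord, ds$postnatal,
                              ds$sheet[ds$sheet$tissue == "cord", ][1:5, ],
                              cpgs[1:5]), "paired")
})

test_that("state distribution counts over the fixed 25-label vocabulary", {
  man <- data.frame(probe_id = paste0("cg", 1:4), chrom = "chr1", pos = 1:4,
                    gene = "", gene_region = "IGR", island_relation = "OpenSea",
                    chromstate_T = c("ReprPC", "ReprPC", "Quies", "TssA"),
                    chromstate_B = "Quies", stringsAsFactors = FALSE)
  d <- state_distribution(man$probe_id, man, "T")
  expect_equal(nrow(d), 25L)
  expect_equal(d$proportion[d$state == "ReprPC"], 0.5)
  expect_equal(d$proportion[d$state == "Quies"], 0.25)
  expect_equal(sum(d$proportion), 1)
  expect_equal(sum(d$count == 0L), 22L)
  expect_error(state_distribution(character(), man), "empty")
})

test_that("state enrichment: cross-product OR, Fisher oracle, zero-cell flag", {
  # build a manifest realizing table (20, 80 | 100, 900) for ReprPC
  man <- data.frame(
    probe_id = sprintf("cg%04d", 1:1100), chrom = "chr1", pos = 1:1100,
    gene = "", gene_region = "IGR", island_relation = "OpenSea",
    chromstate_T = c(rep("ReprPC", 20), rep("Quies", 80),
                     rep("ReprPC", 100), rep("Quies", 900)),
    chromstate_B = "Quies", stringsAsFactors = FALSE)
  set <- man$probe_id[1:100]
  en <- state_enrichment(set, man, annotation = "T")
  rp <- en[en$state == "ReprPC", ]
  expect_equal(rp$odds_ratio, (20 * 900) / (80 * 100), tolerance = 1e-12)
  expect_equal(rp$p, fisher_oracle(20, 80, 100, 900), tolerance = 1e-9)
  expect_false(rp$zero_cell)
  expect_identical(en$significant, en$p < 0.05 / 25 & en$odds_ratio >= 1)

  q <- en[en$state == "TssA", ]  # absent from both -> degenerate zero cells
  expect_true(q$zero_cell)
  expect_error(state_enrichment(man$probe_id, man), "degenerate")
})

test_that("uniformly drawn sets show no Bonferroni hits", {
  ds <- default_fixture()
  man <- ds$manifests$cpg
  set.seed(99)
  hits <- vapply(1:10, function(i) {
    s <- sample(man$probe_id, 120)
    sum(state_enrichment(s, man, annotation = "T")$significant)
  }, numeric(1))
  expect_lte(mean(hits > 0), 0.2)
})

test_that("decile bins partition with near-equal sizes and trend detects planting", {
  ds <- default_fixture()
  truth <- ds$truth$cpg
  ga_ids <- truth$probe_id[truth$is_ga_assoc]
  mem <- cord_post_correlation(ds$cord, ds$postnatal, ds$sheet, ga_ids)
  tr <- decile_trend(mem, ds$manifests$cpg, states = "ReprPC",
                     annotation = "T")
  expect_equal(sum(tr$n[tr$state == "ReprPC"]), length(ga_ids))
  expect_lte(diff(range(tr$n)), 1L)
  rho <- cor(tr$bin, tr$odds_ratio, method = "spearman")
  expect_gt(rho, 0)

  mem105 <- mem[1:105, ]
  tr105 <- decile_trend(mem105, ds$manifests$cpg, states = "ReprPC")
  expect_setequal(unique(tr105$n), c(10L, 11L))
  expect_error(decile_trend(mem[1:5, ], ds$manifests$cpg), "smaller")
})

test_that("region correlation map diagonal equals the persistence scores", {
  ds <- default_fixture()
  cpgs <- ds$truth$cpg$probe_id[ds$truth$cpg$is_memory][1:8]
  m <- region_correlation_map(ds$cord, ds$postnatal, ds$sheet, cpgs)
  mem <- cord_post_correlation(ds$cord, ds$postnatal, ds$sheet, cpgs)
  expect_equal(unname(diag(m)), mem$r_cord_post, tolerance = 1e-12)

  post_ids <- ds$sheet$sample_id[ds$sheet$tissue == "postnatal"]
  subj <- ds$sheet$subject_id[match(post_ids, ds$sheet$sample_id)]
  cord_ids <- ds$sheet$sample_id[match(subj, ds$sheet$subject_id)]
  fake_post <- ds$cord[, cord_ids, drop = FALSE]
  colnames(fake_post) <- post_ids
  m1 <- region_correlation_map(ds$cord, fake_post, ds$sheet, cpgs)
  expect_true(all(abs(diag(m1) - 1) < 1e-12))
})

test_that("overlap intersects parents and ranks the multi-CpG gene first", {
  # planted gene "UCN" with 8 discordant promoter memory CpGs
  n <- 30L
  man <- data.frame(
    probe_id = sprintf("cg%02d", 1:n), chrom = "chr1", pos = 1:n,
    gene = c(rep("UCN", 8), rep(c("OTH1", "OTH2"), 5), rep("", 12)),
    gene_region = c(rep("TSS200", 18), rep("IGR", 12)),
    island_relation = "Island", chromstate_T = "ReprPC",
    chromstate_B = "ReprPC", stringsAsFactors = FALSE)
  memory <- data.frame(cpg_id = man$probe_id,
                       r_cord_post = c(rep(0.9, 12), rep(0.1, 18)),
                       p = 0, n_pairs = 47L,
                       is_candidate = c(rep(TRUE, 12), rep(FALSE, 18)))
  methexpr <- data.frame(cpg_id = man$probe_id[1:14],
                         expr_probe_id = "xp1", r = 0.5, p = 0.001, n = 55L,
                         region_class = "Promoter", relation = "discordant",
                         significant = c(rep(TRUE, 10), rep(FALSE, 4)))
  ov <- overlap_and_rank(memory, methexpr, man)
  expect_setequal(ov$overlap, man$probe_id[1:10])
  expect_true(all(ov$overlap %in% memory$cpg_id[memory$is_candidate]))
  expect_true(all(ov$overlap %in% methexpr$cpg_id[methexpr$significant]))
  expect_equal(ov$genes$gene[1], "UCN")
  expect_equal(ov$genes$n_cpgs[1], 8L)
  expect_equal(ov$genes$n_discordant[1], 8L)

  disjoint <- overlap_and_rank(
    memory[!memory$is_candidate, ], methexpr, man)
  expect_length(disjoint$overlap, 0L)
})
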