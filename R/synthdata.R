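# Miniature synthetic cohort generator.  Emits a cord + paired-postnatal
# methylation study with planted ground truth: GA-associated CpGs in both
# directions, GA-dependent cell composition (the confounder the adjusted
# model must neutralize), subject-level persistence ("memory") intercepts,
# cis-linked expression probes with signed methylation-expression links, and
# manifests whose annotations carry the planted enrichments.
#
# RNG discipline: base R Mersenne-Twister; each stage reseeds from the
# design seed plus a fixed stage offset (cohort +0, methylation +1,
# expression +2, manifests +3), so stages are individually reproducible and
# the whole dataset is byte-identical under a fixed seed.

#' Simulation design
#'
#' Defaults mirror the cohort the pipeline targets: 110 cord samples, 47
#' paired postnatal samples, 55 expression samples, GA 23-41 weeks
#' (truncated normal, mean 34, SD 4.9), draw interval ~2-18 weeks.  Signal
#' defaults: 20 percent of CpGs GA-associated (split between directions);
#' the GA effect defaults to 4x its analytic standard error under the fully
#' adjusted design (`ga_effect_logit_per_week = NULL`); 8 percent of GA
#' CpGs are memory CpGs with target cord-post correlation `memory_icc`
#' (0.85) against `nonmemory_icc` (0.2); 15 percent of GA CpGs carry an
#' expression link, positive (promoter-discordant) with probability 0.34.
#'
#' @param n_cord,n_paired_postnatal,n_expr,n_cpgs,n_expr_probes cohort sizes.
#' @param frac_ga_cpgs proportion of CpGs with a true GA effect.
#' @param ga_effect_logit_per_week GA effect on the logit-beta scale per
#'   week; NULL = auto (4x analytic SE).
#' @param frac_memory proportion of GA CpGs given subject-level persistence.
#' @param memory_icc,nonmemory_icc target cord-post correlations.
#' @param frac_linked fraction of GA CpGs linked to an expression probe.
#' @param frac_discordant_promoter probability a link is positive
#'   (methylation up, expression up).
#' @param link_scale_log2,expr_noise_sd_log2 expression link slope (log2
#'   units per logit-methylation) and noise SD.
#' @param cell_base_weights named baseline mixing weights (7 types).
#' @param cell_ga_slopes named per-week drifts of log mixing weights.
#' @param cell_weight_noise_sd per-sample log-weight noise SD.
#' @param noise_sd_logit methylation noise SD on the logit scale.
#' @param batch_effect_logit additive logit shift for the second batch.
#' @param n_ref_cpgs_per_type discriminative reference CpGs per cell type.
#' @param memory_state_enrichment odds multiplier for ReprPC/PromBiv
#'   annotation at memory CpGs (1 = null).
#' @param frac_outside_window fraction of unlinked expression probes placed
#'   just outside the cis window of some CpG (matcher boundary exercise).
#' @param cov_effect_scale multiplier on all covariate-GA dependences
#'   (0 = null covariate world).
#' @param ga_mean,ga_sd,ga_range GA distribution (weeks).
#' @param seed integer RNG seed.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(n_cord = 110L, n_paired_postnatal = 47L, n_expr = 55L,
                       n_cpgs = 5000L, n_expr_probes = 800L,
                       frac_ga_cpgs = 0.2, ga_effect_logit_per_week = NULL,
                       frac_memory = 0.08, memory_icc = 0.85,
                       nonmemory_icc = 0.2, frac_linked = 0.15,
                       frac_discordant_promoter = 0.34,
                       link_scale_log2 = 1.0, expr_noise_sd_log2 = 0.5,
                       cell_base_weights = c(CD4T = 0.25, CD8T = 0.15,
                                             NK = 0.10, B = 0.15, Gran = 0.20,
                                             Mono = 0.08, nRBC = 0.07),
                       cell_ga_slopes = c(CD4T = 0.03, CD8T = 0.02, NK = 0,
                                          B = 0.03, Gran = -0.05, Mono = 0,
                                          nRBC = -0.20),
                       cell_weight_noise_sd = 0.3, noise_sd_logit = 0.3,
                       batch_effect_logit = 0.05, n_ref_cpgs_per_type = 10L,
                       memory_state_enrichment = 4, frac_outside_window = 0.1,
                       cov_effect_scale = 1, ga_mean = 34, ga_sd = 4.9,
                       ga_range = c(23, 41), seed = 1L) {
  if (n_paired_postnatal > n_cord)
    stop("n_paired_postnatal cannot exceed n_cord")
  if (n_expr > n_cord) stop("n_expr cannot exceed n_cord")
  for (f in c(frac_ga_cpgs, frac_memory, frac_linked,
              frac_discordant_promoter, frac_outside_window))
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]")
  stopifnot(setequal(names(cell_base_weights), CELL_TYPES),
            setequal(names(cell_ga_slopes), CELL_TYPES))
  d <- as.list(environment())
  class(d) <- "sim_design"
  d
}

.softmax_rows <- function(L) {
  e <- exp(L - apply(L, 1L, max))
  e / rowSums(e)
}

# Per-sample mixing weights: softmax of log base weights drifted by age and
# jittered per sample.  Rows sum to 1 exactly.
.cell_fractions <- function(age_weeks, design) {
  n <- length(age_weeks)
  base <- log(design$cell_base_weights[CELL_TYPES])
  slopes <- design$cell_ga_slopes[CELL_TYPES]
  L <- matrix(base, n, 7L, byrow = TRUE) +
    outer(age_weeks - design$ga_mean, slopes) +
    matrix(rnorm(n * 7L, 0, design$cell_weight_noise_sd), n, 7L)
  F <- .softmax_rows(L)
  colnames(F) <- CELL_TYPES
  F
}

#' Simulate the cohort: sample sheet and ground truth
#'
#' Draws GA from a truncated normal (23-41 weeks); binary prenatal
#' covariates with logistic dependence on GA in the canonical directions
#' (male infant, cesarean, smoking before pregnancy, chorioamnionitis,
#' idiopathic PROM, and higher maternal BMI all more frequent at earlier
#' GA); a birth-weight SD score rising with GA and lowered by preeclampsia;
#' paired postnatal draw intervals of roughly 2-18 weeks (median near 7).
#' Also fixes the per-CpG ground-truth flags, reference profiles, and true
#' cell fractions for every sample.
#'
#' @param design a [sim_design()].
#' @return list: `sheet` (sample sheet) and `truth` (ground-truth list).
#' @export
simulate_cohort <- function(design) {
  set.seed(design$seed)
  n <- design$n_cord
  p <- pnorm(design$ga_range, design$ga_mean, design$ga_sd)
  ga <- qnorm(runif(n, p[1L], p[2L]), design$ga_mean, design$ga_sd)

  cs <- design$cov_effect_scale
  draw_bin <- function(base_rate, slope_per_week)
    rbinom(n, 1L, plogis(qlogis(base_rate) + cs * slope_per_week * (ga - design$ga_mean)))
  sex_male <- draw_bin(0.48, -0.08)
  cesarean <- draw_bin(0.81, -0.15)
  smoke_before <- draw_bin(0.064, -0.10)
  cam <- draw_bin(0.23, -0.30)
  iprom <- draw_bin(0.10, -0.15)
  preeclampsia <- draw_bin(0.18, 0)
  gdm <- draw_bin(0.036, 0)
  art <- draw_bin(0.23, 0)
  parity_gt0 <- draw_bin(0.39, 0)
  previa <- draw_bin(0.09, 0)
  maternal_age <- rnorm(n, 33.8, 4.7)
  maternal_bmi <- 21.1 - cs * 0.15 * (ga - design$ga_mean) + rnorm(n, 0, 3.0)
  paternal_age <- rnorm(n, 35.5, 5.5)
  paternal_bmi <- rnorm(n, 23.0, 3.0)
  bw_sd <- -0.45 + cs * (0.06 * (ga - design$ga_mean) - 0.8 * preeclampsia) +
    rnorm(n, 0, 1.3)

  subj <- sprintf("S%03d", seq_len(n))
  batch <- rep(c("B1", "B2"), length.out = n)
  cord <- data.frame(
    sample_id = paste0(subj, "_C"), subject_id = subj, tissue = "cord",
    ga_weeks = round(ga, 1), bw_sd_score = round(bw_sd, 2),
    sex = ifelse(sex_male == 1L, "male", "female"), batch = batch,
    maternal_age = round(maternal_age, 1),
    maternal_bmi = round(maternal_bmi, 1),
    paternal_age = round(paternal_age, 1),
    paternal_bmi = round(paternal_bmi, 1),
    parity_gt0 = parity_gt0, cesarean = cesarean, art = art,
    smoke_before = smoke_before, gdm = gdm, cam = cam, iprom = iprom,
    preeclampsia = preeclampsia, previa = previa,
    postmenstrual_age_at_draw = round(ga, 1), interval_weeks = NA_real_,
    stringsAsFactors = FALSE)

  paired_idx <- sort(sample.int(n, design$n_paired_postnatal))
  interval <- round(2 + 16.1 * rbeta(design$n_paired_postnatal, 1.6, 3.5), 1)
  post <- cord[paired_idx, , drop = FALSE]
  post$sample_id <- paste0(post$subject_id, "_P")
  post$tissue <- "postnatal"
  post$interval_weeks <- interval
  post$postmenstrual_age_at_draw <- round(post$ga_weeks + interval, 1)
  sheet <- validate_sample_sheet(rbind(cord, post))

  # ---- per-CpG ground truth -------------------------------------------------
  m <- design$n_cpgs
  cpg_id <- sprintf("cg%07d", seq_len(m))
  n_ref <- design$n_ref_cpgs_per_type * 7L
  if (n_ref + 10L > m) stop("n_cpgs too small for the reference panel")
  is_ref <- c(rep(TRUE, n_ref), rep(FALSE, m - n_ref))
  ref_type <- rep(NA_character_, m)
  ref_type[seq_len(n_ref)] <- rep(CELL_TYPES, each = design$n_ref_cpgs_per_type)

  eligible <- which(!is_ref)
  n_ga <- min(round(design$frac_ga_cpgs * m), length(eligible))
  ga_idx <- sort(sample(eligible, n_ga))
  direction <- integer(m)
  direction[ga_idx] <- ifelse(seq_along(ga_idx) %% 2L == 0L, 1L, -1L)
  is_ga <- direction != 0L
  mem_idx <- sort(sample(ga_idx, round(design$frac_memory * n_ga)))
  is_memory <- seq_len(m) %in% mem_idx

  # Persistence is a continuum (the paired-correlation histogram of real
  # data is continuous): per-CpG target cord-post correlations drawn from
  # Beta distributions whose means are the two design ICCs.
  rbeta_mean <- function(k, mu, kappa)
    rbeta(k, mu * kappa, (1 - mu) * kappa)
  icc_target <- rbeta_mean(m, design$nonmemory_icc, 10)
  icc_target[is_memory] <- rbeta_mean(sum(is_memory), design$memory_icc, 20)
  icc_target <- pmin(pmax(icc_target, 0.01), 0.98)

  n_link <- round(design$frac_linked * n_ga)
  link_idx <- sort(sample(ga_idx, n_link))
  linked_expr_probe <- rep(NA_character_, m)
  linked_expr_probe[link_idx] <- sprintf("xp%05d", seq_len(n_link))
  link_sign <- rep(NA_integer_, m)
  link_sign[link_idx] <- ifelse(
    runif(n_link) < design$frac_discordant_promoter, 1L, -1L)

  # Reference profiles (beta space).  Non-reference CpGs: a shared per-CpG
  # center plus modest per-type offsets (the composition confounder);
  # reference CpGs: one type high, the others low (discriminative).
  center <- rnorm(m, 0, 1.5)
  offs <- matrix(rnorm(m * 7L, 0, 0.3), m, 7L, dimnames = list(cpg_id, CELL_TYPES))
  Lp <- center + offs
  for (t in seq_along(CELL_TYPES)) {
    rows <- which(ref_type == CELL_TYPES[t])
    Lp[rows, ] <- -2 + matrix(rnorm(length(rows) * 7L, 0, 0.1),
                              length(rows), 7L)
    Lp[rows, t] <- 2 + rnorm(length(rows), 0, 0.1)
  }
  profiles <- plogis(Lp)

  fractions <- .cell_fractions(sheet$postmenstrual_age_at_draw, design)
  rownames(fractions) <- sheet$sample_id

  # Per-unit-residual-SD standard error of the GA coefficient under the
  # fully adjusted design with the true fractions.  The methylation stage
  # multiplies this by the realized residual SD to plant effects at a fixed
  # multiple of their true standard error.
  fr <- data.frame(sample_id = sheet$sample_id, fractions,
                   check.names = FALSE)
  cord_rows <- sheet[sheet$tissue == "cord", , drop = FALSE]
  X <- .ewas_design(cord_rows, fr, MODEL2_COVARIATES)
  se_ga_unit <- tryCatch(sqrt(diag(solve(crossprod(X)))[["GA"]]),
                         error = function(e) {
                           # tiny cohorts can make the full design singular;
                           # fall back to the unadjusted-slope SE
                           1 / (sd(ga) * sqrt(n))
                         })

  expr_samples <- sort(sample(cord$sample_id, design$n_expr))

  truth <- list(
    cpg = data.frame(probe_id = cpg_id, is_ga_assoc = is_ga,
                     direction = direction, is_memory = is_memory,
                     icc_target = icc_target,
                     is_reference = is_ref, ref_type = ref_type,
                     linked_expr_probe = linked_expr_probe,
                     link_sign = link_sign, stringsAsFactors = FALSE),
    profiles = profiles, cell_fractions = fractions,
    se_ga_unit = se_ga_unit, expr_samples = expr_samples,
    paired_subjects = cord$subject_id[paired_idx]
  )
  list(sheet = sheet, truth = truth)
}

# Subject-intercept variance giving target correlation r between
# cord = u + (extra var a) and post = u + (extra var b):
# r = v / sqrt((v + a)(v + b)), solved in closed form (vectorized in r).
.icc_variance <- function(r, a, b) {
  out <- numeric(length(r))
  ok <- r > 0 & (a + b) > 0
  rr <- r[ok]
  disc <- rr^4 * (a + b)^2 + 4 * (1 - rr^2) * rr^2 * a * b
  out[ok] <- (rr^2 * (a + b) + sqrt(disc)) / (2 * (1 - rr^2))
  out
}

#' Simulate cord and postnatal methylation matrices
#'
#' Per sample, beta = inverse-logit( logit(cell-mixture baseline) + GA term
#' + shared subject intercept + batch shift + logit-normal noise ).  The
#' mixture baseline is the reference profile weighted by the sample's true
#' cell fractions, which drift with (postmenstrual) age — the composition
#' confounder.  Persistence is planted two ways:
#'
#' * Non-memory GA CpGs carry the GA effect in cord blood only (the at-birth
#'   change washes out), planted at `ga_effect_multiple` (default 4) times
#'   its true standard error under the fully adjusted design — the residual
#'   SD (noise plus subject intercept) and the effect are solved jointly by
#'   fixed point.  A small shared subject intercept gives the baseline
#'   cord-post correlation `nonmemory_icc`.
#' * Memory CpGs carry a persistent GA effect, present identically in both
#'   tissues and sized so the expected cross-subject cord-post correlation
#'   equals `memory_icc`; this is what "epigenetic memory" means here — the
#'   GA-stamped state itself persists.  (A shared intercept alone cannot
#'   reach a 0.85 correlation once the cord-only GA variance is planted;
#'   see the methods vignette.)
#'
#' Null CpGs get the `nonmemory_icc` intercept and noise only.  Postnatal
#' noise is always redrawn independently.
#'
#' @param sheet,truth from [simulate_cohort()].
#' @param design the same [sim_design()].
#' @return list: `cord` and `postnatal` beta matrices, plus `effects`
#'   (ga_effect_logit_per_week, memory_effect_logit_per_week, and the
#'   intercept variances used).
#' @export
simulate_methylation <- function(sheet, truth, design) {
  set.seed(design$seed + 1L)
  m <- design$n_cpgs
  cpg_id <- truth$cpg$probe_id
  cord_rows <- sheet[sheet$tissue == "cord", , drop = FALSE]
  post_rows <- sheet[sheet$tissue == "postnatal", , drop = FALSE]
  noise <- design$noise_sd_logit
  e2 <- noise^2
  sd_ga <- sd(cord_rows$ga_weeks)

  is_mem <- truth$cpg$is_memory
  is_ga <- truth$cpg$is_ga_assoc
  icc <- truth$cpg$icc_target

  # Fixed point: effect = multiple x typical residual SD x per-unit SE; the
  # non-memory intercept variance (targeting each CpG's icc) feeds back into
  # the residual through its mean over transient GA CpGs.
  mean_v_ga <- function(eff_try) {
    g <- (eff_try * sd_ga)^2
    mean(.icc_variance(icc[is_ga & !is_mem], g + e2, e2))
  }
  if (is.null(design$ga_effect_logit_per_week)) {
    v_bar <- 0; eff <- 0
    for (it in seq_len(50L)) {
      eff_new <- 4 * sqrt(e2 + v_bar) * truth$se_ga_unit
      v_bar <- if (any(is_ga & !is_mem)) mean_v_ga(eff_new) else 0
      if (abs(eff_new - eff) < 1e-12) break
      eff <- eff_new
    }
  } else {
    eff <- design$ga_effect_logit_per_week
  }
  g <- (eff * sd_ga)^2
  # memory CpGs: persistent per-CpG GA effect with variance g_i solving
  # g_i / (g_i + e2) = icc_i
  eff_mem <- if (e2 > 0) sqrt(icc / (1 - icc) * e2) / sd_ga else rep(0, m)
  v <- numeric(m)
  v[is_ga & !is_mem] <- .icc_variance(icc[is_ga & !is_mem], g + e2, e2)
  v[!is_ga] <- .icc_variance(icc[!is_ga], e2, e2)
  u_sd <- sqrt(v)
  per_cpg_eff <- truth$cpg$direction * ifelse(is_mem, eff_mem, eff)

  subjects <- cord_rows$subject_id
  U <- matrix(rnorm(m * length(subjects)), m, length(subjects),
              dimnames = list(cpg_id, subjects)) * u_sd

  mk <- function(rows, tissue) {
    F <- truth$cell_fractions[rows$sample_id, , drop = FALSE]
    L <- qlogis(truth$profiles %*% t(F))          # m x n
    ga_dev <- rows$ga_weeks - design$ga_mean
    if (tissue == "cord") {
      L <- L + outer(per_cpg_eff, ga_dev)
    } else {
      L <- L + outer(per_cpg_eff * is_mem, ga_dev)  # only memory persists
    }
    L <- L + U[, rows$subject_id, drop = FALSE]
    L <- L + matrix(rep(design$batch_effect_logit *
                          as.numeric(rows$batch == "B2"), each = m), m)
    if (noise > 0) L <- L + matrix(rnorm(m * nrow(rows), 0, noise), m)
    B <- plogis(L)
    dimnames(B) <- list(cpg_id, rows$sample_id)
    B
  }
  list(cord = mk(cord_rows, "cord"), postnatal = mk(post_rows, "postnatal"),
       effects = list(
         ga_effect_logit_per_week = eff,
         memory_effect_logit_per_week =
           if (any(is_mem)) mean(eff_mem[is_mem]) else 0,
         mean_intercept_var_ga = if (any(is_ga & !is_mem))
           mean(v[is_ga & !is_mem]) else 0))
}

#' Simulate the cord expression matrix
#'
#' Linked probes: log2 expression = probe baseline + link sign x scale x
#' logit(cord methylation of the linked CpG) + Gaussian noise; unlinked
#' probes are independent of methylation.  Only the designated expression
#' subset of cord samples is emitted; values are floored at 0 (the log2
#' scale of intensities floored at 1).
#'
#' @param sheet,truth from [simulate_cohort()].
#' @param design the [sim_design()].
#' @param cord_beta cord beta matrix from [simulate_methylation()].
#' @return expression matrix (n_expr_probes x n_expr).
#' @export
simulate_expression <- function(sheet, truth, design, cord_beta) {
  set.seed(design$seed + 2L)
  samples <- truth$expr_samples
  linked <- truth$cpg[!is.na(truth$cpg$linked_expr_probe), , drop = FALSE]
  missing <- setdiff(linked$probe_id, rownames(cord_beta))
  if (length(missing))
    stop("linked CpG(s) absent from the methylation matrix: ",
         paste(head(missing, 3L), collapse = ", "))
  ne <- design$n_expr_probes
  if (nrow(linked) > ne) stop("more links than expression probes")
  probe_id <- sprintf("xp%05d", seq_len(ne))
  base <- rnorm(ne, 8, 1.5)
  E <- matrix(base, ne, length(samples),
              dimnames = list(probe_id, samples))
  if (nrow(linked)) {
    i <- match(linked$linked_expr_probe, probe_id)
    Lm <- qlogis(cord_beta[linked$probe_id, samples, drop = FALSE])
    E[i, ] <- E[i, ] + linked$link_sign * design$link_scale_log2 *
      (Lm - rowMeans(Lm))
  }
  E <- E + matrix(rnorm(length(E), 0, design$expr_noise_sd_log2),
                  nrow(E))
  pmax(E, 0)
}

#' Emit CpG and expression probe manifests carrying the planted annotations
#'
#' Places CpGs on a toy genome (one chromosome per ~1000 CpGs, strictly
#' increasing positions), assigns gene/region labels (linked CpGs
#' preferentially promoter-region so the concordant/discordant
#' classification has targets), island relations with GA CpGs modestly
#' Shore-enriched, and 25-state chromatin labels with ReprPC/PromBiv odds
#' multiplied by `memory_state_enrichment` at memory CpGs.  Linked
#' expression probes are placed within the cis window of their CpG; a
#' configurable fraction of unlinked probes lands just outside the window.
#'
#' @param truth,design from [simulate_cohort()] / [sim_design()].
#' @param window cis window the placement respects (default 250000).
#' @return list: `cpg` (probe manifest), `expr` (expression probe manifest).
#' @export
emit_manifests <- function(truth, design, window = 250000L) {
  set.seed(design$seed + 3L)
  m <- design$n_cpgs
  per_chrom <- 1000L
  chrom <- paste0("chr", (seq_len(m) - 1L) %/% per_chrom + 1L)
  gap <- sample(500:2000, m, replace = TRUE)
  pos <- integer(m)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- cumsum(gap[i]) + 10000L
  }

  region_levels <- c("TSS200", "TSS1500", "UTR5", "FirstExon", "Body",
                     "UTR3", "IGR")
  region_prob <- c(0.10, 0.10, 0.08, 0.07, 0.30, 0.05, 0.30)
  region <- sample(region_levels, m, replace = TRUE, prob = region_prob)
  linked <- !is.na(truth$cpg$linked_expr_probe)
  promo <- runif(m) < 0.7
  region[linked & promo] <- sample(PROMOTER_REGIONS, sum(linked & promo),
                                   replace = TRUE)
  gene <- ifelse(region == "IGR", "",
                 paste0("G_", chrom, "_", (pos %/% 50000L)))

  isl_prob_bg <- c(Island = 0.30, Shore = 0.25, Shelf = 0.10, OpenSea = 0.35)
  isl_prob_ga <- c(Island = 0.245, Shore = 0.35, Shelf = 0.085, OpenSea = 0.32)
  island <- character(m)
  ga <- truth$cpg$is_ga_assoc
  island[!ga] <- sample(ISLAND_RELATIONS, sum(!ga), replace = TRUE,
                        prob = isl_prob_bg)
  island[ga] <- sample(ISLAND_RELATIONS, sum(ga), replace = TRUE,
                       prob = isl_prob_ga)

  state_prob <- setNames(rep(0.012, 25L), CHROM_STATES_25)
  state_prob[c("Quies", "TxWk", "TssA", "PromU", "Tx", "EnhW1")] <-
    c(0.30, 0.12, 0.06, 0.05, 0.08, 0.05)
  state_prob["ReprPC"] <- 0.05
  state_prob["PromBiv"] <- 0.02
  state_prob <- state_prob / sum(state_prob)
  # ReprPC/PromBiv odds grade continuously with planted persistence, so the
  # decile trend of enrichment over cord-post correlation rises smoothly;
  # the knob at 1 gives the flat null.
  mult <- 1 + (design$memory_state_enrichment - 1) * truth$cpg$icc_target
  draw_states <- function() {
    P <- matrix(state_prob, m, 25L, byrow = TRUE,
                dimnames = list(NULL, CHROM_STATES_25))
    P[, "ReprPC"] <- P[, "ReprPC"] * mult
    P[, "PromBiv"] <- P[, "PromBiv"] * mult
    P <- P / rowSums(P)
    cp <- P %*% upper.tri(diag(25L), diag = TRUE)
    u <- runif(m)
    CHROM_STATES_25[25L - rowSums(u <= cp) + 1L]
  }
  cpg_manifest <- validate_probe_manifest(data.frame(
    probe_id = truth$cpg$probe_id, chrom = chrom, pos = pos, gene = gene,
    gene_region = region, island_relation = island,
    chromstate_T = draw_states(), chromstate_B = draw_states(),
    is_cpg = 1L, stringsAsFactors = FALSE))

  # expression probes: linked ones inside the window of their CpG
  ne <- design$n_expr_probes
  expr_id <- sprintf("xp%05d", seq_len(ne))
  echrom <- sample(unique(chrom), ne, replace = TRUE)
  epos <- integer(ne)
  for (ch in unique(echrom)) {
    i <- which(echrom == ch)
    rng <- range(pos[chrom == ch])
    epos[i] <- sample(seq(rng[1L], rng[2L] + 100000L), length(i))
  }
  li <- match(truth$cpg$linked_expr_probe[linked], expr_id)
  echrom[li] <- chrom[linked]
  epos[li] <- pmax(1L, pos[linked] +
                     sample(seq(-window, window), sum(linked), replace = TRUE))
  unlinked <- setdiff(seq_len(ne), li)
  n_out <- round(design$frac_outside_window * length(unlinked))
  if (n_out > 0) {
    oi <- unlinked[seq_len(n_out)]
    anchor <- sample.int(m, n_out, replace = TRUE)
    echrom[oi] <- chrom[anchor]
    epos[oi] <- pos[anchor] + window + sample(1:50000, n_out, replace = TRUE)
  }
  egene <- ifelse(!is.na(match(expr_id, truth$cpg$linked_expr_probe)),
                  gene[match(expr_id, truth$cpg$linked_expr_probe)],
                  paste0("GX_", seq_len(ne)))
  egene[egene == ""] <- paste0("GX_", which(egene == ""))
  expr_manifest <- read_expr_manifest_df(data.frame(
    expr_probe_id = expr_id, chrom = echrom, pos = epos, gene = egene,
    stringsAsFactors = FALSE))
  list(cpg = cpg_manifest, expr = expr_manifest)
}

# Internal: validate an in-memory expression manifest
read_expr_manifest_df <- function(df) {
  if (any(df$pos <= 0)) stop("manifest positions must be positive")
  class(df) <- c("expr_manifest", "data.frame")
  df
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_cohort()], [simulate_methylation()],
#' [simulate_expression()] and [emit_manifests()], optionally writing every
#' artifact (matrices as TSV, sheet as CSV, manifests and ground truth as
#' TSV) to a directory.
#'
#' @param design a [sim_design()].
#' @param outdir optional output directory.
#' @return list: sheet, truth, cord, postnatal, expr, manifests.
#' @export
simulate_dataset <- function(design = sim_design(), outdir = NULL) {
  ch <- simulate_cohort(design)
  meth <- simulate_methylation(ch$sheet, ch$truth, design)
  expr <- simulate_expression(ch$sheet, ch$truth, design, meth$cord)
  man <- emit_manifests(ch$truth, design)
  out <- list(sheet = ch$sheet, truth = ch$truth, cord = meth$cord,
              postnatal = meth$postnatal, expr = expr, manifests = man,
              effects = meth$effects)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_sample_sheet(ch$sheet, file.path(outdir, "sample_sheet.csv"))
    write_beta_matrix(meth$cord, file.path(outdir, "beta_cord.tsv"))
    write_beta_matrix(meth$postnatal, file.path(outdir, "beta_postnatal.tsv"))
    write_beta_matrix(expr, file.path(outdir, "expression.tsv"),
                      id_col = "expr_probe_id")
    write_table(man$cpg, file.path(outdir, "cpg_manifest.tsv"))
    write_table(man$expr, file.path(outdir, "expr_manifest.tsv"))
    write_table(ch$truth$cpg, file.path(outdir, "ground_truth.tsv"))
    ref <- data.frame(probe_id = rownames(ch$truth$profiles),
                      ch$truth$profiles, check.names = FALSE)
    ref <- ref[ch$truth$cpg$is_reference, , drop = FALSE]
    write_table(ref, file.path(outdir, "reference_profiles.tsv"))
  }
  out
}
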