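# Per-CpG dual-model EWAS: methylation ~ GA + SDscore + adjustments, fitted
# for all probes at once against a shared design matrix; BH FDR per
# coefficient family; direction-consistent intersection of the two models;
# single-covariate sensitivity fits; island-relation enrichment.

#' Construct an EWAS model specification
#'
#' Model 1 adjusts for infant sex, batch and cell fractions; Model 2 adds
#' the six prenatal covariates carried forward from the covariate screen
#' (chorioamnionitis, idiopathic PROM, preeclampsia, maternal smoking before
#' pregnancy, maternal pre-pregnancy BMI, cesarean section).  A sensitivity
#' spec is Model 1 plus one prenatal covariate.
#'
#' @param model_id "model1", "model2", or "sensitivity".
#' @param sensitivity_covar the single added covariate for a sensitivity fit.
#' @return list with model_id and the adjustment covariate names.
#' @export
ewas_model_spec <- function(model_id = c("model1", "model2", "sensitivity"),
                            sensitivity_covar = NULL) {
  model_id <- match.arg(model_id)
  extra <- switch(model_id,
    model1 = character(),
    model2 = MODEL2_COVARIATES,
    sensitivity = {
      if (is.null(sensitivity_covar))
        stop("sensitivity spec needs the added covariate name")
      sensitivity_covar
    })
  list(model_id = if (model_id == "sensitivity")
         paste0("sensitivity_", sensitivity_covar) else model_id,
       prenatal_covariates = extra)
}

# Internal: build the shared design matrix for a set of samples.
# Columns: intercept, GA, SDscore, sex, batch indicators (treatment coding
# against the first batch level), K-1 cell fractions (drop one near-collinear
# type), then any prenatal covariates.
.ewas_design <- function(sheet, fractions, prenatal_covariates,
                         drop_cell_type = "Gran") {
  n <- nrow(sheet)
  cols <- list("(Intercept)" = rep(1, n), GA = sheet$ga_weeks,
               SDscore = sheet$bw_sd_score,
               sexmale = as.numeric(sheet$sex == "male"))
  for (b in unique(sheet$batch)[-1L])
    cols[[paste0("batch", b)]] <- as.numeric(sheet$batch == b)
  if (!is.null(fractions)) {
    fr <- fractions[match(sheet$sample_id, fractions$sample_id), , drop = FALSE]
    if (anyNA(fr$sample_id))
      stop("cell fractions missing for sample(s): ",
           paste(head(sheet$sample_id[is.na(fr$sample_id)], 3L), collapse = ", "))
    for (ct in setdiff(intersect(CELL_TYPES, colnames(fr)), drop_cell_type))
      cols[[ct]] <- fr[[ct]]
  }
  for (cv in prenatal_covariates) {
    if (!cv %in% colnames(sheet))
      stop("covariate '", cv, "' absent from sample sheet")
    cols[[cv]] <- as.numeric(sheet[[cv]])
  }
  do.call(cbind, cols)
}

# Internal: OLS of every row of Y (features x samples) on shared design X
# (samples x p).  Returns per-feature coefficient, SE, p for the requested
# terms.  Errors on rank deficiency, naming the collinear columns.
.fit_lm_matrix <- function(Y, X, terms) {
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank-deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  B <- qr.coef(qrX, t(Y))                      # p x features
  resid <- t(Y) - X %*% B
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  xtxinv <- chol2inv(chol(crossprod(X)))
  out <- list(n = n, df = df)
  for (term in terms) {
    j <- match(term, colnames(X))
    est <- B[j, ]
    se <- sqrt(sigma2 * xtxinv[j, j])
    tt <- est / se
    out[[term]] <- data.frame(estimate = est, se = se,
                              p = 2 * pt(-abs(tt), df), row.names = NULL)
  }
  out
}

#' Fit the per-CpG EWAS under a model specification
#'
#' For every probe, ordinary least squares of methylation (percent scale by
#' default) on GA + SD score plus the spec's adjustments: infant sex, batch
#' (treatment-coded indicators), cell fractions entered as K-1 of the K
#' types (one type dropped because fractions near-sum to a constant), and,
#' for Model 2 / sensitivity fits, prenatal covariates.  Two-sided t-test
#' p-values per coefficient; BH q-values computed over all tested probes,
#' separately for the GA and SD-score coefficient families.
#'
#' @param beta beta matrix (probes x samples, proportions).
#' @param sheet sample sheet covering the beta columns; all used samples
#'   must share one tissue.
#' @param fractions output of [estimate_cell_fractions()], or NULL to omit
#'   the cell-composition adjustment (used by calibration tests).
#' @param spec model specification from [ewas_model_spec()].
#' @param config [pipeline_config()]; `meth_scale` selects percent
#'   (default; estimates are percent methylation per week) or proportion.
#' @param drop_cell_type cell type excluded from the design (default "Gran").
#' @return data.frame: probe_id, beta_ga, se_ga, p_ga, q_ga, beta_sd, se_sd,
#'   p_sd, q_sd, model_id, n.
#' @export
fit_ewas <- function(beta, sheet, fractions = NULL,
                     spec = ewas_model_spec("model1"),
                     config = pipeline_config(), drop_cell_type = "Gran") {
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("sample sheet does not cover all beta matrix columns")
  if (length(unique(sheet$tissue)) != 1L)
    stop("all samples in one EWAS must share tissue")
  X <- .ewas_design(sheet, fractions, spec$prenatal_covariates, drop_cell_type)
  Y <- if (config$meth_scale == "percent") beta * 100 else beta
  fit <- .fit_lm_matrix(Y, X, c("GA", "SDscore"))
  data.frame(
    probe_id = rownames(beta),
    beta_ga = fit$GA$estimate, se_ga = fit$GA$se, p_ga = fit$GA$p,
    q_ga = bh_adjust(fit$GA$p),
    beta_sd = fit$SDscore$estimate, se_sd = fit$SDscore$se,
    p_sd = fit$SDscore$p, q_sd = bh_adjust(fit$SDscore$p),
    model_id = spec$model_id, n = fit$n,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, where p_(1) <=
#' ... <= p_(m).  Order-preserving; ties resolved by stable sort (no effect
#' on the values).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("bh_adjust: NA/NaN p-values")
  if (any(p < 0 | p > 1)) stop("bh_adjust: p-values outside [0, 1]")
  m <- length(p)
  o <- order(p)                       # stable in base R
  q <- pmin(1, cummin((p[o] * m / seq_len(m))[m:1])[m:1])
  q[order(o)]
}

#' Direction-consistent intersection of two EWAS fits
#'
#' A probe is GA-related (resp. SD-score-related) when its GA (SD)
#' coefficient is FDR-significant in both fits and carries the same sign.
#'
#' @param r1,r2 [fit_ewas()] results over the same probe universe.
#' @param alpha FDR threshold (default 0.05).
#' @return list of class `consensus_cpgs` with data.frames `ga_related` and
#'   `sd_related` (probe_id, sign).
#' @export
intersect_models <- function(r1, r2, alpha = 0.05) {
  if (!setequal(r1$probe_id, r2$probe_id))
    stop("the two results cover different probe universes")
  r2 <- r2[match(r1$probe_id, r2$probe_id), , drop = FALSE]
  pick <- function(q1, b1, q2, b2) {
    hit <- q1 < alpha & q2 < alpha & sign(b1) == sign(b2) & sign(b1) != 0
    data.frame(probe_id = r1$probe_id[hit], sign = sign(b1)[hit],
               stringsAsFactors = FALSE)
  }
  out <- list(
    ga_related = pick(r1$q_ga, r1$beta_ga, r2$q_ga, r2$beta_ga),
    sd_related = pick(r1$q_sd, r1$beta_sd, r2$q_sd, r2$beta_sd)
  )
  out$ga_related <- out$ga_related[order(out$ga_related$probe_id), , drop = FALSE]
  out$sd_related <- out$sd_related[order(out$sd_related$probe_id), , drop = FALSE]
  rownames(out$ga_related) <- rownames(out$sd_related) <- NULL
  class(out) <- "consensus_cpgs"
  out
}

#' Single-covariate sensitivity overlap
#'
#' Refits Model 1 plus each listed prenatal covariate in turn, and reports
#' how many consensus CpGs stay significant (q < alpha, same sign) in every
#' sensitivity fit.
#'
#' @param beta,sheet,fractions as [fit_ewas()].
#' @param consensus a `consensus_cpgs` object.
#' @param covars prenatal covariates to add one at a time (default the six
#'   Model 2 covariates).
#' @param alpha FDR threshold.
#' @param config pipeline configuration.
#' @return list per predictor (`ga`, `sd`): ids surviving all fits, count,
#'   and fraction of the consensus set.
#' @export
sensitivity_overlap <- function(beta, sheet, fractions, consensus,
                                covars = MODEL2_COVARIATES, alpha = 0.05,
                                config = pipeline_config()) {
  keep_ga <- consensus$ga_related
  keep_sd <- consensus$sd_related
  for (cv in covars) {
    fit <- fit_ewas(beta, sheet, fractions,
                    ewas_model_spec("sensitivity", cv), config)
    i <- match(keep_ga$probe_id, fit$probe_id)
    ok <- fit$q_ga[i] < alpha & sign(fit$beta_ga[i]) == keep_ga$sign
    keep_ga <- keep_ga[ok, , drop = FALSE]
    i <- match(keep_sd$probe_id, fit$probe_id)
    ok <- fit$q_sd[i] < alpha & sign(fit$beta_sd[i]) == keep_sd$sign
    keep_sd <- keep_sd[ok, , drop = FALSE]
  }
  frac <- function(kept, full) if (nrow(full)) nrow(kept) / nrow(full) else NA_real_
  list(
    ga = list(ids = keep_ga$probe_id, count = nrow(keep_ga),
              fraction = frac(keep_ga, consensus$ga_related)),
    sd = list(ids = keep_sd$probe_id, count = nrow(keep_sd),
              fraction = frac(keep_sd, consensus$sd_related))
  )
}

#' Island-relation enrichment of a CpG set
#'
#' For each island relation (Island/Shore/Shelf/OpenSea): fold change of the
#' in-set proportion over the background (full-universe) proportion, and a
#' two-sided Fisher's exact p from the 2x2 table of set vs rest by relation
#' vs not.
#'
#' @param cpg_set character probe ids (non-empty, subset of the background).
#' @param manifest probe manifest covering the background.
#' @param background probe ids forming the comparison universe (default all
#'   manifest probes).
#' @return data.frame: relation, n_set, prop_set, prop_background, fold, p.
#' @export
enrich_island_relation <- function(cpg_set, manifest,
                                   background = manifest$probe_id) {
  if (!length(cpg_set)) stop("empty CpG set")
  rel_all <- manifest$island_relation[match(background, manifest$probe_id)]
  in_set <- background %in% cpg_set
  n_set <- sum(in_set); n_bg <- length(background)
  do.call(rbind, lapply(ISLAND_RELATIONS, function(rl) {
    a <- sum(in_set & rel_all == rl)
    b <- n_set - a
    c_ <- sum(!in_set & rel_all == rl)
    d <- (n_bg - n_set) - c_
    prop_set <- a / n_set
    prop_bg <- (a + c_) / n_bg
    p <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
    data.frame(relation = rl, n_set = a, prop_set = prop_set,
               prop_background = prop_bg,
               fold = if (prop_bg > 0) prop_set / prop_bg else NA_real_,
               p = p, stringsAsFactors = FALSE)
  }))
}
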