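# Association of prenatal covariates with GA and birth-weight SD score,
# with 2-SD (Gelman) scaling of continuous covariates so effect estimates
# are comparable with those of binary covariates.

#' Standardize a continuous covariate to SD 0.5
#'
#' Centers to mean 0 and rescales to sample standard deviation 0.5, i.e.
#' divides by two standard deviations, so a "+1" change spans 2 SD and the
#' regression estimate is comparable to a binary category switch.  Binary
#' covariates must be passed through unscaled by the caller.
#'
#' @param values numeric vector with at least two distinct values.
#' @return scaled vector (mean 0, sample SD exactly 0.5).
#' @export
gelman_scale <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2L)
    stop("cannot scale a constant covariate")
  (values - mean(values, na.rm = TRUE)) / (2 * sd(values, na.rm = TRUE))
}

# Internal: one OLS of outcome on a design, returning the row for `term`
.ols_effect <- function(y, X, term, name, model) {
  fit <- lm(y ~ ., data = as.data.frame(X))
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm))
    return(data.frame(covariate = name, estimate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_, model = model))
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  df <- fit$df.residual
  tq <- qt(0.975, df)
  data.frame(covariate = name, estimate = est, ci_low = est - tq * se,
             ci_high = est + tq * se, p = sm[term, "Pr(>|t|)"], model = model,
             stringsAsFactors = FALSE)
}

#' Screen prenatal covariates against GA or birth-weight SD score
#'
#' One univariate OLS per covariate (continuous covariates 2-SD scaled via
#' [gelman_scale()], binaries unscaled), with two-sided t-test p-values and
#' exact-t 95 percent CIs; then one multivariate OLS including infant sex
#' and the covariates passing the screen threshold (default p < 0.05; a
#' `suggestive_p` option widens the multivariate set to suggestive hits,
#' e.g. p = 0.060).
#'
#' @param sheet sample sheet (cord rows are used; postnatal rows dropped).
#' @param outcome "GA" (ga_weeks) or "SDscore" (bw_sd_score).
#' @param screen_p univariate p threshold for entering the multivariate
#'   model (default 0.05).
#' @param suggestive_p optional wider threshold; covariates with
#'   screen_p <= p < suggestive_p also enter the multivariate model.
#' @param include_other_outcome also screen the other outcome variable
#'   (SD score when outcome is GA and vice versa) as a covariate; whether it
#'   enters the multivariate model is governed by the same screen.
#' @param multivariate_covars optional explicit covariate set for the
#'   multivariate model, overriding the screen.
#' @return data.frame of effects (covariate, estimate, ci_low, ci_high, p,
#'   model in {univariate, multivariate}).
#' @export
covariate_screen <- function(sheet, outcome = c("GA", "SDscore"),
                             screen_p = 0.05, suggestive_p = NULL,
                             include_other_outcome = TRUE,
                             multivariate_covars = NULL) {
  outcome <- match.arg(outcome)
  sheet <- sheet[sheet$tissue == "cord", , drop = FALSE]
  y <- if (outcome == "GA") sheet$ga_weeks else sheet$bw_sd_score
  if (length(unique(y)) < 2L) stop("outcome is constant")

  other <- if (outcome == "GA") "bw_sd_score" else "ga_weeks"
  cont <- intersect(CONTINUOUS_COVARIATES, colnames(sheet))
  if (include_other_outcome) cont <- c(other, cont)
  bin <- intersect(BINARY_COVARIATES, colnames(sheet))

  design_col <- function(cv) {
    if (cv == "sex") as.numeric(sheet$sex == "male")
    else if (cv %in% cont && !cv %in% bin) gelman_scale(sheet[[cv]])
    else sheet[[cv]]
  }
  covs <- c("sex", cont, bin)
  uni <- do.call(rbind, lapply(covs, function(cv) {
    X <- data.frame(x = design_col(cv))
    .ols_effect(y, X, "x", cv, "univariate")
  }))

  if (is.null(multivariate_covars)) {
    sel <- uni$covariate[!is.na(uni$p) & uni$p < screen_p]
    if (!is.null(suggestive_p))
      sel <- union(sel, uni$covariate[!is.na(uni$p) & uni$p < suggestive_p])
    sel <- setdiff(sel, "sex")
  } else {
    sel <- multivariate_covars
  }
  Xm <- data.frame(sex = design_col("sex"))
  for (cv in sel) Xm[[cv]] <- design_col(cv)
  multi <- do.call(rbind, lapply(colnames(Xm), function(cv)
    .ols_effect(y, Xm, cv, cv, "multivariate")))
  rbind(uni, multi)
}
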