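# Methylation-transcription integration: cis CpG-transcript matching within
# a +/-250 kb window, transcript association with GA/SD score, and Pearson
# methylation-expression correlation with concordant/discordant promoter
# classification.

#' Match CpGs to expression probes within a cis window
#'
#' All (CpG, expression probe) pairs on the same chromosome with
#' |expr pos - CpG pos| <= window, boundary inclusive; many-to-many pairs
#' allowed.  CpGs without manifest coordinates are skipped with a warning
#' and counted.
#'
#' @param cpgs character CpG probe ids to match.
#' @param cpg_manifest probe manifest with chrom/pos.
#' @param expr_manifest expression probe manifest with chrom/pos.
#' @param window half-width in bp (default 250000).
#' @return data.frame of class `cis_pairs`: cpg_id, expr_probe_id, gene,
#'   distance (expr pos - CpG pos, signed); attribute `n_skipped` counts
#'   CpGs without coordinates.
#' @export
match_cis_pairs <- function(cpgs, cpg_manifest, expr_manifest,
                            window = 250000L) {
  i <- match(cpgs, cpg_manifest$probe_id)
  skipped <- sum(is.na(i))
  if (skipped) {
    warning(skipped, " CpG(s) missing from the manifest were skipped")
    cpgs <- cpgs[!is.na(i)]
    i <- i[!is.na(i)]
  }
  cpos <- cpg_manifest$pos[i]
  cchr <- cpg_manifest$chrom[i]
  out <- vector("list", 0L)
  for (chr in unique(cchr)) {
    ei <- which(expr_manifest$chrom == chr)
    if (!length(ei)) next
    ord <- ei[order(expr_manifest$pos[ei])]
    epos <- expr_manifest$pos[ord]
    ci <- which(cchr == chr)
    lo <- findInterval(cpos[ci] - window, epos, left.open = TRUE) + 1L
    hi <- findInterval(cpos[ci] + window, epos)
    n_each <- pmax(hi - lo + 1L, 0L)
    keep <- n_each > 0L
    if (!any(keep)) next
    idx <- sequence(n_each[keep]) +
      rep(lo[keep], n_each[keep]) - 1L
    rows <- data.frame(
      cpg_id = rep(cpgs[ci][keep], n_each[keep]),
      expr_probe_id = expr_manifest$expr_probe_id[ord][idx],
      gene = expr_manifest$gene[ord][idx],
      distance = epos[idx] - rep(cpos[ci][keep], n_each[keep]),
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- rows
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cpg_id = character(), expr_probe_id = character(),
               gene = character(), distance = integer(),
               stringsAsFactors = FALSE)
  res <- res[order(res$cpg_id, res$expr_probe_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  class(res) <- c("cis_pairs", "data.frame")
  res
}

#' Transcript association with GA and SD score
#'
#' For each matched expression probe, OLS of log2 expression on GA + SD
#' score adjusted for infant sex, batch and cell fractions (the same
#' adjustment engine as the EWAS).  BH q-values are computed over the
#' matched probe set only.
#'
#' @param expr expression matrix (probes x samples).
#' @param sheet sample sheet covering the expression samples (cord tissue).
#' @param fractions cell fractions, or NULL to omit.
#' @param probes expression probe ids to test (the matched set); q is scoped
#'   to these.
#' @return data.frame: expr_probe_id, beta_ga, se_ga, p_ga, q_ga, beta_sd,
#'   se_sd, p_sd, q_sd, n.
#' @export
fit_transcript_assoc <- function(expr, sheet, fractions = NULL,
                                 probes = rownames(expr)) {
  missing <- setdiff(probes, rownames(expr))
  if (length(missing))
    stop("expression matrix lacks probe(s): ",
         paste(head(missing, 3L), collapse = ", "))
  Y <- expr[probes, , drop = FALSE]
  sheet <- sheet[match(colnames(Y), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("sample sheet does not cover all expression samples")
  X <- .ewas_design(sheet, fractions, character())
  fit <- .fit_lm_matrix(Y, X, c("GA", "SDscore"))
  data.frame(
    expr_probe_id = probes,
    beta_ga = fit$GA$estimate, se_ga = fit$GA$se, p_ga = fit$GA$p,
    q_ga = bh_adjust(fit$GA$p),
    beta_sd = fit$SDscore$estimate, se_sd = fit$SDscore$se,
    p_sd = fit$SDscore$p, q_sd = bh_adjust(fit$SDscore$p),
    n = fit$n, stringsAsFactors = FALSE, row.names = NULL
  )
}

# Internal: Pearson r -> two-sided p via the t transform with n-2 df
.pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  p[abs(r) == 1] <- 0
  p
}

#' Correlate CpG methylation with transcript expression
#'
#' Pearson correlation between methylation and log2 expression over the
#' samples shared by the two matrices, for each cis pair.  Promoter CpGs
#' (TSS200/TSS1500/5'UTR/1st exon) are classified 'concordant' when r < 0
#' (transcription falls as methylation rises) and 'discordant' when r > 0;
#' the relation is NA outside promoters.  Pairs with fewer than 3 shared
#' samples are skipped and counted.
#'
#' @param pairs `cis_pairs` rows restricted to the transcripts of interest.
#' @param beta beta matrix (cord samples).
#' @param expr expression matrix.
#' @param cpg_manifest probe manifest supplying gene_region.
#' @param nominal_alpha threshold for the `significant` flag (default 0.05).
#' @return data.frame: cpg_id, expr_probe_id, r, p, n, region_class,
#'   relation, significant; attribute `n_skipped`.
#' @export
correlate_meth_expr <- function(pairs, beta, expr, cpg_manifest,
                                nominal_alpha = 0.05) {
  shared <- intersect(colnames(beta), colnames(expr))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  ok <- pairs$cpg_id %in% rownames(beta) &
    pairs$expr_probe_id %in% rownames(expr)
  skipped <- sum(!ok)
  pr <- pairs[ok, , drop = FALSE]
  B <- beta[pr$cpg_id, shared, drop = FALSE]
  E <- expr[pr$expr_probe_id, shared, drop = FALSE]
  n <- length(shared)
  rB <- B - rowMeans(B); rE <- E - rowMeans(E)
  num <- rowSums(rB * rE)
  den <- sqrt(rowSums(rB^2) * rowSums(rE^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  region <- cpg_manifest$gene_region[match(pr$cpg_id, cpg_manifest$probe_id)]
  region_class <- ifelse(region %in% PROMOTER_REGIONS, "Promoter",
                         ifelse(region %in% GENEBODY_REGIONS, "GeneBody", "IGR"))
  relation <- ifelse(region_class != "Promoter" | is.na(r), NA_character_,
                     ifelse(r > 0, "discordant",
                            ifelse(r < 0, "concordant", NA_character_)))
  p <- .pearson_p(r, n)
  out <- data.frame(cpg_id = pr$cpg_id, expr_probe_id = pr$expr_probe_id,
                    r = r, p = p, n = n, region_class = region_class,
                    relation = relation, significant = !is.na(p) & p < nominal_alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped") <- skipped
  out
}
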