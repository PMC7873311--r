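# Cord -> postnatal persistence scoring ("epigenetic memory"), interval
# confounding check, 25-state chromatin distribution/enrichment, decile
# trend curves, region correlation heatmaps, and overlap/gene ranking.

# Internal: map paired subjects to (cord sample, postnatal sample) columns
.paired_samples <- function(cord, post, sheet) {
  cs <- sheet[sheet$tissue == "cord" & sheet$sample_id %in% colnames(cord), ]
  ps <- sheet[sheet$tissue == "postnatal" & sheet$sample_id %in% colnames(post), ]
  subj <- intersect(cs$subject_id, ps$subject_id)
  if (!length(subj)) stop("no paired subjects between cord and postnatal data")
  data.frame(subject_id = subj,
             cord_sample = cs$sample_id[match(subj, cs$subject_id)],
             post_sample = ps$sample_id[match(subj, ps$subject_id)],
             interval_weeks = ps$interval_weeks[match(subj, ps$subject_id)],
             stringsAsFactors = FALSE)
}

# Internal: rowwise Pearson r between two aligned matrices
.row_cor <- function(A, B) {
  cA <- A - rowMeans(A); cB <- B - rowMeans(B)
  den <- sqrt(rowSums(cA^2) * rowSums(cB^2))
  ifelse(den > 0, rowSums(cA * cB) / den, NA_real_)
}

#' Paired cord-postnatal correlation per CpG
#'
#' Pearson correlation across paired subjects between cord methylation and
#' postnatal methylation of the same CpG.  CpGs with r at or above the
#' threshold (inclusive) are flagged as epigenetic-memory candidates.
#'
#' @param cord,post beta matrices; columns map to subjects via the sheet.
#' @param sheet sample sheet defining the subject pairing.
#' @param cpgs CpG ids to score (e.g. the GA-related consensus set); must be
#'   rows of both matrices.
#' @param r_threshold inclusive candidate threshold (default 0.7).
#' @return data.frame of class `memory_records`: cpg_id, r_cord_post, p,
#'   n_pairs, is_candidate.
#' @export
cord_post_correlation <- function(cord, post, sheet,
                                  cpgs = rownames(cord), r_threshold = 0.7) {
  pairs <- .paired_samples(cord, post, sheet)
  if (nrow(pairs) < 3L) stop("need at least 3 paired subjects")
  missing <- setdiff(cpgs, intersect(rownames(cord), rownames(post)))
  if (length(missing))
    stop("CpG(s) absent from cord/postnatal matrices: ",
         paste(head(missing, 3L), collapse = ", "))
  A <- cord[cpgs, pairs$cord_sample, drop = FALSE]
  B <- post[cpgs, pairs$post_sample, drop = FALSE]
  r <- .row_cor(A, B)
  out <- data.frame(cpg_id = cpgs, r_cord_post = r,
                    p = .pearson_p(r, nrow(pairs)), n_pairs = nrow(pairs),
                    is_candidate = !is.na(r) & r >= r_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("memory_records", "data.frame")
  out
}

#' Draw-interval confounding check
#'
#' Orders paired subjects by the cord-to-postnatal draw interval, splits
#' them into equal bottom/top halves (the median subject is dropped when the
#' count is odd), recomputes each CpG's cord-post correlation within each
#' half, and runs a paired t-test across CpGs of (bottom r - top r).  A
#' small mean difference indicates the persistence signal is not an artifact
#' of short draw intervals.
#'
#' @inheritParams cord_post_correlation
#' @param drop_middle drop the median-interval subject when the pair count
#'   is odd (default TRUE); FALSE assigns it to the bottom half.
#' @return list: mean_diff, ci (length-2), p, n_bottom, n_top,
#'   zero_variance (TRUE when the per-CpG differences are all identical, in
#'   which case p is reported as 1).
#' @export
interval_check <- function(cord, post, sheet, cpgs = rownames(cord),
                           drop_middle = TRUE) {
  pairs <- .paired_samples(cord, post, sheet)
  pairs <- pairs[order(pairs$interval_weeks, pairs$subject_id), , drop = FALSE]
  n <- nrow(pairs)
  if (n < 6L) stop("need at least 6 paired subjects for the interval split")
  h <- n %/% 2L
  if (n %% 2L == 1L && drop_middle) {
    bottom <- pairs[seq_len(h), ]
    top <- pairs[(h + 2L):n, ]
  } else {
    bottom <- pairs[seq_len(h + n %% 2L), ]
    top <- pairs[(h + n %% 2L + 1L):n, ]
  }
  if (nrow(bottom) < 3L || nrow(top) < 3L)
    stop("interval halves smaller than 3 subjects")
  r_half <- function(pp)
    .row_cor(cord[cpgs, pp$cord_sample, drop = FALSE],
             post[cpgs, pp$post_sample, drop = FALSE])
  d <- r_half(bottom) - r_half(top)
  d <- d[!is.na(d)]
  if (length(unique(d)) <= 1L) {
    return(list(mean_diff = if (length(d)) mean(d) else NA_real_,
                ci = c(NA_real_, NA_real_), p = 1,
                n_bottom = nrow(bottom), n_top = nrow(top),
                zero_variance = TRUE))
  }
  tt <- t.test(d)
  list(mean_diff = unname(tt$estimate), ci = unname(tt$conf.int),
       p = tt$p.value, n_bottom = nrow(bottom), n_top = nrow(top),
       zero_variance = FALSE)
}

# Internal: pull the chromatin-state column for an annotation cell type
.state_col <- function(manifest, annotation = c("T", "B")) {
  annotation <- match.arg(annotation)
  col <- paste0("chromstate_", annotation)
  states <- manifest[[col]]
  bad <- setdiff(unique(states), CHROM_STATES_25)
  if (length(bad))
    stop("unknown chromatin state label(s): ", paste(bad, collapse = ", "))
  states
}

#' Distribution of the 25 chromatin states over a CpG set
#'
#' @param cpg_set non-empty character CpG ids.
#' @param manifest probe manifest.
#' @param annotation "T" (cord T-cell annotation) or "B" (B-cell).
#' @return data.frame: state (all 25, fixed order, zero counts included),
#'   count, proportion.
#' @export
state_distribution <- function(cpg_set, manifest, annotation = c("T", "B")) {
  if (!length(cpg_set)) stop("empty CpG set")
  states <- .state_col(manifest, annotation)
  s <- states[match(cpg_set, manifest$probe_id)]
  if (anyNA(s))
    stop("CpG(s) absent from manifest: ",
         paste(head(cpg_set[is.na(s)], 3L), collapse = ", "))
  counts <- table(factor(s, levels = CHROM_STATES_25))
  data.frame(state = CHROM_STATES_25, count = as.integer(counts),
             proportion = as.integer(counts) / length(s),
             stringsAsFactors = FALSE)
}

#' Chromatin-state enrichment of a CpG set
#'
#' Per state, a 2x2 table of set vs background-minus-set by state vs other
#' states (disjoint rows; `mode = "full"` switches to set vs the whole
#' background).  Odds ratio from the cross-product; two-sided Fisher's
#' exact p; 95 percent CI of the log odds ratio by normal approximation,
#' with the Haldane-Anscombe +0.5 correction applied and flagged when any
#' cell is zero.  Significance requires p below the Bonferroni threshold
#' (alpha / family) and OR >= 1.
#'
#' @param cpg_set character CpG ids (strict subset of the background).
#' @param manifest probe manifest.
#' @param background comparison universe ids (default the whole manifest).
#' @param annotation "T" or "B".
#' @param mode "disjoint" (default) or "full" background rows.
#' @param alpha family-wise alpha (default 0.05).
#' @param family number of tests for Bonferroni (default 25).
#' @return data.frame: state, count, proportion, background_proportion,
#'   odds_ratio, ci_low, ci_high, p, zero_cell, significant.
#' @export
state_enrichment <- function(cpg_set, manifest,
                             background = manifest$probe_id,
                             annotation = c("T", "B"),
                             mode = c("disjoint", "full"),
                             alpha = 0.05, family = 25L) {
  mode <- match.arg(mode)
  if (!length(cpg_set)) stop("empty CpG set")
  if (setequal(cpg_set, background))
    stop("set equals background: enrichment is degenerate")
  states <- .state_col(manifest, annotation)
  s_set <- states[match(cpg_set, manifest$probe_id)]
  rest_ids <- if (mode == "disjoint") setdiff(background, cpg_set) else background
  s_rest <- states[match(rest_ids, manifest$probe_id)]
  s_bg <- states[match(background, manifest$probe_id)]
  n1 <- length(s_set); n2 <- length(s_rest)
  do.call(rbind, lapply(CHROM_STATES_25, function(st) {
    a <- sum(s_set == st); b <- n1 - a
    c_ <- sum(s_rest == st); d <- n2 - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))$p.value
    zero <- any(c(a, b, c_, d) == 0)
    cc <- if (zero) 0.5 else 0
    or <- ((a + cc) * (d + cc)) / ((b + cc) * (c_ + cc))
    se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc))
    data.frame(state = st, count = a, proportion = a / n1,
               background_proportion = sum(s_bg == st) / length(s_bg),
               odds_ratio = or,
               ci_low = exp(log(or) - 1.96 * se),
               ci_high = exp(log(or) + 1.96 * se),
               p = p, zero_cell = zero,
               significant = p < alpha / family & or >= 1,
               stringsAsFactors = FALSE)
  }))
}

#' Decile trend of chromatin-state enrichment over cord-post correlation
#'
#' Orders the GA-related CpG universe by cord-post correlation (ties broken
#' by CpG id so bins are deterministic), partitions it into 10 bins of
#' near-equal size (sizes differ by at most 1, larger bins first), and
#' computes each requested state's enrichment odds ratio per bin against the
#' full-manifest background.
#'
#' @param records `memory_records` over the GA-related universe.
#' @param manifest probe manifest.
#' @param states chromatin states to trace (e.g. c("ReprPC", "PromBiv")).
#' @param annotation "T" or "B".
#' @param background background ids (default whole manifest).
#' @return data.frame: bin (1 = lowest correlations), state, n, odds_ratio,
#'   ci_low, ci_high, p, zero_cell.
#' @export
decile_trend <- function(records, manifest, states = c("ReprPC", "PromBiv"),
                         annotation = c("T", "B"),
                         background = manifest$probe_id) {
  n <- nrow(records)
  if (n < 10L) stop("universe smaller than 10 CpGs")
  ord <- order(records$r_cord_post, records$cpg_id)
  sizes <- rep(n %/% 10L, 10L)
  extra <- n %% 10L
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- rep(seq_len(10L), sizes)
  ids <- records$cpg_id[ord]
  out <- do.call(rbind, lapply(seq_len(10L), function(b) {
    en <- state_enrichment(ids[bin == b], manifest, background,
                           annotation = annotation)
    en <- en[en$state %in% states, , drop = FALSE]
    data.frame(bin = b, state = en$state, n = sizes[b],
               odds_ratio = en$odds_ratio, ci_low = en$ci_low,
               ci_high = en$ci_high, p = en$p, zero_cell = en$zero_cell,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-correlation map between cord and postnatal methylation of a region
#'
#' Full matrix of Pearson correlations, entry (i, j) = cor over paired
#' subjects of cord methylation at CpG i with postnatal methylation at
#' CpG j.  The diagonal reproduces [cord_post_correlation()].
#'
#' @inheritParams cord_post_correlation
#' @param cpg_ids ordered CpG ids of the region.
#' @return numeric matrix (cord CpGs x postnatal CpGs).
#' @export
region_correlation_map <- function(cord, post, sheet, cpg_ids) {
  pairs <- .paired_samples(cord, post, sheet)
  if (nrow(pairs) < 3L) stop("need at least 3 paired subjects")
  A <- t(cord[cpg_ids, pairs$cord_sample, drop = FALSE])
  B <- t(post[cpg_ids, pairs$post_sample, drop = FALSE])
  m <- cor(A, B)
  dimnames(m) <- list(cpg_ids, cpg_ids)
  m
}

#' Overlap memory candidates with expression-correlated CpGs, rank genes
#'
#' Intersects the memory-candidate CpGs with the CpGs showing a significant
#' methylation-expression correlation, and ranks genes by the number of
#' qualifying CpGs (ties broken alphabetically), reporting the
#' concordant/discordant composition per gene.
#'
#' @param memory `memory_records`.
#' @param methexpr output of [correlate_meth_expr()].
#' @param manifest probe manifest (gene assignment).
#' @return list: `overlap` (sorted CpG ids), `genes` (data.frame gene,
#'   n_cpgs, n_concordant, n_discordant, ranked).
#' @export
overlap_and_rank <- function(memory, methexpr, manifest) {
  cand <- memory$cpg_id[memory$is_candidate]
  corr <- unique(methexpr$cpg_id[methexpr$significant])
  overlap <- sort(intersect(cand, corr))
  me <- methexpr[methexpr$significant & methexpr$cpg_id %in% overlap, ,
                 drop = FALSE]
  gene <- manifest$gene[match(me$cpg_id, manifest$probe_id)]
  keep <- !is.na(gene) & gene != ""
  me <- me[keep, , drop = FALSE]; gene <- gene[keep]
  per <- unique(data.frame(gene = gene, cpg_id = me$cpg_id,
                           relation = me$relation, stringsAsFactors = FALSE))
  if (nrow(per)) {
    n_cpgs <- tapply(per$cpg_id, per$gene, function(x) length(unique(x)))
    n_con <- tapply(per$relation == "concordant" & !is.na(per$relation),
                    per$gene, sum)
    n_dis <- tapply(per$relation == "discordant" & !is.na(per$relation),
                    per$gene, sum)
    genes <- data.frame(gene = names(n_cpgs), n_cpgs = as.integer(n_cpgs),
                        n_concordant = as.integer(n_con),
                        n_discordant = as.integer(n_dis),
                        stringsAsFactors = FALSE)
    genes <- genes[order(-genes$n_cpgs, genes$gene), , drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(gene = character(), n_cpgs = integer(),
                        n_concordant = integer(), n_discordant = integer(),
                        stringsAsFactors = FALSE)
  }
  list(overlap = overlap, genes = genes)
}
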