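# Beta computation from allele intensities, probe QC filtering, and
# reference-based cell-type deconvolution by constrained projection.

#' Compute array beta values from allele intensities
#'
#' beta = M / (U + M + 100).  The +100 offset regularizes low-intensity
#' probes and bounds the statistic strictly below 1.
#'
#' @param M methylated-allele intensity (>= 0), vectorized.
#' @param U unmethylated-allele intensity (>= 0), vectorized.
#' @return methylation proportion(s) in `[0, 1)`.
#' @export
compute_beta <- function(M, U) {
  if (any(M < 0) || any(U < 0)) stop("intensities must be non-negative")
  M / (U + M + 100)
}

#' Filter CpG probes by QC rules
#'
#' Removes probes in a fixed rule order, attributing each removed probe to
#' the first rule that catches it: (1) non-CpG probes — an explicit `is_cpg`
#' manifest column when present, otherwise the "cg" id-prefix convention;
#' (2) sex chromosomes (X/Y); (3) detection p-value failures; (4) beadcount
#' failures; (5) multi-mapping blacklist; (6) cross-reactive/polymorphic
#' blacklist.  The report reconciles: input = survivors + sum(removals).
#'
#' @param manifest probe manifest (see [read_probe_manifest()]); may carry an
#'   `is_cpg` 0/1 column.
#' @param qc long data.frame with columns probe_id, sample_id, detection_p,
#'   beadcount (one row per probe per sample); NULL skips rules 3-4.
#' @param blacklists list with character-vector elements `multi_mapping` and
#'   `cross_reactive` (either may be empty).
#' @param policy list: `detection` is "any" (drop if detection_p > p_max in
#'   any sample, the default — matching the strictness implied by small
#'   surviving-probe counts on real arrays) or "fraction" (drop if the
#'   failing-sample fraction exceeds `detection_fraction`); `beadcount`
#'   likewise "any" or "fraction"; `detection_p_max` (0.01);
#'   `beadcount_min` (3).
#' @return list with `kept` (character probe ids, manifest order) and
#'   `report` (named integer vector of removal counts plus survivors).
#' @export
filter_probes <- function(manifest, qc = NULL,
                          blacklists = list(multi_mapping = character(),
                                            cross_reactive = character()),
                          policy = list()) {
  pol <- modifyList(list(detection = "any", detection_fraction = 0.05,
                         beadcount = "any", beadcount_fraction = 0.05,
                         detection_p_max = 0.01, beadcount_min = 3), policy)
  if (!pol$detection %in% c("any", "fraction"))
    stop("unknown detection policy: ", pol$detection)
  if (!pol$beadcount %in% c("any", "fraction"))
    stop("unknown beadcount policy: ", pol$beadcount)

  ids <- manifest$probe_id
  alive <- rep(TRUE, length(ids))
  report <- c(non_cpg = 0L, sex_chromosome = 0L, detection = 0L,
              beadcount = 0L, multi_mapping = 0L, cross_reactive = 0L,
              survivors = 0L)
  take <- function(hit, rule) {
    hit <- hit & alive
    report[[rule]] <<- sum(hit)
    alive <<- alive & !hit
  }

  if ("is_cpg" %in% colnames(manifest)) {
    take(manifest$is_cpg == 0, "non_cpg")
  } else {
    take(!startsWith(ids, "cg"), "non_cpg")
  }
  take(manifest$chrom %in% c("X", "Y", "chrX", "chrY"), "sex_chromosome")

  if (!is.null(qc)) {
    bad <- setdiff(unique(qc$probe_id), ids)
    if (length(bad))
      stop("qc table contains probes absent from manifest: ",
           paste(head(bad, 3L), collapse = ", "))
    fail_frac <- function(fail_flag) {
      f <- tapply(fail_flag, qc$probe_id, mean)
      f[match(ids, names(f))]
    }
    det <- fail_frac(qc$detection_p > pol$detection_p_max)
    det[is.na(det)] <- 0
    thr <- if (pol$detection == "any") 0 else pol$detection_fraction
    take(det > thr, "detection")
    bc <- fail_frac(qc$beadcount < pol$beadcount_min)
    bc[is.na(bc)] <- 0
    thr <- if (pol$beadcount == "any") 0 else pol$beadcount_fraction
    take(bc > thr, "beadcount")
  }
  take(ids %in% blacklists$multi_mapping, "multi_mapping")
  take(ids %in% blacklists$cross_reactive, "cross_reactive")

  report[["survivors"]] <- sum(alive)
  stopifnot(length(ids) == sum(report))
  list(kept = ids[alive], report = report)
}

#' Estimate cell-type fractions by constrained projection
#'
#' For each sample, solves the reference-based deconvolution quadratic
#' program min ||y - R f||^2 subject to f >= 0 and sum(f) <= 1, where y is
#' the sample's beta vector over reference CpGs and R is the reference
#' profile matrix (CpGs x cell types).  The inequality sum constraint
#' follows the constrained-projection formulation (an unexplained remainder
#' is allowed); set `renormalize = TRUE` to rescale fractions to sum to 1
#' for downstream regression use.
#'
#' @param beta beta matrix restricted to reference CpGs (rows must cover the
#'   reference rows).
#' @param reference numeric matrix, reference CpGs x cell types, values in
#'   `[0, 1)`; column names are the cell-type labels.
#' @param renormalize rescale each sample's fractions to sum to 1.
#' @return data.frame: sample_id, one column per cell type, residual_norm.
#' @export
estimate_cell_fractions <- function(beta, reference, renormalize = FALSE) {
  if (is.null(colnames(reference)))
    stop("reference matrix needs cell-type column names")
  k <- ncol(reference)
  if (nrow(reference) < k)
    stop("need at least as many reference CpGs as cell types")
  common <- intersect(rownames(beta), rownames(reference))
  if (length(common) < k)
    stop("fewer than ", k, " reference CpGs present in the beta matrix; ",
         "supply more/better reference CpGs")
  R <- reference[common, , drop = FALSE]
  if (qr(R)$rank < k)
    stop("reference profile matrix is rank-deficient; ",
         "supply more/better reference CpGs")
  Y <- beta[common, , drop = FALSE]
  Dmat <- crossprod(R)
  Amat <- cbind(rep(-1, k), diag(k))   # -sum(f) >= -1 ; f_i >= 0
  bvec <- c(-1, rep(0, k))
  res <- matrix(0, ncol(Y), k, dimnames = list(colnames(Y), colnames(R)))
  rn <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    sol <- quadprog::solve.QP(Dmat, crossprod(R, y), Amat, bvec, meq = 0)
    f <- pmax(sol$solution, 0)
    res[j, ] <- f
    rn[j] <- sqrt(sum((y - R %*% f)^2))
  }
  if (renormalize) {
    s <- rowSums(res)
    res <- res / ifelse(s > 0, s, 1)
  }
  data.frame(sample_id = colnames(Y), res, residual_norm = rn,
             check.names = FALSE, row.names = NULL)
}
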