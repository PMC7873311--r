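# End-to-end orchestration: validate inputs up front, run the stages in
# their canonical order, write every stage output as TSV, and record a run
# manifest (config snapshot, content digests, seed, timestamps) so a rerun
# with identical inputs reproduces identical digests.

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Stage order: covariate screen, cell-fraction estimation, EWAS under
#' Models 1 and 2, direction-consistent consensus, sensitivity fits, island
#' enrichment, promoter gene lists (plus gene-set enrichment when a GMT is
#' supplied), cis matching, transcript association, methylation-expression
#' correlation, memory scoring, interval check, chromatin-state enrichment,
#' decile trend, and overlap/gene ranking.  All inputs are validated before
#' any stage runs; any stage error aborts with the stage name.
#'
#' @param paths named list of input paths: sheet, beta_cord, beta_postnatal,
#'   expression, cpg_manifest, expr_manifest, reference (TSV, reference CpGs
#'   x 7 cell types), and optionally gmt.
#' @param outdir output directory for stage TSVs and the run manifest.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the run manifest, the stage-count report,
#'   and the in-memory stage outputs.
#' @export
run_pipeline <- function(paths, outdir, config = pipeline_config()) {
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- fail-fast input validation --------------------------------------------
  inp <- stage("validate", {
    need <- c("sheet", "beta_cord", "beta_postnatal", "expression",
              "cpg_manifest", "expr_manifest", "reference")
    missing <- setdiff(need, names(paths))
    if (length(missing))
      stop("missing input path(s): ", paste(missing, collapse = ", "))
    sheet <- read_sample_sheet(paths$sheet)
    bad <- setdiff(MODEL2_COVARIATES, colnames(sheet))
    if (length(bad))
      stop("Model 2 covariate(s) absent from sample sheet: ",
           paste(bad, collapse = ", "))
    ref_tab <- read.delim(paths$reference, check.names = FALSE)
    reference <- as.matrix(ref_tab[, -1L, drop = FALSE])
    rownames(reference) <- ref_tab[[1L]]
    list(sheet = sheet,
         cord = read_beta_matrix(paths$beta_cord),
         post = read_beta_matrix(paths$beta_postnatal),
         expr = read_expression_matrix(paths$expression),
         cpg_man = read_probe_manifest(paths$cpg_manifest),
         expr_man = read_expr_manifest(paths$expr_manifest),
         reference = reference,
         gmt = if (!is.null(paths$gmt)) read_gmt(paths$gmt))
  })
  sheet <- inp$sheet
  report <- list(n_cord = sum(sheet$tissue == "cord"),
                 n_postnatal = sum(sheet$tissue == "postnatal"),
                 n_cpgs = nrow(inp$cord))
  save <- function(obj, file) write_table(obj, file.path(outdir, file))

  cov_eff <- stage("covariates", rbind(
    cbind(outcome = "GA", covariate_screen(sheet, "GA")),
    cbind(outcome = "SDscore", covariate_screen(sheet, "SDscore"))))
  save(cov_eff, "covariate_effects.tsv")

  fractions <- stage("cellfrac", {
    cf_cord <- estimate_cell_fractions(inp$cord, inp$reference)
    cf_post <- estimate_cell_fractions(inp$post, inp$reference)
    rbind(cf_cord, cf_post)
  })
  save(fractions, "cell_fractions.tsv")

  r1 <- stage("ewas_model1",
              fit_ewas(inp$cord, sheet, fractions, ewas_model_spec("model1"),
                       config))
  r2 <- stage("ewas_model2",
              fit_ewas(inp$cord, sheet, fractions, ewas_model_spec("model2"),
                       config))
  save(r1, "ewas_model1.tsv"); save(r2, "ewas_model2.tsv")
  report$n_model1_ga <- sum(r1$q_ga < config$fdr_alpha)
  report$n_model2_ga <- sum(r2$q_ga < config$fdr_alpha)

  consensus <- stage("consensus", intersect_models(r1, r2, config$fdr_alpha))
  save(consensus$ga_related, "consensus_ga.tsv")
  save(consensus$sd_related, "consensus_sd.tsv")
  report$n_consensus_ga <- nrow(consensus$ga_related)
  report$n_consensus_sd <- nrow(consensus$sd_related)

  sens <- stage("sensitivity",
                sensitivity_overlap(inp$cord, sheet, fractions, consensus,
                                    alpha = config$fdr_alpha, config = config))
  report$sensitivity_ga_fraction <- sens$ga$fraction

  island <- stage("island_enrichment", {
    if (nrow(consensus$ga_related))
      enrich_island_relation(consensus$ga_related$probe_id, inp$cpg_man)
  })
  if (!is.null(island)) save(island, "island_enrichment.tsv")

  lists <- stage("gene_lists",
                 build_gene_lists(consensus, inp$cpg_man,
                                  config$min_cpgs_per_gene))
  save(do.call(rbind, lapply(names(lists), function(nm)
    if (nrow(lists[[nm]])) cbind(category = nm, lists[[nm]]) else NULL)),
    "gene_lists.tsv")
  if (!is.null(inp$gmt)) {
    universe <- unique(inp$cpg_man$gene[inp$cpg_man$gene != ""])
    enr <- do.call(rbind, lapply(names(lists), function(nm)
      cbind(category = nm,
            hypergeom_enrich(lists[[nm]]$gene, inp$gmt, universe,
                             config$enrichment_fdr))))
    save(enr, "geneset_enrichment.tsv")
  }

  all_hits <- union(consensus$ga_related$probe_id,
                    consensus$sd_related$probe_id)
  pairs <- stage("cis_match",
                 match_cis_pairs(all_hits, inp$cpg_man, inp$expr_man,
                                 config$cis_window_bp))
  save(pairs, "cis_pairs.tsv")
  report$n_cis_pairs <- nrow(pairs)

  ta <- stage("transcript_assoc",
              fit_transcript_assoc(inp$expr, sheet, fractions,
                                   intersect(unique(pairs$expr_probe_id),
                                             rownames(inp$expr))))
  save(ta, "transcript_assoc.tsv")
  ga_tx <- ta$expr_probe_id[ta$q_ga < config$fdr_alpha]
  report$n_ga_transcripts <- length(ga_tx)

  me <- stage("meth_expr", {
    sub <- pairs[pairs$expr_probe_id %in% ga_tx &
                   pairs$cpg_id %in% consensus$ga_related$probe_id, ,
                 drop = FALSE]
    if (nrow(sub))
      correlate_meth_expr(sub, inp$cord, inp$expr, inp$cpg_man,
                          config$nominal_alpha)
  })
  if (!is.null(me)) {
    save(me, "meth_expr.tsv")
    report$n_confirmed_combinations <- sum(me$significant)
    report$n_expression_correlated_cpgs <-
      length(unique(me$cpg_id[me$significant]))
  }

  memory <- stage("memory_score",
                  cord_post_correlation(inp$cord, inp$post, sheet,
                                        consensus$ga_related$probe_id,
                                        config$memory_r_threshold))
  save(memory, "memory.tsv")
  report$n_memory_candidates <- sum(memory$is_candidate)

  ic <- stage("interval_check",
              interval_check(inp$cord, inp$post, sheet,
                             consensus$ga_related$probe_id))
  report$interval_mean_diff <- ic$mean_diff

  cand <- memory$cpg_id[memory$is_candidate]
  if (length(cand)) {
    se <- stage("state_enrichment",
                state_enrichment(cand, inp$cpg_man, annotation = "T",
                                 alpha = 0.05,
                                 family = config$bonferroni_family))
    save(se, "state_enrichment_T.tsv")
  }
  if (nrow(memory) >= 10L) {
    trend <- stage("decile_trend", decile_trend(memory, inp$cpg_man))
    save(trend, "decile_trend.tsv")
  }
  ov <- stage("overlap_rank", {
    if (!is.null(me)) overlap_and_rank(memory, me, inp$cpg_man)
  })
  if (!is.null(ov)) {
    save(data.frame(cpg_id = ov$overlap), "overlap_cpgs.tsv")
    save(ov$genes, "gene_rank.tsv")
    report$n_overlap <- length(ov$overlap)
  }

  outputs <- list.files(outdir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("epimemory")),
    config = unclass(config), seed = config$rng_seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(paths, function(p) unname(tools::md5sum(p))),
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs)),
    report = report
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, report = report,
                 consensus = consensus, memory = memory, methexpr = me,
                 ewas = list(model1 = r1, model2 = r2),
                 transcript = ta, pairs = pairs, fractions = fractions))
}
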