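# Direction-stratified promoter gene lists from consensus CpGs, and generic
# one-sided hypergeometric gene-set enrichment against a GMT collection.

#' Build direction-stratified gene lists from consensus CpGs
#'
#' Keeps promoter-region CpGs (TSS200, TSS1500, 5'UTR, 1st exon) with a gene
#' annotation, maps them to genes, and retains genes supported by at least
#' `min_cpgs` promoter CpGs per direction category.  Categories: GA_pos,
#' GA_neg, SD_pos, SD_neg; a gene may appear in several categories.
#'
#' @param consensus `consensus_cpgs` from [intersect_models()].
#' @param manifest probe manifest covering the consensus probes.
#' @param min_cpgs minimum supporting promoter CpGs per gene (default 2).
#' @return named list of data.frames (gene, n_cpgs), one per category.
#' @export
build_gene_lists <- function(consensus, manifest, min_cpgs = 2L) {
  one <- function(members, wanted_sign) {
    ids <- members$probe_id[members$sign == wanted_sign]
    i <- match(ids, manifest$probe_id)
    if (anyNA(i))
      stop("manifest does not cover consensus probe(s): ",
           paste(head(ids[is.na(i)], 3L), collapse = ", "))
    keep <- manifest$gene_region[i] %in% PROMOTER_REGIONS &
      manifest$gene[i] != ""
    counts <- table(manifest$gene[i][keep])
    counts <- counts[counts >= min_cpgs]
    if (!length(counts))
      return(data.frame(gene = character(), n_cpgs = integer(),
                        stringsAsFactors = FALSE))
    df <- data.frame(gene = names(counts), n_cpgs = as.integer(counts),
                     stringsAsFactors = FALSE)
    df[order(df$gene), , drop = FALSE]
  }
  list(
    GA_pos = one(consensus$ga_related, 1),
    GA_neg = one(consensus$ga_related, -1),
    SD_pos = one(consensus$sd_related, 1),
    SD_neg = one(consensus$sd_related, -1)
  )
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided (upper tail) hypergeometric test per gene set: the probability
#' of observing at least the seen overlap between the query list and the
#' set, drawing |list| genes from the universe.  Sets are intersected with
#' the universe first; BH q-values across sets; rows flagged significant at
#' q <= `enrichment_fdr`.
#'
#' @param genes character vector of query genes (deduplicated, intersected
#'   with the universe).
#' @param collection named list of gene sets (e.g. [read_gmt()]).
#' @param universe background gene universe (default: union of collection;
#'   in the pipeline, all genes on post-filter manifest probes).
#' @param enrichment_fdr significance threshold on q (default 0.1).
#' @return data.frame: set, overlap, set_size, universe_size, list_size, p,
#'   q, significant.
#' @export
hypergeom_enrich <- function(genes, collection,
                             universe = unique(unlist(collection)),
                             enrichment_fdr = 0.1) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  genes <- intersect(unique(genes), universe)
  N <- length(universe); n <- length(genes)
  rows <- do.call(rbind, lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    s <- length(set)
    k <- length(intersect(genes, set))
    p <- phyper(k - 1L, s, N - s, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = s, universe_size = N,
               list_size = n, p = p, stringsAsFactors = FALSE)
  }))
  rows$q <- bh_adjust(rows$p)
  rows$significant <- rows$q <= enrichment_fdr
  rows[order(rows$p, rows$set), , drop = FALSE]
}
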