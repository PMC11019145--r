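# metabolite -> gene expansion and hypergeometric pathway over-representation

#' Validate a metabolite-to-gene mapping table
#'
#' @param mapping data.frame: metabolite_id, gene_id, mapping_score
#'   (non-negative, finite); (metabolite, gene) pairs unique.
#' @return the validated data.frame.
#' @export
mapping_table <- function(mapping) {
  need <- c("metabolite_id", "gene_id", "mapping_score")
  if (!all(need %in% names(mapping)))
    stop("mapping needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(mapping$mapping_score)) ||
      any(mapping$mapping_score < 0))
    stop("mapping scores must be finite and non-negative")
  if (anyDuplicated(mapping[, c("metabolite_id", "gene_id")]))
    stop("(metabolite, gene) pairs must be unique")
  mapping
}

#' Expand a metabolite set to genes via mapping scores
#'
#' For each metabolite, the `top_k` genes with the highest mapping score are
#' retained (records tied with the k-th score are all kept, to avoid
#' arbitrary exclusions among score-equal genes); the union over metabolites
#' is returned. Metabolites absent from the mapping are skipped.
#'
#' @param metabolites character vector of metabolite ids.
#' @param mapping a [mapping_table()]-valid data.frame.
#' @param top_k genes retained per metabolite (default 50).
#' @return sorted character vector of gene ids (possibly empty).
#' @export
expand_to_genes <- function(metabolites, mapping, top_k = 50L) {
  mapping <- mapping_table(mapping)
  if (!length(metabolites)) return(character(0))
  hits <- mapping[mapping$metabolite_id %in% metabolites, , drop = FALSE]
  if (!nrow(hits)) return(character(0))
  genes <- lapply(split(hits, hits$metabolite_id), function(d) {
    if (nrow(d) <= top_k) return(d$gene_id)
    s <- sort(d$mapping_score, decreasing = TRUE)
    d$gene_id[d$mapping_score >= s[top_k]]   # keep boundary ties
  })
  sort(unique(unlist(genes, use.names = FALSE)))
}

#' Background gene set from the full measured metabolite panel
#'
#' The same top-k expansion applied to every measured metabolite; enrichment
#' target sets are by construction subsets of this background.
#'
#' @param measured_metabolites all metabolite ids measured in the study.
#' @param mapping a [mapping_table()]-valid data.frame.
#' @param top_k genes retained per metabolite (default 50).
#' @return sorted character vector of background gene ids.
#' @export
build_background <- function(measured_metabolites, mapping, top_k = 50L) {
  if (!length(measured_metabolites)) stop("empty measured metabolite panel")
  bg <- expand_to_genes(measured_metabolites, mapping, top_k)
  if (!length(bg)) stop("background gene set is empty")
  bg
}

#' Hypergeometric pathway over-representation test
#'
#' Upper-tail hypergeometric probability of an overlap at least as large as
#' observed, with population = background genes, successes = pathway genes in
#' the background, draws = target genes; Benjamini-Hochberg adjustment across
#' pathways. Pathways are intersected with the background before testing.
#'
#' @param target_genes character vector (must lie within the background).
#' @param pathways data.frame: pathway_id, gene_id (optionally pathway_name).
#' @param background character vector of background gene ids.
#' @param fdr_level FDR threshold (default 0.05).
#' @return data.frame: pathway, overlap, target_size, pathway_size,
#'   background_size, p, q, significant (sorted by p).
#' @export
enrich_pathways <- function(target_genes, pathways, background,
                            fdr_level = 0.05) {
  if (!all(c("pathway_id", "gene_id") %in% names(pathways)))
    stop("pathways needs columns pathway_id, gene_id")
  background <- unique(background)
  target_genes <- unique(target_genes)
  outside <- setdiff(target_genes, background)
  if (length(outside))
    stop("target gene(s) outside background: ",
         paste(outside, collapse = ", "))
  pw <- pathways[pathways$gene_id %in% background, , drop = FALSE]
  sets <- split(unique(pw[, c("pathway_id", "gene_id")])$gene_id,
                unique(pw[, c("pathway_id", "gene_id")])$pathway_id)
  N <- length(background)
  n_draw <- length(target_genes)
  res <- data.frame(
    pathway = names(sets),
    overlap = vapply(sets, function(g)
      length(intersect(g, target_genes)), 0L),
    target_size = n_draw,
    pathway_size = lengths(sets),
    background_size = N,
    stringsAsFactors = FALSE)
  if (!n_draw) {
    res$p <- 1
    attr(res, "note") <- "empty target set; all p = 1"
  } else {
    res$p <- stats::phyper(res$overlap - 1L, res$pathway_size,
                           N - res$pathway_size, n_draw,
                           lower.tail = FALSE)
  }
  adj <- bh_adjust(res$p, fdr_level)
  res$q <- adj$q
  res$significant <- adj$significant
  if ("pathway_name" %in% names(pathways)) {
    nm <- unique(pathways[, c("pathway_id", "pathway_name")])
    res$pathway_name <- nm$pathway_name[match(res$pathway, nm$pathway_id)]
  }
  res <- res[order(res$p, -res$overlap, res$pathway), ]
  rownames(res) <- NULL
  res
}

#' Top enriched pathways per phenotype
#'
#' Selects, for each phenotype, the `n` smallest-p pathways (ties broken by
#' larger overlap, then pathway id). Phenotypes whose enrichment input had no
#' significant metabolites (empty target set) are omitted from the report.
#'
#' @param results_by_phenotype named list of [enrich_pathways()] results.
#' @param n pathways per phenotype (default 3).
#' @return data.frame: phenotype, pathway, rank, overlap, p, q (plus
#'   pathway_name when available).
#' @export
top_pathways <- function(results_by_phenotype, n = 3L) {
  keep <- Filter(function(r) is.null(attr(r, "note")) && nrow(r) > 0,
                 results_by_phenotype)
  if (!length(keep))
    return(data.frame(phenotype = character(0), pathway = character(0),
                      rank = integer(0), overlap = integer(0),
                      p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(names(keep), function(ph) {
    r <- keep[[ph]]
    r <- r[order(r$p, -r$overlap, r$pathway), , drop = FALSE]
    r <- utils::head(r, n)
    cols <- intersect(c("pathway", "overlap", "p", "q", "pathway_name"),
                      names(r))
    cbind(data.frame(phenotype = ph, stringsAsFactors = FALSE),
          r[, cols, drop = FALSE],
          data.frame(rank = seq_len(nrow(r))))
  }))
  rownames(out) <- NULL
  out
}
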