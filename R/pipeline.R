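#' Pipeline configuration
#'
#' Bundles the file paths and thresholds of a full run. Threshold defaults
#' are the study values: enrichment level 0.025 on the one-sided p, 10-RPKM
#' expression floor, FDR cutoff 0.01 for GO over-representation, nominal
#' p cutoff 0.05 for gene-set significance, 1000 permutations.
#'
#' @param counts Named character vector: tissue -> counts TSV path.
#' @param target_tissue The tissue whose enriched list drives the ontology
#'   stage.
#' @param homologs Homology-map TSV path.
#' @param annotations Annotation TSV path.
#' @param target_matrix Target-species expression matrix TSV path.
#' @param out_dir Output directory.
#' @param alpha,rpkm_min,fdr_cutoff,np_cutoff,n_perm,seed Thresholds and
#'   seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, target_tissue, homologs, annotations,
                            target_matrix, out_dir,
                            alpha = 0.025, rpkm_min = 10,
                            fdr_cutoff = 0.01, np_cutoff = 0.05,
                            n_perm = 1000, seed = 1) {
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("counts must be a named vector (tissue -> path)")
  if (!target_tissue %in% names(counts))
    stop("target_tissue '", target_tissue, "' has no counts table")
  for (th in c(alpha, rpkm_min, fdr_cutoff, np_cutoff, n_perm))
    if (th <= 0) stop("all thresholds must be positive")
  structure(list(counts = counts, target_tissue = target_tissue,
                 homologs = homologs, annotations = annotations,
                 target_matrix = target_matrix, out_dir = out_dir,
                 alpha = alpha, rpkm_min = rpkm_min,
                 fdr_cutoff = fdr_cutoff, np_cutoff = np_cutoff,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full cross-species comparison pipeline
#'
#' Stages, in order: quantify (RPKM per tissue), collapse (transcripts to
#' clusters, matrix assembly), enrich (tissue-enriched gene selection for
#' every tissue), project (homolog projection of the enriched lists),
#' ontology (term over-representation and energy distribution for the target
#' tissue's list), gsea (cross-species NES/FDR relatedness matrix). All
#' intermediate tables are written under `config$out_dir`; a manifest records
#' the seed, thresholds, input checksums and completed stages. Reruns with an
#' identical configuration produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stages_done <- character(0)
  tissues <- names(config$counts)

  # quantify + collapse: cluster-by-tissue RPKM matrix
  mat <- .stage("quantify", {
    cols <- lapply(tissues, function(tis) {
      q <- quantify_counts(read_counts_table(config$counts[[tis]]))
      write_tsv(q, file.path(out, paste0("quant_", tis, ".tsv")))
      collapse_to_clusters(q)
    })
    stages_done <- c(stages_done, "quantify")
    ids <- sort(unique(unlist(lapply(cols, `[[`, "cluster_id"))))
    m <- matrix(0, length(ids), length(tissues),
                dimnames = list(ids, tissues))
    for (j in seq_along(cols))
      m[cols[[j]]$cluster_id, j] <- cols[[j]]$rpkm
    m
  })
  .stage("collapse", {
    write_expression_matrix(mat, file.path(out, "expression_matrix.tsv"))
    stages_done <- c(stages_done, "collapse")
  })

  enriched <- .stage("enrich", {
    res <- lapply(stats::setNames(tissues, tissues), function(tis) {
      e <- select_enriched(mat, tis, alpha = config$alpha,
                           rpkm_min = config$rpkm_min)
      write_tsv(e, file.path(out, paste0("enriched_", tis, ".tsv")))
      e
    })
    stages_done <- c(stages_done, "enrich")
    res
  })

  projected <- .stage("project", {
    map <- parse_mapping_table(config$homologs, "homology")
    res <- lapply(enriched, function(e)
      project_to_species(e$cluster_id, map))
    write_gene_sets_gmt(res, file.path(out, "projected_sets.gmt"),
                        descriptions = paste0("enriched genes projected to ",
                                              attr(map, "species")))
    stages_done <- c(stages_done, "project")
    res
  })

  ontology <- .stage("ontology", {
    ann <- parse_mapping_table(config$annotations, "annotation")
    lst <- enriched[[config$target_tissue]]$cluster_id
    bg <- rownames(mat)
    te <- term_enrichment(lst, bg, ann, method = "hypergeometric")
    write_tsv(te, file.path(out, "term_enrichment.tsv"))
    slim <- classify_slim(lst, ann)
    write_tsv(slim, file.path(out, "slim_classification.tsv"))
    ed <- energy_distribution(mat[, config$target_tissue], ann)
    write_tsv(ed, file.path(out, "energy_distribution.tsv"))
    stages_done <- c(stages_done, "ontology")
    list(term_enrichment = te, slim = slim, energy = ed)
  })

  gsea <- .stage("gsea", {
    tm <- read_expression_matrix(config$target_matrix)
    nm <- cross_species_matrix(projected, tm, n_perm = config$n_perm,
                               seed = config$seed)
    for (piece in c("nes", "p", "fdr"))
      write_expression_matrix(nm[[piece]],
                              file.path(out, paste0("matrix_", piece,
                                                    ".tsv")))
    stages_done <- c(stages_done, "gsea")
    nm
  })

  manifest <- list(
    seed = config$seed,
    thresholds = list(alpha = config$alpha, rpkm_min = config$rpkm_min,
                      fdr_cutoff = config$fdr_cutoff,
                      np_cutoff = config$np_cutoff, n_perm = config$n_perm),
    target_tissue = config$target_tissue,
    input_checksums = as.list(tools::md5sum(
      c(unname(config$counts), config$homologs, config$annotations,
        config$target_matrix))),
    stages_completed = stages_done)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(matrix = mat, enriched = enriched, projected = projected,
                 ontology = ontology, relatedness = gsea,
                 manifest = manifest))
}
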